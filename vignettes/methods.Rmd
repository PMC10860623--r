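---
title: "Methods: simulating and estimating the heritability of beta-band phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and estimating the heritability of beta-band phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaherit)
```

# Overview

`betaherit` is a closed-loop testbed for sibling-based heritability studies
of spontaneous sensorimotor activity. It simulates families whose latent
genetic values drive the parameters of a two-channel signal generator,
parameterizes the resulting recordings exactly as an empirical study would
(spectral decomposition into aperiodic and periodic parts; transient
beta-event extraction), and estimates heritability with a variance-component
model plus permutation inference. Because the generating parameters are
known, every stage of the analysis can be validated against ground truth.

This vignette records the statistical model, the parameter choices and their
rationale, the generator's realism and limitations, and the numerical
conventions that matter for reproducing results.

# The genetic model

## Phenotype simulation

For subject $i$ in family $f$ with phenotypic variance $V_p$ and
heritability $h^2$:

$$ y_i = \mu + g_i + e_i, \qquad
   g_i = \sqrt{0.5}\, a_f + \sqrt{0.5}\, a_i, $$

where $a_f \sim N(0, h^2 V_p)$ is shared by all siblings of family $f$,
$a_i \sim N(0, h^2 V_p)$ is individual, and
$e_i \sim N(0, (1 - h^2) V_p)$. Full siblings therefore share exactly half
the additive genetic variance, giving
$\mathrm{cov}(y_i, y_j) = 0.5\, h^2 V_p$ for siblings and an expected
sibling correlation of $0.5\, h^2$ — a property used directly as an
acceptance check (`sib_pair_correlation`).

The default pedigree (`study_family_sizes()`) is 210 subjects in 100
families: 91 sib-pairs, 8 trios and one quad, matching the scale of a
realistic single-site cohort.

## Variance-component estimation

`fit_variance_components` maximizes the Gaussian likelihood of
$\Sigma_f = \sigma^2_g R_f + \sigma^2_e I$ per family, with $R_f$ having
unit diagonal and 0.5 off-diagonal. Because $R_f$ is compound-symmetric, the
per-family determinant and quadratic form have closed forms, and both the
mean $\mu$ and the total variance are profiled out analytically. What
remains is a one-dimensional profile likelihood in $h^2 \in [0, 1]$,
optimized by a coarse grid (step 0.05) followed by `stats::optimize`
refinement and explicit endpoint checks. A dense-matrix grid-search oracle
in the test suite confirms the profile fit to within $10^{-3}$ in $h^2$.

ML is the default; REML (`reml = TRUE`) is available and agrees with ML to
within 0.03 at large family counts. ML has a small downward bias at this
cohort size (about 0.03 at $h^2 = 0.87$), which is visible in, and
accounted for by, the recovery benchmarks.

## Permutation inference and multiplicity

`permutation_test` shuffles phenotype values against the fixed family
structure and counts permuted estimates $\hat h^2_\pi \ge \hat h^2_{obs}$,
with $p = k / n_{perm}$ and ties counted. Two consequences of this exceedance
rule with a boundary-constrained estimator:

* when $\hat h^2_{obs} = 0$, every permutation ties or exceeds it, so
  $k = n_{perm}$ and $p = 1$ exactly;
* under the null the p-value distribution is *sub-uniform* with a large atom
  at 1 (roughly half of null fits land on the $h^2 = 0$ boundary). The
  correct calibration property is therefore validity,
  $P(p \le x) \le x$, not uniformity; the test suite checks the one-sided
  Kolmogorov–Smirnov statistic $D^+$ rather than the two-sided statistic,
  which would reject any sub-uniform distribution by construction.

The battery (`run_heritability_battery`) Bonferroni-adjusts over 30 tests
(15 phenotypes × 2 hemispheres) by default; `bonferroni` caps adjusted
values at 1 and flags significance at $\alpha / n_{tests}$.

Before fitting, `prepare_phenotype` applies the nonnegativity convention of
pedigree variance-component tools: a pure sign flip when the phenotype
median is negative (heritability is invariant to affine maps), with a
rank-based inverse-normal option (Blom scores,
$\Phi^{-1}((r - 3/8)/(n + 1/4))$).

# The signal generator

## Construction

Each subject's recording is two channels, 180 s at 600 Hz by default:

* **Aperiodic background.** Frequency-domain synthesis: complex spectrum
  with $E|X_k|^2 = S(f_k)\, f_s\, n / 2$ where
  $S(f) = 10^{\text{offset}} f^{-\chi}$, Hermitian symmetry, zeroed DC.
  This gives an exact expected power law at every frequency bin; the default
  offset ($-23$) and exponent ($\chi = 1.05$) put the spectrum in a
  gradiometer-like amplitude range.
* **Beta bursts.** Poisson-timed onsets (default 1 burst/s) of
  Hanning-windowed sinusoids at the carrier frequency (default 19.3 Hz),
  with log-normal durations and amplitudes. Bursts are mixed into the two
  channels with weights $(\cos\theta, \sin\theta)$, $\theta = 45°$ by
  default, so the vector-sum combination recovers the full burst energy
  regardless of $\theta$.

Two calibration choices deserve explanation because they anchor the
generator to *detected* event statistics rather than to nominal waveform
parameters:

* **Amplitude reference.** Burst amplitude is specified as a signal-to-noise
  ratio (`burst_snr`, default 5) times the analytic RMS of the *two-channel
  vector-sum Morlet envelope* of the background,
  $\sqrt{16\sqrt{\pi}\, 10^{\text{offset}} f_0^{-\chi}}$. Referencing the
  background as the detector sees it (through the wavelet) rather than the
  broadband RMS makes `burst_snr` directly interpretable as envelope
  contrast.
* **Duration calibration.** The log-normal duration default (median 120 ms,
  `sdlog` 0.5) is chosen so that *detected* durations — after ~80 ms of
  wavelet/smoothing widening — have mean ≈250 ms and median ≈215 ms, and so
  that the occupancy identity of percentile thresholding
  (rate × mean duration ≈ 25%) holds at 1 burst/s. Longer nominal bursts
  produce merged detections and systematically undercounted rates.

## Realism and limitations

The generator reproduces the statistics the analysis chain consumes — power-
law spectra, a periodic beta peak, burst rate/duration/amplitude
distributions, Poisson-like waiting times — but it is deliberately minimal:

* stationary background (no drifts, no physiological artifacts, no line
  noise);
* a single oscillatory source with fixed carrier frequency per subject and
  fixed channel mixing; no alpha/mu rhythm, no 1/f knee;
* burst timing is exactly Poisson, so the waiting-time dispersion
  $C_V \to 1$; empirical recordings can be over- or under-dispersed;
* genetic effects enter only through the exponent and an amplitude scale;
  other phenotypes inherit heritability indirectly through these.

These simplifications are intentional: the package tests estimator
*recovery*, and a minimal generator makes the ground truth unambiguous.

# Spectral analysis

* **Welch PSD** (`welch_psd`): non-overlapping 1024-point Hamming segments,
  density normalization (divide by $f_s \sum w^2$), one-sided doubling
  except at DC and Nyquist. A 180 s recording at 600 Hz yields 105 segments
  and a 0.586 Hz grid.
* **Vector-sum spectrum** (`vector_sum_psd`):
  $\sqrt{P_1^2 + P_2^2}$ elementwise, the standard combination of a planar
  gradiometer pair.
* **Aperiodic fit** (`fit_aperiodic`): ordinary least squares of
  $\log_{10} P$ on $\log_{10} f$ over 2–48 Hz, followed by one refit that
  excludes bins with positive residuals beyond 2.5 residual SDs. The single
  robust pass removes narrow periodic peaks without iterating to
  convergence; it recovers noiseless power laws exactly (to $10^{-6}$) and
  keeps bias from a realistic beta bump below 0.05 in the exponent.
* **Periodic component** (`periodic_component`): linear residual of the fit;
  beta peak = argmax over 14–30 Hz; total beta power = trapezoidal area of
  the positive part of the residual (clipping applies to the area only).
* **Channel selection** (`select_peak_channel`): the pair with the largest
  in-band residual peak at rest, or (mode `"modulation"`) the pair with the
  strongest task suppression; exact ties resolve to the lowest index, and a
  no-peak flag is raised when no positive residual exists.

# Beta-event extraction

1. Resample to 200 Hz (zero-phase FIR anti-alias + decimation) and
   zero-phase FIR high-pass at 2 Hz.
2. Morlet envelope: wavelets with $n_{cycles} = f/2$ — a constant temporal
   SD of $1/(4\pi) \approx 80$ ms at every frequency — on a 7–47 Hz grid;
   the envelope is the mean magnitude over grid frequencies within the
   subject's peak ± 1.5 Hz, combined across channels as
   $\sqrt{e_1^2 + e_2^2}$.
3. Gaussian smoothing with 100 ms FWHM (reflected edges; mass-preserving).
4. Threshold at the 75th percentile of the smoothed envelope; maximal runs
   of *strictly* supra-threshold samples lasting ≥ 50 ms become events
   (half-open sample intervals; a constant envelope yields zero events).
5. Ten phenotypes: mean/median/SD/robust-max of duration (ms) and amplitude,
   event rate, and waiting-time dispersion
   $C_V = \sigma_{gap} / \mu_{gap}$ over offset-to-next-onset gaps.

Because the threshold is relative, supra-threshold occupancy is pinned near
25%, so the detector is calibrated to an operating point (≈1 event/s with
the default generator) rather than tracking arbitrary generated rates
proportionally — the same property holds for empirical percentile-threshold
burst analyses.

# Numerical conventions

These details change results at the margins and are fixed deliberately:

* **Quantiles**: R's default type-7 (linear interpolation) everywhere,
  including the event threshold.
* **Strict thresholding**: samples exactly at the threshold are *below* it.
* **Population SDs** (denominator $n$) for event duration/amplitude SD and
  the dispersion $C_V$, for internal consistency of the ratio; sample SD
  (denominator $n-1$) for Cohen's d, following convention.
* **Robust maximum**: mean of the top $\lceil 0.05\, n \rceil$ values, so it
  degrades gracefully to the plain maximum for small event counts.
* **Ties counted** in the permutation exceedance ($\ge$), making the test
  conservative rather than anti-conservative at the $h^2 = 0$ boundary.
* **Seed streams**: `derive_seed(root, index)` produces independent
  substreams below $2^{31}$, so every subject, permutation battery and
  benchmark replicate is reproducible from one root seed.
* **No stored signals**: recordings are regenerated from per-subject
  configurations on demand, which keeps pipeline outputs small and makes
  reruns bit-identical (the pipeline manifest records MD5 checksums).

# Problem sizes used

* Default cohort: 210 subjects / 100 families; recovery benchmarks average
  200 simulated cohorts.
* Recordings: 180 s at 600 Hz (105 Welch segments); the demonstration
  workflow under `analysis/` uses 20 families / 45 subjects and 60 s
  recordings to finish in about half a minute.
* Permutations: 6000 per phenotype at full scale (p-value resolution
  $1.7 \times 10^{-4}$); 500 in the demonstration workflow and null-
  calibration tests.
* Sibling-correlation check: 5000 two-sib families, where the Monte Carlo
  standard error of the correlation is ≈0.014.
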