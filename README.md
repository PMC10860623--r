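# betaherit

Simulation and estimation toolkit for the heritability of sensorimotor
beta-band phenotypes in sibling cohorts.

## The scientific problem

Spontaneous cortical activity recorded over sensorimotor cortex is dominated
by two kinds of structure: an aperiodic 1/f background, summarized by the
offset and exponent of a power law fitted to the spectrum, and transient
beta-band (14–30 Hz) events ("bursts") — brief, high-amplitude excursions of
the beta envelope lasting a few hundred milliseconds. Both families of
phenotypes are candidate endophenotypes: if they are strongly heritable,
they index stable, genetically constrained properties of cortical circuits
rather than momentary state.

`betaherit` implements the full in-silico version of such a study:

1. **Cohort simulation** (`make_pedigree`, `simulate_phenotype`,
   `simulate_cohort`): sibling families with an additive genetic model —
   siblings share half their additive genetic variance — whose latent traits
   drive the parameters of a signal generator.
2. **Signal generation** (`signal_gen_config`, `simulate_sensor_pair`):
   two-channel (planar-gradiometer-like) recordings, 180 s at 600 Hz by
   default, combining 1/f background noise with Poisson-timed beta bursts
   (Hanning-windowed sinusoids near 19.3 Hz with log-normal amplitudes and
   durations).
3. **Spectral parameterization** (`welch_psd`, `vector_sum_psd`,
   `fit_aperiodic`, `periodic_component`, `select_peak_channel`): Welch
   spectra of each channel combined as a vector sum, a robust log-log fit of
   the aperiodic component over 2–48 Hz, and the periodic beta residual
   (peak frequency, peak power, band power).
4. **Beta-event extraction** (`beta_envelope`, `smooth_envelope`,
   `detect_events`, `event_statistics`): Morlet amplitude envelope at the
   subject's own peak beta frequency, Gaussian smoothing (100 ms FWHM),
   75th-percentile thresholding with a 50 ms minimum duration, and ten
   summary phenotypes (duration and amplitude statistics, rate, waiting-time
   dispersion).
5. **Heritability estimation** (`fit_variance_components`,
   `permutation_test`, `run_heritability_battery`): maximum-likelihood
   variance-component fits of sibling heritability, permutation tests
   against shuffled family assignment, Bonferroni adjustment over the
   30-phenotype battery (15 phenotypes × 2 hemispheres), and Cohen's d.

## Worked example

Simulate one subject's recording, parameterize it, and estimate heritability
on a simulated cohort:

```r
library(betaherit)

# one subject: two-channel recording, 180 s at 600 Hz
cfg  <- signal_gen_config(noise_seed = 42)
pair <- simulate_sensor_pair(cfg)

sp <- spectral_phenotypes(pair)
sprintf("peak %.2f Hz | exponent %.3f | offset %.2f",
        sp$peak_beta_frequency, sp$aperiodic_exponent, sp$aperiodic_offset)
#> "peak 19.34 Hz | exponent 1.058 | offset -22.76"

ep <- event_phenotypes(pair, sp$peak_beta_frequency)
sprintf("rate %.2f /s | mean duration %.0f ms | dispersion %.2f | n = %d",
        ep$event_rate, ep$duration_mean, ep$dispersion, ep$n_events)
#> "rate 1.01 /s | mean duration 246 ms | dispersion 0.92 | n = 182"

# a 210-subject / 100-family cohort with a strongly heritable phenotype
ped <- make_pedigree()
y   <- simulate_phenotype(ped, h2 = 0.87, seed = 7)
fit_variance_components(y, ped)
#> Variance-component fit (ML): h2 = 0.861 (sigma2_g = 0.9461, sigma2_e = 0.1529)
#>   n = 210 subjects in 100 families, loglik = -296.116

pt <- permutation_test(y, ped, n_perm = 1000L, seed = 8)
sprintf("permutation: k = %d of %d, p = %.3f", pt$k, pt$n_perm, pt$p)
#> "permutation: k = 0 of 1000, p = 0.000"
```

The generated values are recovered by the analysis chain: the fitted
aperiodic exponent (1.058) tracks the configured 1.05, the detected event
rate (1.01/s) tracks the configured 1 burst/s, and the variance-component
estimate (0.861) tracks the generating heritability (0.87).

## The end-to-end workflow

The numbered scripts under `analysis/` run the whole study on a scaled-down
demonstration cohort (20 families / 45 subjects, 60 s recordings, 500
permutations; about half a minute total):

```sh
Rscript analysis/01_simulate_cohort.R      # pedigree + ground-truth parameters
Rscript analysis/02_spectral_phenotypes.R  # Welch / vector-sum / aperiodic fit
Rscript analysis/03_beta_events.R          # envelope, thresholding, event stats
Rscript analysis/04_heritability.R         # 30-phenotype battery
```

Each stage writes TSV tables under `results/analysis/`; signals are
regenerated deterministically from per-subject seeds rather than stored. A
representative run prints, per stage, fitted exponents matching the
generated means to ~0.001 (e.g. `1.024` fitted vs `1.025` generated), event
rates near 1/s, and a battery in which the strongly heritable right-
hemisphere aperiodic exponent tops the ranking (`h2 = 1.00, p = 0.0040`) —
while nothing survives Bonferroni over 30 tests at this small demonstration
size, which is the expected behavior.

The same pipeline at full study scale is one call:

```r
res <- run_pipeline(pipeline_config(out_dir = "results/full"))
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the statistical
model, the generator and its limitations, and every numerical convention
(quantile type, strict thresholding, population SDs, tie handling in the
permutation test, ML vs REML).
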