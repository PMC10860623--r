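#' Welch power spectral density
#'
#' Mean of per-segment Hamming-windowed periodograms over non-overlapping
#' segments of `nfft` samples (trailing partial segment dropped), with density
#' normalization: units are (signal unit)^2 / Hz, one-sided.
#'
#' @param x Numeric signal.
#' @param sampling_rate Sampling rate in Hz.
#' @param nfft Segment / FFT length in samples (default 1024).
#' @return A `power_spectrum`: list with `freqs` (Hz, `0 .. fs/2`), `power`
#'   and `n_segments`.
#' @examples
#' fs <- 600
#' x <- sin(2 * pi * 75 * (0:(fs * 10 - 1)) / fs)
#' psd <- welch_psd(x, fs)
#' @export
welch_psd <- function(x, sampling_rate, nfft = 1024L) {
  nfft <- as.integer(nfft)
  if (length(x) < nfft) stop("signal shorter than one segment ('nfft' samples)")
  n_seg <- length(x) %/% nfft
  w <- signal::hamming(nfft)
  scale <- sampling_rate * sum(w^2)
  half <- nfft %/% 2L
  acc <- numeric(half + 1L)
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1L) * nfft + 1L):(s * nfft)]
    X <- stats::fft(w * seg)
    p <- Mod(X[1:(half + 1L)])^2 / scale
    p[2:half] <- 2 * p[2:half]  # one-sided fold (DC and Nyquist excluded)
    acc <- acc + p
  }
  new_power_spectrum(freqs = (0:half) * sampling_rate / nfft,
                     power = acc / n_seg, n_segments = n_seg)
}

#' Construct a power spectrum object
#'
#' @param freqs Strictly increasing frequencies in Hz.
#' @param power Nonnegative spectral density, same length as `freqs`.
#' @param n_segments Number of averaged segments (metadata).
#' @return A `power_spectrum`.
#' @export
power_spectrum <- function(freqs, power, n_segments = 1L) {
  stopifnot(length(freqs) == length(power), !is.unsorted(freqs, strictly = TRUE),
            all(power >= 0))
  structure(list(freqs = freqs, power = power, n_segments = n_segments),
            class = "power_spectrum")
}

new_power_spectrum <- power_spectrum

#' Vector-sum PSD of a gradiometer pair
#'
#' Combines the spectra of two orthogonal planar gradiometers at one sensor
#' site as `sqrt(PSD_ch1^2 + PSD_ch2^2)` per frequency bin.
#'
#' @param psd_a,psd_b `power_spectrum` objects on identical frequency grids.
#' @return A `power_spectrum`.
#' @export
vector_sum_psd <- function(psd_a, psd_b) {
  stopifnot(inherits(psd_a, "power_spectrum"), inherits(psd_b, "power_spectrum"))
  if (length(psd_a$freqs) != length(psd_b$freqs) ||
      !isTRUE(all.equal(psd_a$freqs, psd_b$freqs))) {
    stop("frequency grids of the two spectra do not match")
  }
  new_power_spectrum(psd_a$freqs, sqrt(psd_a$power^2 + psd_b$power^2),
                     min(psd_a$n_segments, psd_b$n_segments))
}

#' Robust aperiodic (1/f) fit of a power spectrum
#'
#' Fits `log10 P(f) = offset - exponent * log10 f` over `fit_range`: an
#' initial least-squares fit, then one refit excluding bins whose positive
#' residual exceeds `outlier_sd` times the residual SD. The exclusion
#' suppresses contamination by narrow-band oscillatory peaks, which only ever
#' add power above the aperiodic floor ("fixed" aperiodic mode, no knee).
#'
#' @param psd A `power_spectrum`.
#' @param fit_range Length-2 numeric, fit band in Hz (default `c(2, 48)`).
#' @param outlier_sd Positive-residual exclusion threshold in residual SDs.
#' @return An `aperiodic_fit`: list with `offset` (log10 power), `exponent`
#'   (chi), `fit_range`, `fit_error` (RMSE in log10 space over retained bins)
#'   and `n_excluded`.
#' @export
fit_aperiodic <- function(psd, fit_range = c(2, 48), outlier_sd = 2.5) {
  stopifnot(inherits(psd, "power_spectrum"), length(fit_range) == 2L)
  sel <- psd$freqs >= fit_range[1] & psd$freqs <= fit_range[2]
  if (sum(sel) < 10L) stop("fewer than 10 frequency bins in 'fit_range'")
  p <- psd$power[sel]
  if (any(p <= 0)) stop("non-positive power within 'fit_range'")
  lf <- log10(psd$freqs[sel])
  lp <- log10(p)
  co <- stats::coef(stats::lm.fit(cbind(1, lf), lp))
  resid <- lp - (co[1] + co[2] * lf)
  keep <- resid <= outlier_sd * stats::sd(resid)
  if (sum(keep) >= 10L && any(!keep)) {
    co <- stats::coef(stats::lm.fit(cbind(1, lf[keep]), lp[keep]))
  } else {
    keep <- rep(TRUE, length(lp))
  }
  resid2 <- lp[keep] - (co[1] + co[2] * lf[keep])
  structure(list(offset = unname(co[1]), exponent = unname(-co[2]),
                 fit_range = fit_range,
                 fit_error = sqrt(mean(resid2^2)),
                 n_excluded = sum(!keep)),
            class = "aperiodic_fit")
}

#' Evaluate an aperiodic fit on a frequency grid
#'
#' @param fit An `aperiodic_fit`.
#' @param freqs Frequencies in Hz (`> 0`).
#' @return Linear-unit power `10^offset * f^(-exponent)`.
#' @export
predict_aperiodic <- function(fit, freqs) {
  stopifnot(inherits(fit, "aperiodic_fit"), all(freqs > 0))
  10^fit$offset * freqs^(-fit$exponent)
}

#' Periodic (oscillatory) residual and beta-band phenotypes
#'
#' Subtracts the fitted aperiodic component from the spectrum in linear units
#' and summarizes the beta band: the peak is the residual argmax within
#' `band` (reported only when some in-band residual is positive), and the
#' total beta power is the trapezoidal area under the residual clipped at
#' zero — clipping applies to the AUC only, not to peak finding, since band
#' power is nonnegative by definition.
#'
#' @param psd A `power_spectrum`.
#' @param fit The `aperiodic_fit` obtained from the same spectrum.
#' @param band Length-2 numeric, beta band in Hz (default `c(14, 30)`).
#' @return A `periodic_profile`: list with `freqs`, `residual` (full grid,
#'   signed, linear units), `band`, `beta_peak_freq`, `beta_peak_power`,
#'   `total_beta_power` and `has_peak`.
#' @export
periodic_component <- function(psd, fit, band = c(14, 30)) {
  stopifnot(inherits(psd, "power_spectrum"), inherits(fit, "aperiodic_fit"))
  pos <- psd$freqs > 0
  residual <- rep(NA_real_, length(psd$freqs))
  residual[pos] <- psd$power[pos] - predict_aperiodic(fit, psd$freqs[pos])
  in_band <- pos & psd$freqs >= band[1] & psd$freqs <= band[2]
  rb <- residual[in_band]
  fb <- psd$freqs[in_band]
  has_peak <- length(rb) > 0 && any(rb > 0)
  if (has_peak) {
    i <- which.max(rb)
    peak_f <- fb[i]
    peak_p <- rb[i]
  } else {
    peak_f <- NA_real_
    peak_p <- NA_real_
  }
  auc <- if (length(rb) >= 2L) pracma::trapz(fb, pmax(rb, 0)) else 0
  structure(list(freqs = psd$freqs, residual = residual, band = band,
                 beta_peak_freq = peak_f, beta_peak_power = peak_p,
                 total_beta_power = auc, has_peak = has_peak),
            class = "periodic_profile")
}

#' Select the peak channel pair from a region of interest
#'
#' Given the periodic profiles of the ROI channel pairs, selects either the
#' pair with the largest beta peak (`mode = "rest-peak"`) or, when a matching
#' list of task-condition profiles is supplied, the pair whose in-band
#' residual is most suppressed by the task (`mode = "modulation"`, an
#' automated counterpart of manual movement-modulation selection). Ties are
#' broken deterministically towards the lowest pair index.
#'
#' @param roi_profiles List of `periodic_profile` objects (resting state).
#' @param mode `"rest-peak"` or `"modulation"`.
#' @param mot_profiles List of task-condition profiles, required for
#'   `mode = "modulation"`; same length and grids as `roi_profiles`.
#' @return A `channel_selection`: list with `selected_pair_index`,
#'   `peak_beta_frequency`, `selection_mode`, `no_peak`.
#' @export
select_peak_channel <- function(roi_profiles,
                                mode = c("rest-peak", "modulation"),
                                mot_profiles = NULL) {
  mode <- match.arg(mode)
  if (length(roi_profiles) < 1L) stop("empty ROI: no channel-pair profiles")
  if (mode == "rest-peak") {
    scores <- vapply(roi_profiles, function(p) {
      if (isTRUE(p$has_peak)) p$beta_peak_power else -Inf
    }, numeric(1))
  } else {
    if (is.null(mot_profiles) || length(mot_profiles) != length(roi_profiles)) {
      stop("'mot_profiles' must match 'roi_profiles' for modulation mode")
    }
    scores <- vapply(seq_along(roi_profiles), function(i) {
      r <- roi_profiles[[i]]
      m <- mot_profiles[[i]]
      in_band <- r$freqs >= r$band[1] & r$freqs <= r$band[2]
      d <- r$residual[in_band] - m$residual[in_band]
      if (all(is.na(d))) -Inf else max(d, na.rm = TRUE)
    }, numeric(1))
  }
  if (all(!is.finite(scores))) {
    return(structure(list(selected_pair_index = NA_integer_,
                          peak_beta_frequency = NA_real_,
                          selection_mode = mode, no_peak = TRUE),
                     class = "channel_selection"))
  }
  idx <- which.max(scores)  # first maximum = lowest index on ties
  structure(list(selected_pair_index = idx,
                 peak_beta_frequency = roi_profiles[[idx]]$beta_peak_freq,
                 selection_mode = mode, no_peak = FALSE),
            class = "channel_selection")
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-window FIR design applied forwards and backwards. Mirrors the
#' broadband 2-48 Hz conditioning used on real recordings; synthetic signals
#' are already band-limited so the pipeline leaves it off by default.
#'
#' @param x Numeric signal.
#' @param sampling_rate Sampling rate in Hz.
#' @param band Length-2 numeric, pass band in Hz.
#' @param order FIR order (even).
#' @return Filtered signal, same length.
#' @export
bandpass_fir <- function(x, sampling_rate, band = c(2, 48), order = 660L) {
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1],
            band[2] < sampling_rate / 2)
  b <- signal::fir1(order, band / (sampling_rate / 2), type = "pass")
  signal::filtfilt(b, x)
}

#' Spectral phenotypes of one sensor pair
#'
#' Welch PSD per channel, vector-sum combination, aperiodic fit and periodic
#' beta summary, returned as the five spectral phenotype values.
#'
#' @param pair A `sensor_pair` (or any list with `ch1`, `ch2`,
#'   `sampling_rate`).
#' @param fit_range Aperiodic fit band in Hz.
#' @param band Beta band in Hz.
#' @param nfft Welch segment length.
#' @return Named list: `peak_beta_frequency`, `peak_beta_power`,
#'   `total_beta_power`, `aperiodic_exponent`, `aperiodic_offset`, plus the
#'   underlying `psd`, `fit` and `profile` objects.
#' @export
spectral_phenotypes <- function(pair, fit_range = c(2, 48), band = c(14, 30),
                                nfft = 1024L) {
  psd1 <- welch_psd(pair$ch1, pair$sampling_rate, nfft)
  psd2 <- welch_psd(pair$ch2, pair$sampling_rate, nfft)
  psd <- vector_sum_psd(psd1, psd2)
  fit <- fit_aperiodic(psd, fit_range)
  prof <- periodic_component(psd, fit, band)
  list(peak_beta_frequency = prof$beta_peak_freq,
       peak_beta_power = prof$beta_peak_power,
       total_beta_power = prof$total_beta_power,
       aperiodic_exponent = fit$exponent,
       aperiodic_offset = fit$offset,
       psd = psd, fit = fit, profile = prof)
}
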