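#' Complex Morlet wavelet
#'
#' Gaussian-windowed complex exponential with `sigma_t = n_cycles /
#' (2 * pi * freq)`, truncated at five standard deviations, normalized so a
#' unit-amplitude real sinusoid at the centre frequency yields an envelope
#' magnitude of one.
#'
#' @param freq Centre frequency in Hz.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_cycles Number of cycles; the study rule is `freq / 2`, which makes
#'   the temporal width identical (`1 / (4 * pi)` s, ~80 ms) at every
#'   frequency.
#' @return Complex vector (odd length, centred).
#' @keywords internal
morlet_wavelet <- function(freq, sampling_rate, n_cycles = freq / 2) {
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(5 * sigma_t * sampling_rate)
  t <- (-half:half) / sampling_rate
  g <- exp(-t^2 / (2 * sigma_t^2))
  w <- g * exp(2i * pi * freq * t)
  2 * w / sum(g)  # amplitude-preserving: |conv(sin(2*pi*f*t))| ~ 1
}

convolve_same <- function(x, h) {
  # centred FFT convolution, output aligned with x
  n <- length(x)
  m <- length(h)
  nf <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, rep(0, nf - n)))
  H <- stats::fft(c(h, rep(0, nf - m)))
  full <- stats::fft(X * H, inverse = TRUE) / nf
  full[((m - 1L) %/% 2L) + seq_len(n)]
}

#' Anti-aliased downsampling to a target rate
#'
#' Zero-phase FIR low-pass (Hamming design, cutoff at 80% of the target
#' Nyquist) followed by decimation. The source rate must be an integer
#' multiple of the target.
#'
#' @param x Numeric signal.
#' @param sampling_rate Source rate in Hz.
#' @param target_rate Target rate in Hz (default 200).
#' @return Downsampled signal.
#' @export
resample_signal <- function(x, sampling_rate, target_rate = 200) {
  if (sampling_rate == target_rate) return(x)
  if (sampling_rate %% target_rate != 0) {
    stop("'sampling_rate' must be an integer multiple of 'target_rate'")
  }
  dec <- sampling_rate %/% target_rate
  b <- signal::fir1(64, 0.8 / dec)
  y <- signal::filtfilt(b, x)
  y[seq(1L, length(y), by = dec)]
}

#' Zero-phase FIR high-pass filter
#'
#' @param x Numeric signal.
#' @param sampling_rate Sampling rate in Hz.
#' @param cutoff Cutoff in Hz (default 2).
#' @param order FIR order (even; default 330 gives a ~2 Hz transition band at
#'   200 Hz).
#' @return Filtered signal, same length.
#' @export
highpass_fir <- function(x, sampling_rate, cutoff = 2, order = 330L) {
  b <- signal::fir1(order, cutoff / (sampling_rate / 2), type = "high")
  signal::filtfilt(b, x)
}

#' Beta-band amplitude envelope of a sensor pair
#'
#' Per channel: anti-aliased downsampling to `resample_rate`, zero-phase 2 Hz
#' high-pass, complex Morlet decomposition on the 1 Hz grid (`wavelet_grid`,
#' `n_cycles = f/2`), and averaging of the wavelet magnitudes over the grid
#' frequencies within `peak_freq +/- band_halfwidth`. The two channel
#' envelopes are combined as `sqrt(e1^2 + e2^2)` (nonnegative by
#' construction).
#'
#' @param pair A `sensor_pair` (or list with `ch1`, `ch2`, `sampling_rate`).
#' @param peak_freq Individual peak beta frequency in Hz; the averaged band
#'   `peak_freq +/- band_halfwidth` must lie within the wavelet grid.
#' @param resample_rate Envelope rate in Hz (default 200).
#' @param highpass High-pass cutoff in Hz (default 2).
#' @param band_halfwidth Averaging half-width in Hz (default 1.5).
#' @param wavelet_grid Wavelet centre frequencies in Hz (default `7:47`).
#' @return List with `env` (numeric envelope), `rate` (Hz) and `freqs_used`.
#' @export
beta_envelope <- function(pair, peak_freq, resample_rate = 200, highpass = 2,
                          band_halfwidth = 1.5, wavelet_grid = 7:47) {
  lo <- peak_freq - band_halfwidth
  hi <- peak_freq + band_halfwidth
  if (lo < min(wavelet_grid) || hi > max(wavelet_grid)) {
    stop("peak frequency +/- halfwidth falls outside the wavelet grid")
  }
  freqs <- wavelet_grid[wavelet_grid >= lo & wavelet_grid <= hi]
  env_ch <- lapply(list(pair$ch1, pair$ch2), function(x) {
    y <- resample_signal(x, pair$sampling_rate, resample_rate)
    y <- highpass_fir(y, resample_rate, highpass)
    mags <- vapply(freqs, function(f) {
      Mod(convolve_same(y, morlet_wavelet(f, resample_rate)))
    }, numeric(length(y)))
    rowMeans(mags)
  })
  list(env = sqrt(env_ch[[1]]^2 + env_ch[[2]]^2), rate = resample_rate,
       freqs_used = freqs)
}

#' Gaussian smoothing of an amplitude envelope
#'
#' Convolution with a normalized Gaussian kernel of the given full width at
#' half maximum (`sigma = fwhm / (2 * sqrt(2 * log(2)))`), using reflected
#' edges; preserves length and nonnegativity.
#'
#' @param env Numeric envelope.
#' @param rate Envelope sampling rate in Hz.
#' @param fwhm Kernel FWHM in seconds (default 0.1).
#' @return Smoothed envelope.
#' @export
smooth_envelope <- function(env, rate, fwhm = 0.1) {
  if (fwhm <= 0) stop("'fwhm' must be > 0")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma * rate))
  k <- stats::dnorm((-half:half) / rate, sd = sigma)
  k <- k / sum(k)
  n <- length(env)
  pad <- c(rev(env[seq_len(min(half, n))]), env,
           rev(env[(n - min(half, n) + 1L):n]))
  sm <- convolve_same(pad, k)
  Re(sm[min(half, n) + seq_len(n)])
}

#' Detect beta events by percentile thresholding
#'
#' Thresholds the (smoothed) envelope at its `percentile`-th percentile
#' (linear-interpolation quantile). Maximal runs of samples strictly above the
#' threshold lasting at least `min_duration` become events; runs touching the
#' recording edges are kept. A constant envelope yields zero events (nothing
#' exceeds its own percentile).
#'
#' @param env Nonnegative numeric envelope (already smoothed).
#' @param rate Envelope sampling rate in Hz.
#' @param percentile Threshold percentile in (0, 100); default 75.
#' @param min_duration Minimum event duration in seconds; default 0.05.
#' @param amplitude Event amplitude definition: within-event envelope
#'   `"peak"` (default) or `"mean"`.
#' @return Data frame of events: `onset` and `offset` in seconds (half-open
#'   sample intervals), `duration` in ms, `amplitude` in envelope units;
#'   attribute `"threshold"` carries the threshold used.
#' @export
detect_events <- function(env, rate, percentile = 75, min_duration = 0.05,
                          amplitude = c("peak", "mean")) {
  amplitude <- match.arg(amplitude)
  if (percentile <= 0 || percentile >= 100) stop("'percentile' must be in (0, 100)")
  if (min_duration <= 0) stop("'min_duration' must be > 0")
  thr <- unname(stats::quantile(env, percentile / 100))
  r <- rle(env > thr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_samp <- round(min_duration * rate)
  keep <- r$values & r$lengths >= min_samp
  starts <- starts[keep]
  ends <- ends[keep]
  amp <- vapply(seq_along(starts), function(i) {
    seg <- env[starts[i]:ends[i]]
    if (amplitude == "peak") max(seg) else mean(seg)
  }, numeric(1))
  ev <- data.frame(onset = (starts - 1L) / rate,
                   offset = ends / rate,
                   duration = (ends - starts + 1L) / rate * 1000,
                   amplitude = amp)
  attr(ev, "threshold") <- thr
  ev
}

#' Robust maximum: mean of the top 5% of a sample
#'
#' @param x Numeric vector.
#' @param top Top fraction (default 0.05); the mean of the largest
#'   `ceiling(top * length(x))` values is returned.
#' @return Robust maximum.
#' @export
robust_max <- function(x, top = 0.05) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  k <- ceiling(top * n)
  mean(sort(x, decreasing = TRUE)[seq_len(k)])
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Summary phenotypes of a beta-event train
#'
#' Computes the ten event phenotypes: mean, median, SD and robust maximum
#' (mean of the top 5%) of event duration (ms) and amplitude, the event rate
#' (events/s), and the waiting-time dispersion `C_V = sigma / mu`, where the
#' waiting times are the gaps from one event's offset to the next event's
#' onset. SDs are population SDs for internal consistency with `C_V`.
#'
#' With no events all statistics are missing except `event_rate = 0`; with a
#' single event `C_V` is missing (no waiting times).
#'
#' @param events Event data frame from [detect_events()].
#' @param recording_duration Recording length in seconds (`> 0`).
#' @return Named list of 10 phenotypes plus `n_events`.
#' @export
event_statistics <- function(events, recording_duration) {
  if (recording_duration <= 0) stop("'recording_duration' must be > 0")
  n <- nrow(events)
  out <- list(duration_mean = NA_real_, duration_median = NA_real_,
              duration_sd = NA_real_, duration_robust_max = NA_real_,
              amplitude_mean = NA_real_, amplitude_median = NA_real_,
              amplitude_sd = NA_real_, amplitude_robust_max = NA_real_,
              event_rate = n / recording_duration, dispersion = NA_real_,
              n_events = n)
  if (n == 0L) return(out)
  d <- events$duration
  a <- events$amplitude
  out$duration_mean <- mean(d)
  out$duration_median <- stats::median(d)
  out$duration_sd <- pop_sd(d)
  out$duration_robust_max <- robust_max(d)
  out$amplitude_mean <- mean(a)
  out$amplitude_median <- stats::median(a)
  out$amplitude_sd <- pop_sd(a)
  out$amplitude_robust_max <- robust_max(a)
  if (n >= 2L) {
    gaps <- events$onset[-1L] - events$offset[-n]
    out$dispersion <- pop_sd(gaps) / mean(gaps)
  }
  out
}

#' Event phenotypes of one sensor pair
#'
#' Full event-extraction chain: Morlet envelope at the subject's peak beta
#' frequency, Gaussian smoothing, percentile thresholding, minimum-duration
#' filtering and summary statistics.
#'
#' @param pair A `sensor_pair`.
#' @param peak_freq Peak beta frequency in Hz.
#' @param percentile Threshold percentile (default 75).
#' @param min_duration Minimum event duration in s (default 0.05).
#' @param fwhm Smoothing kernel FWHM in s (default 0.1).
#' @param resample_rate Envelope rate in Hz (default 200).
#' @return List with the 10 phenotypes (`event_statistics()` output) plus the
#'   `events` table.
#' @export
event_phenotypes <- function(pair, peak_freq, percentile = 75,
                             min_duration = 0.05, fwhm = 0.1,
                             resample_rate = 200) {
  be <- beta_envelope(pair, peak_freq, resample_rate = resample_rate)
  sm <- smooth_envelope(be$env, be$rate, fwhm)
  ev <- detect_events(sm, be$rate, percentile, min_duration)
  stats <- event_statistics(ev, length(sm) / be$rate)
  c(stats, list(events = ev))
}
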