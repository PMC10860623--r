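# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Brute-force variance-component ML: dense kinship matrix, base-R solve() and
# determinant(), GLS intercept, nested grid refinement over (sigma2_g,
# sigma2_e) down to a resolution well below 1e-3 in h2.
oracle_h2_grid <- function(y, fam) {
  fam <- as.factor(fam)
  n <- length(y)
  R <- 0.5 * outer(as.integer(fam), as.integer(fam), "==")
  diag(R) <- 1
  I <- diag(n)
  ll <- function(sg, se) {
    S <- sg * R + se * I + 1e-14 * I
    ci <- solve(S)
    mu <- sum(ci %*% y) / sum(ci)
    r <- y - mu
    -0.5 * (as.numeric(determinant(S)$modulus) + drop(t(r) %*% ci %*% r))
  }
  lim <- 2.5 * stats::var(y)
  g1 <- seq(0, lim, length.out = 51)
  g2 <- g1
  b1 <- b2 <- NA_real_
  for (pass in 1:5) {
    vals <- outer(g1, g2, Vectorize(ll))
    i <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    b1 <- g1[i[1]]
    b2 <- g2[i[2]]
    s1 <- g1[2] - g1[1]
    s2 <- g2[2] - g2[1]
    g1 <- seq(max(0, b1 - s1), b1 + s1, length.out = 21)
    g2 <- seq(max(0, b2 - s2), b2 + s2, length.out = 21)
  }
  b1 / (b1 + b2)
}

# Plain least-squares log-log slope of a PSD over a frequency range.
oracle_loglog_slope <- function(psd, range = c(4, 40)) {
  sel <- psd$freqs >= range[1] & psd$freqs <= range[2]
  unname(stats::coef(stats::lm(log10(psd$power[sel]) ~ log10(psd$freqs[sel])))[2])
}

# Analytic power-law spectrum on a Welch-like grid.
power_law_psd <- function(offset, exponent, fs = 600, nfft = 1024) {
  f <- (1:(nfft / 2)) * fs / nfft
  power_spectrum(f, 10^offset * f^(-exponent))
}

# Synthetic periodic profile with a single Gaussian bump, for channel
# selection tests.
bump_profile <- function(peak_power, peak_freq = 20, width = 1.5,
                         band = c(14, 30)) {
  f <- seq(2, 48, by = 0.5)
  resid <- peak_power * exp(-(f - peak_freq)^2 / (2 * width^2))
  in_band <- f >= band[1] & f <= band[2]
  structure(list(freqs = f, residual = resid, band = band,
                 beta_peak_freq = f[in_band][which.max(resid[in_band])],
                 beta_peak_power = max(resid[in_band]),
                 total_beta_power = pracma::trapz(f[in_band],
                                                  pmax(resid[in_band], 0)),
                 has_peak = peak_power > 0),
            class = "periodic_profile")
}
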