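#' Prepare a phenotype for variance-component analysis
#'
#' Applies the nonnegativity convention of pedigree variance-component tools:
#' when the median of the phenotype is negative all values are multiplied by
#' -1 (a pure sign flip, which leaves heritability unchanged). A phenotype
#' with both signs and a median at exactly zero is min-shifted to nonnegative
#' with a warning. A rank-based inverse-normal transform (Blom scores,
#' `qnorm((rank - 3/8) / (n + 1/4))`) is available as a separate mode.
#'
#' @param values Numeric phenotype vector (missing values allowed, kept in
#'   place); at least 4 non-missing values required.
#' @param inverse_normal Apply the rank-based inverse-normal transform after
#'   the sign convention (default `FALSE`).
#' @return List with `values` (transformed, same names/length) and
#'   `transform` (`"none"`, `"sign_flip"`, `"min_shift"` or
#'   `"inverse_normal"`, possibly several).
#' @export
prepare_phenotype <- function(values, inverse_normal = FALSE) {
  ok <- !is.na(values)
  if (sum(ok) < 4L) stop("need at least 4 non-missing phenotype values")
  transform <- character(0)
  med <- stats::median(values[ok])
  if (med < 0) {
    values <- -values
    transform <- c(transform, "sign_flip")
  } else if (med == 0 && any(values[ok] < 0) && any(values[ok] > 0)) {
    warning("mixed-sign phenotype with zero median; applying a minimum shift")
    values <- values - min(values[ok])
    transform <- c(transform, "min_shift")
  }
  if (inverse_normal) {
    values[ok] <- blom_scores(values[ok])
    transform <- c(transform, "inverse_normal")
  }
  if (length(transform) == 0L) transform <- "none"
  list(values = values, transform = transform)
}

#' Blom rank-based inverse-normal scores
#'
#' @param x Numeric vector without missing values.
#' @return `qnorm((rank(x) - 3/8) / (length(x) + 1/4))`.
#' @export
blom_scores <- function(x) {
  stats::qnorm((rank(x) - 3 / 8) / (length(x) + 1 / 4))
}

# Precompute the family-block structure of a phenotype for the profile
# likelihood: per-family sizes and sums plus global moments.
vc_setup <- function(y, fam) {
  fam <- factor(fam)
  kf <- as.numeric(tabulate(fam))
  s <- as.numeric(rowsum(y, fam))
  list(y = y, n = length(y), nfam = nlevels(fam), kf = kf, s = s,
       sy = sum(y), syy = sum(y * y), fam = fam)
}

# Profile negative log-likelihood (up to constants) over h2, with the
# intercept and the total variance profiled out in closed form. The family
# covariance is compound-symmetric: Vp * [(1 - h2/2) I + (h2/2) J].
vc_profile_nll <- function(h2, st, reml = FALSE) {
  a <- 1 - 0.5 * h2
  b <- 0.5 * h2
  d <- a + b * st$kf
  A2 <- sum(st$kf / d)
  mu <- sum(st$s / d) / A2
  S1 <- sum(st$s^2 / d)
  S2 <- sum(st$s * st$kf / d)
  S3 <- sum(st$kf^2 / d)
  tq <- S1 - 2 * mu * S2 + mu^2 * S3
  rss <- st$syy - 2 * mu * st$sy + st$n * mu^2
  q <- (rss - b * tq) / a
  logdet <- (st$n - st$nfam) * log(a) + sum(log(d))
  if (reml) {
    vp <- q / (st$n - 1)
    (st$n - 1) * log(vp) + logdet + log(A2)
  } else {
    vp <- q / st$n
    st$n * log(vp) + logdet
  }
}

vc_estimate <- function(st, reml = FALSE) {
  f <- function(h) vc_profile_nll(h, st, reml)
  grid <- seq(0, 1, by = 0.05)
  vals <- vapply(grid, f, numeric(1))
  i <- which.min(vals)
  lo <- max(0, grid[i] - 0.05)
  hi <- min(1, grid[i] + 0.05)
  opt <- stats::optimize(f, c(lo, hi), tol = 1e-8)
  cand_h <- c(opt$minimum, grid[i], 0, 1)
  cand_v <- c(opt$objective, vals[i], vals[1], vals[length(vals)])
  j <- which.min(cand_v)
  list(h2 = cand_h[j], nll = cand_v[j])
}

#' Fit the sibling variance-component model
#'
#' Maximum-likelihood estimation of the additive genetic and residual variance
#' components from family-structured data. The phenotype is modelled as
#' Gaussian with a single intercept and block-diagonal covariance
#' `sigma2_g * R + sigma2_e * I` per family, where `R` has ones on the
#' diagonal and the full-sibling coefficient of relationship 0.5 between
#' siblings. Heritability is `h2 = sigma2_g / (sigma2_g + sigma2_e)`.
#'
#' The compound-symmetric family blocks admit closed-form determinants and
#' inverses, and both the intercept and the total variance are profiled out,
#' leaving a one-dimensional likelihood in `h2 \in [0, 1]` that is maximized
#' by a grid scan plus local refinement (deterministic; nonnegativity of both
#' components is enforced by the box constraint).
#'
#' @param values Named numeric phenotype vector (names = subject ids);
#'   missing values drop the subject for this phenotype.
#' @param ped Pedigree covering the phenotyped subjects.
#' @param reml Use REML instead of ML (default `FALSE`, matching standard
#'   pedigree variance-component software).
#' @return A `heritability_result`: list with `h2`, `sigma2_g`, `sigma2_e`,
#'   `mu`, `loglik`, `n`, `n_families`, `reml`, `degenerate`.
#' @examples
#' ped <- make_pedigree(rep(2, 100))
#' y <- simulate_phenotype(ped, h2 = 0.8, seed = 2)
#' fit_variance_components(y, ped)
#' @export
fit_variance_components <- function(values, ped, reml = FALSE) {
  if (is.null(names(values))) {
    stopifnot(length(values) == nrow(ped))
    names(values) <- ped$subject_id
  }
  keep <- !is.na(values)
  ids <- names(values)[keep]
  miss <- setdiff(ids, ped$subject_id)
  if (length(miss) > 0) stop("subjects missing from pedigree: ",
                             paste(utils::head(miss, 5), collapse = ", "))
  y <- unname(values[keep])
  fam <- ped$family_id[match(ids, ped$subject_id)]
  if (length(y) < 4L) stop("need at least 4 phenotyped subjects")
  if (stats::var(y) == 0) {
    return(structure(list(h2 = NA_real_, sigma2_g = 0, sigma2_e = 0,
                          mu = y[1], loglik = NA_real_, n = length(y),
                          n_families = length(unique(fam)), reml = reml,
                          degenerate = TRUE),
                     class = "heritability_result"))
  }
  st <- vc_setup(y, fam)
  est <- vc_estimate(st, reml)
  h2 <- est$h2
  # recover the profiled intercept and total variance at the optimum
  a <- 1 - 0.5 * h2
  b <- 0.5 * h2
  d <- a + b * st$kf
  mu <- sum(st$s / d) / sum(st$kf / d)
  tq <- sum((st$s - st$kf * mu)^2 / d)
  rss <- st$syy - 2 * mu * st$sy + st$n * mu^2
  q <- (rss - b * tq) / a
  vp <- if (reml) q / (st$n - 1) else q / st$n
  logdet <- (st$n - st$nfam) * log(a) + sum(log(d))
  loglik <- -0.5 * (st$n * log(2 * pi) + st$n * log(vp) + logdet + q / vp)
  structure(list(h2 = h2, sigma2_g = h2 * vp, sigma2_e = (1 - h2) * vp,
                 mu = mu, loglik = loglik, n = st$n,
                 n_families = st$nfam, reml = reml, degenerate = FALSE),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Variance-component fit: degenerate (zero phenotypic variance)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Variance-component fit (%s): h2 = %.3f (sigma2_g = %.4g, sigma2_e = %.4g)\n",
    if (x$reml) "REML" else "ML", x$h2, x$sigma2_g, x$sigma2_e))
  cat(sprintf("  n = %d subjects in %d families, loglik = %.3f\n",
              x$n, x$n_families, x$loglik))
  invisible(x)
}

# Fast internal h2-only fit used inside the permutation loop.
fit_h2_fast <- function(y, fam) {
  st <- vc_setup(y, fam)
  vc_estimate(st, reml = FALSE)$h2
}

#' One-tailed permutation p-value arithmetic
#'
#' @param k Number of permutations whose statistic was at least the observed
#'   one (ties count as exceedances).
#' @param n_perm Number of permutations.
#' @return `k / n_perm`.
#' @export
perm_pvalue <- function(k, n_perm) {
  stopifnot(n_perm > 0, k >= 0, k <= n_perm)
  k / n_perm
}

#' Permutation test of heritability against zero
#'
#' Empirical one-tailed significance of the observed heritability: the family
#' labels of the subjects are permuted uniformly (family sizes preserved;
#' original sibships may recur, which makes the test conservative), the
#' variance-component model is refitted on each permuted dataset, and
#' `k` counts permutations whose heritability is greater than or equal to the
#' observed one. The p-value is `k / n_perm`; an observed heritability of
#' exactly zero therefore yields `k = n_perm` and `p = 1`.
#'
#' @param values Named numeric phenotype vector (prepared; missing dropped).
#' @param ped Pedigree.
#' @param n_perm Number of permutations (default 6000).
#' @param seed Optional integer seed for reproducibility.
#' @return A `permutation_result`: list with `h2_observed`, `k`, `p`,
#'   `n_perm`, `seed`.
#' @export
permutation_test <- function(values, ped, n_perm = 6000L, seed = NULL) {
  if (n_perm <= 0) stop("'n_perm' must be positive")
  obs <- fit_variance_components(values, ped)
  if (isTRUE(obs$degenerate)) stop("degenerate phenotype: zero variance")
  if (!is.null(seed)) set.seed(seed)
  keep <- !is.na(values)
  ids <- names(values)[keep]
  y <- unname(values[keep])
  fam <- ped$family_id[match(ids, ped$subject_id)]
  # permuting subjects' family labels == permuting values against the fixed
  # family structure
  k <- 0L
  for (b in seq_len(n_perm)) {
    h2b <- fit_h2_fast(sample(y), fam)
    if (h2b >= obs$h2) k <- k + 1L
  }
  structure(list(h2_observed = obs$h2, k = k, p = perm_pvalue(k, n_perm),
                 n_perm = as.integer(n_perm), seed = seed),
            class = "permutation_result")
}

#' Bonferroni correction
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param n_tests Number of tests corrected for (default 30, the full
#'   phenotype battery).
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `adjusted` (`pmin(1, p * n_tests)`) and `significant`
#'   (`p < alpha / n_tests`).
#' @export
bonferroni <- function(p_values, n_tests = 30L, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  list(adjusted = pmin(1, p_values * n_tests),
       significant = p_values < alpha / n_tests)
}

#' Single-group Cohen's d
#'
#' Effect size `D = M / S` for a one-sample design: the mean of the values
#' divided by their sample standard deviation.
#'
#' @param values Numeric vector (missing values dropped); at least two
#'   distinct values required.
#' @return Cohen's d.
#' @export
cohens_d <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation: Cohen's d undefined")
  mean(values) / s
}

#' Moment-based sibling heritability (2 x intraclass correlation)
#'
#' ANOVA intraclass correlation of siblings within families, doubled to undo
#' the 0.5 coefficient of relationship. Serves as an independent cross-check
#' of the likelihood fit on balanced designs.
#'
#' @param values Named phenotype vector.
#' @param ped Pedigree (balanced sibships recommended).
#' @return `2 * ICC` estimate (may fall outside `[0, 1]` by sampling error).
#' @export
sib_icc_h2 <- function(values, ped) {
  keep <- !is.na(values)
  ids <- names(values)[keep]
  y <- unname(values[keep])
  fam <- factor(ped$family_id[match(ids, ped$subject_id)])
  fit <- stats::aov(y ~ fam)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  k <- length(y) / nlevels(fam)  # balanced group size
  icc <- (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
  2 * icc
}
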