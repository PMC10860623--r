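#' Simulate a sibling-structured quantitative phenotype
#'
#' Draws one value per pedigree subject under the additive polygenic model
#' `y = mean + g + e`, with `var(g) = h2 * var_p`, `var(e) = (1 - h2) * var_p`,
#' and a genetic covariance of `0.5 * h2 * var_p` between full siblings (the
#' coefficient of relationship for full sibs) and zero across families.
#'
#' The genetic value is constructed as
#' `g_i = sqrt(0.5) * a_family + sqrt(0.5) * a_individual`, where both terms
#' are independent zero-mean Gaussians with variance `h2 * var_p`; this yields
#' exactly the target marginal variance and sibling covariance.
#'
#' @param ped A [make_pedigree()] pedigree.
#' @param h2 True narrow-sense heritability, in `[0, 1]`.
#' @param mean Phenotype mean.
#' @param var_p Total phenotypic variance (`> 0`).
#' @param seed Optional integer seed; when given the draw is reproducible.
#' @return Named numeric vector of phenotype values, names = subject ids.
#' @examples
#' ped <- make_pedigree(rep(2, 50))
#' y <- simulate_phenotype(ped, h2 = 0.5, seed = 1)
#' @export
simulate_phenotype <- function(ped, h2, mean = 0, var_p = 1, seed = NULL) {
  if (!is.numeric(h2) || length(h2) != 1L || is.na(h2) || h2 < 0 || h2 > 1) {
    stop("'h2' must be a single value in [0, 1]")
  }
  if (!is.numeric(var_p) || var_p <= 0) stop("'var_p' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  fam <- factor(ped$family_id, levels = unique(ped$family_id))
  n <- nrow(ped)
  sd_a <- sqrt(h2 * var_p)
  a_fam <- stats::rnorm(nlevels(fam), 0, sd_a)[as.integer(fam)]
  a_ind <- stats::rnorm(n, 0, sd_a)
  g <- sqrt(0.5) * a_fam + sqrt(0.5) * a_ind
  e <- stats::rnorm(n, 0, sqrt((1 - h2) * var_p))
  y <- mean + g + e
  names(y) <- ped$subject_id
  y
}

#' Empirical sibling-pair correlation of a phenotype
#'
#' Pearson correlation across all unordered within-family sibling pairs.
#' Under the additive model its expectation is `0.5 * h2`.
#'
#' @param values Named phenotype vector (names = subject ids).
#' @param ped Matching pedigree.
#' @return Correlation coefficient (NA with fewer than 2 pairs).
#' @export
sib_pair_correlation <- function(values, ped) {
  pr <- sib_pairs(ped)
  if (nrow(pr) < 2L) return(NA_real_)
  stats::cor(values[pr$subject_a], values[pr$subject_b])
}
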