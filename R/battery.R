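#' Names of the 15 beta phenotypes per hemisphere
#'
#' Five spectral phenotypes (peak beta frequency and power, total periodic
#' beta power, aperiodic exponent and offset) and ten beta-event phenotypes
#' (mean/median/SD/robust maximum of duration and amplitude, event rate,
#' waiting-time dispersion).
#'
#' @return Character vector of length 15.
#' @export
beta_phenotype_names <- function() {
  c("peak_beta_frequency", "peak_beta_power", "total_beta_power",
    "aperiodic_exponent", "aperiodic_offset",
    "duration_mean", "duration_median", "duration_sd", "duration_robust_max",
    "amplitude_mean", "amplitude_median", "amplitude_sd",
    "amplitude_robust_max", "event_rate", "dispersion")
}

#' Names of the full 30-phenotype battery (15 per hemisphere)
#'
#' @return Character vector of length 30 (`lh_*`, then `rh_*`).
#' @export
battery_phenotype_names <- function() {
  c(paste0("lh_", beta_phenotype_names()), paste0("rh_", beta_phenotype_names()))
}

#' Heritability battery over a phenotype table
#'
#' For each phenotype column: sign-convention preparation (optional
#' inverse-normal transform), variance-component fit, family-label permutation
#' test, Bonferroni correction across the battery, and single-group Cohen's d
#' on the raw values.
#'
#' @param table Data frame with a `subject_id` column plus one numeric column
#'   per phenotype (missing values drop the subject for that phenotype only).
#' @param ped Pedigree covering the subjects.
#' @param phenotypes Character vector of phenotype column names to test;
#'   defaults to all non-id columns. Missing columns raise an error naming
#'   them.
#' @param n_perm Permutations per phenotype (default 6000).
#' @param seed Root seed; each phenotype uses a derived substream seed.
#' @param n_tests Bonferroni denominator (default: number of phenotypes).
#' @param inverse_normal Apply the inverse-normal transform (default `FALSE`).
#' @return Data frame with one row per phenotype: `phenotype`, `transform`,
#'   `h2`, `k`, `p`, `p_bonferroni`, `significant`, `cohens_d`, `n_used`.
#' @export
run_heritability_battery <- function(table, ped, phenotypes = NULL,
                                     n_perm = 6000L, seed = 1L,
                                     n_tests = NULL, inverse_normal = FALSE) {
  stopifnot(is.data.frame(table), "subject_id" %in% names(table))
  if (is.null(phenotypes)) {
    phenotypes <- setdiff(names(table), "subject_id")
  }
  missing_cols <- setdiff(phenotypes, names(table))
  if (length(missing_cols) > 0) {
    stop("phenotype columns missing from table: ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(n_tests)) n_tests <- length(phenotypes)
  rows <- lapply(seq_along(phenotypes), function(i) {
    ph <- phenotypes[i]
    vals <- table[[ph]]
    names(vals) <- table$subject_id
    prep <- prepare_phenotype(vals, inverse_normal = inverse_normal)
    perm <- permutation_test(prep$values, ped, n_perm = n_perm,
                             seed = derive_seed(seed, i))
    d <- tryCatch(cohens_d(vals), error = function(e) NA_real_)
    data.frame(phenotype = ph,
               transform = paste(prep$transform, collapse = "+"),
               h2 = perm$h2_observed, k = perm$k, p = perm$p,
               cohens_d = d, n_used = sum(!is.na(vals)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  bf <- bonferroni(res$p, n_tests = n_tests)
  res$p_bonferroni <- bf$adjusted
  res$significant <- bf$significant
  res[, c("phenotype", "transform", "h2", "k", "p", "p_bonferroni",
          "significant", "cohens_d", "n_used")]
}
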