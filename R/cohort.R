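#' Default mapping from heritable phenotypes to signal parameters
#'
#' Recognizes two phenotype names: `aperiodic_exponent` replaces the
#' background exponent of the subject's signal configuration, and
#' `amplitude_scale` multiplies the median burst amplitude (must be positive).
#' Any other phenotype is carried in the ground-truth table but does not alter
#' the signal.
#'
#' @param pheno Named numeric vector of one subject's phenotype values.
#' @param base_cfg Base [signal_gen_config()].
#' @return Modified configuration list (unvalidated).
#' @export
default_phenotype_link <- function(pheno, base_cfg) {
  cfg <- base_cfg
  if ("aperiodic_exponent" %in% names(pheno)) {
    cfg$aperiodic_exponent <- unname(pheno["aperiodic_exponent"])
  }
  if ("amplitude_scale" %in% names(pheno)) {
    sc <- unname(pheno["amplitude_scale"])
    if (!is.finite(sc) || sc <= 0) stop("'amplitude_scale' must be positive")
    cfg$burst_amp_dist$meanlog <- cfg$burst_amp_dist$meanlog + log(sc)
  }
  cfg
}

validate_signal_gen_config <- function(cfg) {
  if (cfg$sampling_rate <= 2 * 47) stop("sampling rate too low for a 47 Hz analysis band")
  if (cfg$duration <= 0) stop("duration must be > 0")
  if (!is.finite(cfg$aperiodic_exponent) || cfg$aperiodic_exponent < 0) {
    stop("aperiodic exponent must be finite and >= 0")
  }
  if (cfg$burst_rate < 0) stop("burst rate must be >= 0")
  if (!is.finite(cfg$burst_amp_dist$meanlog)) stop("invalid burst amplitude scale")
  invisible(cfg)
}

#' Simulate a sibling cohort of sensor recordings with known ground truth
#'
#' Draws heritable phenotypes for every pedigree subject
#' ([simulate_phenotype()], one column per entry of `pheno_cfgs`), maps them
#' into per-subject signal configurations through `link`, and generates one
#' two-channel recording per subject. The generating parameters therefore
#' carry the simulated family covariance, and the returned ground-truth table
#' supports end-to-end recovery tests.
#'
#' @param ped A [make_pedigree()] pedigree.
#' @param pheno_cfgs Named list; each element a list with `h2`, `mean`,
#'   `var_p` describing one heritable phenotype.
#' @param link Function `(pheno, base_cfg) -> cfg` mapping one subject's named
#'   phenotype vector into a signal configuration
#'   ([default_phenotype_link()] by default). A link that produces an invalid
#'   configuration raises an error naming the subject.
#' @param base_cfg Base [signal_gen_config()] shared by all subjects.
#' @param seed Root seed; phenotype draws and per-subject noise seeds are
#'   derived substreams.
#' @param keep_signals Generate and return the signal pairs (default `TRUE`);
#'   with `FALSE` only the ground truth and per-subject configurations are
#'   returned and signals can be regenerated on demand with
#'   [cohort_subject_signal()].
#' @return List with `truth` (data frame: subject, family, phenotype values,
#'   noise seed), `configs` (named list of per-subject configurations) and,
#'   when requested, `signals` (named list of `sensor_pair`s).
#' @export
simulate_cohort <- function(ped, pheno_cfgs, link = default_phenotype_link,
                            base_cfg = signal_gen_config(), seed = 1L,
                            keep_signals = TRUE) {
  stopifnot(length(pheno_cfgs) >= 1L, !is.null(names(pheno_cfgs)))
  truth <- data.frame(subject_id = ped$subject_id, family_id = ped$family_id,
                      stringsAsFactors = FALSE)
  for (j in seq_along(pheno_cfgs)) {
    pc <- pheno_cfgs[[j]]
    truth[[names(pheno_cfgs)[j]]] <-
      simulate_phenotype(ped, h2 = pc$h2,
                         mean = if (is.null(pc$mean)) 0 else pc$mean,
                         var_p = if (is.null(pc$var_p)) 1 else pc$var_p,
                         seed = derive_seed(seed, j))
  }
  truth$noise_seed <- vapply(seq_len(nrow(ped)),
                             function(i) derive_seed(seed, 1000L + i),
                             integer(1))
  configs <- vector("list", nrow(truth))
  names(configs) <- truth$subject_id
  for (i in seq_len(nrow(truth))) {
    pheno <- unlist(truth[i, names(pheno_cfgs), drop = FALSE])
    cfg <- tryCatch({
      cfg_i <- link(pheno, base_cfg)
      cfg_i$noise_seed <- truth$noise_seed[i]
      validate_signal_gen_config(cfg_i)
      cfg_i
    }, error = function(e) {
      stop(sprintf("invalid signal configuration for subject '%s': %s",
                   truth$subject_id[i], conditionMessage(e)), call. = FALSE)
    })
    configs[[i]] <- cfg
  }
  out <- list(truth = truth, configs = configs)
  if (keep_signals) {
    out$signals <- lapply(configs, simulate_sensor_pair)
  }
  out
}

#' Regenerate one subject's recording from a cohort
#'
#' Recordings are deterministic in the per-subject configuration, so a cohort
#' built with `keep_signals = FALSE` can stream subjects without storing any
#' signal.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param subject_id Subject identifier.
#' @return A `sensor_pair`.
#' @export
cohort_subject_signal <- function(cohort, subject_id) {
  cfg <- cohort$configs[[subject_id]]
  if (is.null(cfg)) stop("unknown subject: ", subject_id)
  simulate_sensor_pair(cfg)
}
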