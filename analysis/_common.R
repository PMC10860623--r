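# Shared parameters and helpers for the numbered analysis scripts.
# A scaled-down demonstration cohort keeps each stage to roughly a minute;
# the full study layout (100 families, 180 s recordings, 6000 permutations)
# uses the same code paths via run_pipeline().

library(betaherit)

params <- list(
  root_seed    = 20260101L,
  family_sizes = c(rep(2L, 16L), rep(3L, 3L), 4L),  # 45 subjects
  duration     = 60,      # s per recording
  sampling_rate = 600,    # Hz
  burst_rate   = 1.0,     # events/s
  n_perm       = 500L,    # permutations per phenotype
  out_dir      = file.path("results", "analysis")
)

hemisphere_phenotypes <- list(
  lh = list(
    aperiodic_exponent = list(h2 = 0.47, mean = 1.03, var_p = 0.19^2),
    amplitude_scale    = list(h2 = 0.35, mean = 1,    var_p = 0.2^2)),
  rh = list(
    aperiodic_exponent = list(h2 = 0.87, mean = 1.07, var_p = 0.18^2),
    amplitude_scale    = list(h2 = 0.75, mean = 1,    var_p = 0.2^2)))

demo_pedigree <- function() make_pedigree(params$family_sizes)

# Rebuild one hemisphere's cohort deterministically from the root seed.
# Signals are regenerated on demand from per-subject configs, never stored.
demo_cohort <- function(hemisphere) {
  h <- match(hemisphere, names(hemisphere_phenotypes))
  simulate_cohort(
    demo_pedigree(), hemisphere_phenotypes[[hemisphere]],
    base_cfg = signal_gen_config(sampling_rate = params$sampling_rate,
                                 duration = params$duration,
                                 burst_rate = params$burst_rate),
    seed = derive_seed(params$root_seed, h), keep_signals = FALSE)
}

write_result <- function(x, name) {
  dir.create(params$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(params$out_dir, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}

read_result <- function(name) {
  utils::read.table(file.path(params$out_dir, name), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}
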