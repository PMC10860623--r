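#!/usr/bin/env Rscript
# Stage 3 — transient beta events.
#
# For each subject: regenerate the recording, compute the Morlet amplitude
# envelope at the subject's own peak beta frequency (from stage 2; the
# generator carrier is the fallback when no periodic peak was found), smooth
# it, threshold at the 75th percentile, and summarize the resulting event
# train into ten phenotypes per subject and hemisphere.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "_common.R"))

event_cols <- c("duration_mean", "duration_median", "duration_sd",
                "duration_robust_max", "amplitude_mean", "amplitude_median",
                "amplitude_sd", "amplitude_robust_max", "event_rate",
                "dispersion")

for (hem in names(hemisphere_phenotypes)) {
  cohort <- demo_cohort(hem)
  spectral <- read_result(sprintf("spectral_%s.tsv", hem))
  ids <- cohort$truth$subject_id
  rows <- lapply(ids, function(id) {
    pair <- cohort_subject_signal(cohort, id)
    peak <- spectral$peak_beta_frequency[spectral$subject_id == id]
    if (!is.finite(peak)) peak <- pair$cfg$beta_freq
    peak <- min(max(peak, 8.5), 45.5)  # keep the averaged band on the grid
    ep <- event_phenotypes(pair, peak)
    as.data.frame(ep[event_cols])
  })
  out <- cbind(data.frame(subject_id = ids), do.call(rbind, rows))
  write_result(out, sprintf("events_%s.tsv", hem))
  message(sprintf("  [%s] event rate: mean %.3f /s | duration: mean %.0f ms",
                  hem, mean(out$event_rate), mean(out$duration_mean)))
}
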