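#!/usr/bin/env Rscript
# Stage 1 — simulate the sibling cohort.
#
# Draws heritable generator parameters (aperiodic exponent, burst amplitude
# scale) for every subject in each hemisphere under the additive sibling
# model, and records the pedigree and the ground-truth parameter tables.
# Later stages regenerate each subject's two-channel recording from these
# parameters and per-subject seeds, so no raw signals are stored.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "_common.R"))

ped <- demo_pedigree()
message(sprintf("cohort: %d subjects in %d families",
                nrow(ped), length(unique(ped$family_id))))
write_result(as.data.frame(ped), "pedigree.tsv")

for (hem in names(hemisphere_phenotypes)) {
  cohort <- demo_cohort(hem)
  write_result(cohort$truth, sprintf("ground_truth_%s.tsv", hem))
  message(sprintf("  [%s] exponent: mean %.3f sd %.3f | amplitude scale: mean %.3f sd %.3f",
                  hem,
                  mean(cohort$truth$aperiodic_exponent),
                  sd(cohort$truth$aperiodic_exponent),
                  mean(cohort$truth$amplitude_scale),
                  sd(cohort$truth$amplitude_scale)))
}
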