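#!/usr/bin/env Rscript
# Stage 4 — heritability battery.
#
# Assembles the 30-column phenotype table (15 phenotypes x 2 hemispheres)
# from stages 2-3, then for every phenotype: sign convention, maximum-
# likelihood variance-component fit of sibling heritability, permutation
# test against shuffled family assignment, Bonferroni adjustment over the
# battery, and Cohen's d of the phenotype distribution.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "_common.R"))

ped_df <- read_result("pedigree.tsv")
ped <- make_pedigree(as.integer(table(factor(ped_df$family_id,
                                             levels = unique(ped_df$family_id)))))
stopifnot(identical(ped$subject_id, ped_df$subject_id))

table30 <- data.frame(subject_id = ped$subject_id, stringsAsFactors = FALSE)
for (hem in names(hemisphere_phenotypes)) {
  merged <- merge(read_result(sprintf("spectral_%s.tsv", hem)),
                  read_result(sprintf("events_%s.tsv", hem)),
                  by = "subject_id", sort = FALSE)
  merged <- merged[match(ped$subject_id, merged$subject_id), ]
  vals <- merged[, setdiff(names(merged), "subject_id")]
  names(vals) <- paste0(hem, "_", names(vals))
  table30 <- cbind(table30, vals)
}
write_result(table30, "phenotypes.tsv")

battery <- run_heritability_battery(table30, ped, n_perm = params$n_perm,
                                    seed = derive_seed(params$root_seed, 99L))
write_result(battery, "battery.tsv")

top <- battery[order(battery$p, -battery$h2), ]
message("top phenotypes by permutation p-value:")
for (i in seq_len(min(5, nrow(top)))) {
  message(sprintf("  %-28s h2 = %.2f  p = %.4f  (Bonferroni %.4f)",
                  top$phenotype[i], top$h2[i], top$p[i], top$p_bonferroni[i]))
}
message(sprintf("significant after Bonferroni over %d tests: %d",
                nrow(battery), sum(top$significant, na.rm = TRUE)))
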