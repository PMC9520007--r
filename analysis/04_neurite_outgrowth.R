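#!/usr/bin/env Rscript
# Step 4: neurite outgrowth quantification and knockdown statistics.
#
# Re-generates the chamber profiles from the step-1 seed (the CSVs under
# results/data/profiles are the file-facing copies of the same scans),
# runs cell-body damage QC, normalizes to the per-experiment control
# mean at 100 um, finds the 75/50/25% reference distances, screens
# outliers with Dixon's Q and classifies every gene's knockdown effect.

suppressPackageStartupMessages(library(scpdyn))
out <- "results"
seed <- 1

pr <- synth_profiles(
  profile_spec(genes = c(KD1 = 0.5, NULL1 = 1.0),
               damaged = "control2", damage_type = "displaced"),
  seed = seed
)
scr <- nog_screen(pr$experiments)

utils::write.table(scr$qc, file.path(out, "nog_qc.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(scr$measurements, file.path(out, "nog_measurements.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
res <- dplyr::mutate(scr$results,
                     n_used = vapply(n_used, paste, "", collapse = "/"))
utils::write.table(res, file.path(out, "nog_results.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("QC: ", sum(scr$qc$status == "damaged"), " of ", nrow(scr$qc),
    " chambers flagged damaged (and dropped with their profiles)\n",
    sep = "")
for (i in seq_len(nrow(res))) {
  cat(sprintf("%s: p(75/50/25) = %.3g / %.3g / %.3g -> %s%s\n",
              res$gene[i], res$p_75[i], res$p_50[i], res$p_25[i],
              res$classification[i],
              ifelse(is.na(res$direction[i]), "",
                     paste0(" (", res$direction[i], ")"))))
}
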