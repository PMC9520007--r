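#!/usr/bin/env Rscript
# Step 1: generate the full synthetic study under a fixed seed.
#
# Emits every input the downstream steps consume, in the same text
# dialects real data would arrive in: ontology files (hierarchy TSV, GMT
# annotations, interaction TSV, background list), a treated-vs-control
# expression table over 2/4/6/8 h with a planted two-SCP signal at 6 h,
# a two-run proteomics table with planted shifts, and chamber line-scan
# CSVs with one planted knockdown, one null gene and one damaged
# chamber.  Ground-truth manifests go alongside so later steps can
# score themselves.

suppressPackageStartupMessages(library(scpdyn))
seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

so <- synth_ontology(seed = seed)
write_ontology_files(so$ontology, file.path(out, "ontology"))
cat("ontology: ", length(so$ontology$background), "background genes;",
    "designated strong level-2 pair:",
    paste(so$truth$strong_pair, collapse = " - "), "\n")

se <- synth_expression(
  so$ontology,
  expression_spec(planted = planted_pair_spec(so$truth, n_genes = 8),
                  mid_fraction = 0.25),
  seed = seed
)
utils::write.table(se$table, file.path(out, "expression.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(se$truth, file.path(out, "expression_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("expression: ", nrow(se$table), "gene x time rows,",
    nrow(se$truth), "planted gene-time signals\n")

sp <- synth_proteomics(seed = seed)
utils::write.table(sp$table, file.path(out, "proteomics.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(sp$truth, file.path(out, "proteomics_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("proteomics: ", length(unique(sp$table$protein)), "proteins,",
    sum(sp$truth$planted), "planted shifts of log2(1.2)\n")

pr <- synth_profiles(
  profile_spec(genes = c(KD1 = 0.5, NULL1 = 1.0),
               damaged = "control2", damage_type = "displaced"),
  seed = seed
)
write_profile_csvs(pr, file.path(out, "profiles"))
utils::write.table(pr$truth, file.path(out, "profiles_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("profiles: ", nrow(pr$manifest), "chambers across",
    length(pr$experiments), "experiments (control2 damaged everywhere)\n")
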