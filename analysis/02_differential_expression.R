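#!/usr/bin/env Rscript
# Step 2: differential expression and proteomics filtering.
#
# Applies the two-tier DEG rule (FDR 5% with fold-change cutoffs
# log2(1.5) for the stringent list and log2(1.3) for the relaxed one)
# and the DEP chain (two-peptide filter, within-run normalization
# against untreated references, equal-variance t-test, +/- log2(1.1)).

suppressPackageStartupMessages(library(scpdyn))
data_dir <- "results/data"
out <- "results"

expr <- utils::read.delim(file.path(data_dir, "expression.tsv"))
strict <- call_degs(expr, min_abs_log2fc = log2(1.5))
relaxed <- call_degs(expr, min_abs_log2fc = log2(1.3))
utils::write.table(strict, file.path(out, "degs_log2_1.5.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(relaxed, file.path(out, "degs_log2_1.3.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("DEGs at least one time point: ", length(union_over_time(strict)),
    " (log2(1.5) cutoff), ", length(union_over_time(relaxed)),
    " (log2(1.3) cutoff)\n", sep = "")

truth <- utils::read.delim(file.path(data_dir, "expression_truth.tsv"))
strong <- toupper(truth$gene[truth$class == "strong"])
cat("recall of strongly planted genes under the stringent cutoff: ",
    round(mean(strong %in% strict$feature), 3), "\n", sep = "")
cat("mid-effect plants (between the cutoffs) recovered only by the ",
    "relaxed list: ",
    sum(toupper(truth$gene[truth$class == "mid"]) %in% relaxed$feature),
    " of ", sum(truth$class == "mid"), "\n", sep = "")

prot <- utils::read.delim(file.path(data_dir, "proteomics.tsv"))
deps <- suppressWarnings(call_deps(prot, time_h = 5))
utils::write.table(deps, file.path(out, "deps.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
ptruth <- utils::read.delim(file.path(data_dir, "proteomics_truth.tsv"))
eligible <- ptruth$planted & ptruth$peptides >= 2
cat("DEPs called: ", nrow(deps), "; planted-and-eligible recovered: ",
    sum(toupper(ptruth$protein[eligible]) %in% deps$feature), " of ",
    sum(eligible), "\n", sep = "")
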