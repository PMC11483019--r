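#!/usr/bin/env Rscript
# Step 6 — program covariation across samples: per-sample percentile matrices
# of program usage (25/50/75/90/95), pairwise program correlations with
# clustermap ordering, and permutation p-values at the 75th percentile.

source("analysis/00_config.R")

usages <- as.matrix(utils::read.table(file.path(results_dir, "program_usages.tsv"),
                                      header = TRUE, sep = "\t", row.names = 1))
mal <- utils::read.table(file.path(results_dir, "malignancy.tsv"),
                         header = TRUE, sep = "\t")
raw <- read_counts(cohort_dir)
meta <- raw$cell_meta[rownames(usages), ]
types <- rep("tumor", nrow(usages))

for (p in c(25, 50, 75, 90, 95)) {
  pm <- percentile_matrix(usages, meta$sample, types, "tumor",
                          percentile = p, min_cells = 5)
  write_tsv(round(pm, 6), sprintf("percentile_matrix_p%02d.tsv", p), rows = TRUE)
  if (p == 75) {
    pc <- program_correlations(pm)
    write_tsv(round(pc$correlation, 6), "program_correlation_p75.tsv", rows = TRUE)
    writeLines(pc$order, file.path(results_dir, "program_dendrogram_order.txt"))
  }
}

pv <- permutation_pvalues(usages, meta$sample, types, "tumor",
                          n_iterations = 1000, percentile = 75, min_cells = 5,
                          seed = analysis_seed)
write_tsv(round(pv$pvalues, 4), "program_covariation_pvalues.tsv", rows = TRUE)
sig <- which(pv$pvalues < 0.05 & upper.tri(pv$pvalues), arr.ind = TRUE)
message(sprintf("%d of %d program pairs co-vary at p < 0.05 (75th percentile, %d shuffles)",
                nrow(sig), sum(upper.tri(pv$pvalues)), pv$n_iterations))
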