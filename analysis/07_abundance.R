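#!/usr/bin/env Rscript
# Step 7 — compositional statistics: per-sample major-type proportions,
# pre- versus on-treatment comparisons (all samples and paired-only), and the
# positive-tumor-cell-fraction test for a chosen gene.

source("analysis/00_config.R")

raw <- read_counts(cohort_dir)
filtered <- filter_matrix(raw, qc_thresholds())
ann <- utils::read.table(file.path(results_dir, "malignancy.tsv"),
                         header = TRUE, sep = "\t")
filtered <- subset_cells(filtered, cells = match(ann$cell, rownames(filtered$counts)))

comp <- composition_table(ann$type, filtered$cell_meta, denominator = "all")
write_tsv(comp, "composition.tsv")

for (mode in c("all-samples", "paired-only")) {
  cmp <- paired_comparison(comp, mode = mode)
  write_tsv(cmp, sprintf("comparison_%s.tsv", gsub("-", "_", mode)))
  message("pre vs on (", mode, "):")
  for (i in seq_len(nrow(cmp))) {
    message(sprintf("  %-12s pre %.3f  on %.3f  t %+ .2f  p %.3f (adj %.3f)",
                    cmp$category[i], cmp$mean_pre[i], cmp$mean_on[i],
                    cmp$t_statistic[i], cmp$p_raw[i], cmp$p_adjusted[i]))
  }
}

# positive-fraction comparison for the top gene of the program whose usage
# varies most across malignant cells (skipping mitochondrial genes)
spectra <- as.matrix(utils::read.table(file.path(results_dir, "consensus_spectra.tsv"),
                                       header = TRUE, sep = "\t", row.names = 1,
                                       check.names = FALSE))
usages <- as.matrix(utils::read.table(file.path(results_dir, "program_usages.tsv"),
                                      header = TRUE, sep = "\t", row.names = 1,
                                      check.names = FALSE))
prog <- colnames(usages)[which.max(apply(usages, 2, var))]
gene <- setdiff(top_program_genes(spectra, 10)[[prog]],
                grep("^MT-", colnames(spectra), value = TRUE))[1]
pf <- positive_fraction_test(filtered, ann$malignant, gene, mode = "paired-only")
write_tsv(pf, "positive_fraction_test.tsv")
message(sprintf("fraction of %s-positive tumor cells, pre %.3f vs on %.3f: p = %.3f",
                gene, pf$mean_pre, pf$mean_on, pf$p_raw))
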