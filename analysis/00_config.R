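# Shared settings for the analysis scripts. Every step reads and writes under
# results/ so the scripts can be run in order:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_qc_cluster.R
#   ... up to 07_abundance.R
# The cohort emulates the study design: patients biopsied at baseline (pre)
# and on treatment (on), a mixture of malignant and five non-malignant cell
# types, five planted tumor expression programs, and chromosome-scale
# expression shifts in the malignant cells.

library(bilestate)

results_dir <- "results"
cohort_dir <- file.path(results_dir, "cohort")
dir.create(results_dir, showWarnings = FALSE)

analysis_seed <- 20260920L

cohort_cfg <- cohort_config(
  n_patients = 5,
  timepoints_per_patient = c("pre", "on"),
  cells_per_sample = 300,
  n_genes = 2000,
  n_programs = 5,
  program_overdispersion = 0.3,
  cnv_segments = list(
    list(chromosome = "chr1", start_gene_index = 1, end_gene_index = 60,
         fold_change = 2),
    list(chromosome = "chr8", start_gene_index = 1, end_gene_index = 60,
         fold_change = 2),
    list(chromosome = "chr13", start_gene_index = 1, end_gene_index = 40,
         fold_change = 0.5)),
  malignant_fraction = 0.4,
  doublet_rate = 0.05,
  mito_gene_fraction = 0.03,
  depth_mean = 2500,
  seed = analysis_seed)

reference_types <- c("T", "myeloid", "NK", "endothelial", "fibroblast")
state_names <- c("basal", "classical", "endothelial-like", "mesenchymal",
                 "neural-like")

write_tsv <- function(x, name, rows = FALSE) {
  path <- file.path(results_dir, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = rows)
  message("wrote ", path)
}
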