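#!/usr/bin/env Rscript
# Step 5 — classify malignant cells into the five tumor states plus
# "intermediate" from their program usages, and map discovered programs onto
# the planted reference programs by score correlation.

source("analysis/00_config.R")

usages <- as.matrix(utils::read.table(file.path(results_dir, "program_usages.tsv"),
                                      header = TRUE, sep = "\t", row.names = 1))
if (ncol(usages) < length(state_names)) {
  stop("need at least ", length(state_names), " programs to name states")
}

# name the first five programs as states (a user decision in real cohorts,
# made from each program's top genes)
su <- usages[, seq_along(state_names)]
colnames(su) <- state_names
calls <- assign_tumor_states(su, intermediate_threshold = 0.25)
write_tsv(calls, "tumor_states.tsv")
message("state composition of malignant cells:")
print(round(table(calls$state) / nrow(calls), 3))

# correlation of discovered program usage with planted-truth program scores
raw <- read_counts(cohort_dir)
filtered <- filter_matrix(raw, qc_thresholds())
tumor <- subset_cells(filtered,
                      cells = match(rownames(usages), rownames(filtered$counts)))
expr <- normalize_log(tumor)
truth_sets <- read_gmt(file.path(cohort_dir, "truth_programs.gmt"))
ref_scores <- sapply(truth_sets, function(s) {
  score_gene_set(expr, s, seed = analysis_seed)
})
corr <- map_programs_to_reference(usages, ref_scores)
write_tsv(round(corr, 4), "program_reference_correlation.tsv", rows = TRUE)
message("best reference match per discovered program:")
print(attr(corr, "best_match"))
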