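#!/usr/bin/env Rscript
# Step 1 — generate the ground-truthed synthetic cohort and write it in the
# 10x triplet layout. Later steps only read the written files, mimicking a
# pipeline over real Cellranger output.

source("analysis/00_config.R")

cohort <- generate_cohort(cohort_cfg)
write_cohort(cohort$counts, cohort$truth, cohort_dir, overwrite = TRUE)
write_gmt(cohort$truth$marker_blocks, file.path(results_dir, "markers.gmt"))

message(sprintf("cohort: %d cells x %d genes across %d samples (%d patients)",
                nrow(cohort$counts$counts), ncol(cohort$counts$counts),
                length(unique(cohort$counts$cell_meta$sample)),
                cohort_cfg$n_patients))
message(sprintf("planted: %d tumor programs, %d CNV segments, %.0f%% malignant, %.0f%% doublets",
                cohort_cfg$n_programs, length(cohort_cfg$cnv_segments),
                100 * mean(cohort$truth$true_malignant),
                100 * mean(cohort$truth$true_doublet)))
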