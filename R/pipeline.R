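#' Run the full cohort analysis end to end
#'
#' Chains every stage on a cohort directory (10x-style triplets, as written by
#' [write_cohort()]): QC filtering, doublet removal, normalization, HVG
#' selection, clustering, marker-based major-type annotation, copy-number
#' profiling with the squared-deviation malignancy score, consensus NMF over a
#' rank grid on the malignant cells, tumor-state assignment, percentile
#' covariation with permutation p-values, and pre/on composition comparisons.
#' All stage outputs are written as TSV under `out_dir`; the run is
#' deterministic under a fixed `seed` (bit-identical files across runs).
#'
#' @param input_dir cohort directory readable by [read_counts()]. Marker sets
#'   for annotation are taken from `marker_sets`.
#' @param out_dir output directory (created; overwritten if present).
#' @param marker_sets named list of marker gene sets, one per major type.
#' @param state_names names for the first `length(state_names)` discovered
#'   programs when assigning tumor states (default the five tumor states).
#' @param k_values rank grid for consensus NMF.
#' @param n_runs NMF restarts per rank.
#' @param n_hvg genes for the factorization step.
#' @param n_iterations permutation iterations for covariation p-values.
#' @param reference_types annotated types used as the copy-number reference;
#'   defaults to every non-tumor marker-set name.
#' @param thresholds QC thresholds ([qc_thresholds()]).
#' @param seed master seed.
#' @return (invisibly) a list with the main in-memory results.
#' @export
run_pipeline <- function(input_dir, out_dir, marker_sets,
                         state_names = c("basal", "classical",
                                         "endothelial-like", "mesenchymal",
                                         "neural-like"),
                         k_values = c(4, 5, 6), n_runs = 8, n_hvg = 1000,
                         n_iterations = 200,
                         reference_types = NULL,
                         thresholds = qc_thresholds(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name, rows = FALSE) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = rows, col.names = TRUE)
  }

  raw <- read_counts(input_dir)
  filtered <- filter_matrix(raw, thresholds)
  tsv(attr(filtered, "qc_report"), "qc_report.tsv")

  dbl <- detect_doublets(filtered, seed = seed)
  filtered <- subset_cells(filtered, cells = !dbl)

  expr <- normalize_log(filtered, target_sum = 1000)
  hvgs <- select_hvg(expr)
  emb <- cluster_cells(expr, hvgs, n_components = min(40, nrow(expr) - 1),
                       resolution = 0.5, seed = seed)
  types <- annotate_major_types(expr, emb$cluster_labels, marker_sets, seed = seed)
  tsv(data.frame(cell = rownames(expr), cluster = as.character(emb$cluster_labels),
                 type = unname(types)), "clusters.tsv")

  if (is.null(reference_types)) reference_types <- setdiff(names(marker_sets), "tumor")
  ordering <- gene_ordering(filtered$gene_meta)
  profile <- cnv_profile(expr, ordering, types, reference_types)
  states_cnv <- discretize_states(profile, emb$cluster_labels)
  scores <- malignancy_score(states_cnv, emb$cluster_labels)
  malignant <- call_malignant(scores$cell_scores, method = "threshold",
                              threshold = 0)
  tsv(data.frame(cell = rownames(expr), cluster = as.character(emb$cluster_labels),
                 score = unname(scores$cell_scores), malignant = unname(malignant)),
      "cnv_scores.tsv")

  res <- list(counts = filtered, expression = expr, embedding = emb,
              types = types, malignant = malignant, cnv_scores = scores)

  mal_cells <- which(malignant)
  if (length(mal_cells) >= max(k_values) + 2) {
    mal_expr <- expr[mal_cells, , drop = FALSE]
    mat <- prepare_matrix(mal_expr, n_hvg = n_hvg)
    decomps <- lapply(k_values, function(k) {
      run_cnmf(mat, k, n_runs = n_runs, seed = seed)
    })
    ksel <- select_k(decomps)
    tsv(ksel, "k_selection.tsv")
    chosen <- attr(ksel, "chosen_k")
    dec <- decomps[[which(vapply(decomps, `[[`, numeric(1), "k") == chosen)]]
    tsv(round(dec$consensus_spectra, 10), "spectra.tsv", rows = TRUE)
    tsv(round(dec$usages, 10), "usages.tsv", rows = TRUE)
    res$decomposition <- dec
    res$k_selection <- ksel

    usage <- dec$usages
    n_states <- min(length(state_names), ncol(usage))
    su <- usage[, seq_len(n_states), drop = FALSE]
    colnames(su) <- state_names[seq_len(n_states)]
    if (n_states == length(state_names)) {
      calls <- assign_tumor_states(su)
      tsv(calls, "state_calls.tsv")
      res$state_calls <- calls
    }

    # covariation over tumor programs within tumor cells
    cell_types_cov <- ifelse(malignant, "tumor", "normal")
    all_usage <- matrix(0, nrow(expr), ncol(usage),
                        dimnames = list(rownames(expr), colnames(usage)))
    all_usage[mal_cells, ] <- usage
    pm <- percentile_matrix(all_usage, filtered$cell_meta$sample, cell_types_cov,
                            "tumor", percentile = 90, min_cells = 5)
    pc <- program_correlations(pm)
    tsv(round(pc$correlation, 10), "correlation_p90.tsv", rows = TRUE)
    pv <- permutation_pvalues(all_usage, filtered$cell_meta$sample, cell_types_cov,
                              "tumor", n_iterations = n_iterations,
                              percentile = 75, min_cells = 5, seed = seed)
    tsv(round(pv$pvalues, 10), "pvalues_p75.tsv", rows = TRUE)
    res$covariation <- list(percentiles = pm, correlations = pc, pvalues = pv)
  }

  comp <- composition_table(types, filtered$cell_meta, denominator = "all")
  tsv(comp, "composition.tsv")
  cmp <- tryCatch(paired_comparison(comp, mode = "all-samples"),
                  error = function(e) NULL)
  if (!is.null(cmp)) tsv(cmp, "comparisons.tsv")
  res$composition <- comp
  res$comparisons <- cmp

  log_df <- data.frame(
    parameter = c("seed", "n_hvg", "k_values", "n_runs", "n_iterations",
                  "reference_types"),
    value = c(seed, n_hvg, paste(k_values, collapse = ","), n_runs,
              n_iterations, paste(reference_types, collapse = ",")))
  tsv(log_df, "run_log.tsv")
  invisible(res)
}

#' Default marker sets matching the synthetic generator's types
#'
#' Convenience for synthetic cohorts: builds one marker set per major type
#' from the generator's truth (the planted marker blocks for the non-malignant
#' types; the union of program-block genes for tumor).
#'
#' @param truth a `SyntheticTruth`.
#' @return named list of marker gene vectors.
#' @export
truth_marker_sets <- function(truth) {
  sets <- truth$marker_blocks
  sets$tumor <- unique(unlist(truth$program_blocks))
  sets
}
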