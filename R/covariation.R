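#' Per-sample percentile aggregation of program activity
#'
#' Builds a samples x programs matrix whose entry (s, p) is the given
#' percentile (linear interpolation) of program p's per-cell activity over
#' sample s's cells of the program's declared cell type (tumor programs over
#' tumor cells, and so on). Samples with fewer than `min_cells` cells of the
#' relevant type get a missing entry, excluded pairwise downstream.
#'
#' @param scores cells x programs activity matrix.
#' @param sample_labels per-cell sample labels.
#' @param cell_types per-cell type labels.
#' @param program_types character vector naming, for each program column, the
#'   cell type it is computed over; a single value is recycled.
#' @param percentile percentile in (0, 100) (default 90).
#' @param min_cells minimum relevant-type cells per sample (default 10).
#' @return samples x programs matrix (NA where insufficient cells), with the
#'   percentile recorded as `attr(out, "percentile")`.
#' @export
percentile_matrix <- function(scores, sample_labels, cell_types, program_types,
                              percentile = 90, min_cells = 10) {
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must lie strictly between 0 and 100")
  }
  scores <- as.matrix(scores)
  program_types <- rep_len(program_types, ncol(scores))
  samples <- sort(unique(as.character(sample_labels)))
  out <- matrix(NA_real_, length(samples), ncol(scores),
                dimnames = list(samples, colnames(scores)))
  for (s in samples) {
    in_sample <- sample_labels == s
    for (p in seq_len(ncol(scores))) {
      sel <- in_sample & cell_types == program_types[p]
      if (sum(sel) >= min_cells) {
        out[s, p] <- stats::quantile(scores[sel, p], probs = percentile / 100,
                                     type = 7, names = FALSE)
      }
    }
  }
  attr(out, "percentile") <- percentile
  out
}

#' Program-program correlation with hierarchical clustering
#'
#' Pearson correlation between percentile-matrix columns over
#' pairwise-complete samples, plus average-linkage hierarchical clustering of
#' programs on Euclidean distance between correlation rows (the clustermap
#' ordering). Zero-variance columns get `NA` correlations and are excluded
#' from the clustering with a warning.
#'
#' @param pmat samples x programs matrix from [percentile_matrix()].
#' @return `list(correlation = programs x programs matrix, linkage = hclust,
#'   order = program names in dendrogram order)`.
#' @export
program_correlations <- function(pmat) {
  pmat <- as.matrix(pmat)
  complete <- colSums(!is.na(pmat)) >= 3
  if (any(!complete)) {
    warning("program(s) with < 3 non-missing samples excluded: ",
            paste(colnames(pmat)[!complete], collapse = ", "))
  }
  corr <- suppressWarnings(stats::cor(pmat, use = "pairwise.complete.obs"))
  sds <- apply(pmat, 2, stats::sd, na.rm = TRUE)
  degenerate <- is.na(sds) | sds == 0 | !complete
  if (any(degenerate & complete)) {
    warning("zero-variance program column(s); correlations reported missing")
  }
  corr[degenerate, ] <- NA_real_
  corr[, degenerate] <- NA_real_
  diag(corr)[!degenerate] <- 1
  usable <- which(!degenerate)
  linkage <- NULL
  ord <- colnames(pmat)[usable]
  if (length(usable) > 2) {
    rows <- corr[usable, usable, drop = FALSE]
    linkage <- stats::hclust(stats::dist(rows, method = "euclidean"),
                             method = "average")
    ord <- colnames(rows)[linkage$order]
  }
  list(correlation = corr, linkage = linkage, order = ord)
}

#' Permutation p-values for program covariation
#'
#' For each of `n_iterations` iterations, the per-cell sample labels are
#' shuffled (by default within cell-type strata, so each program's percentile
#' is still computed over its own cell type), the percentile matrix and
#' correlations are recomputed, and each program pair's p-value is the count
#' of null correlations strictly greater than the observed correlation divided
#' by `n_iterations` — so p may be exactly 0. An add-one-smoothed estimator
#' `(count + 1) / (n + 1)` is available behind `smoothed = TRUE`.
#'
#' @inheritParams percentile_matrix
#' @param n_iterations shuffles (default 1000).
#' @param percentile significance percentile (default 75).
#' @param stratify_by_type shuffle within cell-type strata (default TRUE);
#'   FALSE shuffles the whole label vector.
#' @param smoothed use the add-one estimator (default FALSE).
#' @param seed integer seed.
#' @return `list(pvalues = symmetric programs x programs matrix, observed =
#'   observed correlation matrix, n_iterations = count)`.
#' @export
permutation_pvalues <- function(scores, sample_labels, cell_types, program_types,
                                n_iterations = 1000, percentile = 75,
                                min_cells = 10, stratify_by_type = TRUE,
                                smoothed = FALSE, seed = 1L) {
  stopifnot(n_iterations >= 1)
  scores <- as.matrix(scores)
  sample_labels <- as.character(sample_labels)
  cell_types <- as.character(cell_types)
  obs_pmat <- percentile_matrix(scores, sample_labels, cell_types, program_types,
                                percentile = percentile, min_cells = min_cells)
  observed <- suppressWarnings(stats::cor(obs_pmat, use = "pairwise.complete.obs"))
  exceed <- matrix(0, ncol(scores), ncol(scores),
                   dimnames = dimnames(observed))
  set.seed(seed)
  strata <- if (stratify_by_type) cell_types else rep("all", length(cell_types))
  for (it in seq_len(n_iterations)) {
    shuffled <- sample_labels
    for (st in unique(strata)) {
      i <- which(strata == st)
      shuffled[i] <- sample_labels[i][sample.int(length(i))]
    }
    pm <- percentile_matrix(scores, shuffled, cell_types, program_types,
                            percentile = percentile, min_cells = min_cells)
    nullcor <- suppressWarnings(stats::cor(pm, use = "pairwise.complete.obs"))
    exceed <- exceed + (!is.na(nullcor) & !is.na(observed) & nullcor > observed)
  }
  pvals <- if (smoothed) (exceed + 1) / (n_iterations + 1) else exceed / n_iterations
  pvals[is.na(observed)] <- NA_real_
  pvals <- (pvals + t(pvals)) / 2  # numerical symmetry; counts are symmetric already
  list(pvalues = pvals, observed = observed, n_iterations = n_iterations)
}
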