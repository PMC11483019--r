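#' Quality-control thresholds
#'
#' Defaults follow the standard droplet-scRNA-seq filter set used throughout
#' this pipeline: cells with fewer than 50 genes expressed, fewer than 200
#' total counts, or more than 25% mitochondrial counts are removed; genes then
#' must be detected in at least 3 retained cells.
#'
#' @param min_genes_per_cell minimum genes detected per cell.
#' @param min_counts_per_cell minimum total counts per cell.
#' @param max_mito_fraction maximum mitochondrial count fraction per cell.
#' @param min_cells_per_gene minimum retained cells a gene must be detected in.
#' @return a `QCThresholds` list.
#' @export
qc_thresholds <- function(min_genes_per_cell = 50,
                          min_counts_per_cell = 200,
                          max_mito_fraction = 0.25,
                          min_cells_per_gene = 3) {
  stopifnot(min_genes_per_cell >= 0, min_counts_per_cell >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1,
            min_cells_per_gene >= 0)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 min_counts_per_cell = min_counts_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = min_cells_per_gene),
            class = "QCThresholds")
}

#' Filter cells and genes on QC thresholds
#'
#' Cells failing any per-cell criterion are removed first; genes detected in
#' fewer than `min_cells_per_gene` of the *retained* cells are removed second
#' (the gene filter depends on which cells remain). A per-criterion removal
#' report is attached as `attr(out, "qc_report")`. The operation is idempotent.
#'
#' A cell removed for "over 25% mitochondrial" means mito fraction strictly
#' greater than the threshold; counts and genes use strictly-less-than the
#' minima, so a cell at exactly the minimum is kept.
#'
#' @param counts a `CountMatrix` of nonnegative integers.
#' @param thresholds a [qc_thresholds()].
#' @return filtered `CountMatrix` with a `qc_report` attribute
#'   (`data.frame(criterion, removed)`).
#' @export
filter_matrix <- function(counts, thresholds = qc_thresholds()) {
  stopifnot(inherits(counts, "CountMatrix"))
  mat <- counts$counts
  genes_per_cell <- Matrix::rowSums(mat > 0)
  counts_per_cell <- Matrix::rowSums(mat)
  mito_counts <- if (any(counts$gene_meta$mito)) {
    Matrix::rowSums(mat[, counts$gene_meta$mito, drop = FALSE])
  } else rep(0, nrow(mat))
  mito_frac <- ifelse(counts_per_cell > 0, mito_counts / counts_per_cell, 0)

  fail_genes <- genes_per_cell < thresholds$min_genes_per_cell
  fail_counts <- counts_per_cell < thresholds$min_counts_per_cell
  fail_mito <- mito_frac > thresholds$max_mito_fraction
  keep_cells <- !(fail_genes | fail_counts | fail_mito)
  if (!any(keep_cells)) {
    stop("all cells removed by QC; review thresholds (min_genes=",
         thresholds$min_genes_per_cell, ", min_counts=",
         thresholds$min_counts_per_cell, ", max_mito=",
         thresholds$max_mito_fraction, ")")
  }
  cells_detected <- Matrix::colSums(mat[keep_cells, , drop = FALSE] > 0)
  keep_genes <- cells_detected >= thresholds$min_cells_per_gene

  out <- subset_cells(counts, cells = keep_cells, genes = keep_genes)
  attr(out, "qc_report") <- data.frame(
    criterion = c("low_genes", "low_counts", "high_mito", "cells_removed",
                  "genes_removed"),
    removed = c(sum(fail_genes), sum(fail_counts), sum(fail_mito),
                sum(!keep_cells), sum(!keep_genes))
  )
  out
}

#' Depth-normalize and log-transform counts
#'
#' Scales each cell to `target_sum` total counts, then applies the natural
#' log(1 + x) transform.
#'
#' @param counts a filtered `CountMatrix`.
#' @param target_sum per-cell total after scaling (default 1000).
#' @return sparse cells x genes matrix of log-normalized expression.
#' @export
normalize_log <- function(counts, target_sum = 1000) {
  stopifnot(inherits(counts, "CountMatrix"), target_sum > 0)
  totals <- Matrix::rowSums(counts$counts)
  if (any(totals == 0)) {
    stop(sum(totals == 0), " cell(s) with zero total counts; filter first")
  }
  scaled <- Matrix::Diagonal(x = target_sum / totals) %*% counts$counts
  out <- scaled
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts$counts)
  methods::as(out, "CsparseMatrix")
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Genes are binned into `n_bins` equal-frequency bins of mean log expression;
#' within each bin the dispersion (variance / mean, computed on the
#' exponentiated scale as in the standard Seurat-flavor recipe) is standardized
#' to a z-score. Genes with mean in `[mean_min, mean_max]` and normalized
#' dispersion at or above `min_dispersion` are returned. Bins with fewer than 2
#' genes are merged with their lower neighbor.
#'
#' @param expression log-normalized cells x genes matrix.
#' @param mean_min,mean_max inclusive bounds on mean log expression
#'   (defaults 0.0125 and 3).
#' @param min_dispersion minimum normalized dispersion (default 0.5).
#' @param n_bins number of equal-frequency mean bins (default 20).
#' @return character vector of selected gene names.
#' @export
select_hvg <- function(expression, mean_min = 0.0125, mean_max = 3,
                       min_dispersion = 0.5, n_bins = 20) {
  X <- expm1(as.matrix(expression))
  mu <- colMeans(X)
  v <- apply(X, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  mean_log <- log1p(mu)
  # equal-frequency bins on mean; merge bins with < 2 members into neighbor
  br <- unique(stats::quantile(mean_log, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(mean_log, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- table(bins)
  small <- as.integer(names(tab)[tab < 2])
  for (b in small) {
    neighbor <- if (b > 1) b - 1L else b + 1L
    bins[bins == b] <- neighbor
  }
  bin_mean <- tapply(disp, bins, mean)
  bin_sd <- tapply(disp, bins, stats::sd)
  bin_sd[is.na(bin_sd) | bin_sd == 0] <- 1
  norm_disp <- (disp - bin_mean[as.character(bins)]) / bin_sd[as.character(bins)]
  keep <- mean_log >= mean_min & mean_log <= mean_max & norm_disp >= min_dispersion
  keep[is.na(keep)] <- FALSE
  colnames(expression)[keep]
}
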