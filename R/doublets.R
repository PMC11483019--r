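#' Detect doublets with a simulated-doublet kNN classifier
#'
#' Runs independently per sample. Within each sample, `n_synthetic` artificial
#' doublets are built by summing random cell pairs; real and synthetic profiles
#' are depth-normalized, log-transformed, reduced by PCA on the most variable
#' genes, and each real cell is scored by the fraction of synthetic doublets
#' among its `k_neighbors` nearest neighbors. Cells whose score exceeds
#' `threshold` are flagged. Deterministic under a fixed seed.
#'
#' @param counts a `CountMatrix`; the `sample` column of `cell_meta` defines
#'   the per-sample strata.
#' @param n_synthetic synthetic doublets per sample; `NULL` (default) uses the
#'   sample's cell count.
#' @param k_neighbors neighborhood size (default 30).
#' @param threshold synthetic-neighbor fraction above which a cell is flagged
#'   (default 0.5).
#' @param n_pcs PCA dimensionality for the joint embedding (default 15).
#' @param n_top_genes number of high-variance genes used (default 500).
#' @param seed integer seed.
#' @return named logical vector, `TRUE` for flagged cells.
#' @export
detect_doublets <- function(counts, n_synthetic = NULL, k_neighbors = 30,
                            threshold = 0.5, n_pcs = 15, n_top_genes = 500,
                            seed = 1L) {
  stopifnot(inherits(counts, "CountMatrix"))
  set.seed(seed)
  samples <- counts$cell_meta$sample
  flags <- stats::setNames(rep(FALSE, nrow(counts$counts)), rownames(counts$counts))
  for (s in unique(samples)) {
    idx <- which(samples == s)
    n <- length(idx)
    if (n < k_neighbors + 1) {
      warning("sample ", s, " has ", n, " cells (< k_neighbors + 1); no doublets flagged")
      next
    }
    raw <- counts$counts[idx, , drop = FALSE]
    n_syn <- if (is.null(n_synthetic)) n else n_synthetic
    p1 <- sample.int(n, n_syn, replace = TRUE)
    p2 <- sample.int(n, n_syn, replace = TRUE)
    syn <- raw[p1, , drop = FALSE] + raw[p2, , drop = FALSE]
    joint <- rbind(raw, syn)
    totals <- Matrix::rowSums(joint)
    totals[totals == 0] <- 1
    norm <- as.matrix(Matrix::Diagonal(x = 1000 / totals) %*% joint)
    norm <- log1p(norm)
    v <- apply(norm, 2, stats::var)
    top <- order(v, decreasing = TRUE)[seq_len(min(n_top_genes, ncol(norm)))]
    sub <- scale(norm[, top, drop = FALSE])
    sub[is.na(sub)] <- 0
    k_pc <- min(n_pcs, nrow(sub) - 1L, ncol(sub))
    pcs <- stats::prcomp(sub, rank. = k_pc, center = FALSE)$x
    d <- as.matrix(stats::dist(pcs))
    is_syn <- c(rep(FALSE, n), rep(TRUE, n_syn))
    k <- min(k_neighbors, nrow(d) - 1L)
    scores <- vapply(seq_len(n), function(i) {
      nn <- order(d[i, ])[2:(k + 1)]
      mean(is_syn[nn])
    }, numeric(1))
    flags[idx] <- scores > threshold
  }
  flags
}
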