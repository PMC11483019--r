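#' Genome ordering for copy-number profiling
#'
#' Orders genes by chromosome (chr1..chr22) and start coordinate, using 0-based
#' half-open intervals. Mitochondrial genes (chromosome "MT") and genes without
#' coordinates are excluded. Within each chromosome starts must be
#' non-decreasing, and each gene appears exactly once.
#'
#' @param gene_meta data.frame with `symbol`, `chromosome`, `start`, `end`
#'   columns (as in a `CountMatrix`), or a path to a BED-like TSV
#'   (chromosome, start, end, symbol).
#' @return data.frame (symbol, chromosome, start, end) in genome order.
#' @export
gene_ordering <- function(gene_meta) {
  if (is.character(gene_meta) && length(gene_meta) == 1) {
    bed <- utils::read.table(gene_meta, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    gene_meta <- data.frame(symbol = bed[[4]], chromosome = bed[[1]],
                            start = bed[[2]], end = bed[[3]],
                            stringsAsFactors = FALSE)
  }
  gm <- gene_meta[!is.na(gene_meta$chromosome) & gene_meta$chromosome != "MT",
                  c("symbol", "chromosome", "start", "end")]
  if (anyDuplicated(gm$symbol)) stop("duplicate gene symbols in ordering")
  chr_levels <- paste0("chr", 1:22)
  chr_levels <- c(chr_levels, setdiff(unique(gm$chromosome), chr_levels))
  gm <- gm[order(match(gm$chromosome, chr_levels), gm$start), ]
  rownames(gm) <- NULL
  gm
}

#' Windowed expression-derived copy-number profile
#'
#' Estimates a per-cell copy-number signal from expression deviations relative
#' to reference (non-malignant) cells: genes with mean normalized counts
#' (before log) under `expression_cutoff` are dropped; each gene is centered on
#' the reference-cell mean; centered values are averaged over consecutive
#' non-overlapping windows of `window` genes within each chromosome (the
#' regions); each cell is re-centered by its median region value; values are
#' clipped to `+-clip`.
#'
#' @param expression log-normalized cells x genes matrix.
#' @param ordering genome ordering from [gene_ordering()].
#' @param cell_types per-cell type labels (named or in matrix row order).
#' @param reference_types labels in `cell_types` to use as the diploid
#'   reference.
#' @param window genes per region (default 51).
#' @param expression_cutoff minimum mean normalized count (default 0.1).
#' @param clip symmetric bound on profile values (default 1).
#' @return cells x regions matrix with a `regions` attribute
#'   (`data.frame(region, chromosome, n_genes)`).
#' @export
cnv_profile <- function(expression, ordering, cell_types, reference_types,
                        window = 51, expression_cutoff = 0.1, clip = 1) {
  stopifnot(window >= 1)
  cell_types <- as.character(cell_types)
  ref_cells <- cell_types %in% reference_types
  if (!any(ref_cells)) stop("no reference cells: none typed as ",
                            paste(reference_types, collapse = ", "))
  genes <- intersect(ordering$symbol, colnames(expression))
  ord <- ordering[match(genes, ordering$symbol), ]
  X <- as.matrix(expression[, ord$symbol, drop = FALSE])
  mean_norm <- colMeans(expm1(X))
  keep <- mean_norm >= expression_cutoff
  X <- X[, keep, drop = FALSE]
  ord <- ord[keep, , drop = FALSE]
  if (ncol(X) == 0) stop("no genes pass the expression cutoff")

  centered <- sweep(X, 2, colMeans(X[ref_cells, , drop = FALSE]))
  # bound single-gene outliers (e.g. lineage markers) before averaging
  centered[centered > clip] <- clip
  centered[centered < -clip] <- -clip

  # non-overlapping windows of `window` genes within each chromosome; a
  # trailing remainder shorter than window/2 is merged into the last window
  chrs <- unique(ord$chromosome)
  region_chr <- character(0)
  region_cols <- list()
  small <- character(0)
  for (chr in chrs) {
    idx <- which(ord$chromosome == chr)
    if (length(idx) < window) {
      small <- c(small, chr)
      groups <- list(idx)
    } else {
      groups <- unname(split(idx, ceiling(seq_along(idx) / window)))
      last <- length(groups)
      if (last > 1 && length(groups[[last]]) < window / 2) {
        groups[[last - 1]] <- c(groups[[last - 1]], groups[[last]])
        groups[[last]] <- NULL
      }
    }
    region_cols <- c(region_cols, groups)
    region_chr <- c(region_chr, rep(chr, length(groups)))
  }
  if (length(small)) {
    warning("chromosome(s) with fewer genes than window, kept as single regions: ",
            paste(small, collapse = ", "))
  }
  profile <- vapply(region_cols, function(cols) {
    rowMeans(centered[, cols, drop = FALSE])
  }, numeric(nrow(centered)))
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = nrow(centered))
  profile <- profile - apply(profile, 1, stats::median)
  rownames(profile) <- rownames(expression)
  colnames(profile) <- sprintf("region_%03d", seq_len(ncol(profile)))
  attr(profile, "regions") <- data.frame(
    region = colnames(profile),
    chromosome = region_chr,
    n_genes = lengths(region_cols)
  )
  profile
}

#' Discretize copy-number profiles into per-cluster region states
#'
#' For each cluster, the mean profile per region is median-centered, optionally
#' median-filtered along the genome (width 5, within chromosomes), and
#' thresholded into a symmetric state-value set centered on 0 (neutral).
#' Clusters with fewer than 3 cells are assigned all-neutral with a warning.
#'
#' @param profile cells x regions matrix from [cnv_profile()].
#' @param cluster_labels per-cell cluster labels.
#' @param state_values centered state encoding, symmetric around 0
#'   (default `c(-1, -0.5, 0, 0.5, 1)`).
#' @param breaks thresholds between states, length `length(state_values) - 1`
#'   (default `c(-0.4, -0.15, 0.15, 0.4)`).
#' @param median_filter apply a width-5 running median within chromosomes
#'   before thresholding (default TRUE).
#' @return clusters x regions matrix of state values.
#' @export
discretize_states <- function(profile, cluster_labels,
                              state_values = c(-1, -0.5, 0, 0.5, 1),
                              breaks = c(-0.4, -0.15, 0.15, 0.4),
                              median_filter = TRUE) {
  stopifnot(length(breaks) == length(state_values) - 1,
            all(diff(breaks) > 0), 0 %in% state_values)
  clusters <- as.character(cluster_labels)
  cl_ids <- sort(unique(clusters))
  regions <- attr(profile, "regions")
  states <- matrix(0, length(cl_ids), ncol(profile),
                   dimnames = list(cl_ids, colnames(profile)))
  for (cl in cl_ids) {
    sel <- clusters == cl
    if (sum(sel) < 3) {
      warning("cluster ", cl, " has < 3 cells; assigned all-neutral")
      next
    }
    m <- colMeans(profile[sel, , drop = FALSE])
    m <- m - stats::median(m)
    if (median_filter && !is.null(regions)) {
      for (chr in unique(regions$chromosome)) {
        i <- which(regions$chromosome == chr)
        if (length(i) >= 5) m[i] <- stats::runmed(m[i], k = 5, endrule = "median")
      }
    }
    states[cl, ] <- state_values[findInterval(m, breaks) + 1L]
  }
  states
}

#' Cluster-level squared-deviation malignancy score
#'
#' The score of a cluster is the sum over regions of its squared centered
#' state values (neutral contributes 0); every cell then inherits its
#' cluster's score. The score is 0 iff all of the cluster's states are
#' neutral, and adding any non-neutral region can only increase it.
#'
#' @param region_states clusters x regions matrix of centered state values
#'   from [discretize_states()].
#' @param cluster_labels per-cell cluster labels (values must appear in
#'   `rownames(region_states)`).
#' @return `list(cluster_scores = named numeric, cell_scores = named numeric)`.
#' @export
malignancy_score <- function(region_states, cluster_labels) {
  cluster_scores <- rowSums(region_states^2)
  clusters <- as.character(cluster_labels)
  if (!all(clusters %in% rownames(region_states))) {
    stop("cluster label(s) absent from region_states rows")
  }
  cell_scores <- cluster_scores[clusters]
  names(cell_scores) <- names(cluster_labels)
  list(cluster_scores = cluster_scores, cell_scores = cell_scores)
}

#' Call malignant cells from malignancy scores
#'
#' The `threshold` method flags cells with score strictly greater than
#' `threshold`. The `bimodal` method fits a two-component Gaussian mixture to
#' `log1p(score)` and flags the upper component; when the fit is degenerate
#' (a single effective mode) it falls back to the threshold method with a
#' warning.
#'
#' @param cell_scores named numeric vector of per-cell scores.
#' @param method `"threshold"` or `"bimodal"`.
#' @param threshold cut for the threshold method / fallback (default 0).
#' @return named logical vector of malignant calls.
#' @export
call_malignant <- function(cell_scores, method = c("bimodal", "threshold"),
                           threshold = 0) {
  method <- match.arg(method)
  if (method == "threshold") return(cell_scores > threshold)
  x <- log1p(cell_scores)
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(x, G = 2, modelNames = "E", verbose = FALSE)),
    error = function(e) NULL)
  degenerate <- is.null(fit) ||
    abs(diff(fit$parameters$mean)) < 1e-6 ||
    length(unique(fit$classification)) < 2
  if (degenerate) {
    warning("bimodal fit degenerate; falling back to threshold = ", threshold)
    return(cell_scores > threshold)
  }
  upper <- which.max(fit$parameters$mean)
  out <- fit$classification == upper
  names(out) <- names(cell_scores)
  out
}
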