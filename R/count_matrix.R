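#' Sparse cell-by-gene count container
#'
#' Bundles a sparse nonnegative integer count matrix (cells in rows, genes in
#' columns) with cell-level metadata (sample, patient, timepoint, optional type
#' labels) and gene-level metadata (symbol, chromosome, start, end, mito flag).
#' This is the object every pipeline stage consumes and returns.
#'
#' @param counts sparse or dense cells x genes matrix of nonnegative integers;
#'   coerced to [Matrix::dgCMatrix-class]. Row names are cell barcodes, column
#'   names gene identifiers.
#' @param cell_meta data.frame with one row per cell. Must contain a `sample`
#'   column; `patient` and `timepoint` are carried when present.
#' @param gene_meta data.frame with one row per gene. Expected columns:
#'   `symbol`, `chromosome`, `start`, `end`, `mito` (logical).
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, cell_meta, gene_meta) {
  if (is.matrix(counts)) storage.mode(counts) <- "double"
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  if (nrow(cell_meta) != nrow(counts)) {
    stop("cell_meta has ", nrow(cell_meta), " rows but counts has ", nrow(counts), " cells")
  }
  if (nrow(gene_meta) != ncol(counts)) {
    stop("gene_meta has ", nrow(gene_meta), " rows but counts has ", ncol(counts), " genes")
  }
  if (is.null(rownames(counts))) rownames(counts) <- rownames(cell_meta)
  if (is.null(colnames(counts))) colnames(counts) <- gene_meta$symbol
  rownames(cell_meta) <- rownames(counts)
  rownames(gene_meta) <- colnames(counts)
  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "cells x", ncol(x$counts), "genes\n")
  cat("  cell_meta:", paste(names(x$cell_meta), collapse = ", "), "\n")
  cat("  gene_meta:", paste(names(x$gene_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a CountMatrix by cells and/or genes
#'
#' Metadata rows are kept aligned with the matrix. Order of retained cells and
#' genes follows the index vectors.
#'
#' @param x a `CountMatrix`
#' @param cells,genes logical, integer, or character index vectors; `NULL`
#'   keeps everything.
#' @return a `CountMatrix`
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  if (is.null(cells)) cells <- seq_len(nrow(x$counts))
  if (is.null(genes)) genes <- seq_len(ncol(x$counts))
  count_matrix(x$counts[cells, genes, drop = FALSE],
               x$cell_meta[cells, , drop = FALSE],
               x$gene_meta[genes, , drop = FALSE])
}
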