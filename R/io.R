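#' Write a synthetic cohort to a 10x-style directory
#'
#' Emits `matrix.mtx` (Matrix Market coordinate, genes x cells as in the 10x
#' triplet dialect), `barcodes.tsv`, `features.tsv` (gene id, symbol,
#' chromosome, start, end), `cells.tsv` (sample, patient, timepoint plus truth
#' columns when truth is supplied), and `truth_programs.gmt` with the planted
#' program gene blocks. Round-trips losslessly through [read_counts()].
#'
#' @param counts a `CountMatrix`.
#' @param truth optional `SyntheticTruth`; adds truth columns and the GMT file.
#' @param directory output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(counts, truth = NULL, directory, overwrite = FALSE) {
  if (dir.exists(directory) && length(dir(directory)) > 0 && !overwrite) {
    stop("directory ", directory, " exists and is not empty; set overwrite = TRUE")
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  mat <- Matrix::drop0(Matrix::t(counts$counts))  # genes x cells
  Matrix::writeMM(mat, file.path(directory, "matrix.mtx"))
  writeLines(rownames(counts$counts), file.path(directory, "barcodes.tsv"))
  gm <- counts$gene_meta
  utils::write.table(
    data.frame(gene_id = gm$gene_id, symbol = gm$symbol, chromosome = gm$chromosome,
               start = gm$start, end = gm$end),
    file.path(directory, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  cells <- counts$cell_meta[, intersect(c("sample", "patient", "timepoint"),
                                        names(counts$cell_meta)), drop = FALSE]
  if (!is.null(truth)) {
    cells$true_type <- unname(truth$true_type)
    cells$true_malignant <- unname(truth$true_malignant)
    cells$true_doublet <- unname(truth$true_doublet)
  }
  utils::write.table(cbind(barcode = rownames(counts$counts), cells),
                     file.path(directory, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    write_gmt(stats::setNames(truth$program_blocks,
                              rownames(truth$true_spectra)),
              file.path(directory, "truth_programs.gmt"))
  }
  invisible(directory)
}

#' Read a 10x-style triplet directory into a CountMatrix
#'
#' Expects `matrix.mtx` (genes x cells), `barcodes.tsv`, and `features.tsv`
#' (gene id, symbol, chromosome, start, end; only the first two columns are
#' required). The mitochondrial flag is set from gene symbols with the
#' (case-sensitive) prefix `"MT-"`. Cell metadata is taken from `cells.tsv`
#' when present. Duplicate gene symbols are retained under disambiguated
#' identifiers (`symbol.1`, `symbol.2`, ...) with a warning.
#'
#' @param directory path containing the triplet files.
#' @return a `CountMatrix` (cells x genes).
#' @export
read_counts <- function(directory) {
  need <- c("matrix.mtx", "barcodes.tsv", "features.tsv")
  missing <- need[!file.exists(file.path(directory, need))]
  if (length(missing)) stop("missing input file(s): ", paste(missing, collapse = ", "))
  mat <- Matrix::readMM(file.path(directory, "matrix.mtx"))
  barcodes <- readLines(file.path(directory, "barcodes.tsv"))
  feats <- utils::read.table(file.path(directory, "features.tsv"), sep = "\t",
                             header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
  if (nrow(feats) != nrow(mat)) {
    stop("format error: features.tsv has ", nrow(feats),
         " rows but matrix.mtx declares ", nrow(mat), " genes")
  }
  if (length(barcodes) != ncol(mat)) {
    stop("format error: barcodes.tsv has ", length(barcodes),
         " rows but matrix.mtx declares ", ncol(mat), " cells")
  }
  symbols <- feats[[min(2L, ncol(feats))]]
  if (anyDuplicated(symbols)) {
    warning("duplicate gene symbols in features.tsv; identifiers disambiguated")
    symbols <- make.unique(symbols)
  }
  gene_meta <- data.frame(
    gene_id = feats[[1]],
    symbol = symbols,
    chromosome = if (ncol(feats) >= 3) feats[[3]] else NA_character_,
    start = if (ncol(feats) >= 4) as.integer(feats[[4]]) else NA_integer_,
    end = if (ncol(feats) >= 5) as.integer(feats[[5]]) else NA_integer_,
    stringsAsFactors = FALSE
  )
  gene_meta$mito <- startsWith(gene_meta$symbol, "MT-")
  cells_path <- file.path(directory, "cells.tsv")
  if (file.exists(cells_path)) {
    cells <- utils::read.table(cells_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    rownames(cells) <- cells$barcode
    cells$barcode <- NULL
    cell_meta <- cells[barcodes, , drop = FALSE]
  } else {
    cell_meta <- data.frame(sample = rep("sample1", length(barcodes)),
                            row.names = barcodes, stringsAsFactors = FALSE)
  }
  counts <- Matrix::t(mat)
  rownames(counts) <- barcodes
  colnames(counts) <- gene_meta$symbol
  count_matrix(counts, cell_meta, gene_meta)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (set name, description, member genes per line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path. The description column is set to the set name.
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
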