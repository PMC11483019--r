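#' Control-subtracted gene-set score
#'
#' Scores each cell as the mean expression of the set genes minus the mean of
#' control genes sampled from the same expression-level bins: all genes are
#' binned into `n_control_bins` equal-frequency bins by mean expression, and
#' each set gene contributes `n_control_per_gene` controls drawn (with
#' replacement) from its bin. Deterministic under `seed`.
#'
#' @param expression log-normalized cells x genes matrix.
#' @param gene_set character vector of gene symbols.
#' @param n_control_bins expression bins (default 25).
#' @param n_control_per_gene controls per set gene (default 50).
#' @param seed integer seed for the control draw.
#' @return named numeric vector of per-cell scores.
#' @export
score_gene_set <- function(expression, gene_set, n_control_bins = 25,
                           n_control_per_gene = 50, seed = 1L) {
  genes <- colnames(expression)
  set_genes <- intersect(gene_set, genes)
  if (!length(set_genes)) {
    stop("no gene-set genes measured; missing: ",
         paste(utils::head(setdiff(gene_set, genes), 10), collapse = ", "))
  }
  mu <- Matrix::colMeans(expression)
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_control_bins + 1)))
  bins <- cut(mu, breaks = br, include.lowest = TRUE, labels = FALSE)
  names(bins) <- genes
  set.seed(seed)
  controls <- unlist(lapply(set_genes, function(g) {
    pool <- genes[bins == bins[[g]]]
    sample(pool, n_control_per_gene, replace = TRUE)
  }), use.names = FALSE)
  set_mean <- Matrix::rowMeans(expression[, set_genes, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(expression[, controls, drop = FALSE])
  out <- as.numeric(set_mean - ctrl_mean)
  names(out) <- rownames(expression)
  out
}

#' Top-weighted genes of each program
#'
#' @param spectra programs x genes weight matrix.
#' @param n genes per program (default 50); when `n` exceeds the gene count all
#'   genes are returned with a warning. Ties are broken by gene order.
#' @return named list of character vectors, one per program.
#' @export
top_program_genes <- function(spectra, n = 50) {
  if (n > ncol(spectra)) {
    warning("n exceeds gene count; returning all genes")
    n <- ncol(spectra)
  }
  out <- lapply(seq_len(nrow(spectra)), function(p) {
    w <- spectra[p, ]
    colnames(spectra)[order(-w, seq_along(w))[seq_len(n)]]
  })
  names(out) <- rownames(spectra)
  out
}

#' Classify malignant cells into tumor states
#'
#' Assigns each malignant cell one of the five biliary-tract-cancer states
#' (classical, basal, mesenchymal, neural-like, endothelial-like) by argmax of
#' its per-state activity, except that cells with both mesenchymal and
#' neural-like activity at or above `intermediate_threshold` are called
#' "intermediate". Activities are cNMF usages or gene-set scores; exact argmax
#' ties are broken lexicographically by state name and recorded with margin 0.
#'
#' @param state_scores cells x states matrix of activities; column names must
#'   include the five state names.
#' @param states the five state names (default
#'   `c("basal", "classical", "endothelial-like", "mesenchymal", "neural-like")`).
#' @param intermediate_pair the co-activity pair triggering "intermediate"
#'   (default mesenchymal + neural-like).
#' @param intermediate_threshold co-activity cut (default 0.25); set above the
#'   activity range (e.g. > 1 for normalized usages) to disable the rule.
#' @return data.frame (cell, state, margin, one score column per state).
#' @export
assign_tumor_states <- function(state_scores,
                                states = c("basal", "classical",
                                           "endothelial-like", "mesenchymal",
                                           "neural-like"),
                                intermediate_pair = c("mesenchymal", "neural-like"),
                                intermediate_threshold = 0.25) {
  missing <- setdiff(states, colnames(state_scores))
  if (length(missing)) {
    stop("configuration error: missing state score(s): ",
         paste(missing, collapse = ", "))
  }
  S <- as.matrix(state_scores[, sort(states), drop = FALSE])
  ord <- t(apply(S, 1, function(r) order(-r)))
  top <- colnames(S)[ord[, 1]]
  second <- S[cbind(seq_len(nrow(S)), ord[, 2])]
  best <- S[cbind(seq_len(nrow(S)), ord[, 1])]
  margin <- best - second
  call <- top
  inter <- S[, intermediate_pair[1]] >= intermediate_threshold &
    S[, intermediate_pair[2]] >= intermediate_threshold
  call[inter] <- "intermediate"
  out <- data.frame(cell = rownames(S) %||% seq_len(nrow(S)),
                    state = call, margin = margin,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(S))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlate discovered program activities with reference program activities
#'
#' Pearson correlation between every discovered-program score vector and every
#' reference-program score vector over the same cells. Zero-variance vectors
#' yield `NA` correlations with a warning. A best-match table is attached as
#' `attr(out, "best_match")`.
#'
#' @param discovered cells x programs activity matrix.
#' @param reference cells x reference-programs activity matrix (same cells).
#' @return discovered x reference correlation matrix.
#' @export
map_programs_to_reference <- function(discovered, reference) {
  if (nrow(discovered) != nrow(reference)) {
    stop("score sets must cover the same cells")
  }
  sd_d <- apply(discovered, 2, stats::sd)
  sd_r <- apply(reference, 2, stats::sd)
  if (any(sd_d == 0) || any(sd_r == 0)) {
    warning("zero-variance score vector(s); correlations reported as NA")
  }
  out <- suppressWarnings(stats::cor(as.matrix(discovered), as.matrix(reference)))
  out[sd_d == 0, ] <- NA_real_
  out[, sd_r == 0] <- NA_real_
  best <- data.frame(
    program = rownames(out),
    best_reference = colnames(out)[apply(out, 1, function(r) {
      if (all(is.na(r))) NA_integer_ else which.max(r)
    })],
    correlation = apply(out, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  attr(out, "best_match") <- best
  out
}
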