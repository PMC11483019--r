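# Shared synthetic fixtures, built once per session and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small mixed cohort with planted CNVs, used across qc / cnv tests
small_cnv_cohort <- function() {
  fixture("small_cnv", function() {
    cfg <- cohort_config(
      n_patients = 2, cells_per_sample = 150, n_genes = 900, depth_mean = 5000,
      malignant_fraction = 0.4, n_programs = 3,
      cnv_segments = list(
        list(chromosome = "chr1", start_gene_index = 1, end_gene_index = 30,
             fold_change = 2),
        list(chromosome = "chr7", start_gene_index = 1, end_gene_index = 30,
             fold_change = 0.5)),
      seed = 7L)
    generate_cohort(cfg)
  })
}

# all-tumor cohort with 5 planted programs, used by cnmf / state tests
program_cohort <- function() {
  fixture("programs", function() {
    cfg <- cohort_config(
      n_patients = 2, cells_per_sample = 300, n_genes = 1200, n_programs = 5,
      malignant_fraction = 1, depth_mean = 2500, mito_gene_fraction = 0,
      program_overdispersion = 0.2, seed = 11L)
    generate_cohort(cfg)
  })
}

# planted spectra mapped through the measurement transform the factorization
# sees: expected normalized expression of a pure-program cell (target sum
# 1000), log1p, then the same per-gene sd scaling as prepare_matrix
observable_truth_spectra <- function(truth, expression, cols) {
  sp <- truth$true_spectra[, cols, drop = FALSE]
  obs <- log1p(sp * 1000)
  sds <- apply(as.matrix(expression[, cols, drop = FALSE]), 2, sd)
  sweep(obs, 2, sds, "/")
}

normalized_expression <- function(cohort) {
  normalize_log(filter_matrix(cohort$counts))
}

# mean cosine similarity under the best program-to-truth assignment
# (exhaustive over permutations; oracle-grade for k <= 7)
best_match_cosines <- function(spectra, truth_spectra) {
  truth <- truth_spectra[, colnames(spectra), drop = FALSE]
  truth <- truth / sqrt(rowSums(truth^2))
  sp <- spectra / sqrt(rowSums(spectra^2))
  cs <- sp %*% t(truth)
  k <- nrow(cs)
  perms <- perm_all(k)
  best <- -Inf
  best_assign <- NULL
  for (p in perms) {
    v <- mean(cs[cbind(seq_len(k), p)])
    if (v > best) {
      best <- v
      best_assign <- p
    }
  }
  list(cosines = cs[cbind(seq_len(k), best_assign)], assignment = best_assign)
}

perm_all <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in perm_all(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}
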