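#' Configuration for a synthetic tumor-biopsy cohort
#'
#' Defines the cohort layout (patients x timepoints), the per-cell generative
#' model (planted gene expression programs, negative-binomial overdispersion,
#' sequencing depth), and the malignant-cell features the downstream analysis
#' must recover (chromosome-arm-scale expression shifts, doublets,
#' mitochondrial-fraction variation).
#'
#' Samples are laid out as the full patient x timepoint grid, so `n_samples`
#' must equal `n_patients * length(timepoints_per_patient)`.
#'
#' @param n_patients number of patients.
#' @param timepoints_per_patient character vector of timepoint labels drawn
#'   from `c("pre", "on")`; every patient contributes one sample per label.
#' @param cells_per_sample cells generated per sample.
#' @param n_genes total genes, including mitochondrial genes.
#' @param n_programs number of planted gene expression programs used by tumor
#'   cells.
#' @param program_overdispersion negative-binomial overdispersion phi shared
#'   across genes (variance = mu + phi * mu^2); 0 gives Poisson counts.
#' @param cnv_segments list of `list(chromosome=, start_gene_index=,
#'   end_gene_index=, fold_change=)` with 1-based inclusive within-chromosome
#'   gene indices; fold changes are multiplied into malignant cells' rates.
#' @param malignant_fraction fraction of each sample's cells that are tumor
#'   cells, in `[0, 1]`.
#' @param doublet_rate fraction of cells replaced by synthetic doublets after
#'   generation, in `[0, 1)`.
#' @param mito_gene_fraction fraction of genes that are mitochondrial
#'   (chromosome "MT", symbols prefixed "MT-").
#' @param depth_mean expected total counts per cell.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return a validated `CohortConfig` list.
#' @export
cohort_config <- function(n_patients = 4,
                          timepoints_per_patient = c("pre", "on"),
                          cells_per_sample = 250,
                          n_genes = 1000,
                          n_programs = 5,
                          program_overdispersion = 0.3,
                          cnv_segments = list(),
                          malignant_fraction = 0.4,
                          doublet_rate = 0,
                          mito_gene_fraction = 0.03,
                          depth_mean = 2000,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              timepoints_per_patient = as.character(timepoints_per_patient),
              n_samples = as.integer(n_patients) * length(timepoints_per_patient),
              cells_per_sample = as.integer(cells_per_sample),
              n_genes = as.integer(n_genes),
              n_programs = as.integer(n_programs),
              program_overdispersion = program_overdispersion,
              cnv_segments = cnv_segments,
              malignant_fraction = malignant_fraction,
              doublet_rate = doublet_rate,
              mito_gene_fraction = mito_gene_fraction,
              depth_mean = depth_mean,
              seed = as.integer(seed))
  class(cfg) <- "CohortConfig"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  counts_ok <- c(n_patients = cfg$n_patients, cells_per_sample = cfg$cells_per_sample,
                 n_genes = cfg$n_genes, n_programs = cfg$n_programs)
  bad <- names(counts_ok)[counts_ok < 1L]
  if (length(bad)) stop("invalid config: ", paste(bad, collapse = ", "), " must be >= 1")
  if (!all(cfg$timepoints_per_patient %in% c("pre", "on"))) {
    stop("invalid config: timepoints must be drawn from {pre, on}")
  }
  props <- c(malignant_fraction = cfg$malignant_fraction,
             mito_gene_fraction = cfg$mito_gene_fraction)
  if (any(props < 0 | props > 1)) stop("invalid config: proportions must lie in [0, 1]")
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 1) {
    stop("invalid config: doublet_rate must lie in [0, 1)")
  }
  if (cfg$n_programs > cfg$n_genes) stop("invalid config: n_programs > n_genes")
  if (cfg$depth_mean <= 0) stop("invalid config: depth_mean must be positive")
  if (cfg$program_overdispersion < 0) stop("invalid config: overdispersion must be >= 0")
  gm <- synth_gene_meta(cfg$n_genes, cfg$mito_gene_fraction)
  per_chr <- table(gm$chromosome[gm$chromosome != "MT"])
  seen <- list()
  for (seg in cfg$cnv_segments) {
    need <- c("chromosome", "start_gene_index", "end_gene_index", "fold_change")
    if (!all(need %in% names(seg))) stop("invalid config: cnv segment missing fields")
    chr <- as.character(seg$chromosome)
    if (!chr %in% names(per_chr)) stop("invalid config: unknown chromosome ", chr)
    if (seg$start_gene_index < 1 || seg$end_gene_index > per_chr[[chr]] ||
        seg$start_gene_index > seg$end_gene_index) {
      stop("invalid config: cnv segment indices out of range on ", chr)
    }
    if (seg$fold_change <= 0) stop("invalid config: fold_change must be positive")
    for (prev in seen[[chr]]) {
      if (seg$start_gene_index <= prev[2] && seg$end_gene_index >= prev[1]) {
        stop("invalid config: overlapping cnv segments on ", chr)
      }
    }
    seen[[chr]] <- c(seen[[chr]], list(c(seg$start_gene_index, seg$end_gene_index)))
  }
  invisible(cfg)
}

# Gene metadata: autosomal genes spread uniformly over 22 chromosomes in order,
# 0-based half-open intervals; mitochondrial genes last, on "MT".
synth_gene_meta <- function(n_genes, mito_gene_fraction) {
  n_mito <- round(mito_gene_fraction * n_genes)
  n_auto <- n_genes - n_mito
  chr <- rep(paste0("chr", 1:22), length.out = 0)
  sizes <- diff(floor(seq(0, n_auto, length.out = 23)))
  chr <- rep(paste0("chr", 1:22), times = sizes)
  pos <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  gm <- data.frame(
    gene_id = sprintf("GENE%05d", seq_len(n_genes)),
    symbol = c(sprintf("G%05d", seq_len(n_auto)),
               if (n_mito > 0) sprintf("MT-G%03d", seq_len(n_mito))),
    chromosome = c(chr, rep("MT", n_mito)),
    start = c((pos - 1L) * 1000L, if (n_mito > 0) (seq_len(n_mito) - 1L) * 100L),
    end = c((pos - 1L) * 1000L + 500L, if (n_mito > 0) (seq_len(n_mito) - 1L) * 100L + 50L),
    stringsAsFactors = FALSE
  )
  gm$mito <- gm$chromosome == "MT"
  gm
}

#' Generate a ground-truthed synthetic cohort
#'
#' Draws counts per cell from a depth-scaled Poisson (or negative binomial when
#' `program_overdispersion > 0`) around `usage \%*\% spectra`. Tumor cells mix
#' the planted programs with a Dirichlet-dominant usage; the five non-malignant
#' types (T, myeloid, NK, endothelial, fibroblast) are generated from disjoint
#' marker-gene blocks over a shared baseline, which makes marker-based
#' annotation solvable. When `cnv_segments` is non-empty, tumor cells are
#' malignant and the fold changes are multiplied into their segment-gene rates
#' (profiles renormalized, so depth is unchanged and the within-cell
#' segment-to-flank rate ratio equals the fold change exactly).
#'
#' @param config a [cohort_config()].
#' @return `list(counts = CountMatrix, truth = SyntheticTruth)` where truth
#'   holds `true_usages` (unit row sums), `true_spectra` (rows sum to 1),
#'   `true_type`, `true_malignant`, `true_doublet`, and the marker/program gene
#'   blocks used for generation.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  gm <- synth_gene_meta(config$n_genes, config$mito_gene_fraction)
  n_genes <- config$n_genes
  auto_idx <- which(!gm$mito)
  mito_idx <- which(gm$mito)

  # shared baseline gene weights, heavy-tailed
  baseline <- stats::rgamma(n_genes, shape = 0.4, rate = 1) + 0.02
  if (length(mito_idx)) baseline[mito_idx] <- mean(baseline[auto_idx])

  # disjoint gene blocks: first the program blocks, then marker blocks
  block_size <- max(10L, round(0.02 * n_genes))
  marker_size <- max(8L, round(0.01 * n_genes))
  normal_types <- c("T", "myeloid", "NK", "endothelial", "fibroblast")
  need <- config$n_programs * block_size + length(normal_types) * marker_size
  if (need > length(auto_idx)) {
    block_size <- max(5L, floor(length(auto_idx) / (config$n_programs + length(normal_types)) * 0.6))
    marker_size <- block_size
  }
  pool <- sample(auto_idx)
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  program_blocks <- lapply(seq_len(config$n_programs), function(p) sort(take(block_size)))
  marker_blocks <- lapply(normal_types, function(t) sort(take(marker_size)))
  names(marker_blocks) <- normal_types

  # program spectra: baseline everywhere, block genes strongly up-weighted
  spectra <- matrix(rep(baseline, each = config$n_programs),
                    nrow = config$n_programs, ncol = n_genes)
  for (p in seq_len(config$n_programs)) {
    spectra[p, program_blocks[[p]]] <-
      spectra[p, program_blocks[[p]]] * stats::rgamma(block_size, shape = 8, rate = 1)
  }
  spectra <- spectra / rowSums(spectra)
  rownames(spectra) <- sprintf("program_%d", seq_len(config$n_programs))
  colnames(spectra) <- gm$symbol

  # non-malignant type profiles: baseline with the type's marker block boosted
  type_profiles <- sapply(normal_types, function(t) {
    pr <- baseline
    pr[marker_blocks[[t]]] <- pr[marker_blocks[[t]]] * 12
    pr / sum(pr)
  })

  # cohort layout
  samples <- expand.grid(timepoint = config$timepoints_per_patient,
                         patient = sprintf("P%02d", seq_len(config$n_patients)),
                         stringsAsFactors = FALSE)[, c("patient", "timepoint")]
  samples$sample <- paste0(samples$patient, "_", samples$timepoint)
  n_cells <- config$n_samples * config$cells_per_sample

  cell_meta <- data.frame(
    sample = rep(samples$sample, each = config$cells_per_sample),
    patient = rep(samples$patient, each = config$cells_per_sample),
    timepoint = rep(samples$timepoint, each = config$cells_per_sample),
    stringsAsFactors = FALSE
  )
  rownames(cell_meta) <- sprintf("CELL%06d", seq_len(n_cells))

  # per-sample cell types
  n_mal <- round(config$malignant_fraction * config$cells_per_sample)
  true_type <- character(n_cells)
  for (s in seq_len(config$n_samples)) {
    idx <- (s - 1L) * config$cells_per_sample + seq_len(config$cells_per_sample)
    types <- c(rep("tumor", n_mal),
               sample(normal_types, config$cells_per_sample - n_mal, replace = TRUE))
    true_type[idx] <- sample(types)
  }
  tumor <- true_type == "tumor"
  has_cnv <- length(config$cnv_segments) > 0
  true_malignant <- tumor & has_cnv

  # tumor usages: Dirichlet with one dominant program per cell
  usages <- matrix(1 / config$n_programs, n_cells, config$n_programs,
                   dimnames = list(rownames(cell_meta), rownames(spectra)))
  if (any(tumor)) {
    nt <- sum(tumor)
    dominant <- sample.int(config$n_programs, nt, replace = TRUE)
    alpha <- matrix(0.25, nt, config$n_programs)
    alpha[cbind(seq_len(nt), dominant)] <- 6
    draws <- matrix(stats::rgamma(nt * config$n_programs, shape = as.vector(alpha)),
                    nt, config$n_programs)
    usages[tumor, ] <- draws / rowSums(draws)
  }

  # expected profiles
  profiles <- matrix(0, n_cells, n_genes)
  profiles[tumor, ] <- usages[tumor, , drop = FALSE] %*% spectra
  for (t in normal_types) {
    sel <- true_type == t
    if (any(sel)) profiles[sel, ] <- matrix(type_profiles[, t], sum(sel), n_genes, byrow = TRUE)
  }

  # per-cell mitochondrial tilt
  if (length(mito_idx)) {
    mito_frac <- stats::rbeta(n_cells, 2, 22)
    mito_unit <- baseline[mito_idx] / sum(baseline[mito_idx])
    nonmito <- profiles[, auto_idx, drop = FALSE]
    nonmito <- nonmito / rowSums(nonmito)
    profiles[, auto_idx] <- nonmito * (1 - mito_frac)
    profiles[, mito_idx] <- outer(mito_frac, mito_unit)
  }

  # planted copy-number fold changes in malignant cells
  if (has_cnv && any(true_malignant)) {
    fold <- rep(1, n_genes)
    for (seg in config$cnv_segments) {
      chr_genes <- which(gm$chromosome == as.character(seg$chromosome))
      fold[chr_genes[seg$start_gene_index:seg$end_gene_index]] <- seg$fold_change
    }
    mal <- which(true_malignant)
    shifted <- profiles[mal, , drop = FALSE] *
      matrix(fold, length(mal), n_genes, byrow = TRUE)
    profiles[mal, ] <- shifted / rowSums(shifted)
  }

  mu <- profiles * config$depth_mean
  phi <- config$program_overdispersion
  if (phi > 0) {
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(t(mu)), size = 1 / phi),
                     n_cells, n_genes, byrow = TRUE)
  } else {
    counts <- matrix(stats::rpois(length(mu), as.vector(t(mu))), n_cells, n_genes,
                     byrow = TRUE)
  }
  dimnames(counts) <- list(rownames(cell_meta), gm$symbol)

  cm <- count_matrix(Matrix::Matrix(counts, sparse = TRUE), cell_meta, gm)
  truth <- list(
    true_usages = usages,
    true_spectra = spectra,
    true_type = stats::setNames(true_type, rownames(cell_meta)),
    true_malignant = stats::setNames(true_malignant, rownames(cell_meta)),
    true_doublet = stats::setNames(rep(FALSE, n_cells), rownames(cell_meta)),
    doublet_parents = NULL,
    program_blocks = lapply(program_blocks, function(i) gm$symbol[i]),
    marker_blocks = lapply(marker_blocks, function(i) gm$symbol[i])
  )
  class(truth) <- "SyntheticTruth"

  if (config$doublet_rate > 0) {
    injected <- inject_doublets(cm, truth, config$doublet_rate,
                                seed = config$seed + 1L)
    cm <- injected$counts
    truth <- injected$truth
  }
  list(counts = cm, truth = truth)
}

#' Replace a fraction of cells with synthetic doublets
#'
#' `floor(rate * n)` cells are replaced in place by the sum of two distinct
#' randomly chosen parent cells' counts (parents drawn from the original
#' matrix). Truth gains `true_doublet` flags and the two parent types.
#'
#' @param counts a `CountMatrix`.
#' @param truth the matching `SyntheticTruth`.
#' @param rate fraction of cells to replace, in `[0, 1)`.
#' @param seed integer seed.
#' @return `list(counts=, truth=)` with updated objects.
#' @export
inject_doublets <- function(counts, truth, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("doublet rate must lie in [0, 1)")
  if (rate == 0) return(list(counts = counts, truth = truth))
  set.seed(seed)
  n <- nrow(counts$counts)
  n_dbl <- floor(rate * n)
  if (n_dbl == 0) return(list(counts = counts, truth = truth))
  targets <- sample.int(n, n_dbl)
  parents <- t(vapply(seq_len(n_dbl), function(i) sample.int(n, 2), integer(2)))
  mat <- counts$counts
  mat[targets, ] <- mat[parents[, 1], , drop = FALSE] + mat[parents[, 2], , drop = FALSE]
  truth$true_doublet[targets] <- TRUE
  pt <- data.frame(parent1 = truth$true_type[parents[, 1]],
                   parent2 = truth$true_type[parents[, 2]],
                   row.names = rownames(counts$counts)[targets],
                   stringsAsFactors = FALSE)
  truth$doublet_parents <- pt
  truth$true_type[targets] <- truth$true_type[parents[, 1]]
  list(counts = count_matrix(mat, counts$cell_meta, counts$gene_meta), truth = truth)
}
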