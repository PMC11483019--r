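test_that("config validation rejects impossible cohorts", {
  expect_error(cohort_config(n_genes = 10, n_programs = 20), "n_programs")
  expect_error(cohort_config(depth_mean = 0), "depth_mean")
  expect_error(cohort_config(malignant_fraction = 1.2), "proportions")
  expect_error(cohort_config(doublet_rate = 1), "doublet_rate")
  expect_error(cohort_config(cnv_segments = list(
    list(chromosome = "chr1", start_gene_index = 1, end_gene_index = 5000,
         fold_change = 2))), "out of range")
  expect_error(cohort_config(cnv_segments = list(
    list(chromosome = "chr1", start_gene_index = 1, end_gene_index = 10, fold_change = 2),
    list(chromosome = "chr1", start_gene_index = 5, end_gene_index = 12, fold_change = 0.5))),
    "overlapping")
})

test_that("degenerate config gives no malignant cells and no doublets", {
  cfg <- cohort_config(n_patients = 1, cells_per_sample = 60, n_genes = 300,
                       doublet_rate = 0, cnv_segments = list(), seed = 3L)
  g <- generate_cohort(cfg)
  expect_false(any(g$truth$true_malignant))
  expect_false(any(g$truth$true_doublet))
})

test_that("generation is deterministic and structurally sound", {
  cfg <- cohort_config(n_patients = 1, cells_per_sample = 80, n_genes = 400,
                       doublet_rate = 0.05, seed = 5L)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$counts$counts, g2$counts$counts)
  expect_identical(g1$truth$true_usages, g2$truth$true_usages)
  # counts are nonnegative integers
  expect_true(all(g1$counts$counts@x >= 0))
  expect_true(all(g1$counts$counts@x == round(g1$counts$counts@x)))
  # usage rows sum to 1
  expect_equal(rowSums(g1$truth$true_usages),
               setNames(rep(1, nrow(g1$truth$true_usages)),
                        rownames(g1$truth$true_usages)),
               tolerance = 1e-9)
  # doublets record their two parent types
  expect_equal(sum(g1$truth$true_doublet), floor(0.05 * 160))
  expect_equal(nrow(g1$truth$doublet_parents), sum(g1$truth$true_doublet))
})

test_that("per-cell depth matches depth_mean within 3 standard errors", {
  cfg <- cohort_config(n_patients = 2, cells_per_sample = 300, n_genes = 500,
                       depth_mean = 2000, program_overdispersion = 0, seed = 9L)
  g <- generate_cohort(cfg)
  totals <- Matrix::rowSums(g$counts$counts)
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 2000), 3 * se)
})

test_that("planted fold-change doubles segment-gene expression in malignant cells", {
  # Monte-Carlo check against the generative rates: at a fold change of 2 the
  # within-cell rate ratio of segment genes to equal-baseline flank genes is 2
  cfg <- cohort_config(n_patients = 1, cells_per_sample = 10000, n_genes = 300,
                       malignant_fraction = 1, n_programs = 2,
                       mito_gene_fraction = 0, program_overdispersion = 0,
                       depth_mean = 3000,
                       cnv_segments = list(list(chromosome = "chr10",
                                                start_gene_index = 1,
                                                end_gene_index = 13,
                                                fold_change = 2)),
                       seed = 13L)
  g <- generate_cohort(cfg)
  gm <- g$counts$gene_meta
  seg <- which(gm$chromosome == "chr10")
  flank <- which(gm$chromosome %in% c("chr9", "chr11"))
  expect_true(all(g$truth$true_malignant))
  # expected (pre-fold) rates per gene, averaged over cells
  rates <- g$truth$true_usages %*% g$truth$true_spectra
  base_seg <- colMeans(rates[, seg])
  base_flank <- colMeans(rates[, flank])
  obs_seg <- Matrix::colMeans(g$counts$counts[, seg]) / base_seg
  obs_flank <- Matrix::colMeans(g$counts$counts[, flank]) / base_flank
  # rate-normalized segment counts should be ~2x the flank, within 5%
  ratio <- mean(obs_seg) / mean(obs_flank)
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("gene means converge to usage %*% spectra without overdispersion", {
  cfg <- cohort_config(n_patients = 1, cells_per_sample = 4000, n_genes = 300,
                       malignant_fraction = 1, n_programs = 3,
                       mito_gene_fraction = 0, program_overdispersion = 0,
                       depth_mean = 5000, seed = 17L)
  g <- generate_cohort(cfg)
  expected <- colMeans(g$truth$true_usages %*% g$truth$true_spectra) * 5000
  observed <- Matrix::colMeans(g$counts$counts)
  hi <- expected > 1
  rel <- abs(observed[hi] - expected[hi]) / expected[hi]
  expect_lt(stats::quantile(rel, 0.95), 0.05)
})

test_that("inject_doublets is additive, exact in count, and identity at rate 0", {
  g <- small_cnv_cohort()
  out0 <- inject_doublets(g$counts, g$truth, rate = 0, seed = 1)
  expect_identical(out0$counts$counts, g$counts$counts)
  expect_error(inject_doublets(g$counts, g$truth, rate = 1), "rate")

  out <- inject_doublets(g$counts, g$truth, rate = 0.1, seed = 2)
  n <- nrow(g$counts$counts)
  expect_equal(sum(out$truth$true_doublet), floor(0.1 * n))
  # spot-check additivity: every doublet total is a sum of two parent totals,
  # so doublet totals exceed the minimum possible parent-pair total
  dbl <- which(out$truth$true_doublet)
  tot_orig <- Matrix::rowSums(g$counts$counts)
  tot_new <- Matrix::rowSums(out$counts$counts)
  expect_true(all(tot_new[dbl] >= 2 * min(tot_orig)))
})

test_that("write_cohort round-trips through read_counts", {
  g <- small_cnv_cohort()
  dir <- withr::local_tempdir()
  write_cohort(g$counts, g$truth, file.path(dir, "cohort"))
  expect_error(write_cohort(g$counts, g$truth, file.path(dir, "cohort")),
               "overwrite")
  back <- read_counts(file.path(dir, "cohort"))
  expect_equal(unname(as.matrix(back$counts)), unname(as.matrix(g$counts$counts)))
  expect_identical(rownames(back$counts), rownames(g$counts$counts))
  expect_identical(back$gene_meta$symbol, g$counts$gene_meta$symbol)
  expect_identical(back$cell_meta$sample, g$counts$cell_meta$sample)
  expect_identical(back$cell_meta$true_type, unname(g$truth$true_type))
  # sparse contract: no explicit zeros in the triplet file
  mtx <- readLines(file.path(dir, "cohort", "matrix.mtx"))
  body <- mtx[-(1:2)]
  vals <- as.numeric(vapply(strsplit(body, " "), `[`, character(1), 3))
  expect_true(all(vals != 0))
  # features.tsv row count equals n_genes
  feats <- readLines(file.path(dir, "cohort", "features.tsv"))
  expect_length(feats, ncol(g$counts$counts))
  # truth programs round-trip as GMT
  gmt <- read_gmt(file.path(dir, "cohort", "truth_programs.gmt"))
  expect_length(gmt, nrow(g$truth$true_spectra))
})
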