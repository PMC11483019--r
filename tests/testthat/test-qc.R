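# hand-built CountMatrix for exact filter checks
tiny_counts <- function(mat, mito = NULL, sample = "s1") {
  n_genes <- ncol(mat)
  symbols <- sprintf("G%03d", seq_len(n_genes))
  if (!is.null(mito)) symbols[mito] <- sprintf("MT-%03d", mito)
  gm <- data.frame(gene_id = symbols, symbol = symbols,
                   chromosome = "chr1", start = seq_len(n_genes) * 10,
                   end = seq_len(n_genes) * 10 + 5,
                   mito = seq_len(n_genes) %in% (mito %||% integer(0)))
  cm <- data.frame(sample = rep(sample, nrow(mat)),
                   row.names = sprintf("C%03d", seq_len(nrow(mat))))
  count_matrix(mat, cm, gm)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("filter_matrix applies each cell criterion and then the gene filter", {
  # 5 cells x 60 genes; cell 1 expresses 40 genes (< 50), cell 2 has 26% mito,
  # cell 3 has 150 total counts (< 200); cells 4-5 pass everything
  mat <- matrix(0, 5, 60)
  mat[1, 1:40] <- 10                      # 40 genes, 400 counts
  mat[2, 1:50] <- 8; mat[2, 60] <- 140    # 540 total, 140 mito = 25.9%
  mat[3, 1:50] <- 3                       # 150 counts
  mat[4, 1:55] <- 10
  mat[5, 2:56] <- 10
  cm <- tiny_counts(mat, mito = 60)
  out <- filter_matrix(cm)
  expect_identical(rownames(out$counts), c("C004", "C005"))
  # gene 1 is detected only in cell 4 among retained cells -> dropped (needs 3)
  expect_false("G001" %in% colnames(out$counts))
  # genes detected in both retained cells still fail min_cells_per_gene = 3
  out2 <- filter_matrix(cm, qc_thresholds(min_cells_per_gene = 2))
  expect_true("G002" %in% colnames(out2$counts))
  rep <- attr(out, "qc_report")
  expect_equal(rep$removed[rep$criterion == "low_genes"], 1)
  expect_equal(rep$removed[rep$criterion == "low_counts"], 1)
  expect_equal(rep$removed[rep$criterion == "high_mito"], 1)
})

test_that("filter_matrix matches a brute-force filter and is idempotent", {
  g <- small_cnv_cohort()
  th <- qc_thresholds()
  out <- filter_matrix(g$counts, th)
  # independent brute-force filter with explicit loops
  m <- as.matrix(g$counts$counts)
  mito <- g$counts$gene_meta$mito
  keep_cells <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    genes_expr <- sum(m[i, ] > 0)
    total <- sum(m[i, ])
    mito_frac <- sum(m[i, mito]) / total
    keep_cells[i] <- genes_expr >= th$min_genes_per_cell &&
      total >= th$min_counts_per_cell && mito_frac <= th$max_mito_fraction
  }
  keep_genes <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    keep_genes[j] <- sum(m[keep_cells, j] > 0) >= th$min_cells_per_gene
  }
  expect_identical(rownames(out$counts), rownames(m)[keep_cells])
  expect_identical(colnames(out$counts), colnames(m)[keep_genes])
  expect_equal(as.matrix(out$counts),
               m[keep_cells, keep_genes, drop = FALSE])
  # idempotence
  twice <- filter_matrix(out, th)
  expect_identical(as.matrix(twice$counts), as.matrix(out$counts))
})

test_that("filter_matrix errors when nothing survives", {
  mat <- matrix(1, 3, 10)
  expect_error(filter_matrix(tiny_counts(mat)), "review thresholds")
})

test_that("normalize_log scales to target then log1p", {
  mat <- matrix(0, 2, 4)
  mat[1, ] <- c(100, 1900, 0, 0)   # total 2000
  mat[2, ] <- c(500, 500, 500, 500)
  cm <- tiny_counts(mat)
  e <- normalize_log(cm, target_sum = 1000)
  expect_equal(e[1, 1], log(51))   # 100/2000*1000 = 50
  expect_equal(e[1, 3], 0)
  expect_equal(unname(rowSums(expm1(as.matrix(e)))), c(1000, 1000))
})

test_that("select_hvg matches a hand-rolled binned-dispersion oracle", {
  g <- small_cnv_cohort()
  e <- normalized_expression(g)
  e50 <- e[, 1:200]
  got <- select_hvg(e50, n_bins = 5)
  # independent oracle
  X <- expm1(as.matrix(e50))
  mu <- colMeans(X)
  v <- apply(X, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  ml <- log1p(mu)
  br <- unique(quantile(ml, seq(0, 1, length.out = 6)))
  bins <- cut(ml, br, include.lowest = TRUE, labels = FALSE)
  tab <- table(bins)
  for (b in as.integer(names(tab)[tab < 2])) {
    bins[bins == b] <- if (b > 1) b - 1L else b + 1L
  }
  nd <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- sd(disp[i]); if (is.na(s) || s == 0) s <- 1
    nd[i] <- (disp[i] - mean(disp[i])) / s
  }
  want <- colnames(e50)[ml >= 0.0125 & ml <= 3 & nd >= 0.5]
  expect_setequal(got, want)
  # constant gene is never selected
  e2 <- cbind(e50, CONST = rep(2, nrow(e50)))
  expect_false("CONST" %in% select_hvg(e2))
  # mean above mean_max excluded regardless of dispersion
  expect_false(any(log1p(colMeans(expm1(as.matrix(e50[, select_hvg(e50), drop = FALSE])))) > 3))
})

test_that("detect_doublets is calibrated, recovers heterotypic doublets, and is deterministic", {
  # clean 2000-cell sample: false-positive rate should be low
  cfg0 <- cohort_config(n_patients = 1, timepoints_per_patient = "pre",
                        cells_per_sample = 2000, n_genes = 600,
                        malignant_fraction = 0.4, doublet_rate = 0,
                        n_programs = 2, seed = 20L)
  g0 <- generate_cohort(cfg0)
  flags0 <- detect_doublets(g0$counts, seed = 4L)
  expect_lte(mean(flags0), 0.05)
  # doublet-rich sample between two well-separated types
  cfg <- cohort_config(n_patients = 1, timepoints_per_patient = "pre",
                       cells_per_sample = 1000, n_genes = 600,
                       malignant_fraction = 0.5, doublet_rate = 0.15,
                       n_programs = 1, seed = 21L)
  gd <- generate_cohort(cfg)
  flags <- detect_doublets(gd$counts, seed = 4L)
  parents <- gd$truth$doublet_parents
  hetero_cells <- rownames(parents)[parents$parent1 != parents$parent2]
  expect_gte(mean(flags[hetero_cells]), 0.6)
  # determinism
  expect_identical(flags, detect_doublets(gd$counts, seed = 4L))
  # tiny sample skipped with warning
  tiny <- subset_cells(gd$counts, cells = 1:10)
  expect_warning(f <- detect_doublets(tiny, k_neighbors = 30), "no doublets")
  expect_false(any(f))
})

test_that("read_counts validates sidecar dimensions and disambiguates symbols", {
  dir <- withr::local_tempdir()
  g <- small_cnv_cohort()
  write_cohort(g$counts, NULL, file.path(dir, "c"))
  # corrupt barcodes
  writeLines("only_one", file.path(dir, "c", "barcodes.tsv"))
  expect_error(read_counts(file.path(dir, "c")), "barcodes.tsv")

  # duplicate symbols on a 3-gene fixture
  d2 <- file.path(dir, "dup")
  dir.create(d2)
  m <- Matrix::Matrix(matrix(c(1, 0, 2, 3, 4, 0), 3, 2), sparse = TRUE)
  Matrix::writeMM(m, file.path(d2, "matrix.mtx"))
  writeLines(c("c1", "c2"), file.path(d2, "barcodes.tsv"))
  writeLines(c("id1\tGA", "id2\tGA", "id3\tGB"), file.path(d2, "features.tsv"))
  expect_warning(cm <- read_counts(d2), "duplicate")
  expect_identical(colnames(cm$counts), c("GA", "GA.1", "GB"))

  # header-only empty matrix: 0 cells, no crash
  d3 <- file.path(dir, "empty")
  dir.create(d3)
  m0 <- Matrix::Matrix(0, 3, 0, sparse = TRUE)
  Matrix::writeMM(m0, file.path(d3, "matrix.mtx"))
  writeLines(character(0), file.path(d3, "barcodes.tsv"))
  writeLines(c("id1\tG1", "id2\tG2", "id3\tG3"), file.path(d3, "features.tsv"))
  cm0 <- read_counts(d3)
  expect_equal(dim(cm0), c(0L, 3L))
})
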