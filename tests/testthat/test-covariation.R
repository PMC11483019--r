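# deterministic toy scores: cells in 4-6 samples, two cell types
toy_scores <- function(n_per_sample = 30, samples = paste0("s", 1:4),
                       n_programs = 3, seed = 61) {
  set.seed(seed)
  n <- n_per_sample * length(samples)
  list(scores = matrix(rnorm(n * n_programs), n, n_programs,
                       dimnames = list(NULL, paste0("p", seq_len(n_programs)))),
       samples = rep(samples, each = n_per_sample),
       types = rep("tumor", n))
}

test_that("percentile_matrix implements linear-interpolation percentiles", {
  sc <- matrix(c(1, 2, 3, 4, 5), 5, 1, dimnames = list(NULL, "p1"))
  s <- rep("a", 5)
  ty <- rep("tumor", 5)
  expect_equal(percentile_matrix(sc, s, ty, "tumor", 50, min_cells = 1)["a", "p1"], 3)
  sc10 <- matrix(0:9, 10, 1, dimnames = list(NULL, "p1"))
  expect_equal(percentile_matrix(sc10, rep("a", 10), rep("tumor", 10), "tumor",
                                 90, min_cells = 1)["a", "p1"], 8.1)
  # constant scores give the constant at any percentile
  scc <- matrix(4.2, 8, 1, dimnames = list(NULL, "p1"))
  for (p in c(25, 50, 75, 90, 95)) {
    expect_equal(percentile_matrix(scc, rep("a", 8), rep("tumor", 8), "tumor",
                                   p, min_cells = 1)["a", "p1"], 4.2)
  }
  expect_error(percentile_matrix(sc, s, ty, "tumor", 0), "percentile")
  expect_error(percentile_matrix(sc, s, ty, "tumor", 100), "percentile")
})

test_that("percentile_matrix respects cell-type restriction and min_cells", {
  t <- toy_scores()
  types <- t$types
  types[1:15] <- "T"   # first half of sample s1 is T cells
  pm <- percentile_matrix(t$scores, t$samples, types, "tumor", 90, min_cells = 20)
  expect_true(is.na(pm["s1", "p1"]))      # only 15 tumor cells left in s1
  expect_false(anyNA(pm[c("s2", "s3", "s4"), ]))
  # restriction: values computed over tumor cells only
  pm1 <- percentile_matrix(t$scores, t$samples, types, "tumor", 90, min_cells = 5)
  manual <- quantile(t$scores[16:30, "p1"], 0.9, names = FALSE)
  expect_equal(pm1["s1", "p1"], manual)
  # permuting cells within a sample leaves the matrix unchanged
  perm <- c(sample(1:30), 31:120)
  pm2 <- percentile_matrix(t$scores[perm, ], t$samples[perm], types[perm],
                           "tumor", 90, min_cells = 5)
  expect_equal(pm1, pm2)
})

test_that("program_correlations matches a hand-computed Pearson oracle", {
  pm <- rbind(c(1, 2, 1.5), c(2, 4, 1.0), c(3, 6, 0.5), c(4, 8, 0.1))
  colnames(pm) <- c("a", "b", "c")
  rownames(pm) <- paste0("s", 1:4)
  out <- program_correlations(pm)
  expect_equal(out$correlation["a", "b"], 1)           # identical up to scale
  expect_lt(out$correlation["a", "c"], -0.98)          # near anti-correlated
  # exact hand fixture: Pearson by formula
  x <- pm[, "a"]; y <- pm[, "c"]
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$correlation["a", "c"], r, tolerance = 1e-12)
  # negation gives exactly -1
  pm2 <- cbind(pm, d = -pm[, "a"])
  out2 <- program_correlations(pm2)
  expect_equal(out2$correlation["a", "d"], -1)
  # zero-variance column excluded with warning
  pm3 <- cbind(pm, flat = 1)
  expect_warning(out3 <- program_correlations(pm3), "zero-variance")
  expect_true(all(is.na(out3$correlation["flat", ])))
  expect_false("flat" %in% out3$order)
  expect_s3_class(out2$linkage, "hclust")
})

test_that("permutation p-values are valid, symmetric, and deterministic", {
  t <- toy_scores(n_per_sample = 25, samples = paste0("s", 1:5))
  pv <- permutation_pvalues(t$scores, t$samples, t$types, "tumor",
                            n_iterations = 100, min_cells = 5, seed = 3)
  p <- pv$pvalues[upper.tri(pv$pvalues)]
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(pv$pvalues, t(pv$pvalues))
  pv2 <- permutation_pvalues(t$scores, t$samples, t$types, "tumor",
                             n_iterations = 100, min_cells = 5, seed = 3)
  expect_identical(pv$pvalues, pv2$pvalues)
  # smoothed estimator never returns 0
  pvs <- permutation_pvalues(t$scores, t$samples, t$types, "tumor",
                             n_iterations = 50, min_cells = 5, seed = 3,
                             smoothed = TRUE)
  expect_true(all(pvs$pvalues[upper.tri(pvs$pvalues)] > 0))
})

test_that("p-values are calibrated under a label-independent null", {
  # scores independent of sample labels: p-value distribution ~ uniform
  t <- toy_scores(n_per_sample = 20, samples = paste0("s", 1:6),
                  n_programs = 15, seed = 71)
  pv <- permutation_pvalues(t$scores, t$samples, t$types, "tumor",
                            n_iterations = 200, min_cells = 5, seed = 9)
  p <- pv$pvalues[upper.tri(pv$pvalues)]
  n_pairs <- length(p)   # 105 pairs
  frac05 <- mean(p <= 0.05)
  ci <- 1.96 * sqrt(0.05 * 0.95 / n_pairs)
  expect_lte(frac05, 0.05 + ci)
  # mean should be near 0.5 for a uniform distribution
  expect_lt(abs(mean(p) - 0.5), 0.1)
})

test_that("a correlation above every null draw gets p = 0", {
  # two programs perfectly co-varying across samples via a strong sample effect
  set.seed(83)
  samples <- rep(paste0("s", 1:6), each = 20)
  effect <- rep(seq(0, 5, length.out = 6), each = 20)
  scores <- cbind(p1 = effect + rnorm(120, 0, 0.01),
                  p2 = effect + rnorm(120, 0, 0.01))
  pv <- permutation_pvalues(scores, samples, rep("tumor", 120), "tumor",
                            n_iterations = 200, min_cells = 5, seed = 5)
  expect_equal(pv$pvalues["p1", "p2"], 0)
})

test_that("Monte-Carlo p matches exhaustive enumeration on a tiny instance", {
  # 3 samples, 4 cells each; stratum = single type, so the null is the set of
  # distinct assignments of cells to samples; enumerate label permutations
  set.seed(91)
  n <- 12
  samples <- rep(c("a", "b", "c"), each = 4)
  scores <- cbind(p1 = rnorm(n), p2 = rnorm(n))
  types <- rep("tumor", n)
  obs <- cor(percentile_matrix(scores, samples, types, "tumor", 75, min_cells = 1))["p1", "p2"]
  # the permutation null depends only on the partition of the 12 cells into
  # the three 4-cell samples: enumerate all C(12,4)*C(8,4) = 34650 partitions
  # with hand-rolled percentile (type-7, n=4: x(3) + 0.25 (x(4) - x(3))) and
  # Pearson arithmetic, independent of the package's implementation
  q75 <- function(x) {
    s <- sort(x)
    s[3] + 0.25 * (s[4] - s[3])
  }
  pearson3 <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  combs1 <- utils::combn(1:12, 4)
  exceed <- 0; total <- 0
  for (i in seq_len(ncol(combs1))) {
    rest <- setdiff(1:12, combs1[, i])
    combs2 <- utils::combn(rest, 4)
    for (j in seq_len(ncol(combs2))) {
      ga <- combs1[, i]
      gb <- combs2[, j]
      gc <- setdiff(rest, gb)
      v1 <- c(q75(scores[ga, 1]), q75(scores[gb, 1]), q75(scores[gc, 1]))
      v2 <- c(q75(scores[ga, 2]), q75(scores[gb, 2]), q75(scores[gc, 2]))
      exceed <- exceed + (pearson3(v1, v2) > obs)
      total <- total + 1
    }
  }
  p_exact <- exceed / total
  pv <- permutation_pvalues(scores, samples, types, "tumor",
                            n_iterations = 1000, percentile = 75,
                            min_cells = 1, seed = 13)
  p_mc <- pv$pvalues["p1", "p2"]
  se <- sqrt(p_exact * (1 - p_exact) / 1000)
  expect_lt(abs(p_mc - p_exact), 3 * max(se, 1e-3))
})
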