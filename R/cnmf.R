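#' Prepare an expression matrix for factorization
#'
#' Subsets to the `n_hvg` most variable genes and scales each gene by its
#' standard deviation without mean-centering, so values stay nonnegative.
#' Zero-variance genes are dropped.
#'
#' @param expression log-normalized cells x genes matrix.
#' @param n_hvg number of highly variable genes to keep (default 2000); when it
#'   exceeds the available genes all are used with a warning.
#' @return dense nonnegative cells x genes matrix with unit gene variance.
#' @export
prepare_matrix <- function(expression, n_hvg = 2000) {
  X <- as.matrix(expression)
  if (n_hvg > ncol(X)) {
    warning("n_hvg (", n_hvg, ") exceeds available genes (", ncol(X), "); using all")
    n_hvg <- ncol(X)
  }
  v <- apply(X, 2, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(n_hvg)]
  top <- sort(top)
  X <- X[, top, drop = FALSE]
  v <- v[top]
  nz <- v > 0
  X <- X[, nz, drop = FALSE]
  sweep(X, 2, sqrt(v[nz]), "/")
}

#' Single NMF run with multiplicative updates
#'
#' Minimizes the Frobenius reconstruction error `||X - W H||_F` over
#' nonnegative `W` (cells x k usages) and `H` (k x genes spectra) with the
#' classical multiplicative update rules, whose objective is non-increasing at
#' every iteration. Stops when the relative objective improvement falls below
#' `tol` or at `max_iter`. Spectra rows are L2-normalized on return (with the
#' compensating scale folded into the usages, so `W H` is unchanged).
#'
#' @param matrix nonnegative cells x genes matrix.
#' @param k factorization rank, `k < min(dim(matrix))`.
#' @param seed integer seed for the random initialization.
#' @param max_iter maximum iterations (default 300).
#' @param tol relative-improvement stopping tolerance (default 1e-5).
#' @return a `FactorizationRun` list: `k`, `seed`, `spectra`, `usages`,
#'   `reconstruction_error`, `objective_trace`.
#' @export
factorize_once <- function(matrix, k, seed = 1L, max_iter = 300, tol = 1e-5) {
  X <- as.matrix(matrix)
  if (any(X < 0)) stop("matrix must be nonnegative")
  if (k >= min(dim(X))) stop("invalid rank: k must be < min(dim(matrix))")
  init <- nmf_init(dim(X), k, mean(X), seed)
  W <- init$W
  H <- init$H
  eps <- .Machine$double.eps
  sumX2 <- sum(X^2)
  obj <- numeric(max_iter)
  n_it <- 0L
  prev <- Inf
  for (it in seq_len(max_iter)) {
    WtX <- crossprod(W, X)
    WtW <- crossprod(W)
    H <- H * WtX / (WtW %*% H + eps)
    # ||X - W H||^2 = ||X||^2 - 2<H, W'X> + <W'W, H H'>, no residual matrix
    err <- sqrt(max(0, sumX2 - 2 * sum(H * WtX) + sum(WtW * tcrossprod(H))))
    n_it <- it
    obj[it] <- err
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (is.finite(prev) && (prev - err) / max(prev, eps) < tol) break
    prev <- err
  }
  obj <- obj[seq_len(n_it)]
  out <- nmf_finalize(W, H, X, k, seed)
  out$reconstruction_error <- obj[length(obj)]
  out$objective_trace <- obj
  out
}

# shared seeded initialization so single and batched solvers agree
nmf_init <- function(dims, k, mean_x, seed) {
  set.seed(seed)
  scale0 <- sqrt(mean_x / k)
  W <- stats::runif(dims[1] * k) * scale0
  dim(W) <- c(dims[1], k)
  H <- stats::runif(k * dims[2]) * scale0
  dim(H) <- c(k, dims[2])
  list(W = W, H = H)
}

nmf_finalize <- function(W, H, X, k, seed) {
  norms <- sqrt(rowSums(H^2))
  norms[norms == 0] <- 1
  H <- H / norms
  W <- sweep(W, 2, norms, "*")
  rownames(H) <- sprintf("component_%d", seq_len(k))
  colnames(H) <- colnames(X)
  rownames(W) <- rownames(X)
  colnames(W) <- rownames(H)
  structure(list(k = k, seed = seed, spectra = H, usages = W,
                 reconstruction_error = NA_real_, objective_trace = NULL),
            class = "FactorizationRun")
}

# All restarts advanced together: the two data-matrix products per iteration
# are computed once on column-stacked factors, which is far more efficient for
# small k than per-run thin products. Mathematically identical to running
# factorize_once per seed (identical seeded initialization and update rule).
factorize_batch <- function(X, k, seeds, max_iter = 300, tol = 1e-5) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("matrix must be nonnegative")
  if (k >= min(dim(X))) stop("invalid rank: k must be < min(dim(matrix))")
  R <- length(seeds)
  eps <- .Machine$double.eps
  sumX2 <- sum(X^2)
  mean_x <- mean(X)
  W <- vector("list", R)
  H <- vector("list", R)
  for (r in seq_len(R)) {
    init <- nmf_init(dim(X), k, mean_x, seeds[r])
    W[[r]] <- init$W
    H[[r]] <- init$H
  }
  active <- rep(TRUE, R)
  prev <- rep(Inf, R)
  err <- rep(NA_real_, R)
  trace <- vector("list", R)
  for (it in seq_len(max_iter)) {
    act <- which(active)
    if (!length(act)) break
    Wall <- do.call(cbind, W[act])
    WtX <- crossprod(Wall, X)
    for (j in seq_along(act)) {
      r <- act[j]
      rows <- (j - 1L) * k + seq_len(k)
      WtXr <- WtX[rows, , drop = FALSE]
      WtWr <- crossprod(W[[r]])
      H[[r]] <- H[[r]] * WtXr / (WtWr %*% H[[r]] + eps)
      e <- sqrt(max(0, sumX2 - 2 * sum(H[[r]] * WtXr) +
                      sum(WtWr * tcrossprod(H[[r]]))))
      err[r] <- e
      trace[[r]] <- c(trace[[r]], e)
    }
    Hall <- do.call(rbind, H[act])
    XHt <- X %*% t(Hall)
    for (j in seq_along(act)) {
      r <- act[j]
      cols <- (j - 1L) * k + seq_len(k)
      W[[r]] <- W[[r]] * XHt[, cols, drop = FALSE] /
        (W[[r]] %*% tcrossprod(H[[r]]) + eps)
      if (is.finite(prev[r]) && (prev[r] - err[r]) / max(prev[r], eps) < tol) {
        active[r] <- FALSE
      }
      prev[r] <- err[r]
    }
  }
  lapply(seq_len(R), function(r) {
    out <- nmf_finalize(W[[r]], H[[r]], X, k, seeds[r])
    out$reconstruction_error <- err[r]
    out$objective_trace <- trace[[r]]
    out
  })
}

# kmeans++ initial centers, deterministic under the caller's RNG state
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    prob <- d2 / sum(d2)
    idx <- sample.int(n, 1, prob = prob)
    centers[j + 1, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums((X - matrix(X[idx, ], n, ncol(X), byrow = TRUE))^2))
  }
  centers
}

#' Consensus programs from repeated NMF runs
#'
#' Pools the L2-normalized spectra components of all runs, discards outlier
#' components whose local density (mean cosine distance to their nearest
#' `n_runs - 1` neighbors) exceeds `density_threshold`, clusters the survivors
#' into `k` groups (k-means with k-means++ initialization seeded by the first
#' run's seed), takes the per-cluster component median as the consensus
#' spectra, and refits per-cell usages by nonnegative least squares against
#' those spectra. Stability is the mean silhouette width of the component
#' clustering on cosine distance; error is the Frobenius error of the refit.
#'
#' @param runs list of [factorize_once()] results, all at the same rank.
#' @param matrix the nonnegative matrix the runs factorized (for the refit).
#' @param density_threshold cosine-distance local-density cut (default 0.5).
#' @return a `ProgramDecomposition` list: `k`, `consensus_spectra`, `usages`
#'   (unit row sums), `usages_raw`, `component_kept`, `stability`, `error`.
#' @export
consensus_programs <- function(runs, matrix, density_threshold = 0.5) {
  if (length(runs) < 2) stop("need at least 2 runs")
  ks <- vapply(runs, `[[`, numeric(1), "k")
  if (length(unique(ks)) != 1) stop("all runs must share one rank")
  k <- ks[1]
  n_runs <- length(runs)
  pooled <- do.call(rbind, lapply(runs, `[[`, "spectra"))
  pooled <- pooled / sqrt(rowSums(pooled^2))

  cosd <- 1 - tcrossprod(pooled)
  cosd[cosd < 0] <- 0
  n_neighbors <- n_runs - 1L
  # self-distance is excluded; average the nearest (n_runs - 1) other components
  density <- vapply(seq_len(nrow(cosd)), function(i) {
    d <- cosd[i, -i]
    mean(sort(d)[seq_len(min(n_neighbors, length(d)))])
  }, numeric(1))
  kept <- density <= density_threshold
  if (!any(kept)) stop("density threshold too strict: all components filtered")
  comp <- pooled[kept, , drop = FALSE]

  set.seed(runs[[1]]$seed)
  centers <- kmeanspp_centers(comp, k)
  km <- stats::kmeans(comp, centers = centers, iter.max = 100)
  medians <- t(vapply(seq_len(k), function(j) {
    apply(comp[km$cluster == j, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(comp))))
  norms <- sqrt(rowSums(medians^2))
  norms[norms == 0] <- 1
  spectra <- medians / norms
  rownames(spectra) <- sprintf("program_%d", seq_len(k))
  colnames(spectra) <- colnames(runs[[1]]$spectra)

  X <- as.matrix(matrix)
  C <- t(spectra)
  usages_raw <- t(apply(X, 1, function(x) pracma::lsqnonneg(C, x)$x))
  dimnames(usages_raw) <- list(rownames(X), rownames(spectra))
  rs <- rowSums(usages_raw)
  usages <- usages_raw
  usages[rs > 0, ] <- usages_raw[rs > 0, , drop = FALSE] / rs[rs > 0]
  usages[rs == 0, ] <- 1 / k

  stability <- if (length(unique(km$cluster)) > 1) {
    sil <- cluster::silhouette(km$cluster, stats::as.dist(cosd[kept, kept]))
    mean(sil[, "sil_width"])
  } else NA_real_
  error <- sqrt(sum((X - usages_raw %*% spectra)^2))

  structure(list(k = k, consensus_spectra = spectra, usages = usages,
                 usages_raw = usages_raw, component_kept = kept,
                 component_cluster = km$cluster,
                 stability = stability, error = error),
            class = "ProgramDecomposition")
}

#' Repeated-restart consensus NMF at one rank
#'
#' Convenience wrapper: runs [factorize_once()] `n_runs` times with seeds
#' `seed, seed + 1, ...` and combines them with [consensus_programs()].
#'
#' @param matrix nonnegative cells x genes matrix from [prepare_matrix()].
#' @param k rank.
#' @param n_runs restarts (default 20).
#' @param seed base seed.
#' @param density_threshold passed to [consensus_programs()].
#' @param ... passed to [factorize_once()].
#' @return a `ProgramDecomposition`.
#' @export
run_cnmf <- function(matrix, k, n_runs = 20, seed = 1L, density_threshold = 0.5,
                     ...) {
  runs <- factorize_batch(as.matrix(matrix), k, seeds = seed + seq_len(n_runs) - 1L,
                          ...)
  consensus_programs(runs, matrix, density_threshold = density_threshold)
}

#' Rank-selection diagnostics
#'
#' Tabulates stability (component-clustering silhouette) and consensus
#' reconstruction error across the evaluated ranks. Selection is a user
#' decision; an automatic suggestion (maximum stability among ranks whose
#' error is within 10% of the minimum) is attached as `attr(out, "chosen_k")`.
#'
#' @param decompositions list of `ProgramDecomposition` objects over a k grid.
#' @return data.frame `(k, stability, error)` ordered by k.
#' @export
select_k <- function(decompositions) {
  if (length(decompositions) < 2) stop("need at least 2 evaluated ranks")
  tab <- data.frame(
    k = vapply(decompositions, `[[`, numeric(1), "k"),
    stability = vapply(decompositions, `[[`, numeric(1), "stability"),
    error = vapply(decompositions, `[[`, numeric(1), "error")
  )
  tab <- tab[order(tab$k), ]
  rownames(tab) <- NULL
  ok <- tab$error <= min(tab$error) * 1.1
  cand <- tab[ok, ]
  attr(tab, "chosen_k") <- cand$k[which.max(cand$stability)]
  tab
}

#' The rank grid used for program discovery
#'
#' @param k_min,k_max,k_step grid bounds and step (defaults 5, 101, 3).
#' @return integer vector of ranks.
#' @export
k_grid <- function(k_min = 5, k_max = 101, k_step = 3) {
  seq.int(k_min, k_max, by = k_step)
}
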