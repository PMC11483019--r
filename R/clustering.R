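#' Embed and cluster cells
#'
#' PCA on the per-gene standardized (clipped at +-10) highly-variable-gene
#' submatrix, a k-nearest-neighbor graph on the top components, and
#' modularity-based Leiden community detection at the given resolution.
#' Deterministic under a fixed seed.
#'
#' @param expression log-normalized cells x genes matrix.
#' @param hvgs character vector of genes to embed on.
#' @param n_components number of principal components (default 40; reduced with
#'   a warning when it exceeds `min(cells, genes) - 1`).
#' @param n_neighbors neighbors in the kNN graph (default 15).
#' @param resolution Leiden resolution (default 0.5).
#' @param seed integer seed for the community detection initialization.
#' @return an `EmbeddingResult` list: `pca_coordinates`, `neighbor_graph`
#'   (symmetric sparse adjacency), `cluster_labels` (factor).
#' @export
cluster_cells <- function(expression, hvgs, n_components = 40, n_neighbors = 15,
                          resolution = 0.5, seed = 1L) {
  hvgs <- intersect(hvgs, colnames(expression))
  if (length(hvgs) < 2) stop("need at least 2 measured highly variable genes")
  X <- as.matrix(expression[, hvgs, drop = FALSE])
  X <- scale(X)
  X[is.na(X)] <- 0
  X[X > 10] <- 10
  X[X < -10] <- -10
  max_pc <- min(nrow(X) - 1L, ncol(X))
  if (n_components > max_pc) {
    warning("n_components reduced from ", n_components, " to ", max_pc)
    n_components <- max_pc
  }
  pcs <- stats::prcomp(X, rank. = n_components, center = FALSE)$x
  graph <- knn_graph(pcs, n_neighbors)
  set.seed(seed)
  comm <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  labels <- factor(igraph::membership(comm))
  names(labels) <- rownames(expression)
  adj <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = TRUE)
  dimnames(adj) <- list(rownames(expression), rownames(expression))
  structure(list(pca_coordinates = pcs, neighbor_graph = adj,
                 cluster_labels = labels),
            class = "EmbeddingResult")
}

# Symmetric (union) kNN graph on embedding rows; edge weight 1.
knn_graph <- function(coords, k) {
  n <- nrow(coords)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(coords))
  from <- rep(seq_len(n), each = k)
  to <- as.vector(apply(d, 1, function(r) order(r)[2:(k + 1)]))
  edges <- cbind(pmin(from, to), pmax(from, to))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- 1
  g
}

#' Annotate clusters with major cell types from marker gene sets
#'
#' Each cluster receives, for every candidate type, the cluster-mean
#' control-subtracted gene-set score ([score_gene_set()]); the cluster is
#' assigned the argmax type and all its cells inherit the label. Ties are
#' broken lexicographically by type name (with a warning). Marker sets that
#' have no measured gene are dropped with a warning.
#'
#' @param expression log-normalized cells x genes matrix.
#' @param cluster_labels factor or vector of per-cell cluster labels.
#' @param marker_sets named list of marker gene vectors (one per type), e.g.
#'   from [read_gmt()].
#' @param seed seed for the control-gene draw in scoring.
#' @return named character vector of per-cell type labels.
#' @export
annotate_major_types <- function(expression, cluster_labels, marker_sets,
                                 seed = 1L) {
  measured <- colnames(expression)
  keep <- vapply(marker_sets, function(s) length(intersect(s, measured)) > 0,
                 logical(1))
  if (!all(keep)) {
    warning("marker set(s) with no measured genes dropped: ",
            paste(names(marker_sets)[!keep], collapse = ", "))
    marker_sets <- marker_sets[keep]
  }
  if (!length(marker_sets)) stop("no usable marker sets")
  types <- sort(names(marker_sets))
  scores <- sapply(types, function(t) {
    score_gene_set(expression, marker_sets[[t]], seed = seed)
  })
  clusters <- as.character(cluster_labels)
  cl_ids <- sort(unique(clusters))
  cl_type <- vapply(cl_ids, function(cl) {
    m <- colMeans(scores[clusters == cl, , drop = FALSE])
    top <- which(m == max(m))
    if (length(top) > 1) warning("score tie in cluster ", cl,
                                 "; broken lexicographically")
    types[min(top)]
  }, character(1))
  out <- cl_type[clusters]
  names(out) <- rownames(expression)
  out
}
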