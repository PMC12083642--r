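#' Latent embedding by PCA on standardized HVGs
#'
#' Restricts the normalized matrix to the highly variable genes, standardizes
#' each gene (zero mean, unit variance; constant genes become zero), and takes
#' the top `d` principal components. A deterministic sign convention is
#' applied: the largest-|loading| entry of each component is made positive.
#' This PCA latent stands in for a deep generative embedding: with one sample
#' per condition there is no batch structure to correct, and downstream
#' clustering only needs a denoised low-dimensional representation.
#'
#' @param norm NormalizedMatrix from [normalize_log1p()]
#' @param hvgs character vector of gene ids (subset of the genes)
#' @param d number of components (must not exceed the numerical rank)
#' @return numeric matrix observations x d, with loadings in attribute
#'   `rotation`
#' @export
latent_embed <- function(norm, hvgs, d = 30) {
  j <- match(hvgs, norm$var$id)
  if (anyNA(j)) stop("hvgs contains gene ids absent from the matrix")
  X <- as.matrix(norm$values[, j, drop = FALSE])
  X <- scale(X)
  X[, attr(X, "scaled:scale") == 0] <- 0
  X[is.nan(X)] <- 0
  sv <- svd(X)
  rank <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  if (d > rank) stop("d = ", d, " exceeds the numerical rank (", rank, ")")
  U <- sv$u[, seq_len(d), drop = FALSE]
  V <- sv$v[, seq_len(d), drop = FALSE]
  for (k in seq_len(d)) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) { V[, k] <- -V[, k]; U[, k] <- -U[, k] }
  }
  emb <- U %*% diag(sv$d[seq_len(d)], d)
  rownames(emb) <- rownames(norm$values)
  attr(emb, "rotation") <- V
  emb
}

# k nearest neighbors by Euclidean distance, blockwise to bound memory;
# returns indices and distances (self excluded)
knn_euclidean <- function(X, k, block = 1024L) {
  n <- nrow(X)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of observations")
  sq <- rowSums(X^2)
  idx <- matrix(0L, n, k); dmat <- matrix(0, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    D2 <- outer(sq[rows], sq, "+") - 2 * X[rows, , drop = FALSE] %*% t(X)
    D2[cbind(seq_along(rows), rows)] <- Inf
    D2[D2 < 0] <- 0
    for (ii in seq_along(rows)) {
      o <- order(D2[ii, ])[seq_len(k)]
      idx[rows[ii], ] <- o
      dmat[rows[ii], ] <- sqrt(D2[ii, o])
    }
  }
  list(index = idx, dist = dmat)
}

#' Expression connectivity graph
#'
#' kNN graph in the latent space with a local adaptive kernel: directed
#' weights a_ij = exp(-max(0, d_ij - d_i1) / sigma_i) for j among i's k
#' nearest neighbors, where d_i1 is the distance to the nearest neighbor and
#' sigma_i the mean distance to the k neighbors; symmetrized by the fuzzy
#' union w_ij = a_ij + a_ji - a_ij a_ji. Weights lie in `[0,1]` with zero
#' diagonal.
#'
#' @param emb embedding matrix (observations x d)
#' @param k number of neighbors (default 15)
#' @return sparse symmetric ConnectivityGraph (dgCMatrix)
#' @export
expression_connectivities <- function(emb, k = 15) {
  nn <- knn_euclidean(as.matrix(emb), k)
  n <- nrow(emb)
  sigma <- pmax(rowMeans(nn$dist), .Machine$double.eps)
  a <- exp(-pmax(0, nn$dist - nn$dist[, 1]) / sigma)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn$index),
                            x = as.vector(a), dims = c(n, n))
  At <- Matrix::t(A)
  W <- A + At - A * At
  W <- Matrix::drop0(W)
  assert_connectivity_graph(W, tol = 1e-9)
  W
}

#' Spatial adjacency graph
#'
#' k nearest spatial neighbors (default k = 6, matching hex Visium geometry)
#' with unit weights; symmetrized by the union (max), zero diagonal.
#'
#' @param coords matrix or data.frame with x/y columns
#' @param k number of spatial neighbors
#' @return sparse symmetric ConnectivityGraph with 0/1 weights
#' @export
spatial_adjacency <- function(coords, k = 6) {
  if (is.null(coords) || !NROW(coords)) stop("missing coordinates")
  X <- as.matrix(coords)
  if (anyNA(X)) stop("missing coordinates")
  nn <- knn_euclidean(X, k)
  n <- nrow(X)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn$index),
                            x = 1, dims = c(n, n))
  W <- A + Matrix::t(A)
  W@x <- rep(1, length(W@x))
  assert_connectivity_graph(W)
  W
}

#' Fuse expression and spatial connectivity graphs
#'
#' Weighted sum W = alpha_expr * W_expr + (1 - alpha_expr) * W_spatial. The
#' default alpha_expr = 0.8 gives the expression graph a 0.8 importance
#' weight and the spatial graph 0.2.
#'
#' @param g_expr,g_spatial ConnectivityGraphs over the same observations
#' @param alpha_expr weight of the expression graph, in `[0,1]`
#' @return fused ConnectivityGraph
#' @export
fuse_graphs <- function(g_expr, g_spatial, alpha_expr = 0.8) {
  if (!all(dim(g_expr) == dim(g_spatial))) stop("graph dimensions differ")
  if (alpha_expr < 0 || alpha_expr > 1) stop("alpha_expr must be in [0,1]")
  W <- alpha_expr * g_expr + (1 - alpha_expr) * g_spatial
  assert_connectivity_graph(W, tol = 1e-9)
  W
}

#' Leiden clustering of a connectivity graph
#'
#' Partitions the weighted graph with the Leiden algorithm under the
#' resolution-parameterized modularity objective. Deterministic given `seed`;
#' labels are relabeled by decreasing cluster size (cluster 1 is largest).
#'
#' @param W ConnectivityGraph
#' @param resolution resolution parameter (0.8 for spatial spots, 1.0 for
#'   nuclei are the module defaults used by the pipeline)
#' @param seed RNG seed
#' @param n_iterations Leiden refinement iterations
#' @return integer vector of cluster labels with attributes `resolution` and
#'   `seed`
#' @export
leiden_cluster <- function(W, resolution = 0.8, seed = 1L, n_iterations = 5L) {
  if (!nrow(W)) stop("empty graph")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = n_iterations)
  raw <- igraph::membership(cl)
  sizes <- sort(table(raw), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- as.integer(relab[as.character(raw)])
  attr(labels, "resolution") <- resolution
  attr(labels, "seed") <- seed
  labels
}

#' Assign inhibitory subtypes from marker expression
#'
#' For each cluster, the mean normalized expression of each subtype marker
#' gene is computed and the cluster is assigned the subtype of the arg-max
#' marker (ties broken by marker order as given; all-zero marker means give
#' "unassigned"). Each cluster maps to exactly one subtype.
#'
#' @param norm NormalizedMatrix over the inhibitory nuclei
#' @param labels cluster labels from [leiden_cluster()]
#' @param markers named character vector subtype -> marker gene id, e.g.
#'   `c(Inh_Kit = "Kit.like", Inh_Zfhx4 = "Zfhx4.like", Inh_Piezo2 = "Piezo2.like")`
#' @return character vector of per-observation subtype labels with a
#'   `cluster_map` attribute (per-cluster subtype)
#' @export
assign_inhibitory_subtypes <- function(norm, labels, markers) {
  j <- match(markers, norm$var$id)
  if (anyNA(j)) stop("marker gene(s) absent: ",
                     paste(markers[is.na(j)], collapse = ", "))
  M <- as.matrix(norm$values[, j, drop = FALSE])
  colnames(M) <- names(markers)
  cl <- sort(unique(labels))
  cluster_map <- stats::setNames(character(length(cl)), cl)
  for (c_ in cl) {
    means <- colMeans(M[labels == c_, , drop = FALSE])
    cluster_map[as.character(c_)] <-
      if (all(means == 0)) "unassigned" else names(markers)[which.max(means)]
  }
  out <- unname(cluster_map[as.character(labels)])
  attr(out, "cluster_map") <- cluster_map
  out
}
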