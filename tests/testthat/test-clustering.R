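test_that("latent embedding: duplicates, variance ordering, separation", {
  set.seed(1)
  ds <- generate_spatial(four_region_cfg(1, n_spots = 300, n_genes = 200))
  nrm <- normalize_log1p(ds)
  hv <- select_hvg(ds, 120)
  emb <- latent_embed(nrm, hv, d = 10)
  # component variances non-increasing
  v <- apply(emb, 2, var)
  expect_true(all(diff(v) <= 1e-8))
  # duplicate observations map to identical rows
  ds2 <- ds
  ds2$counts[2, ] <- ds2$counts[1, ]
  nrm2 <- normalize_log1p(ds2)
  emb2 <- latent_embed(nrm2, hv, d = 5)
  expect_equal(emb2[1, ], emb2[2, ], tolerance = 1e-8)
  # three well-separated programs: top-2 components separate the regions
  cfg3 <- spatial_sim_config(
    n_spots_per_sample = 240, n_genes = 150,
    regions = lapply(c("A", "B", "C"), function(n)
      list(name = n, fraction = 1 / 3, n_markers = 12, marker_log2 = 4)),
    effect_programs = list(), baseline_programs = list(),
    conditions = "HC", seed = 2)
  ds3 <- generate_spatial(cfg3)
  e3 <- latent_embed(normalize_log1p(ds3), select_hvg(ds3, 100), d = 5)
  sil <- cereFC:::mean_silhouette(dist(e3[, 1:2]), ds3$obs$region)
  expect_gte(sil, 0.5)
  expect_error(latent_embed(nrm, hv, d = 1e4), "rank")
})

test_that("expression connectivities: kernel extremes, symmetry, bounds", {
  set.seed(3)
  X <- matrix(rnorm(60 * 4), 60, 4)
  W <- expression_connectivities(X, k = 8)
  expect_s4_class(W, "dgCMatrix")
  # nearest-neighbour edges carry weight 1 (a_ij = exp(0) = 1 survives the union)
  nn <- cereFC:::knn_euclidean(X, 8)
  for (i in 1:60) expect_equal(W[i, nn$index[i, 1]], 1, tolerance = 1e-12)
  # duplicated points with k = n-1: all off-diagonal weights 1
  D <- matrix(1, 7, 2)
  Wd <- expression_connectivities(D, k = 6)
  expect_true(all(abs(Wd[upper.tri(Wd)] - 1) < 1e-12))
  # symmetry and [0,1] bounds over random embeddings
  for (t in 1:50) {
    Xr <- matrix(rnorm(30 * 3), 30, 3)
    Wr <- expression_connectivities(Xr, k = 5)
    expect_lt(max(abs(Wr - Matrix::t(Wr))), 1e-12)
    expect_true(all(Wr@x >= 0 & Wr@x <= 1 + 1e-12))
    expect_true(all(Matrix::diag(Wr) == 0))
  }
  expect_error(expression_connectivities(X, k = 0), "positive")
})

test_that("spatial adjacency: hex lattice degree, islands, symmetry", {
  lay <- cereFC:::hex_layout(11 * 11, 1)
  W <- spatial_adjacency(cbind(lay$x, lay$y), k = 6)
  expect_identical(as.matrix(W), t(as.matrix(W)))
  # interior spots: > 2 units from every lattice edge (boundary spots pad
  # their k = 6 list with ring-2 neighbours at distance sqrt(3)..2, so the
  # unit-degree-6 property holds strictly inside that margin)
  inner <- which(lay$x >= 3 & lay$x <= 7 & lay$y >= 2.6 & lay$y <= 6.1)
  degs <- Matrix::rowSums(W[inner, , drop = FALSE])
  expect_true(all(degs == 6))
  expect_true(all(W@x == 1))
  # two far-apart islands: block-diagonal graph
  pts <- rbind(cbind(rnorm(10), rnorm(10)), cbind(rnorm(10) + 1000, rnorm(10)))
  Wi <- spatial_adjacency(pts, k = 3)
  expect_equal(sum(Wi[1:10, 11:20]), 0)
  expect_error(spatial_adjacency(NULL), "coordinates")
})

test_that("graph fusion is the stated convex combination", {
  set.seed(4)
  X <- matrix(rnorm(40 * 3), 40, 3)
  ge <- expression_connectivities(X, k = 5)
  gs <- spatial_adjacency(matrix(runif(80), 40, 2), k = 4)
  expect_equal(as.matrix(fuse_graphs(ge, gs, 1)), as.matrix(ge))
  expect_equal(as.matrix(fuse_graphs(ge, gs, 0)), as.matrix(gs))
  f <- fuse_graphs(ge, gs, 0.8)
  expect_equal(as.matrix(f), 0.8 * as.matrix(ge) + 0.2 * as.matrix(gs))
  # fusing a graph with itself returns it for any weight
  expect_equal(as.matrix(fuse_graphs(ge, ge, 0.3)), as.matrix(ge))
  expect_error(fuse_graphs(ge, gs[1:10, 1:10]), "dimensions")
})

test_that("Leiden: disconnected cliques, determinism, size-ordered labels", {
  n <- 16
  W <- Matrix::bdiag(matrix(1, 10, 10), matrix(1, 6, 6))
  Matrix::diag(W) <- 0
  W <- methods::as(W, "CsparseMatrix")
  lab <- leiden_cluster(W, resolution = 0.8, seed = 1)
  expect_equal(length(unique(lab)), 2)
  expect_true(all(lab[1:10] == lab[1]) && all(lab[11:16] == lab[11]))
  expect_equal(lab[1], 1L)  # largest clique labelled first
  lab2 <- leiden_cluster(W, resolution = 0.8, seed = 1)
  expect_identical(lab, lab2)
  expect_error(leiden_cluster(W[0, 0]), "empty")
})

test_that("fused clustering recovers planted contiguous regions", {
  ok <- 0
  for (s in 1:3) {
    ds <- generate_spatial(four_region_cfg(s))
    nrm <- normalize_log1p(ds)
    emb <- latent_embed(nrm, select_hvg(ds, 200), d = 15)
    ge <- expression_connectivities(emb, k = 15)
    gs <- spatial_adjacency(ds$obs[, c("x", "y")], k = 6)
    lab <- leiden_cluster(fuse_graphs(ge, gs, 0.8), 0.8, seed = s)
    ok <- ok + (ari(lab, ds$obs$region) >= 0.8)
  }
  expect_gte(ok, 2)
})

test_that("inhibitory subtype assignment follows the arg-max marker rule", {
  # three clusters, each dominated by one marker gene
  counts <- rbind(matrix(c(5, 0, 0), 10, 3, byrow = TRUE),
                  matrix(c(0, 6, 0), 8, 3, byrow = TRUE),
                  matrix(c(0, 0, 4), 6, 3, byrow = TRUE))
  colnames(counts) <- c("Kit.like", "Zfhx4.like", "Piezo2.like")
  ds <- tiny_dataset(counts)
  nrm <- normalize_log1p(ds)
  lab <- rep(1:3, c(10, 8, 6))
  sub <- assign_inhibitory_subtypes(nrm, lab, default_subtype_markers)
  expect_identical(unname(attr(sub, "cluster_map")),
                   c("Inh_Kit", "Inh_Zfhx4", "Inh_Piezo2"))
  # all-zero marker means: unassigned
  ds0 <- tiny_dataset(matrix(0, 4, 3,
                             dimnames = list(NULL, colnames(counts))))
  n0 <- suppressWarnings(normalize_log1p(ds0))
  s0 <- assign_inhibitory_subtypes(n0, rep(1, 4), default_subtype_markers)
  expect_true(all(s0 == "unassigned"))
  expect_error(assign_inhibitory_subtypes(nrm, lab, c(A = "missing.gene")),
               "absent")
})

test_that("planted subtype programs are recovered with high accuracy", {
  types <- list(list(name = "Inh_DCN", fraction = 1, n_markers = 0, marker_log2 = 0))
  cfg <- sn_sim_config(n_nuclei = 900, n_genes = 300, cell_types = types,
                       baseline_programs = list(), effect_programs = list(),
                       seed = 11)
  ds <- generate_snrna(cfg)
  nrm <- normalize_log1p(ds)
  emb <- latent_embed(nrm, select_hvg(ds, 150), d = 10)
  lab <- leiden_cluster(expression_connectivities(emb, k = 15), 1.0, seed = 11)
  sub <- assign_inhibitory_subtypes(nrm, lab, default_subtype_markers)
  expect_gte(mean(sub == ds$obs$subtype), 0.95)
})
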