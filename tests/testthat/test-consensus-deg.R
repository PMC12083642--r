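test_that("pseudo-replication: exclusion, near-equal splits, conservation", {
  set.seed(1)
  counts <- matrix(rpois(60 * 20, 5), 60, 20)
  obs_group <- rep(c("A", "B", "C"), c(9, 11, 40))  # A has < 10 spots
  ds <- tiny_dataset(counts)
  ds$obs$group <- obs_group
  ds$obs$sample <- "HC_1"
  ds$obs$condition <- factor("HC", levels = c("HC", "CD", "TN"), ordered = TRUE)
  des <- pseudobulk_design("group", n_splits = 2, min_spots = 10, seed = 7)
  pb <- make_pseudoreplicates(ds, des)
  expect_false("A" %in% pb$meta$group)              # 9 spots -> excluded
  sizes_b <- sort(pb$meta$n_spots[pb$meta$group == "B"])
  expect_equal(sizes_b, c(5, 6))                    # 11 spots -> {5, 6}
  # gene-wise conservation within each retained pair
  for (g in c("B", "C")) {
    total <- colSums(counts[obs_group == g, , drop = FALSE])
    expect_equal(unname(colSums(pb$counts[pb$meta$group == g, , drop = FALSE])),
                 unname(total))
  }
  # deterministic given seed
  pb2 <- make_pseudoreplicates(ds, des)
  expect_identical(pb$counts, pb2$counts)
  des_all_small <- pseudobulk_design("group", n_splits = 2, min_spots = 100)
  expect_error(make_pseudoreplicates(ds, des_all_small), "no usable groups")
})

test_that("gene prevalence filter honours min_reps and mito flag", {
  Y <- rbind(c(1, 0, 3, 2), c(0, 0, 5, 1), c(2, 0, 0, 4))
  pb <- as_pb(Y, c("HC", "CD", "TN"), mito = c(FALSE, FALSE, FALSE, TRUE))
  f3 <- gene_prevalence_filter(pb, min_reps = 3, drop_mito = FALSE)
  expect_identical(colnames(f3$counts), "g004")   # others in < 3 reps: removed
  f2 <- gene_prevalence_filter(pb, min_reps = 2, drop_mito = FALSE)
  expect_identical(colnames(f2$counts), c("g001", "g003", "g004"))
  f0 <- gene_prevalence_filter(pb, min_reps = 0, drop_mito = FALSE)
  expect_identical(f0$counts, pb$counts)
  fm <- gene_prevalence_filter(pb, min_reps = 0, drop_mito = TRUE)
  expect_false("g004" %in% colnames(fm$counts))
})

test_that("size factors are median-of-ratios", {
  A <- c(10, 20, 30, 40)
  pb <- as_pb(rbind(A, 2 * A), c("HC", "CD"))
  sf <- size_factors(pb)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  pb_id <- as_pb(rbind(A, A, A), c("HC", "CD", "TN"))
  expect_equal(unname(size_factors(pb_id)), c(1, 1, 1))
  # hand-computed oracle on a 3x4 integer matrix
  Y <- rbind(c(4, 9, 10, 8), c(8, 3, 20, 16), c(16, 27, 40, 2))
  geo <- apply(Y, 2, function(col) prod(col)^(1 / 3))
  oracle <- apply(sweep(Y, 2, geo, "/"), 1, median)
  expect_equal(unname(size_factors(as_pb(Y, c("HC", "CD", "TN")))), oracle)
  # all-zero-containing genes only -> informative error
  expect_error(size_factors(as_pb(rbind(c(1, 0), c(0, 1)), c("HC", "CD"))),
               "prevalence")
})

test_that("NB LRT: degenerate identity, positivity, planted-effect power", {
  # identical counts across replicates: statistic 0, p = 1
  Y <- matrix(rep(c(5, 7, 11), each = 6), 6, 3)
  pb <- as_pb(Y, rep(c("HC", "CD", "TN"), 2))
  res <- nb_lrt(pb)
  expect_equal(res$stat, rep(0, 3), tolerance = 1e-6)
  expect_equal(res$p, rep(1, 3), tolerance = 1e-6)
  expect_true(all(res$stat >= 0))
  # planted 2-fold effect, mean 100, dispersion 0.05, 3v3: power >= 95%
  set.seed(21)
  G <- 500
  Yp <- rbind(matrix(rnbinom(3 * G, mu = 100, size = 20), 3),
              matrix(rnbinom(3 * G, mu = 200, size = 20), 3))
  pb2 <- as_pb(Yp, rep(c("HC", "CD"), each = 3))
  res2 <- nb_lrt(pb2, sf = rep(1, 6))   # unit size factors: pure NB simulation
  # analytic power of this configuration is ~0.93 (z ~ 3.5 at the 1.96 cut);
  # observed ~0.95
  expect_gte(mean(res2$p < 0.05), 0.90)
})

test_that("pairwise Wald test: exact ratios, antisymmetry, BH", {
  # condB counts exactly 4x condA at equal size factors -> log2FC = 2
  set.seed(3)
  base <- matrix(rnbinom(2 * 50, mu = 400, size = 50), 2)
  pb <- as_pb(rbind(base, 4 * base), rep(c("HC", "CD"), each = 2))
  pw <- pairwise_test(pb, "HC", "CD", sf = rep(1, 4))
  expect_equal(pw$log2FC, rep(2, 50), tolerance = 0.05)
  rev <- pairwise_test(pb, "CD", "HC", sf = rep(1, 4),
                       dispersion = rep(0.01, 50))
  fwd <- pairwise_test(pb, "HC", "CD", sf = rep(1, 4),
                       dispersion = rep(0.01, 50))
  expect_equal(rev$log2FC, -fwd$log2FC, tolerance = 1e-9)
  # BH oracle
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_error(pairwise_test(pb, "HC", "TN"), "present")
})

test_that("consensus: R = 1 degenerates, fractions bounded, flags consistent", {
  cfg <- spatial_sim_config(
    n_spots_per_sample = 120, n_genes = 150,
    regions = list(list(name = "DCN", fraction = 1, n_markers = 0, marker_log2 = 0)),
    seed = 5)
  ds <- generate_spatial(cfg)
  des <- pseudobulk_design("region", n_splits = 3, min_spots = 10, seed = 50)
  res <- run_consensus(ds, des, R = 1, min_reps = 5)$DCN
  expect_true(all(res$lrt$fraction %in% c(0, 1)))
  for (ct in res$contrasts) {
    expect_true(all(ct$fraction %in% c(0, 1)))
    expect_true(all(ct$sig == (res$lrt$sig_lrt & ct$fraction > 0.8)))
  }
  expect_equal(res$thresholds$R, 1)
})

test_that("larger R tightens the Monte-Carlo spread of consensus fractions", {
  # weak planted effect so per-run significance is genuinely borderline
  progs <- list(list(genes = c("Fos.like", "Junb.like", "Egr1.like", "Npas4.like"),
                     region = "DCN", conditions = c("CD", "TN"), log2fc = 0.5))
  cfg <- spatial_sim_config(
    n_spots_per_sample = 400, n_genes = 120,
    regions = list(list(name = "DCN", fraction = 1, n_markers = 0, marker_log2 = 0)),
    effect_programs = progs, seed = 9)
  ds <- generate_spatial(cfg)
  frac_block <- function(R, base_seed) {
    des <- pseudobulk_design("region", n_splits = 2, min_spots = 10, seed = base_seed)
    run_consensus(ds, des, R = R)$DCN$contrasts$CD_vs_HC$fraction
  }
  small <- sapply(1:4, function(b) frac_block(8, 1000 * b))
  large <- sapply(1:4, function(b) frac_block(32, 1000 * b))
  vs <- apply(small, 1, var); vl <- apply(large, 1, var)
  keep <- vs + vl > 0
  expect_gt(mean(vs[keep]), mean(vl[keep]))
})
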