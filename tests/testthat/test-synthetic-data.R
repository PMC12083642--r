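test_that("generators are deterministic given config and seed", {
  cfg <- spatial_sim_config(n_spots_per_sample = 200, n_genes = 120,
                            effect_programs = list(), seed = 3)
  d1 <- generate_spatial(cfg); d2 <- generate_spatial(cfg)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$obs, d2$obs)

  scfg <- sn_sim_config(n_nuclei = 300, n_genes = 150, seed = 4)
  s1 <- generate_snrna(scfg); s2 <- generate_snrna(scfg)
  expect_identical(s1$counts, s2$counts)

  g1 <- generate_gene_sets("regulon", scfg, n_sets = 4, seed = 9)
  g2 <- generate_gene_sets("regulon", scfg, n_sets = 4, seed = 9)
  expect_identical(g1, g2)
})

test_that("invalid configurations are rejected", {
  expect_error(spatial_sim_config(baseline_mean = 0), "baseline_mean")
  expect_error(spatial_sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(spatial_sim_config(mito_fraction_range = c(0.5, 0.2)), "mito")
  bad <- default_spatial_regions(); bad[[1]]$fraction <- 0.5
  expect_error(spatial_sim_config(regions = bad), "sum to 1")
  expect_error(sn_sim_config(cdr_spread = -0.1), "cdr_spread")
})

test_that("a +2 log2 marker elevation yields an in/out mean ratio near 4", {
  regions <- list(list(name = "A", fraction = 0.5, n_markers = 10, marker_log2 = 2),
                  list(name = "B", fraction = 0.5, n_markers = 0, marker_log2 = 0))
  cfg <- spatial_sim_config(n_spots_per_sample = 3000, n_genes = 200,
                            regions = regions, effect_programs = list(),
                            baseline_programs = list(), baseline_sdlog = 0,
                            conditions = "HC", seed = 5)
  ds <- generate_spatial(cfg)
  markers <- attr(ds$var, "markers")$A
  inA <- ds$obs$region == "A"
  ratio <- mean(as.matrix(ds$counts[inA, markers])) /
    mean(as.matrix(ds$counts[!inA, markers]))
  expect_gte(ratio, 3.5)
  expect_lte(ratio, 4.5)
})

test_that("degenerate mito range gives zero mitochondrial counts", {
  cfg <- spatial_sim_config(n_spots_per_sample = 100, n_genes = 100,
                            mito_fraction_range = c(0, 0),
                            effect_programs = list(), baseline_programs = list(),
                            conditions = "HC", seed = 1)
  ds <- generate_spatial(cfg)
  expect_true(all(ds$counts[, ds$var$mito] == 0))
})

test_that("counts match the configured NB marginals without library scaling", {
  cfg <- spatial_sim_config(
    n_spots_per_sample = 4000, n_genes = 60, baseline_mean = 2,
    baseline_sdlog = 0,
    nb_dispersion = 0.4, libsize_sdlog = 0, mito_fraction_range = c(0, 0),
    regions = list(list(name = "A", fraction = 1, n_markers = 0, marker_log2 = 0)),
    effect_programs = list(), baseline_programs = list(),
    conditions = "HC", seed = 8)
  ds <- generate_spatial(cfg)
  X <- as.matrix(ds$counts[, !ds$var$mito])
  m <- colMeans(X); v <- apply(X, 2, var)
  expect_lt(max(abs(m - 2)), 0.15)                  # Monte-Carlo band, n = 4000
  expect_lt(max(abs(v - (2 + 0.4 * 4))), 0.6)       # var = mu + alpha mu^2 = 3.6
})

test_that("ground-truth labels partition every observation", {
  ds <- generate_spatial(spatial_sim_config(n_spots_per_sample = 300,
                                            n_genes = 120, seed = 2))
  expect_false(anyNA(ds$obs$region))
  expect_setequal(unique(ds$obs$region),
                  vapply(default_spatial_regions(), `[[`, character(1), "name"))
  sn <- generate_snrna(sn_sim_config(n_nuclei = 600, n_genes = 150, seed = 2))
  expect_false(anyNA(sn$obs$cell_type))
  expect_true(all(is.na(sn$obs$subtype) == (sn$obs$cell_type != "Inh_DCN")))
})

test_that("zero subtype fraction yields no such nuclei; cdr_spread controls detection spread", {
  subs <- default_inhibitory_subtypes()
  subs[[1]]$fraction <- 0; subs[[2]]$fraction <- 0.75
  cfg <- sn_sim_config(n_nuclei = 600, n_genes = 150,
                       inhibitory_subtypes = subs, seed = 3)
  ds <- generate_snrna(cfg)
  expect_false("Inh_Kit" %in% ds$obs$subtype)

  one_type <- list(list(name = "Astrocyte", fraction = 1, n_markers = 0, marker_log2 = 0))
  base <- list(n_nuclei = 900, n_genes = 200, cell_types = one_type,
               inhibitory_subtypes = default_inhibitory_subtypes(),
               baseline_programs = list(), effect_programs = list(),
               mito_fraction_range = c(0, 0), seed = 6)
  flat <- generate_snrna(do.call(sn_sim_config, c(base, cdr_spread = 0)))
  wide <- generate_snrna(do.call(sn_sim_config, c(base, cdr_spread = 0.6)))
  expect_gt(sd(compute_cdr(wide)), 2 * sd(compute_cdr(flat)))
})

test_that("planted Grm5-like effect is recovered by group means within 0.2 log2", {
  types <- list(list(name = "Inh_DCN", fraction = 1, n_markers = 0, marker_log2 = 0))
  subs <- default_inhibitory_subtypes()
  subs[[1]]$fraction <- 1; subs[[2]]$fraction <- 0; subs[[3]]$fraction <- 0
  cfg <- sn_sim_config(n_nuclei = 1000, n_genes = 200, cell_types = types,
                       inhibitory_subtypes = subs, seed = 7)
  ds <- generate_snrna(cfg)   # >= 300 Kit-like nuclei per condition
  j <- match("Grm5.like", ds$var$id)
  m <- tapply(as.numeric(ds$counts[, j]), as.character(ds$obs$condition), mean)
  expect_lt(abs(log2(m[["CD"]] / m[["HC"]]) - 1), 0.2)
  expect_lt(abs(log2(m[["TN"]] / m[["HC"]]) - 1), 0.2)
})

test_that("reference signatures align with the generator truth", {
  cfg <- spatial_sim_config(n_spots_per_sample = 200, n_genes = 150, seed = 1)
  sig <- generate_reference_signatures(cfg)
  sig2 <- generate_reference_signatures(cfg)
  expect_identical(sig, sig2)
  markers <- attr(cereFC:::build_gene_table(cfg), "markers")
  for (r in names(attr(sig, "region_map"))) {
    region <- attr(sig, "region_map")[[r]]
    for (g in markers[[region]])
      expect_equal(unname(which.max(sig[, g])), match(r, rownames(sig)))
  }
})

test_that("NNLS round-trips a pure pseudo-spot onto its cell type", {
  cfg <- spatial_sim_config(n_spots_per_sample = 100, n_genes = 150, seed = 1)
  sig <- generate_reference_signatures(cfg)
  pure <- round(20 * sig["DCN_type", , drop = FALSE])
  ds <- tiny_dataset(pure, mito = startsWith(colnames(sig), "mt-"))
  ds$var$id <- colnames(sig)
  colnames(ds$counts) <- colnames(sig)
  ab <- estimate_abundance(ds, sig)
  expect_gte(ab[1, "DCN_type"] / sum(ab[1, ]), 0.9)
})

test_that("gene set generation: empty request, full program overlap, null distractors", {
  cfg <- sn_sim_config(n_nuclei = 300, n_genes = 200, seed = 2)
  empty <- generate_gene_sets("pathway", cfg, n_sets = 0, active_genes = NULL)
  expect_length(empty, 0)

  regs <- generate_gene_sets("regulon", cfg, n_sets = 5, set_size = 10, seed = 2)
  expect_identical(regs$Reg.active, cfg$effect_programs[[1]]$genes)

  expect_error(generate_gene_sets("regulon", cfg, active_genes = "nope"),
               "unknown gene id")

  # distractor score distribution centres at the null expectation of the
  # recovery-curve score: E[score] = (R/G) * T(T+1)/2 / sum(min(k, R))
  ds <- generate_snrna(cfg)
  nrm <- normalize_log1p(ds)
  set.seed(99)
  scores <- replicate(40, {
    rg <- sample(ds$var$id, 12)
    mean(vapply(sample(n_obs(ds), 25), function(i) {
      v <- as.numeric(nrm$values[i, ]); names(v) <- ds$var$id
      aucell_score(v, rg, 0.1)
    }, numeric(1)))
  })
  G <- 200; T_ <- 20; R <- 12
  e_null <- (R / G) * T_ * (T_ + 1) / 2 / sum(pmin(seq_len(T_), R))
  expect_lt(abs(mean(scores) - e_null), 0.03)
})
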