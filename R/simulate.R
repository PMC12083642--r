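#' Configuration for the spatial (Visium-like) simulator
#'
#' Describes a stated world the downstream pipeline assumes: spots on a
#' hexagonal lattice partitioned into contiguous region bands, gene-independent
#' negative-binomial counts (variance mu + dispersion * mu^2) with region
#' marker programs, log-normal library-size factors, per-spot mitochondrial
#' fractions, and condition-dependent effect programs. One sample per
#' condition mirrors the n = 1 Visium design; `samples_per_condition` can be
#' raised to exercise batch handling.
#'
#' Default effect programs plant an immediate-early-gene-like program of four
#' genes in the DCN: three genes (Fos/Junb/Egr1-like) induced in both CD and
#' TN with log2 effect 1, and one Npas4-like gene induced in CD only.
#'
#' @param n_spots_per_sample spots per sample (paper-scale: 3,000-3,500)
#' @param n_genes size of the gene universe
#' @param baseline_mean mean UMI per gene per spot before programs; marker,
#'   mitochondrial and program genes sit exactly at this baseline (times their
#'   configured elevations) so planted effects act at a controlled expression
#'   level
#' @param baseline_sdlog sdlog of the log-normal spread of baseline means for
#'   the remaining (filler) genes, centred so their expectation stays at
#'   `baseline_mean`; a realistic transcriptome spans a continuum of
#'   expression levels, which anchors the mean-variance trend used by HVG
#'   selection (0 gives every filler the same mean)
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha * mu^2)
#' @param spacing hex lattice spacing, arbitrary units
#' @param regions list of `list(name, fraction, n_markers, marker_log2)`;
#'   fractions must sum to 1
#' @param mito_fraction_range per-spot expected mitochondrial fraction is
#'   drawn uniformly from this interval
#' @param n_mito_genes number of `mt-` prefixed genes
#' @param libsize_sdlog sdlog of log-normal library-size factors
#' @param conditions condition labels (one sample each by default)
#' @param samples_per_condition samples per condition
#' @param baseline_programs list of `list(genes, group, log2)` applied in all
#'   conditions (group = region name); the default elevates the IEG-program
#'   genes x4 in the DCN so the planted effects act on well-expressed genes,
#'   as immediate early genes are in tissue
#' @param effect_programs list of `list(genes, region, conditions, log2fc)`
#' @param seed RNG seed; identical config + seed gives identical data
#' @return SpatialSimConfig object
#' @export
spatial_sim_config <- function(n_spots_per_sample = 3200,
                               n_genes = 2000,
                               baseline_mean = 0.5,
                               baseline_sdlog = 1,
                               nb_dispersion = 0.5,
                               spacing = 1,
                               regions = default_spatial_regions(),
                               mito_fraction_range = c(0.05, 0.25),
                               n_mito_genes = 13,
                               libsize_sdlog = 0.35,
                               conditions = c("HC", "CD", "TN"),
                               samples_per_condition = 1,
                               baseline_programs = default_spatial_baseline_programs(),
                               effect_programs = default_ieg_programs(),
                               seed = 1L) {
  cfg <- list(n_spots_per_sample = n_spots_per_sample, n_genes = n_genes,
              baseline_mean = baseline_mean, baseline_sdlog = baseline_sdlog,
              nb_dispersion = nb_dispersion,
              spacing = spacing, regions = regions,
              mito_fraction_range = mito_fraction_range,
              n_mito_genes = n_mito_genes, libsize_sdlog = libsize_sdlog,
              conditions = conditions,
              samples_per_condition = samples_per_condition,
              baseline_programs = baseline_programs,
              effect_programs = effect_programs, seed = as.integer(seed))
  class(cfg) <- c("SpatialSimConfig", "list")
  validate_sim_config(cfg)
  cfg
}

#' @rdname spatial_sim_config
#' @export
default_spatial_regions <- function() {
  mk <- function(name, fraction) list(name = name, fraction = fraction,
                                      n_markers = 10, marker_log2 = 3)
  list(mk("molecular_layer", 0.22), mk("granular_layer", 0.28),
       mk("purkinje_layer", 0.08), mk("DCN", 0.12),
       mk("white_matter", 0.10), mk("medulla", 0.20))
}

#' @rdname spatial_sim_config
#' @export
default_spatial_baseline_programs <- function() {
  list(list(genes = c("Fos.like", "Junb.like", "Egr1.like", "Npas4.like"),
            group = "DCN", log2 = 2))
}

#' @rdname spatial_sim_config
#' @export
default_ieg_programs <- function(log2fc = 1.0) {
  list(list(genes = c("Fos.like", "Junb.like", "Egr1.like"), region = "DCN",
            conditions = c("CD", "TN"), log2fc = log2fc),
       list(genes = "Npas4.like", region = "DCN",
            conditions = "CD", log2fc = log2fc))
}

#' Configuration for the single-nucleus simulator
#'
#' Six DCN cell types with marker programs; inhibitory nuclei carry one of
#' three subtypes tagged by a single high marker gene (Kit/Zfhx4/Piezo2-like)
#' plus a small support program. Per-cell detection rate varies through a
#' log-normal whole-transcriptome scaling with sdlog `cdr_spread`
#' (`cdr_spread = 0` makes expected detection equal across nuclei). Baseline
#' programs elevate a Grm5-like gene in all inhibitory nuclei and
#' myelination-like genes in oligodendrocytes so the planted condition effects
#' act on well-expressed genes: Grm5-like +1 log2 in the Kit-like subtype
#' under CD and TN; the myelination-like program +1 log2 in oligodendrocytes
#' under TN only (hence TN vs CD differential).
#'
#' @param n_nuclei total nuclei across conditions (paper-scale: 24,290)
#' @param cell_types list of `list(name, fraction, n_markers, marker_log2)`
#' @param inhibitory_subtypes list of `list(name, marker, fraction,
#'   marker_log2, n_support, support_log2)`; fractions sum to 1 within
#'   inhibitory nuclei
#' @param cdr_spread sdlog of the per-cell detection scaling (>= 0)
#' @param baseline_programs list of `list(genes, group, log2)` applied in all
#'   conditions to a cell type or subtype
#' @param effect_programs list of `list(genes, group, conditions, log2fc)`
#' @inheritParams spatial_sim_config
#' @return SnSimConfig object
#' @export
sn_sim_config <- function(n_nuclei = 24000,
                          n_genes = 2000,
                          baseline_mean = 0.5,
                          baseline_sdlog = 1,
                          nb_dispersion = 0.5,
                          cell_types = default_sn_cell_types(),
                          inhibitory_subtypes = default_inhibitory_subtypes(),
                          cdr_spread = 0.35,
                          mito_fraction_range = c(0.01, 0.10),
                          n_mito_genes = 13,
                          conditions = c("HC", "CD", "TN"),
                          samples_per_condition = 1,
                          baseline_programs = default_sn_baseline_programs(),
                          effect_programs = default_sn_programs(),
                          seed = 1L) {
  cfg <- list(n_nuclei = n_nuclei, n_genes = n_genes,
              baseline_mean = baseline_mean, baseline_sdlog = baseline_sdlog,
              nb_dispersion = nb_dispersion,
              cell_types = cell_types, inhibitory_subtypes = inhibitory_subtypes,
              cdr_spread = cdr_spread, mito_fraction_range = mito_fraction_range,
              n_mito_genes = n_mito_genes, conditions = conditions,
              samples_per_condition = samples_per_condition,
              baseline_programs = baseline_programs,
              effect_programs = effect_programs, seed = as.integer(seed))
  class(cfg) <- c("SnSimConfig", "list")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sn_sim_config
#' @export
default_sn_cell_types <- function() {
  mk <- function(name, fraction) list(name = name, fraction = fraction,
                                      n_markers = 10, marker_log2 = 3)
  list(mk("Exc_DCN", 0.20), mk("Inh_DCN", 0.08), mk("Astrocyte", 0.20),
       mk("Oligodendrocyte", 0.35), mk("OPC", 0.10), mk("Microglia", 0.07))
}

#' @rdname sn_sim_config
#' @export
default_inhibitory_subtypes <- function() {
  mk <- function(name, marker, fraction)
    list(name = name, marker = marker, fraction = fraction,
         marker_log2 = 4, n_support = 5, support_log2 = 2)
  list(mk("Inh_Kit", "Kit.like", 0.35),
       mk("Inh_Zfhx4", "Zfhx4.like", 0.40),
       mk("Inh_Piezo2", "Piezo2.like", 0.25))
}

#' @rdname sn_sim_config
#' @export
default_sn_baseline_programs <- function() {
  list(list(genes = "Grm5.like", group = "Inh_DCN", log2 = 2),
       list(genes = paste0("Myel.like", 1:8), group = "Oligodendrocyte", log2 = 2))
}

#' @rdname sn_sim_config
#' @export
default_sn_programs <- function() {
  list(list(genes = "Grm5.like", group = "Inh_Kit",
            conditions = c("CD", "TN"), log2fc = 1.0),
       list(genes = paste0("Myel.like", 1:8), group = "Oligodendrocyte",
            conditions = "TN", log2fc = 1.0))
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(...) stop("invalid simulator configuration: ", ..., call. = FALSE)
  if (cfg$baseline_mean <= 0) stop_cfg("baseline_mean must be > 0")
  if (cfg$nb_dispersion <= 0) stop_cfg("nb_dispersion must be > 0")
  r <- cfg$mito_fraction_range
  if (length(r) != 2 || any(r < 0) || any(r >= 1) || r[1] > r[2])
    stop_cfg("mito_fraction_range must be an interval within [0,1)")
  groups <- if (inherits(cfg, "SpatialSimConfig")) cfg$regions else cfg$cell_types
  fr <- vapply(groups, `[[`, numeric(1), "fraction")
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
    stop_cfg("group fractions must be nonnegative and sum to 1")
  if (!is.null(cfg$inhibitory_subtypes)) {
    sf <- vapply(cfg$inhibitory_subtypes, `[[`, numeric(1), "fraction")
    if (any(sf < 0) || abs(sum(sf) - 1) > 1e-8)
      stop_cfg("inhibitory subtype fractions must sum to 1")
  }
  for (p in cfg$effect_programs %||% list())
    if (!all(is.finite(p$log2fc))) stop_cfg("effect sizes must be finite")
  if (!is.null(cfg$cdr_spread) && cfg$cdr_spread < 0)
    stop_cfg("cdr_spread must be >= 0")
  invisible(cfg)
}

# ---- gene universe -------------------------------------------------------

# Assigns readable ids to the gene universe: mt-* mitochondrial genes first,
# then per-group marker blocks, then named special genes used by baseline and
# effect programs; the remainder keep generic g#### ids.
build_gene_table <- function(cfg) {
  n <- cfg$n_genes
  ids <- sprintf("g%04d", seq_len(n))
  ptr <- 1L
  take <- function(k) {
    if (k <= 0) return(integer(0))
    if (ptr + k - 1L > n) stop("n_genes too small for configured programs")
    idx <- seq.int(ptr, ptr + k - 1L)
    ptr <<- ptr + k
    idx
  }
  mito_idx <- take(cfg$n_mito_genes)
  ids[mito_idx] <- paste0("mt-", seq_along(mito_idx))
  groups <- if (inherits(cfg, "SpatialSimConfig")) cfg$regions else cfg$cell_types
  markers <- list()
  for (g in groups) {
    idx <- take(g$n_markers)
    ids[idx] <- paste0(g$name, ".mk", seq_along(idx))
    markers[[g$name]] <- ids[idx]
  }
  if (!is.null(cfg$inhibitory_subtypes)) {
    for (s in cfg$inhibitory_subtypes) {
      idx <- take(1L + s$n_support)
      ids[idx] <- c(s$marker, paste0(s$name, ".prog", seq_len(s$n_support)))
      markers[[s$name]] <- ids[idx]
    }
  }
  special <- unique(unlist(c(lapply(cfg$baseline_programs %||% list(), `[[`, "genes"),
                             lapply(cfg$effect_programs %||% list(), `[[`, "genes"))))
  special <- setdiff(special, ids)
  if (length(special)) ids[take(length(special))] <- special
  var <- data.frame(id = ids, mito = seq_len(n) %in% mito_idx,
                    stringsAsFactors = FALSE)
  # filler genes get log-normal baseline means (expectation baseline_mean);
  # named/marker/mito genes sit exactly at baseline_mean; drawn from a
  # dedicated RNG stream so signatures and generators agree
  baseline <- rep(cfg$baseline_mean, n)
  sdl <- cfg$baseline_sdlog %||% 0
  if (sdl > 0 && ptr <= n) {
    idx <- seq.int(ptr, n)
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed((cfg$seed + 77711L) %% .Machine$integer.max)
    baseline[idx] <- cfg$baseline_mean *
      stats::rlnorm(length(idx), meanlog = -sdl^2 / 2, sdlog = sdl)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv) else
      rm(".Random.seed", envir = .GlobalEnv)
  }
  attr(var, "baseline") <- baseline
  attr(var, "markers") <- markers
  var
}

# expected mean vector for one group (region or cell type/subtype) under one
# condition; mitochondrial scaling is applied per observation later
group_mean_vector <- function(cfg, var, group, condition, subtype = NULL) {
  mu <- attr(var, "baseline") %||% rep(cfg$baseline_mean, nrow(var))
  names(mu) <- var$id
  markers <- attr(var, "markers")
  groups <- if (inherits(cfg, "SpatialSimConfig")) cfg$regions else cfg$cell_types
  for (g in groups) if (g$name == group)
    mu[markers[[g$name]]] <- mu[markers[[g$name]]] * 2^g$marker_log2
  if (!is.null(subtype)) {
    for (s in cfg$inhibitory_subtypes) if (s$name == subtype) {
      mu[s$marker] <- mu[s$marker] * 2^s$marker_log2
      supp <- setdiff(markers[[s$name]], s$marker)
      mu[supp] <- mu[supp] * 2^s$support_log2
    }
  }
  for (p in cfg$baseline_programs %||% list())
    if (p$group %in% c(group, subtype)) mu[p$genes] <- mu[p$genes] * 2^p$log2
  for (p in cfg$effect_programs %||% list()) {
    hits <- if (inherits(cfg, "SpatialSimConfig")) p$region %in% group
            else p$group %in% c(group, subtype)
    if (hits && condition %in% p$conditions) mu[p$genes] <- mu[p$genes] * 2^p$log2fc
  }
  mu
}

# draw NB counts for a block of observations sharing a mean vector, with
# per-observation scaling factors and per-observation mito fractions
draw_counts_block <- function(mu, sf, mito, mito_frac, size) {
  G <- length(mu); n <- length(sf)
  M <- matrix(mu, G, n)
  nonmito_sum <- sum(mu[!mito])
  mito_sum <- sum(mu[mito])
  if (any(mito)) {
    fac <- ifelse(mito_frac >= 1, 0,
                  mito_frac / (1 - mito_frac) * nonmito_sum / mito_sum)
    M[mito, ] <- M[mito, , drop = FALSE] * rep(fac, each = sum(mito))
  }
  M <- M * rep(sf, each = G)
  matrix(stats::rnbinom(G * n, mu = as.vector(M), size = size), G, n)
}

# ---- generators ----------------------------------------------------------

#' Generate a synthetic spatial dataset
#'
#' Spots are laid on a hex lattice; regions occupy contiguous vertical bands
#' whose widths follow the configured fractions. Counts are drawn
#' gene-independently from a negative binomial with log-normal library-size
#' factors; ground-truth region labels are stored per spot. Deterministic
#' given `config$seed`.
#'
#' @param config a [spatial_sim_config()]
#' @return ExpressionDataset with obs columns `sample`, `condition`, `x`,
#'   `y`, `region`
#' @export
generate_spatial <- function(config) {
  stopifnot(inherits(config, "SpatialSimConfig"))
  validate_sim_config(config)
  set.seed(config$seed)
  var <- build_gene_table(config)
  lay <- hex_layout(config$n_spots_per_sample, config$spacing)
  region_names <- vapply(config$regions, `[[`, character(1), "name")
  fr <- vapply(config$regions, `[[`, numeric(1), "fraction")
  region <- band_partition(lay$x, lay$y, region_names, fr)
  size <- 1 / config$nb_dispersion

  blocks <- list(); obs <- list()
  for (cond in config$conditions) for (s in seq_len(config$samples_per_condition)) {
    sample_id <- paste0(cond, "_", s)
    mu_by_region <- vapply(region_names, function(r)
      group_mean_vector(config, var, r, cond), numeric(nrow(var)))
    sf <- stats::rlnorm(length(region), 0, config$libsize_sdlog)
    mf <- stats::runif(length(region), config$mito_fraction_range[1],
                       config$mito_fraction_range[2])
    cnt <- matrix(0L, nrow(var), length(region))
    for (r in region_names) {
      j <- which(region == r)
      cnt[, j] <- draw_counts_block(mu_by_region[, r], sf[j], var$mito, mf[j], size)
    }
    blocks[[sample_id]] <- Matrix::Matrix(cnt, sparse = TRUE)  # bound peak memory
    obs[[sample_id]] <- data.frame(sample = sample_id, condition = cond,
                                   x = lay$x, y = lay$y, region = region,
                                   stringsAsFactors = FALSE)
  }
  counts <- Matrix::t(Reduce(Matrix::cbind2, blocks))
  expression_dataset(Matrix::Matrix(counts, sparse = TRUE),
                     do.call(rbind, c(obs, list(make.row.names = FALSE))), var)
}

hex_layout <- function(n, spacing) {
  ncols <- ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  r <- rep(seq_len(nrows) - 1L, each = ncols)[seq_len(n)]
  c_ <- rep(seq_len(ncols) - 1L, times = nrows)[seq_len(n)]
  list(x = (c_ + 0.5 * (r %% 2)) * spacing, y = r * spacing * sqrt(3) / 2)
}

band_partition <- function(x, y, names, fractions) {
  ord <- order(x, y)
  sizes <- diff(round(cumsum(c(0, fractions)) * length(x)))
  lab <- rep(names, times = sizes)
  out <- character(length(x))
  out[ord] <- lab[seq_along(ord)]
  out
}

#' Generate a synthetic single-nucleus dataset
#'
#' As [generate_spatial()] but without coordinates: nuclei carry ground-truth
#' cell type (and, for inhibitory nuclei, subtype) labels, and the per-cell
#' detection rate varies through the `cdr_spread` scaling, recoverable with
#' [compute_cdr()]. Cell-type and subtype counts per sample are fixed at the
#' rounded configured fractions, so a zero fraction yields exactly zero nuclei.
#'
#' @param config a [sn_sim_config()]
#' @return ExpressionDataset with obs columns `sample`, `condition`,
#'   `cell_type`, `subtype`
#' @export
generate_snrna <- function(config) {
  stopifnot(inherits(config, "SnSimConfig"))
  validate_sim_config(config)
  set.seed(config$seed)
  var <- build_gene_table(config)
  type_names <- vapply(config$cell_types, `[[`, character(1), "name")
  tf <- vapply(config$cell_types, `[[`, numeric(1), "fraction")
  sub_names <- vapply(config$inhibitory_subtypes, `[[`, character(1), "name")
  sf_sub <- vapply(config$inhibitory_subtypes, `[[`, numeric(1), "fraction")
  n_samples <- length(config$conditions) * config$samples_per_condition
  n_per_sample <- round(config$n_nuclei / n_samples)
  size <- 1 / config$nb_dispersion

  blocks <- list(); obs <- list()
  for (cond in config$conditions) for (s in seq_len(config$samples_per_condition)) {
    sample_id <- paste0(cond, "_", s)
    type_n <- diff(round(cumsum(c(0, tf)) * n_per_sample))
    names(type_n) <- type_names
    cells <- data.frame(cell_type = rep(type_names, times = type_n),
                        subtype = NA_character_, stringsAsFactors = FALSE)
    inh <- which(cells$cell_type == "Inh_DCN")
    if (length(inh)) {
      sub_n <- diff(round(cumsum(c(0, sf_sub)) * length(inh)))
      cells$subtype[inh] <- rep(sub_names, times = sub_n)
    }
    n <- nrow(cells)
    sf <- if (config$cdr_spread > 0) stats::rlnorm(n, 0, config$cdr_spread) else rep(1, n)
    mf <- stats::runif(n, config$mito_fraction_range[1], config$mito_fraction_range[2])
    cnt <- matrix(0L, nrow(var), n)
    key <- paste(cells$cell_type, cells$subtype)
    for (k in unique(key)) {
      j <- which(key == k)
      ct <- cells$cell_type[j[1]]
      st <- cells$subtype[j[1]]
      mu <- group_mean_vector(config, var, ct, cond,
                              subtype = if (is.na(st)) NULL else st)
      cnt[, j] <- draw_counts_block(mu, sf[j], var$mito, mf[j], size)
    }
    blocks[[sample_id]] <- Matrix::Matrix(cnt, sparse = TRUE)
    obs[[sample_id]] <- data.frame(sample = sample_id, condition = cond,
                                   cell_type = cells$cell_type,
                                   subtype = cells$subtype,
                                   stringsAsFactors = FALSE)
  }
  counts <- Matrix::t(Reduce(Matrix::cbind2, blocks))
  expression_dataset(Matrix::Matrix(counts, sparse = TRUE),
                     do.call(rbind, c(obs, list(make.row.names = FALSE))), var)
}

#' Reference signature table for the spatial simulator
#'
#' One pseudo cell type per region, whose signature row is the generator's
#' true mean expression profile under the control (first-listed) condition
#' with mitochondrial scaling at the midpoint of the configured range.
#' Columns align with the gene ids of [generate_spatial()] output. A synthetic
#' stand-in for an external single-cell reference atlas.
#'
#' @param config a [spatial_sim_config()]
#' @return matrix (cell types x genes) with a `region_map` attribute (named
#'   character vector: cell type -> region)
#' @export
generate_reference_signatures <- function(config) {
  stopifnot(inherits(config, "SpatialSimConfig"))
  validate_sim_config(config)
  var <- build_gene_table(config)
  region_names <- vapply(config$regions, `[[`, character(1), "name")
  f_mid <- mean(config$mito_fraction_range)
  sig <- t(vapply(region_names, function(r) {
    mu <- group_mean_vector(config, var, r, config$conditions[1])
    if (any(var$mito)) {
      fac <- if (f_mid >= 1) 0 else
        f_mid / (1 - f_mid) * sum(mu[!var$mito]) / sum(mu[var$mito])
      mu[var$mito] <- mu[var$mito] * fac
    }
    mu
  }, numeric(nrow(var))))
  rownames(sig) <- paste0(region_names, "_type")
  colnames(sig) <- var$id
  attr(sig, "region_map") <- stats::setNames(region_names, rownames(sig))
  sig
}

#' Generate regulon or pathway gene-set collections
#'
#' For `kind = "regulon"`, one designated active regulon is built from the
#' member genes of a configured effect program (100% overlap by construction);
#' the remaining sets are random draws from the gene universe excluding
#' program genes. For `kind = "pathway"` the target set is constructed the
#' same way. All gene ids must exist in the configured universe.
#'
#' @param kind "regulon" or "pathway"
#' @param config a simulator config (gene universe source)
#' @param n_sets number of distractor sets
#' @param set_size genes per distractor set
#' @param active_genes member genes of the active set; defaults to the first
#'   effect program of the config; NULL with `n_sets = 0` gives an empty
#'   collection
#' @param seed RNG seed for distractor sampling
#' @return named list of character vectors (GMT-style collection)
#' @export
generate_gene_sets <- function(kind = c("regulon", "pathway"), config,
                               n_sets = 10, set_size = 15,
                               active_genes = NULL, seed = 1L) {
  kind <- match.arg(kind)
  var <- build_gene_table(config)
  universe <- var$id
  if (missing(active_genes) && length(config$effect_programs %||% list()))
    active_genes <- config$effect_programs[[1]]$genes
  sets <- list()
  if (!is.null(active_genes)) {
    missing <- setdiff(active_genes, universe)
    if (length(missing))
      stop("unknown gene id(s) in gene set: ", paste(missing, collapse = ", "))
    sets[[if (kind == "regulon") "Reg.active" else "Path.target"]] <- active_genes
  }
  if (n_sets > 0) {
    set.seed(seed)
    program_genes <- unique(unlist(c(lapply(config$effect_programs %||% list(), `[[`, "genes"),
                                     lapply(config$baseline_programs %||% list(), `[[`, "genes"))))
    pool <- setdiff(universe, program_genes)
    prefix <- if (kind == "regulon") "Reg.d" else "Path.d"
    for (i in seq_len(n_sets))
      sets[[paste0(prefix, i)]] <- sample(pool, set_size)
  }
  sets
}
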