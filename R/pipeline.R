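#' Pipeline configuration
#'
#' Bundles dataset location, stage parameters and output directory for
#' [run_pipeline()]. Defaults carry the module defaults: spatial QC profile,
#' 2,000 HVGs, 30 latent components, k = 15 expression neighbors, k = 6
#' spatial neighbors, fusion weight 0.8, Leiden resolution 0.8 (spatial) or
#' 1.0 (snRNA), 99th-quantile binarization with FDR 0.05, and the consensus
#' DEG thresholds (padj < 0.05, |log2FC| > 0.1, consensus > 0.8).
#'
#' @param track "spatial" or "snrna"
#' @param dataset an ExpressionDataset or a directory readable by
#'   [read_dataset()]
#' @param out_dir output directory
#' @param qc,cluster,annotate,deg,sn named lists overriding stage defaults
#' @param resume skip stages whose outputs already exist
#' @param seed pipeline-wide base seed
#' @return PipelineConfig object
#' @export
pipeline_config <- function(track = c("spatial", "snrna"), dataset, out_dir,
                            qc = list(), cluster = list(), annotate = list(),
                            deg = list(), sn = list(), resume = FALSE,
                            seed = 1L) {
  track <- match.arg(track)
  if (is.character(dataset) && !dir.exists(dataset))
    stop("dataset path does not exist: ", dataset)
  defaults <- list(
    qc = list(profile = if (track == "spatial") "spatial" else "snrna"),
    cluster = list(n_hvg = 2000, d = 30, k_expr = 15, k_spatial = 6,
                   alpha_expr = 0.8,
                   resolution = if (track == "spatial") 0.8 else 1.0),
    annotate = list(signatures = NULL, region_map = NULL,
                    quantile = 0.99, fdr = 0.05),
    deg = list(mode = "subregion", group_col = "region",
               repeats = 100, consensus = 0.8, padj = 0.05, lfc = 0.1,
               min_spots = 10, n_splits = 2, min_reps = 3),
    sn = list(inhibitory_type = "Inh_DCN",
              markers = c(Inh_Kit = "Kit.like", Inh_Zfhx4 = "Zfhx4.like",
                          Inh_Piezo2 = "Piezo2.like"),
              regulons = NULL, pathways = NULL,
              top_fraction = 0.05, tf_alpha = 0.01, enrich_fdr = 0.05))
  merged <- list(qc = utils::modifyList(defaults$qc, qc),
                 cluster = utils::modifyList(defaults$cluster, cluster),
                 annotate = utils::modifyList(defaults$annotate, annotate),
                 deg = utils::modifyList(defaults$deg, deg),
                 sn = utils::modifyList(defaults$sn, sn))
  structure(c(list(track = track, dataset = dataset, out_dir = out_dir,
                   resume = resume, seed = as.integer(seed)), merged),
            class = c("PipelineConfig", "list"))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Spatial track: qc -> cluster -> annotate -> deg-spatial. Single-nucleus
#' track: qc -> cluster -> subtype -> deg-sn -> tf -> enrich. Every stage
#' writes TSV outputs under `out_dir` and is recorded (with seeds and file
#' checksums) in `manifest.json`. With `resume = TRUE`, stages whose outputs
#' already exist are skipped; once a stage is recomputed, all downstream
#' stages are recomputed too. Re-running with identical config and seeds
#' reproduces identical outputs.
#'
#' @param cfg a [pipeline_config()]
#' @return RunManifest (list), invisibly; also written as JSON
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("cereFC")),
                   track = cfg$track, seed = cfg$seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   parameters = cfg[c("qc", "cluster", "deg")],
                   stages = list())
  dirty <- FALSE
  stage <- function(name, outputs, fn) {
    paths <- file.path(cfg$out_dir, outputs)
    if (cfg$resume && !dirty && all(file.exists(paths))) {
      manifest$stages[[name]] <<- list(status = "resumed", outputs = outputs)
      return(invisible(NULL))
    }
    dirty <<- TRUE
    fn(paths)
    manifest$stages[[name]] <<- list(
      status = "computed", outputs = outputs,
      md5 = unname(tools::md5sum(paths[file.exists(paths)])))
    invisible(NULL)
  }

  ds <- if (is.character(cfg$dataset)) read_dataset(cfg$dataset) else cfg$dataset
  message("pipeline defaults: qc profile=", cfg$qc$profile,
          " | hvg=", cfg$cluster$n_hvg, " d=", cfg$cluster$d,
          " k_expr=", cfg$cluster$k_expr, " k_spatial=", cfg$cluster$k_spatial,
          " alpha_expr=", cfg$cluster$alpha_expr,
          " resolution=", cfg$cluster$resolution,
          " | binarize q=", cfg$annotate$quantile, " fdr=", cfg$annotate$fdr,
          " | deg repeats=", cfg$deg$repeats, " consensus=", cfg$deg$consensus,
          " padj=", cfg$deg$padj, " lfc=", cfg$deg$lfc, " seed=", cfg$seed)

  qc_dir <- file.path(cfg$out_dir, "qc")
  stage("qc", c("qc/matrix.mtx", "qc/obs.tsv", "qc/var.tsv", "qc_report.tsv"),
        function(paths) {
          ds_f <- filter_dataset(ds, qc_profile(cfg$qc$profile))
          write_dataset(ds_f, qc_dir)
          write_tsv(attr(ds_f, "qc_report"), file.path(cfg$out_dir, "qc_report.tsv"))
        })
  ds_f <- read_dataset(qc_dir)

  stage("cluster", "clusters.tsv", function(paths) {
    norm <- normalize_log1p(ds_f)
    hvgs <- select_hvg(ds_f, min(cfg$cluster$n_hvg, n_genes(ds_f)))
    emb <- latent_embed(norm, hvgs, d = min(cfg$cluster$d, length(hvgs)))
    g_expr <- expression_connectivities(emb, k = cfg$cluster$k_expr)
    W <- if (cfg$track == "spatial") {
      g_sp <- spatial_adjacency(ds_f$obs[, c("x", "y")], k = cfg$cluster$k_spatial)
      fuse_graphs(g_expr, g_sp, alpha_expr = cfg$cluster$alpha_expr)
    } else g_expr
    labels <- leiden_cluster(W, resolution = cfg$cluster$resolution, seed = cfg$seed)
    write_tsv(data.frame(obs = rownames(ds_f$counts), cluster = labels),
              paths[1])
  })
  clusters <- utils::read.table(file.path(cfg$out_dir, "clusters.tsv"),
                                header = TRUE, sep = "\t")$cluster

  if (cfg$track == "spatial") {
    stage("annotate", c("abundance.tsv", "enrichment.tsv", "regions.tsv"),
          function(paths) {
            sig <- cfg$annotate$signatures
            if (is.character(sig))
              sig <- as.matrix(utils::read.table(sig, header = TRUE, sep = "\t",
                                                 check.names = FALSE))
            if (is.null(sig)) stop("annotate stage requires signatures")
            region_map <- cfg$annotate$region_map %||% attr(sig, "region_map")
            ab <- estimate_abundance(ds_f, sig)
            bin <- binarize_abundance(ab, q = cfg$annotate$quantile)
            enr <- annotate_clusters(bin, clusters, region_map,
                                     fdr_max = cfg$annotate$fdr)
            write_tsv(as.data.frame(ab), paths[1])
            write_tsv(enr$table, paths[2])
            write_tsv(data.frame(obs = rownames(ds_f$counts), cluster = clusters,
                                 region = unname(enr$assignment[as.character(clusters)])),
                      paths[3])
          })
    regions <- utils::read.table(file.path(cfg$out_dir, "regions.tsv"),
                                 header = TRUE, sep = "\t")$region
    stage("deg-spatial", "deg_manifest.tsv", function(paths) {
      ds_deg <- ds_f
      ds_deg$obs$deg_group <- regions
      keep <- !is.na(regions) & regions != "unassigned"
      ds_deg <- ds_deg[keep, ]
      design <- pseudobulk_design("deg_group", n_splits = cfg$deg$n_splits,
                                  min_spots = cfg$deg$min_spots, seed = cfg$seed)
      res <- run_consensus(ds_deg, design, R = cfg$deg$repeats,
                           consensus = cfg$deg$consensus,
                           padj_max = cfg$deg$padj, lfc_min = cfg$deg$lfc,
                           min_reps = cfg$deg$min_reps)
      files <- character(0)
      for (g in names(res)) {
        f <- paste0("deg_", gsub("[^A-Za-z0-9_.-]", "_", g), "_lrt.tsv")
        write_tsv(res[[g]]$lrt, file.path(cfg$out_dir, f)); files <- c(files, f)
        for (ct in names(res[[g]]$contrasts)) {
          f <- paste0("deg_", gsub("[^A-Za-z0-9_.-]", "_", g), "_", ct, ".tsv")
          write_tsv(res[[g]]$contrasts[[ct]], file.path(cfg$out_dir, f))
          files <- c(files, f)
        }
      }
      write_tsv(data.frame(file = files), paths[1])
    })
  } else {
    stage("subtype", "subtypes.tsv", function(paths) {
      inh <- if (!is.null(ds_f$obs$cell_type))
        which(ds_f$obs$cell_type == cfg$sn$inhibitory_type)
      else seq_len(n_obs(ds_f))
      ds_i <- ds_f[inh, ]
      norm_i <- normalize_log1p(ds_i)
      hvgs <- select_hvg(ds_i, min(cfg$cluster$n_hvg, n_genes(ds_i)))
      emb <- latent_embed(norm_i, hvgs,
                          d = min(cfg$cluster$d, length(hvgs), n_obs(ds_i) - 1))
      g <- expression_connectivities(emb, k = min(cfg$cluster$k_expr, n_obs(ds_i) - 1))
      lab <- leiden_cluster(g, resolution = 1.0, seed = cfg$seed)
      sub <- assign_inhibitory_subtypes(norm_i, lab, cfg$sn$markers)
      write_tsv(data.frame(obs = rownames(ds_i$counts), cluster = lab,
                           subtype = sub), paths[1])
    })
    subtab <- utils::read.table(file.path(cfg$out_dir, "subtypes.tsv"),
                                header = TRUE, sep = "\t")
    stage("deg-sn", "deg_sn_manifest.tsv", function(paths) {
      rows <- match(subtab$obs, rownames(ds_f$counts))
      norm_i <- normalize_log1p(ds_f[rows, ])
      res <- run_hurdle_deg(norm_i, subtab$subtype)
      files <- character(0)
      for (g in names(res)) {
        f <- paste0("deg_sn_", g, "_lrt.tsv")
        write_tsv(res[[g]]$lrt, file.path(cfg$out_dir, f)); files <- c(files, f)
        for (ct in names(res[[g]]$contrasts)) {
          f <- paste0("deg_sn_", g, "_", ct, ".tsv")
          write_tsv(res[[g]]$contrasts[[ct]], file.path(cfg$out_dir, f))
          files <- c(files, f)
        }
      }
      write_tsv(data.frame(file = files), paths[1])
    })
    if (!is.null(cfg$sn$regulons)) {
      stage("tf", c("ras.tsv", "tf_test.tsv"), function(paths) {
        regs <- cfg$sn$regulons
        if (is.character(regs)) regs <- read_gmt(regs)
        norm <- normalize_log1p(ds_f)
        ras <- ras_matrix(norm, regs, top_fraction = cfg$sn$top_fraction)
        write_tsv(as.data.frame(ras), paths[1])
        grpcol <- ds_f$obs$cell_type %||% rep("all", n_obs(ds_f))
        tt <- differential_tf(ras, grpcol, as.character(ds_f$obs$condition),
                              cfg$sn$tf_cell_type %||% grpcol[1],
                              "CD", "TN", alpha = cfg$sn$tf_alpha)
        write_tsv(tt, paths[2])
      })
    }
    if (!is.null(cfg$sn$pathways)) {
      stage("enrich", "enrichment_sn.tsv", function(paths) {
        sets <- cfg$sn$pathways
        if (is.character(sets)) sets <- read_gmt(sets)
        manif <- utils::read.table(file.path(cfg$out_dir, "deg_sn_manifest.tsv"),
                                   header = TRUE, sep = "\t")
        degs <- character(0)
        for (f in manif$file) {
          if (grepl("_lrt\\.tsv$", f)) next
          tab <- utils::read.table(file.path(cfg$out_dir, f), header = TRUE, sep = "\t")
          degs <- union(degs, tab$gene[tab$sig])
        }
        res <- ora(intersect(degs, ds_f$var$id), ds_f$var$id, sets)
        write_tsv(res, paths[1])
      })
    }
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
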