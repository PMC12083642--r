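# shared small simulator configurations

# four equal contiguous regions, no condition effects; marker_log2 sets the
# expression signal-to-noise for clustering tests
four_region_cfg <- function(seed, marker_log2 = 3, n_spots = 900,
                            n_genes = 400, n_markers = 10) {
  regions <- lapply(c("R1", "R2", "R3", "R4"), function(n)
    list(name = n, fraction = 0.25, n_markers = n_markers,
         marker_log2 = marker_log2))
  spatial_sim_config(n_spots_per_sample = n_spots, n_genes = n_genes,
                     regions = regions, effect_programs = list(),
                     baseline_programs = list(), conditions = "HC",
                     seed = seed)
}

# paper-structure spatial world at reduced gene count, with the planted DCN
# IEG program (Fos/Junb/Egr1-like in CD+TN, Npas4-like CD only)
ieg_world_cfg <- function(seed, n_spots = 3200, n_genes = 2100) {
  spatial_sim_config(n_spots_per_sample = n_spots, n_genes = n_genes,
                     seed = seed)
}

# desk-scale snRNA world for the subtype-resolved end-to-end test: the
# inhibitory population is kept at study scale (~1,920 nuclei, matching the
# ~1,980 analyzed inhibitory nuclei) because its size sets the power of the
# subtype DEG statistics; the unrelated cell types are shrunk proportionally
# for runtime
sn_world_cfg <- function(seed, n_nuclei = 6000, n_genes = 800) {
  mk <- function(name, fraction) list(name = name, fraction = fraction,
                                      n_markers = 10, marker_log2 = 3)
  ct <- list(mk("Exc_DCN", 0.148), mk("Inh_DCN", 0.32), mk("Astrocyte", 0.148),
             mk("Oligodendrocyte", 0.258), mk("OPC", 0.074), mk("Microglia", 0.052))
  sn_sim_config(n_nuclei = n_nuclei, n_genes = n_genes, cell_types = ct,
                seed = seed)
}

default_subtype_markers <- c(Inh_Kit = "Kit.like", Inh_Zfhx4 = "Zfhx4.like",
                             Inh_Piezo2 = "Piezo2.like")

# small hand-built dataset: counts matrix with explicit metadata
tiny_dataset <- function(counts, condition = NULL, mito = NULL, x = NULL, y = NULL) {
  n <- nrow(counts); G <- ncol(counts)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("g%03d", seq_len(G))
  obs <- data.frame(sample = rep("HC_1", n))
  if (!is.null(condition)) { obs$condition <- condition; obs$sample <- paste0(condition, "_1") }
  if (!is.null(x)) { obs$x <- x; obs$y <- y }
  var <- data.frame(id = colnames(counts),
                    mito = mito %||% rep(FALSE, G))
  expression_dataset(counts, obs, var)
}
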