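#' Pseudo-replicate design
#'
#' Describes how spots are collapsed into pseudo-replicates: the obs column
#' holding the grouping label (region or subregion), the number of random
#' splits per (group, sample) pair (2 for subregion mode, 3 for region mode),
#' the minimum spot count for a pair to be usable (10), and the base seed.
#'
#' @param group_col obs column with the grouping label
#' @param n_splits pseudo-replicates per (group, sample) pair (>= 2)
#' @param min_spots minimum spots per pair (pairs below are excluded)
#' @param seed base RNG seed
#' @return PseudobulkDesign object
#' @export
pseudobulk_design <- function(group_col, n_splits = 2, min_spots = 10, seed = 1L) {
  if (n_splits < 2) stop("n_splits must be >= 2")
  structure(list(group_col = group_col, n_splits = as.integer(n_splits),
                 min_spots = as.integer(min_spots), seed = as.integer(seed)),
            class = c("PseudobulkDesign", "list"))
}

#' Collapse spots into pseudo-replicates
#'
#' (group, sample) pairs with fewer than `min_spots` spots are excluded; the
#' remaining spots are randomly partitioned into `n_splits` subsets whose
#' sizes differ by at most one, and counts are summed gene-wise per subset.
#' Deterministic given `seed`; gene-wise count totals are conserved exactly
#' within each retained pair.
#'
#' @param ds ExpressionDataset with `sample` and `condition` obs columns
#' @param design a [pseudobulk_design()]
#' @param seed overrides `design$seed` when given (used by the consensus loop)
#' @return PseudobulkMatrix: list with `counts` (pseudo-replicates x genes),
#'   `meta` (group, sample, condition, split) and `var`
#' @export
make_pseudoreplicates <- function(ds, design, seed = NULL) {
  groups <- ds$obs[[design$group_col]]
  if (is.null(groups)) stop("obs column '", design$group_col, "' not found")
  if (is.null(ds$obs$sample)) stop("obs column 'sample' not found")
  set.seed(seed %||% design$seed)
  pairs <- unique(ds$obs[, c("sample"), drop = FALSE])
  key <- paste(groups, ds$obs$sample, sep = "\r")
  counts_list <- list(); meta_list <- list()
  for (k in sort(unique(key))) {
    idx <- which(key == k)
    if (length(idx) < design$min_spots) next
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    shuffled <- idx[sample.int(length(idx))]
    sizes <- rep(length(idx) %/% design$n_splits, design$n_splits)
    extra <- length(idx) %% design$n_splits
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    offsets <- cumsum(c(0, sizes))
    for (s in seq_len(design$n_splits)) {
      members <- shuffled[(offsets[s] + 1):offsets[s + 1]]
      counts_list[[length(counts_list) + 1L]] <-
        Matrix::colSums(ds$counts[members, , drop = FALSE])
      meta_list[[length(meta_list) + 1L]] <- data.frame(
        group = parts[1], sample = parts[2],
        condition = as.character(ds$obs$condition[members[1]]),
        split = s, n_spots = length(members), stringsAsFactors = FALSE)
    }
  }
  if (!length(counts_list))
    stop("no usable groups: every (group, sample) pair has fewer than ",
         design$min_spots, " spots")
  counts <- do.call(rbind, counts_list)
  colnames(counts) <- ds$var$id
  meta <- do.call(rbind, meta_list)
  meta$condition <- factor(meta$condition, levels = c("HC", "CD", "TN"))
  rownames(counts) <- rownames(meta) <-
    paste(meta$group, meta$sample, meta$split, sep = ".")
  structure(list(counts = counts, meta = meta, var = ds$var),
            class = c("PseudobulkMatrix", "list"))
}

#' Gene prevalence filter for pseudo-bulk matrices
#'
#' Removes genes with nonzero counts in fewer than `min_reps`
#' pseudo-replicates, and mitochondrial genes when `drop_mito` is TRUE
#' (3 replicates in subregion mode, 5 in region mode).
#'
#' @param pb PseudobulkMatrix
#' @param min_reps minimum number of pseudo-replicates with nonzero count
#' @param drop_mito drop mito-flagged genes
#' @return filtered PseudobulkMatrix
#' @export
gene_prevalence_filter <- function(pb, min_reps = 3, drop_mito = TRUE) {
  keep <- colSums(pb$counts > 0) >= min_reps
  if (drop_mito) keep <- keep & !pb$var$mito
  pb$counts <- pb$counts[, keep, drop = FALSE]
  pb$var <- pb$var[keep, , drop = FALSE]
  pb
}

#' Pseudo-replicate consensus differential expression
#'
#' For r = 1..R: pseudo-replicates are drawn with seed `design$seed + r`, the
#' prevalence filter applied, and per retained group an NB LRT across
#' conditions plus a Wald test per pairwise contrast is run. A gene's LRT
#' consensus fraction is the share of runs with LRT padj below `padj_max`;
#' `sig_lrt` requires fraction strictly greater than `consensus` ("more than
#' 80%"). Per contrast, the fraction of runs with padj < `padj_max` and
#' |log2FC| > `lfc_min` is recorded; `sig_pairwise` requires `sig_lrt` and
#' that fraction > `consensus`. Genes filtered out (or not converged) in a
#' run count as non-significant in that run. The median log2FC across runs
#' where the gene was tested is reported. R = 1 reproduces the single-run
#' region-mode rule (fractions in {0,1}).
#'
#' @param ds ExpressionDataset (spatial)
#' @param design a [pseudobulk_design()]
#' @param contrasts list of length-2 character vectors, second over first
#' @param R number of repeats (paper default 100 for subregion mode, 1 for
#'   region mode)
#' @param consensus consensus fraction threshold (strict), default 0.8
#' @param padj_max BH-adjusted p threshold, default 0.05
#' @param lfc_min absolute log2FC threshold, default 0.1
#' @param min_reps prevalence filter (3 subregion / 5 region)
#' @param drop_mito drop mitochondrial genes before testing
#' @return named list per group of ConsensusDEGTable objects: each a list
#'   with `lrt` (gene, fraction, sig_lrt) and `contrasts` (per contrast:
#'   gene, fraction, median_log2FC, sig) plus the thresholds used
#' @export
run_consensus <- function(ds, design,
                          contrasts = list(c("HC", "CD"), c("HC", "TN"), c("CD", "TN")),
                          R = 100, consensus = 0.8, padj_max = 0.05,
                          lfc_min = 0.1, min_reps = 3, drop_mito = TRUE) {
  if (R < 1) stop("R must be >= 1")
  if (consensus <= 0 || consensus > 1) stop("consensus must be in (0,1]")
  genes <- ds$var$id
  cnames <- vapply(contrasts, function(ct) paste0(ct[2], "_vs_", ct[1]), character(1))
  groups <- NULL
  acc <- list()   # per group: lrt_sig counts, pair_sig counts, lfc store
  for (r in seq_len(R)) {
    pb_all <- make_pseudoreplicates(ds, design, seed = design$seed + r)
    pb_all <- gene_prevalence_filter(pb_all, min_reps = min_reps, drop_mito = drop_mito)
    if (is.null(groups)) groups <- sort(unique(pb_all$meta$group))
    for (g in groups) {
      sel <- pb_all$meta$group == g
      pb <- pb_all
      pb$counts <- pb$counts[sel, , drop = FALSE]
      pb$meta <- pb$meta[sel, , drop = FALSE]
      if (is.null(acc[[g]])) {
        acc[[g]] <- list(
          lrt = numeric(length(genes)),
          pair = matrix(0, length(genes), length(cnames), dimnames = list(genes, cnames)),
          lfc = array(NA_real_, c(length(genes), length(cnames), R),
                      dimnames = list(genes, cnames, NULL)))
      }
      sf <- size_factors(pb)
      lrt <- nb_lrt(pb, sf = sf)
      lrt_padj <- stats::p.adjust(lrt$p, method = "BH")
      hit <- lrt$gene[!is.na(lrt_padj) & lrt_padj < padj_max]
      acc[[g]]$lrt[match(hit, genes)] <- acc[[g]]$lrt[match(hit, genes)] + 1
      disp <- attr(lrt, "dispersion")
      for (ci in seq_along(contrasts)) {
        ct <- contrasts[[ci]]
        pw <- pairwise_test(pb, ct[1], ct[2], sf = sf, dispersion = disp)
        gi <- match(pw$gene, genes)
        acc[[g]]$lfc[cbind(gi, ci, r)] <- pw$log2FC
        hit <- !is.na(pw$padj) & pw$padj < padj_max & abs(pw$log2FC) > lfc_min
        acc[[g]]$pair[gi[hit], ci] <- acc[[g]]$pair[gi[hit], ci] + 1
      }
    }
  }
  out <- lapply(groups, function(g) {
    a <- acc[[g]]
    lrt_frac <- a$lrt / R
    sig_lrt <- lrt_frac > consensus
    ctabs <- lapply(seq_along(cnames), function(ci) {
      frac <- a$pair[, ci] / R
      med <- apply(a$lfc[, ci, , drop = FALSE], 1, stats::median, na.rm = TRUE)
      data.frame(gene = genes, fraction = unname(frac),
                 median_log2FC = unname(med),
                 sig = unname(sig_lrt & frac > consensus),
                 stringsAsFactors = FALSE)
    })
    names(ctabs) <- cnames
    structure(list(lrt = data.frame(gene = genes, fraction = lrt_frac,
                                    sig_lrt = sig_lrt, stringsAsFactors = FALSE),
                   contrasts = ctabs,
                   thresholds = list(R = R, consensus = consensus,
                                     padj_max = padj_max, lfc_min = lfc_min,
                                     min_reps = min_reps, seed = design$seed)),
              class = c("ConsensusDEGTable", "list"))
  })
  names(out) <- groups
  out
}
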