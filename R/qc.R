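#' QC threshold profiles
#'
#' The two named presets used for spot-level and nucleus-level filtering.
#' Spatial: fewer than 100 genes, more than 8,000 genes, more than 50,000 UMI,
#' or over 35% mitochondrial content excludes a spot. Single-nucleus: fewer
#' than 200 genes, more than 8,000 genes, more than 60,000 UMI, or over 20%
#' mitochondrial content excludes a nucleus. Both drop genes expressed in
#' fewer than 3 observations and the blocklisted rRNA-contamination gene
#' Gm42418.
#'
#' @param min_genes,max_genes detected-gene bounds per observation
#' @param max_umi maximum UMI count per observation
#' @param max_mito_frac maximum mitochondrial fraction, in `[0,1]`
#' @param min_cells_per_gene gene must be detected in at least this many
#'   observations
#' @param gene_blocklist gene ids removed unconditionally
#' @return QCThresholds object
#' @export
qc_thresholds <- function(min_genes, max_genes, max_umi, max_mito_frac,
                          min_cells_per_gene = 3, gene_blocklist = "Gm42418") {
  if (min_genes >= max_genes) stop("min_genes must be < max_genes")
  if (max_mito_frac < 0 || max_mito_frac > 1) stop("max_mito_frac must be in [0,1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_umi = max_umi, max_mito_frac = max_mito_frac,
                 min_cells_per_gene = min_cells_per_gene,
                 gene_blocklist = gene_blocklist),
            class = c("QCThresholds", "list"))
}

#' @rdname qc_thresholds
#' @param profile "spatial" or "snrna"
#' @export
qc_profile <- function(profile = c("spatial", "snrna")) {
  switch(match.arg(profile),
         spatial = qc_thresholds(100, 8000, 50000, 0.35),
         snrna   = qc_thresholds(200, 8000, 60000, 0.20))
}

#' Apply QC filters to a dataset
#'
#' Fixed order of operations: (1) blocklisted genes removed; (2) genes
#' detected in fewer than `min_cells_per_gene` observations removed; (3)
#' observations violating any threshold removed, with detected-gene counts,
#' UMI totals and mitochondrial fractions computed on the gene-filtered
#' matrix. Filtering is idempotent and never alters retained count values.
#'
#' @param ds ExpressionDataset (gene metadata must carry the `mito` flag)
#' @param thresholds a [qc_thresholds()] object
#' @return filtered ExpressionDataset with a `qc_report` attribute
#'   (per-observation pass/fail and reasons)
#' @export
filter_dataset <- function(ds, thresholds) {
  stopifnot(inherits(thresholds, "QCThresholds"))
  if (is.null(ds$var$mito)) stop("gene metadata lacks the 'mito' flag")
  keep_g <- !(ds$var$id %in% thresholds$gene_blocklist)
  ds1 <- ds[, keep_g]
  detected_in <- Matrix::colSums(ds1$counts > 0)
  ds1 <- ds1[, detected_in >= thresholds$min_cells_per_gene]
  if (n_genes(ds1) == 0) stop("empty dataset: no genes pass the QC filters")

  genes_per_obs <- Matrix::rowSums(ds1$counts > 0)
  umi <- Matrix::rowSums(ds1$counts)
  mito_counts <- Matrix::rowSums(ds1$counts[, ds1$var$mito, drop = FALSE])
  mito_frac <- ifelse(umi > 0, mito_counts / umi, 0)
  fail_low <- genes_per_obs < thresholds$min_genes
  fail_high <- genes_per_obs > thresholds$max_genes
  fail_umi <- umi > thresholds$max_umi
  fail_mito <- mito_frac > thresholds$max_mito_frac
  keep_o <- !(fail_low | fail_high | fail_umi | fail_mito)
  if (!any(keep_o)) stop("empty dataset: no observations pass the QC filters")
  out <- ds1[keep_o, ]
  attr(out, "qc_report") <- data.frame(
    n_genes = genes_per_obs, n_umi = umi, mito_frac = mito_frac,
    fail_min_genes = fail_low, fail_max_genes = fail_high,
    fail_max_umi = fail_umi, fail_mito = fail_mito, pass = keep_o)
  out
}

#' Library-size normalization and log transform
#'
#' Scales each observation to `scale_target` total counts (default: the
#' median of per-observation totals) and applies `log1p`. Zeros map to zeros,
#' so sparsity is preserved; observations with zero total stay all-zero (with
#' a warning).
#'
#' @param ds ExpressionDataset
#' @param scale_target positive scalar, or NULL for the median total
#' @return NormalizedMatrix object: list with sparse `values`
#'   (observations x genes), `scale_target`, and the source `var`/`obs`
#' @export
normalize_log1p <- function(ds, scale_target = NULL) {
  totals <- Matrix::rowSums(ds$counts)
  if (is.null(scale_target)) scale_target <- stats::median(totals)
  if (any(totals == 0)) warning(sum(totals == 0), " observation(s) with zero total count")
  fac <- ifelse(totals > 0, scale_target / totals, 0)
  vals <- Matrix::Diagonal(x = fac) %*% ds$counts
  vals@x <- log1p(vals@x)
  structure(list(values = methods::as(vals, "CsparseMatrix"),
                 scale_target = scale_target, obs = ds$obs, var = ds$var),
            class = c("NormalizedMatrix", "list"))
}

#' Highly variable gene selection (Seurat v3 flavor)
#'
#' Per-gene standardized variance on raw counts: a local polynomial
#' (loess, degree 2, span 0.3) regression of log10(variance) on log10(mean)
#' gives an expected standard deviation per gene; counts are standardized
#' with it, clipped at sqrt(n_observations), and the variance of the clipped
#' z-scores ranks the genes (ties broken by gene id; all-zero genes rank
#' last). The default of 2,000 genes matches common practice for this data
#' type.
#'
#' @param ds ExpressionDataset
#' @param n_top number of genes to return (<= number of genes)
#' @return character vector of gene ids, ranked by decreasing standardized
#'   variance, with the full ranking table in attribute `hvg_table`
#' @export
select_hvg <- function(ds, n_top = 2000) {
  if (n_top > n_genes(ds)) stop("n_top exceeds the number of genes")
  X <- ds$counts
  n <- nrow(X)
  mu <- Matrix::colMeans(X)
  ex2 <- Matrix::colSums(X^2) / n
  v <- (ex2 - mu^2) * n / (n - 1)
  std_var <- numeric(length(mu))
  pos <- mu > 0 & v > 0
  if (sum(pos) > 10) {
    fit <- stats::loess(log10(v[pos]) ~ log10(mu[pos]), span = 0.3, degree = 2)
    sd_exp <- sqrt(10^stats::predict(fit, log10(mu[pos])))
    clip <- sqrt(n)
    Xp <- X[, pos, drop = FALSE]
    # variance of clipped z-scores, computed from the sparse structure:
    # zero entries contribute (-mu/sd)^2 (never clipped upward)
    sq <- numeric(sum(pos))
    for (k in seq_len(ncol(Xp))) {
      idx <- (Xp@p[k] + 1):Xp@p[k + 1]
      xs <- if (Xp@p[k + 1] > Xp@p[k]) Xp@x[idx] else numeric(0)
      m <- mu[pos][k]; s <- sd_exp[k]
      z_nz <- pmin((xs - m) / s, clip)
      z_nz <- pmax(z_nz, -clip)
      z0 <- max(min(-m / s, clip), -clip)
      sq[k] <- (sum(z_nz^2) + (n - length(xs)) * z0^2 -
                  (sum(z_nz) + (n - length(xs)) * z0)^2 / n) / (n - 1)
    }
    std_var[pos] <- sq
  } else {
    std_var[pos] <- v[pos]
  }
  ord <- order(-std_var, ds$var$id)
  tab <- data.frame(id = ds$var$id[ord], mean = mu[ord], variance = v[ord],
                    std_variance = std_var[ord], stringsAsFactors = FALSE)
  out <- tab$id[seq_len(n_top)]
  attr(out, "hvg_table") <- tab
  out
}

#' Cellular detection rate
#'
#' Per observation, the fraction of measured genes with a nonzero count.
#' Invariant under library-size scaling of the counts.
#'
#' @param ds ExpressionDataset or NormalizedMatrix
#' @return numeric vector in `[0,1]`, one value per observation
#' @export
compute_cdr <- function(ds) {
  m <- if (inherits(ds, "NormalizedMatrix")) ds$values else ds$counts
  as.numeric(Matrix::rowSums(m > 0) / ncol(m))
}

#' Placeholder doublet-removal stage
#'
#' Doublet detection is delegated to upstream tooling and out of scope here;
#' this no-op stage holds its position in the pipeline and logs that fact.
#'
#' @param ds ExpressionDataset
#' @return `ds`, unchanged
#' @export
remove_doublets <- function(ds) {
  message("doublet removal: no-op stage (handled upstream; synthetic data contains no doublets)")
  ds
}
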