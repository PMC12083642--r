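#' Per-cell-type expressed-gene filter
#'
#' A gene is kept for a cell type iff it is detected (count > 0) in strictly
#' more than `min_frac` of that type's nuclei (default 5%).
#'
#' @param ds ExpressionDataset or NormalizedMatrix
#' @param cell_type_labels per-observation labels covering all nuclei
#' @param min_frac detection-fraction threshold (strict)
#' @return named list: per cell type, character vector of retained gene ids
#' @export
expressed_gene_filter <- function(ds, cell_type_labels, min_frac = 0.05) {
  m <- if (inherits(ds, "NormalizedMatrix")) ds$values else ds$counts
  ids <- if (inherits(ds, "NormalizedMatrix")) ds$var$id else ds$var$id
  types <- unique(cell_type_labels)
  out <- lapply(types, function(ct) {
    rows <- which(cell_type_labels == ct)
    if (!length(rows)) stop("empty cell type: ", ct)
    frac <- Matrix::colSums(m[rows, , drop = FALSE] > 0) / length(rows)
    ids[frac > min_frac]
  })
  stats::setNames(out, types)
}

# internal: component fits for one gene
# y: log2-scale normalized expression; condition: factor; cdr: covariate
hurdle_components <- function(y, condition, cdr) {
  L <- nlevels(condition)
  det <- y > 0
  n <- length(y)
  Xf <- stats::model.matrix(~ condition + cdr)
  Xr <- stats::model.matrix(~ cdr)
  res <- list(disc_lr = 0, disc_df = 0, cont_lr = 0, cont_df = 0,
              disc_coef = NULL, cont_coef = NULL,
              detect_rate = mean(det),
              pos_mean = if (any(det)) mean(y[det]) else 0)
  if (any(det) && !all(det)) {
    ff <- suppressWarnings(stats::glm.fit(Xf, det, family = stats::binomial()))
    fr <- suppressWarnings(stats::glm.fit(Xr, det, family = stats::binomial()))
    res$disc_lr <- max(fr$deviance - ff$deviance, 0)
    res$disc_df <- L - 1
    res$disc_coef <- ff$coefficients
  }
  pos <- which(det)
  if (length(pos) >= 3) {
    npos_per_cond <- table(condition[pos])
    if (all(npos_per_cond >= 2) && length(npos_per_cond) == L) {
      yf <- y[pos]
      ff <- stats::lm.fit(Xf[pos, , drop = FALSE], yf)
      fr <- stats::lm.fit(Xr[pos, , drop = FALSE], yf)
      rss_f <- sum(ff$residuals^2); rss_r <- sum(fr$residuals^2)
      if (rss_f > 0) {
        res$cont_lr <- max(length(pos) * log(rss_r / rss_f), 0)
        res$cont_df <- L - 1
        res$cont_coef <- ff$coefficients
      }
    }
  }
  res
}

#' Fit the hurdle model for a single gene
#'
#' Two-part model: a logistic component for the detection indicator
#' (detected ~ condition + CDR) and a Gaussian component on the log-normalized
#' expression of detected cells (expression ~ condition + CDR). Degenerate
#' components (all detected / all undetected / fewer than 2 positive cells in
#' a condition) contribute 0 with df 0. The combined likelihood-ratio test
#' against models dropping `condition` from both components has statistic
#' LR_disc + LR_cont and df = df_disc + df_cont; p is NA (flagged) when both
#' components are degenerate.
#'
#' @param y numeric vector of log2-scale normalized expression, one value per
#'   nucleus (zeros mean undetected)
#' @param condition factor with >= 2 levels
#' @param cdr cellular detection rate covariate, from [compute_cdr()]
#' @return HurdleFit entry: list with `stat`, `df`, `p`, component
#'   coefficients and degeneracy fallbacks
#' @export
fit_hurdle <- function(y, condition, cdr) {
  condition <- droplevels(factor(condition))
  if (nlevels(condition) < 2) stop("need at least 2 conditions")
  comp <- hurdle_components(y, condition, cdr)
  stat <- comp$disc_lr + comp$cont_lr
  df <- comp$disc_df + comp$cont_df
  p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_
  structure(c(comp, list(stat = stat, df = df, p = p,
                         levels = levels(condition))),
            class = c("HurdleFit", "list"))
}

# internal: fit all genes of a log2 expression matrix (cells x genes)
hurdle_fit_matrix <- function(E, condition, cdr) {
  condition <- droplevels(factor(condition))
  fits <- vector("list", ncol(E))
  for (g in seq_len(ncol(E)))
    fits[[g]] <- fit_hurdle(E[, g], condition, cdr)
  stats_df <- data.frame(
    gene = colnames(E),
    stat = vapply(fits, `[[`, numeric(1), "stat"),
    df = vapply(fits, `[[`, numeric(1), "df"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  stats_df$padj <- stats::p.adjust(stats_df$p, method = "BH")
  list(stats = stats_df, fits = stats::setNames(fits, colnames(E)),
       cdr_mean = mean(cdr))
}

#' Hurdle log2 fold change
#'
#' Model-expected value per condition at a reference CDR:
#' E[Y | cond] = P(detected | cond, cdr_ref) * E[Y | detected, cond, cdr_ref]
#' on the log2-normalized scale; log2FC = E[Y | B] - E[Y | A]. Degenerate
#' components fall back to the observed detection rate / positive-cell mean
#' (shared across conditions, so they contribute no fold change).
#'
#' @param fit a [fit_hurdle()] result
#' @param contrast length-2 character vector `c(A, B)`; the value is B vs A
#' @param cdr_ref reference CDR (callers default to the mean CDR)
#' @return numeric log2 fold change
#' @export
hurdle_log2fc <- function(fit, contrast, cdr_ref) {
  levs <- fit$levels
  stopifnot(all(contrast %in% levs))
  eval_cond <- function(cond) {
    dummy <- as.numeric(levs[-1] == cond)
    xrow <- c(1, dummy, cdr_ref)
    p_det <- if (is.null(fit$disc_coef)) fit$detect_rate
             else stats::plogis(sum(fit$disc_coef * xrow))
    mu <- if (is.null(fit$cont_coef)) fit$pos_mean
          else sum(fit$cont_coef * xrow)
    p_det * mu
  }
  eval_cond(contrast[2]) - eval_cond(contrast[1])
}

#' Hurdle differential expression for grouped nuclei
#'
#' Runs the MAST-style two-stage hurdle DEG per group (cell type or subtype):
#' (1) an LRT across all conditions dropping the condition factor, BH-adjusted;
#' (2) per pairwise contrast, a hurdle fit restricted to the two conditions
#' with its own LRT p, BH-adjusted, and the hurdle log2FC at the mean CDR.
#' A gene is a significant pairwise DEG iff it is a significant LRT DEG
#' (padj < `padj_max`) and passes padj < `padj_max` and |log2FC| > `lfc_min`
#' in the contrast. Expression is taken to the log2 scale internally; only
#' genes detected in more than `min_frac` of the group's nuclei are tested.
#'
#' @param norm NormalizedMatrix (natural-log scale, from [normalize_log1p()])
#' @param groupby per-observation group labels
#' @param contrasts list of length-2 character vectors (second vs first)
#' @param padj_max,lfc_min significance thresholds (0.05 / 0.1)
#' @param min_frac expressed-gene filter threshold
#' @return named list per group: list with `lrt` data.frame and `contrasts`
#'   (per contrast data.frame gene, p, padj, log2FC, sig)
#' @export
run_hurdle_deg <- function(norm, groupby,
                           contrasts = list(c("HC", "CD"), c("HC", "TN"), c("CD", "TN")),
                           padj_max = 0.05, lfc_min = 0.1, min_frac = 0.05) {
  cdr_all <- compute_cdr(norm)
  genes_by_group <- expressed_gene_filter(norm, groupby, min_frac = min_frac)
  out <- list()
  for (grp in names(genes_by_group)) {
    rows <- which(groupby == grp)
    genes <- genes_by_group[[grp]]
    if (!length(genes)) next
    E <- as.matrix(norm$values[rows, match(genes, norm$var$id), drop = FALSE]) / log(2)
    colnames(E) <- genes
    cond <- droplevels(factor(as.character(norm$obs$condition[rows]),
                              levels = c("HC", "CD", "TN")))
    if (nlevels(cond) < 2) next   # group present in a single condition
    cdr <- cdr_all[rows]
    lrt <- hurdle_fit_matrix(E, cond, cdr)
    sig_lrt <- !is.na(lrt$stats$padj) & lrt$stats$padj < padj_max
    ctabs <- list()
    for (ct in contrasts) {
      keep <- cond %in% ct
      sub_cond <- droplevels(cond[keep])
      if (nlevels(sub_cond) < 2) next
      fitp <- hurdle_fit_matrix(E[keep, , drop = FALSE], sub_cond, cdr[keep])
      lfc <- vapply(fitp$fits, hurdle_log2fc, numeric(1),
                    contrast = ct, cdr_ref = fitp$cdr_mean)
      tab <- data.frame(gene = genes, p = fitp$stats$p, padj = fitp$stats$padj,
                        log2FC = unname(lfc), stringsAsFactors = FALSE)
      tab$sig <- sig_lrt & !is.na(tab$padj) & tab$padj < padj_max &
        abs(tab$log2FC) > lfc_min
      ctabs[[paste0(ct[2], "_vs_", ct[1])]] <- tab
    }
    out[[grp]] <- list(lrt = cbind(lrt$stats, sig_lrt = sig_lrt),
                       contrasts = ctabs)
  }
  out
}
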