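# Negative-binomial GLM engine for pseudo-bulk group-means designs.
#
# All fits are vectorized across genes: the design is always a condition
# factor (full model) or an intercept (reduced model), so group-wise means
# are fitted by Newton iterations on eta = log(q) with per-gene dispersion
# alpha (variance mu + alpha mu^2). Dispersion is estimated once per gene
# under the full model by maximizing the Cox-Reid adjusted profile
# likelihood over log(alpha) with a vectorized golden-section search
# (method-of-moments start, floor 1e-8), and reused for reduced-model and
# pairwise fits.

NB_ALPHA_FLOOR <- 1e-8
NB_ALPHA_CEIL <- 50

# Y: genes x replicates; sf: size factors; group: factor over replicates.
# Returns eta (genes x levels), mu (genes x reps), loglik, and the
# per-(gene,level) Fisher information of eta.
nb_fit_groups <- function(Y, sf, group, alpha) {
  G <- nrow(Y)
  group <- droplevels(as.factor(group))
  levs <- levels(group)
  eta <- matrix(0, G, length(levs), dimnames = list(NULL, levs))
  info <- matrix(0, G, length(levs), dimnames = list(NULL, levs))
  mu <- matrix(0, G, ncol(Y))
  for (l in seq_along(levs)) {
    j <- which(group == levs[l])
    Yl <- Y[, j, drop = FALSE]
    sfl <- sf[j]
    e <- log((rowSums(Yl) + 0.1) / sum(sfl))
    for (it in 1:50) {
      M <- exp(e) %*% t(sfl)
      u <- rowSums((Yl - M) / (1 + alpha * M))
      h <- rowSums(M * (1 + alpha * Yl) / (1 + alpha * M)^2)
      step <- u / pmax(h, 1e-12)
      step <- pmax(pmin(step, 3), -3)
      e <- pmin(pmax(e + step, -30), 30)
      if (max(abs(step)) < 1e-10) break
    }
    eta[, l] <- e
    M <- exp(e) %*% t(sfl)
    mu[, j] <- M
    info[, l] <- rowSums(M / (1 + alpha * M))
  }
  list(eta = eta, mu = mu, info = info,
       loglik = nb_loglik(Y, mu, alpha), group = group)
}

nb_loglik <- function(Y, mu, alpha) {
  r <- 1 / alpha
  mu <- pmax(mu, 1e-300)
  rowSums(lgamma(Y + r) - lgamma(r) - lgamma(Y + 1) +
            r * log(r / (r + mu)) + Y * log(mu / (r + mu)))
}

# Cox-Reid adjusted profile log-likelihood at given alpha (vector per gene);
# refits the group means internally
nb_apl <- function(log_alpha, Y, sf, group) {
  alpha <- exp(log_alpha)
  fit <- nb_fit_groups(Y, sf, group, alpha)
  fit$loglik - 0.5 * rowSums(log(pmax(fit$info, 1e-300)))
}

# vectorized golden-section maximization of a per-gene objective over
# log(alpha); `penalty(la)` is added to the APL (zero for the plain MLE)
nb_golden_max <- function(Y, sf, group, penalty = NULL, iterations = 40) {
  G <- nrow(Y)
  obj <- function(la) {
    v <- nb_apl(la, Y, sf, group)
    if (!is.null(penalty)) v <- v + penalty(la)
    v
  }
  lo <- rep(log(NB_ALPHA_FLOOR), G)
  hi <- rep(log(NB_ALPHA_CEIL), G)
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- obj(x1); f2 <- obj(x2)
  for (it in seq_len(iterations)) {
    left <- f1 > f2
    hi[left] <- x2[left]; x2[left] <- x1[left]; f2[left] <- f1[left]
    x1[left] <- hi[left] - gr * (hi[left] - lo[left])
    lo[!left] <- x1[!left]; x1[!left] <- x2[!left]; f1[!left] <- f2[!left]
    x2[!left] <- lo[!left] + gr * (hi[!left] - lo[!left])
    xn <- ifelse(left, x1, x2)
    fn <- obj(xn)
    f1[left] <- fn[left]; f2[!left] <- fn[!left]
  }
  pmax(exp((lo + hi) / 2), NB_ALPHA_FLOOR)
}

# Per-gene dispersion: Cox-Reid adjusted profile MLE, optionally moderated by
# an empirical-Bayes log-normal prior centred on the constant dispersion
# trend (median of the unmoderated estimates), with prior variance
# max(spread^2 - sampling variance, 0.25) where the sampling variance of a
# log dispersion estimate is trigamma((m - p) / 2). Unmoderated per-gene
# estimates at small replicate numbers are noisy enough to break the
# chi-square calibration of the LRT; the MAP estimate restores it while
# leaving well-estimated genes essentially untouched.
nb_estimate_dispersion <- function(Y, sf, group, shrink = TRUE) {
  gene_wise <- nb_golden_max(Y, sf, group)
  m <- ncol(Y); p <- nlevels(droplevels(as.factor(group)))
  if (!shrink || nrow(Y) < 10 || m - p < 1) return(gene_wise)
  usable <- gene_wise > 2 * NB_ALPHA_FLOOR
  if (sum(usable) < 10) return(gene_wise)
  la0 <- log(mean(gene_wise[usable]))   # constant trend: mean of gene-wise estimates
  spread2 <- stats::mad(log(gene_wise[usable]) - la0)^2
  prior_var <- max(spread2 - trigamma((m - p) / 2), 0.25)
  nb_golden_max(Y, sf, group,
                penalty = function(la) -(la - la0)^2 / (2 * prior_var))
}

#' Median-of-ratios size factors
#'
#' Per-replicate normalization factors: the geometric mean of each gene over
#' replicates is computed on genes with no zero count, and each replicate's
#' factor is the median over those genes of count / geometric mean.
#'
#' @param pb PseudobulkMatrix (or replicates x genes count matrix)
#' @return positive numeric vector, one factor per replicate
#' @export
size_factors <- function(pb) {
  Y <- if (inherits(pb, "PseudobulkMatrix")) pb$counts else pb
  ok <- colSums(Y == 0) == 0
  if (!any(ok))
    stop("no gene is nonzero in all replicates; apply gene_prevalence_filter first")
  L <- log(Y[, ok, drop = FALSE])
  geo <- colMeans(L)
  sf <- apply(exp(sweep(L, 2, geo)), 1, stats::median)
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  sf
}

#' Negative-binomial likelihood-ratio test across conditions
#'
#' Per gene: NB log-likelihood maximized under the full model
#' (mean = size_factor * exp(condition effect)) and the intercept-only
#' reduced model, with a shared per-gene dispersion estimated once under the
#' full model (Cox-Reid adjusted profile likelihood, floored at 1e-8) and
#' reused for both fits. Statistic = 2 * delta logLik (clamped at 0), p from
#' chi-square with df = levels - 1. Genes with all-zero counts are flagged
#' (`converged = FALSE`, p = NA) and are excluded from consensus denominators
#' by the callers.
#'
#' @param pb PseudobulkMatrix
#' @param condition optional condition factor (defaults to `pb$meta$condition`)
#' @param sf optional size factors (defaults to [size_factors()])
#' @param dispersion optional per-gene dispersion vector to reuse
#' @return data.frame (gene, stat, df, p, converged) with the per-gene
#'   `dispersion` and `sf` as attributes
#' @export
nb_lrt <- function(pb, condition = NULL, sf = NULL, dispersion = NULL) {
  Y <- t(pb$counts)                                # genes x replicates
  condition <- droplevels(factor(condition %||% pb$meta$condition))
  if (nlevels(condition) < 2) stop("need at least 2 conditions")
  if (is.null(sf)) sf <- size_factors(pb)
  ok <- rowSums(Y) > 0
  if (is.null(dispersion))
    dispersion <- nb_estimate_dispersion(Y[ok, , drop = FALSE], sf,
                                         condition)[match(seq_len(nrow(Y)), which(ok))]
  alpha <- pmax(dispersion, NB_ALPHA_FLOOR)
  alpha[is.na(alpha)] <- NB_ALPHA_FLOOR
  full <- nb_fit_groups(Y, sf, condition, alpha)
  red <- nb_fit_groups(Y, sf, rep("all", ncol(Y)), alpha)
  stat <- pmax(2 * (full$loglik - red$loglik), 0)
  df <- nlevels(condition) - 1
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  p[!ok] <- NA
  out <- data.frame(gene = colnames(pb$counts), stat = stat, df = df, p = p,
                    converged = ok, stringsAsFactors = FALSE)
  attr(out, "dispersion") <- alpha
  attr(out, "sf") <- sf
  out
}

#' Pairwise NB Wald test between two conditions
#'
#' Wald test on the condition coefficient of the NB GLM restricted to the two
#' conditions; log2FC = coefficient / ln(2), oriented second-listed over
#' first (`pairwise_test(pb, "HC", "TN")` reports log2(TN/HC)). BH adjustment
#' over all tested genes with no independent filtering.
#'
#' @param pb PseudobulkMatrix
#' @param condA,condB condition labels; the contrast is condB vs condA
#' @param sf optional size factors computed on the full replicate set
#' @param dispersion optional per-gene dispersion to reuse (e.g. from
#'   [nb_lrt()]); estimated on the two-condition subset when NULL
#' @return data.frame (gene, log2FC, se, stat, p, padj, converged)
#' @export
pairwise_test <- function(pb, condA, condB, sf = NULL, dispersion = NULL) {
  cond <- as.character(pb$meta$condition)
  keep <- cond %in% c(condA, condB)
  if (!any(cond == condA) || !any(cond == condB))
    stop("both conditions must be present")
  if (is.null(sf)) sf <- size_factors(pb)
  Y <- t(pb$counts[keep, , drop = FALSE])
  sfk <- sf[keep]
  grp <- factor(cond[keep], levels = c(condA, condB))
  ok <- rowSums(Y) > 0
  if (is.null(dispersion))
    dispersion <- nb_estimate_dispersion(Y[ok, , drop = FALSE], sfk,
                                         grp)[match(seq_len(nrow(Y)), which(ok))]
  alpha <- pmax(dispersion, NB_ALPHA_FLOOR)
  alpha[is.na(alpha)] <- NB_ALPHA_FLOOR
  fit <- nb_fit_groups(Y, sfk, grp, alpha)
  beta <- fit$eta[, condB] - fit$eta[, condA]
  se <- sqrt(1 / pmax(fit$info[, condA], 1e-12) + 1 / pmax(fit$info[, condB], 1e-12))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  p[!ok] <- NA
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(gene = colnames(pb$counts), log2FC = beta / log(2),
             se = se / log(2), stat = z, p = p, padj = padj,
             converged = ok, stringsAsFactors = FALSE)
}
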