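#' Filter a single-cell reference and build signatures
#'
#' Retains genes detected in more than 5 cells, in more than 3 percent of
#' cells, and with average expression in non-zero cells higher than 1.12 (all
#' strict inequalities); per-type mean expression over the retained genes
#' forms the signature matrix.
#'
#' @param ref_counts matrix or sparse matrix, cells x genes
#' @param cell_types character vector of per-cell type labels
#' @param min_cells,min_frac,min_nonzero_mean filter rules (defaults above)
#' @return SignatureMatrix: cell types x genes mean-expression matrix
#' @export
filter_reference <- function(ref_counts, cell_types, min_cells = 5,
                             min_frac = 0.03, min_nonzero_mean = 1.12) {
  if (is.matrix(ref_counts)) {
    storage.mode(ref_counts) <- "double"
    ref_counts <- Matrix::Matrix(ref_counts, sparse = TRUE)
  }
  X <- methods::as(methods::as(ref_counts, "generalMatrix"), "CsparseMatrix")
  n <- nrow(X)
  det <- Matrix::colSums(X > 0)
  nz_mean <- ifelse(det > 0, Matrix::colSums(X) / det, 0)
  keep <- det > min_cells & det / n > min_frac & nz_mean > min_nonzero_mean
  if (!any(keep)) stop("no genes pass the reference filter")
  X <- X[, keep, drop = FALSE]
  types <- sort(unique(cell_types))
  sig <- do.call(rbind, lapply(types, function(ct)
    Matrix::colMeans(X[cell_types == ct, , drop = FALSE])))
  dimnames(sig) <- list(types, colnames(X))
  dead <- rownames(sig)[Matrix::rowSums(sig) == 0]
  if (length(dead))
    stop("cell type(s) with all-zero signature after filtering: ",
         paste(dead, collapse = ", "))
  sig
}

# Lawson-Hanson nonnegative least squares: min ||A x - b||, x >= 0
nnls_fit <- function(A, b, tol = 1e-10, max_iter = NULL) {
  p <- ncol(A)
  if (is.null(max_iter)) max_iter <- 3L * p
  x <- numeric(p)
  passive <- logical(p)
  w <- drop(crossprod(A, b))
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(p)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- drop(solve(crossprod(Ap), crossprod(Ap, b)))
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Estimate per-spot cell-type abundances
#'
#' Per spot, nonnegative least squares of the spot's count vector on the
#' signature rows over the shared genes. A deterministic, desk-scale stand-in
#' for probabilistic deconvolution: the downstream binarize/Fisher annotation
#' logic only requires a nonnegative abundance estimate.
#'
#' @param ds ExpressionDataset of spots
#' @param sig SignatureMatrix (cell types x genes)
#' @return AbundanceMatrix: spots x cell types nonnegative matrix with
#'   per-spot residual norms in attribute `residuals`
#' @export
estimate_abundance <- function(ds, sig) {
  shared <- intersect(ds$var$id, colnames(sig))
  if (!length(shared)) stop("empty gene intersection between spots and signatures")
  A <- t(sig[, shared, drop = FALSE])
  Y <- ds$counts[, shared, drop = FALSE]
  n <- n_obs(ds)
  out <- matrix(0, n, nrow(sig), dimnames = list(rownames(ds$counts), rownames(sig)))
  res <- numeric(n)
  for (i in seq_len(n)) {
    b <- as.numeric(Y[i, ])
    if (all(b == 0)) next
    x <- nnls_fit(A, b)
    out[i, ] <- x
    res[i] <- sqrt(sum((b - A %*% x)^2))
  }
  attr(out, "residuals") <- res
  out
}

#' Binarize an abundance matrix at a quantile
#'
#' Per cell type, the threshold is the `q`-quantile (linear interpolation) of
#' that type's abundances across all spots; a spot is positive iff its
#' abundance strictly exceeds the threshold. A constant column therefore
#' yields zero positives.
#'
#' @param A AbundanceMatrix (spots x cell types)
#' @param q quantile in (0,1); default 0.99
#' @return logical matrix of the same shape, thresholds in attribute
#'   `thresholds`
#' @export
binarize_abundance <- function(A, q = 0.99) {
  if (q <= 0 || q >= 1) stop("q must be in (0,1)")
  th <- apply(A, 2, stats::quantile, probs = q, type = 7, names = FALSE)
  B <- sweep(A, 2, th, ">")
  attr(B, "thresholds") <- th
  B
}

# two-sided Fisher exact p for a 2x2 table (a,b // c,d): sum of
# hypergeometric probabilities not exceeding the observed one (with the
# customary relative tolerance for floating-point ties)
fisher_exact2x2 <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Cluster enrichment and region assignment
#'
#' For every (cluster, cell type) pair a 2x2 table of in-cluster vs
#' out-of-cluster against binarized-positive vs negative spots is tested with
#' a two-sided Fisher's exact test; the sample odds ratio uses the
#' Haldane-Anscombe 0.5 correction when any cell is zero. P-values are
#' BH-adjusted across all pairs. Each cluster is assigned the region of the
#' region-specific cell type with the highest odds ratio among those with
#' FDR below `fdr_max`; clusters with no significant region-specific type
#' return "unassigned" (mirroring a fallback to manual anatomy, which is out
#' of scope).
#'
#' @param binary logical matrix spots x cell types from [binarize_abundance()]
#' @param labels cluster labels (one per spot)
#' @param region_map named character vector: cell type -> region, covering
#'   the region-specific cell types
#' @param fdr_max FDR threshold for assignment (default 0.05)
#' @return list with `table` (per-pair a,b,c,d, odds ratio, p, fdr) and
#'   `assignment` (named character vector cluster -> region)
#' @export
annotate_clusters <- function(binary, labels, region_map, fdr_max = 0.05) {
  if (length(labels) != nrow(binary)) stop("labels do not match the binary matrix")
  clusters <- sort(unique(labels))
  types <- colnames(binary)
  rows <- expand.grid(cluster = clusters, cell_type = types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  a <- b <- c_ <- d <- or <- p <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    inc <- labels == rows$cluster[i]
    pos <- binary[, rows$cell_type[i]]
    a[i] <- sum(inc & pos); b[i] <- sum(inc & !pos)
    c_[i] <- sum(!inc & pos); d[i] <- sum(!inc & !pos)
    or[i] <- if (any(c(a[i], b[i], c_[i], d[i]) == 0))
      ((a[i] + 0.5) * (d[i] + 0.5)) / ((b[i] + 0.5) * (c_[i] + 0.5))
    else (a[i] * d[i]) / (b[i] * c_[i])
    p[i] <- fisher_exact2x2(a[i], b[i], c_[i], d[i])
  }
  fdr <- stats::p.adjust(p, method = "BH")
  tab <- cbind(rows, a = a, b = b, c = c_, d = d,
               odds_ratio = or, p = p, fdr = fdr)
  assignment <- stats::setNames(rep("unassigned", length(clusters)), clusters)
  for (cl in clusters) {
    sel <- tab$cluster == cl & tab$cell_type %in% names(region_map) &
      tab$fdr < fdr_max
    if (any(sel)) {
      best <- tab[sel, ][which.max(tab$odds_ratio[sel]), ]
      assignment[as.character(cl)] <- unname(region_map[best$cell_type])
    }
  }
  list(table = tab, assignment = assignment)
}
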