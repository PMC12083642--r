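#' Expression dataset container
#'
#' Lightweight container for a sparse nonnegative integer count matrix
#' (observations x genes) together with per-observation and per-gene metadata.
#' Observations are Visium-style spots or single nuclei; genes carry an `id`
#' and a logical `mito` flag. Conditions, when present, must be drawn from the
#' ordered study design HC < CD < TN (home cage, conditioned, tone retrieval).
#'
#' @param counts sparse or dense nonnegative integer matrix, observations in
#'   rows, genes in columns. Coerced to `Matrix::dgCMatrix`.
#' @param obs data.frame of per-observation metadata; row count must match
#'   `nrow(counts)`. Recognized columns: `sample`, `condition`, `x`, `y`,
#'   plus arbitrary label columns.
#' @param var data.frame of per-gene metadata with at least `id`; a logical
#'   `mito` column is added from the `mt-` prefix when missing.
#' @return an object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(counts, obs, var) {
  if (is.matrix(counts)) {
    storage.mode(counts) <- "double"
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  }
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  if (!is.data.frame(obs)) obs <- as.data.frame(obs, stringsAsFactors = FALSE)
  if (!is.data.frame(var)) var <- as.data.frame(var, stringsAsFactors = FALSE)
  if (nrow(obs) != nrow(counts))
    stop("obs has ", nrow(obs), " rows but counts has ", nrow(counts), " observations")
  if (nrow(var) != ncol(counts))
    stop("var has ", nrow(var), " rows but counts has ", ncol(counts), " genes")
  if (is.null(var$id)) stop("var must contain an 'id' column")
  var$id <- as.character(var$id)
  if (anyDuplicated(var$id)) stop("gene ids must be unique")
  if (is.null(var$mito)) var$mito <- startsWith(var$id, "mt-")
  if (!is.null(obs$condition)) {
    obs$condition <- as.character(obs$condition)
    bad <- setdiff(unique(obs$condition), c("HC", "CD", "TN"))
    if (length(bad)) stop("unknown condition value(s): ", paste(bad, collapse = ", "))
    obs$condition <- factor(obs$condition, levels = c("HC", "CD", "TN"), ordered = TRUE)
  }
  colnames(counts) <- var$id
  rownames(counts) <- rownames(obs) <- sprintf("obs%d", seq_len(nrow(counts)))
  rownames(var) <- var$id
  structure(list(counts = counts, obs = obs, var = var), class = "ExpressionDataset")
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d observations x %d genes\n", nrow(x$counts), ncol(x$counts)))
  cat("  obs columns:", paste(colnames(x$obs), collapse = ", "), "\n")
  cat("  var columns:", paste(colnames(x$var), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an ExpressionDataset
#'
#' @param x ExpressionDataset
#' @param i observation index (logical/integer)
#' @param j gene index (logical/integer or character gene ids)
#' @param ... ignored
#' @export
`[.ExpressionDataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(j)) j <- match(j, x$var$id)
  expression_dataset(x$counts[i, j, drop = FALSE],
                     x$obs[i, , drop = FALSE],
                     x$var[j, , drop = FALSE])
}

#' Number of observations / genes
#' @param ds ExpressionDataset
#' @export
n_obs <- function(ds) nrow(ds$counts)

#' @rdname n_obs
#' @export
n_genes <- function(ds) ncol(ds$counts)
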