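#' AUC-based regulon activity score for one cell
#'
#' Genes are ranked by decreasing expression (ties broken by the fixed gene
#' order of the vector); with cutoff T = ceiling(top_fraction * G), the raw
#' score is the area under the recovery curve, sum_{k=1..T} hits(k), where
#' hits(k) counts regulon genes among the top k ranks. The score is the raw
#' area divided by its maximum sum_{k=1..T} min(k, |regulon|), so it lies in
#' `[0,1]`, reaching 1 only when the regulon genes occupy the top ranks.
#' Being rank-based, the score is invariant under monotone transforms of the
#' expression vector.
#'
#' @param expr named numeric vector of normalized expression for one cell
#'   (names are gene ids; the fixed gene order is the vector order)
#' @param regulon character vector of member gene ids (non-empty, must be a
#'   subset of the gene universe)
#' @param top_fraction fraction of the ranking considered (default 0.05)
#' @return numeric score in `[0,1]`
#' @export
aucell_score <- function(expr, regulon, top_fraction = 0.05) {
  G <- length(expr)
  if (!length(regulon)) stop("regulon is empty")
  hit <- match(regulon, names(expr))
  if (anyNA(hit)) stop("regulon gene(s) outside the universe: ",
                       paste(regulon[is.na(hit)], collapse = ", "))
  if (length(regulon) > G) stop("regulon larger than the gene universe")
  T_ <- ceiling(top_fraction * G)
  pos <- rank_positions(expr)[hit]
  inside <- pos[pos <= T_]
  raw <- sum(T_ - inside + 1)
  maxv <- sum(pmin(seq_len(T_), length(regulon)))
  raw / maxv
}

# position of each gene in the decreasing-expression ranking (ties broken by
# gene order)
rank_positions <- function(expr) {
  ord <- order(-expr, seq_along(expr))
  pos <- integer(length(expr))
  pos[ord] <- seq_along(expr)
  pos
}

#' Regulon activity score matrix
#'
#' Applies [aucell_score()] to every cell and regulon.
#'
#' @param norm NormalizedMatrix
#' @param regulons named list of gene-id vectors (e.g. from [read_gmt()])
#' @param top_fraction ranking cutoff fraction
#' @return RASMatrix: cells x regulons numeric matrix in `[0,1]`
#' @export
ras_matrix <- function(norm, regulons, top_fraction = 0.05) {
  G <- ncol(norm$values)
  ids <- norm$var$id
  T_ <- ceiling(top_fraction * G)
  hits <- lapply(regulons, function(rg) {
    j <- match(rg, ids)
    if (anyNA(j)) stop("regulon gene(s) outside the universe: ",
                       paste(rg[is.na(j)], collapse = ", "))
    j
  })
  maxv <- vapply(regulons, function(rg) sum(pmin(seq_len(T_), length(rg))), numeric(1))
  n <- nrow(norm$values)
  out <- matrix(0, n, length(regulons),
                dimnames = list(rownames(norm$values), names(regulons)))
  V <- as.matrix(norm$values)
  for (i in seq_len(n)) {
    pos <- rank_positions(V[i, ])
    for (s in seq_along(hits)) {
      inside <- pos[hits[[s]]]
      inside <- inside[inside <= T_]
      out[i, s] <- sum(T_ - inside + 1) / maxv[s]
    }
  }
  out
}

#' Differential transcription-factor activity test
#'
#' Within one cell type, regulons whose mean activity in the cell type
#' exceeds the dataset-wide mean activity are tested with a one-sided
#' Wilcoxon rank-sum test comparing condition B against condition A
#' (alternative: greater in B). The exact distribution is used when both
#' groups have at most 25 observations and there are no ties; otherwise the
#' normal approximation with tie and continuity correction. Bonferroni
#' adjustment is applied over the tested regulons; significance requires
#' adjusted p below `alpha` (default 0.01).
#'
#' @param ras RASMatrix (all cells)
#' @param cell_type_labels per-cell labels aligned with `ras` rows
#' @param conditions per-cell condition labels
#' @param cell_type the cell type to test within
#' @param condA,condB conditions compared (alternative: B > A)
#' @param alpha Bonferroni-adjusted significance threshold
#' @return data.frame (regulon, mean_ras, W, p, padj, sig), sorted by padj
#' @export
differential_tf <- function(ras, cell_type_labels, conditions, cell_type,
                            condA, condB, alpha = 0.01) {
  rows <- which(cell_type_labels == cell_type)
  if (!length(rows)) stop("no cells of type ", cell_type)
  mean_in <- colMeans(ras[rows, , drop = FALSE])
  mean_all <- colMeans(ras)
  tested <- which(mean_in > mean_all)
  ia <- rows[conditions[rows] == condA]
  ib <- rows[conditions[rows] == condB]
  if (length(ia) < 2 || length(ib) < 2)
    stop("fewer than 2 cells per condition in ", cell_type)
  res <- lapply(tested, function(s) {
    a <- ras[ia, s]; b <- ras[ib, s]
    exact <- length(a) <= 25 && length(b) <= 25 && !any(duplicated(c(a, b)))
    w <- suppressWarnings(stats::wilcox.test(b, a, alternative = "greater",
                                             exact = exact, correct = TRUE))
    data.frame(regulon = colnames(ras)[s], mean_ras = mean_in[s],
               W = unname(w$statistic), p = w$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(regulon = character(), mean_ras = numeric(),
                      W = numeric(), p = numeric(), padj = numeric(),
                      sig = logical()))
  out$padj <- stats::p.adjust(out$p, method = "bonferroni")
  out$sig <- out$padj < alpha
  out[order(out$padj, out$p), , drop = FALSE]
}

#' Over-representation analysis
#'
#' Hypergeometric upper-tail test of the overlap between a query gene list
#' and each gene set: p = P(X >= overlap) with X hypergeometric on the
#' universe; sets are intersected with the universe first. BH adjustment
#' across sets; results sorted by FDR.
#'
#' @param query character vector of genes (must be a subset of `universe`)
#' @param universe character vector defining the background
#' @param gene_sets named list of gene-id vectors
#' @return ORAResult data.frame (set, overlap, set_size, universe_size, p, fdr)
#' @export
ora <- function(query, universe, gene_sets) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (length(setdiff(query, universe)))
    stop("query contains genes outside the universe")
  N <- length(universe); n <- length(query)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    m <- length(set)
    k <- length(intersect(set, query))
    p <- if (m == 0) 1 else stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = m, universe_size = N,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), universe_size = integer(),
                      p = numeric(), fdr = numeric()))
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[order(out$fdr, out$p), , drop = FALSE]
}
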