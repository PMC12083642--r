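# independent brute-force oracles used across tests; deliberately written
# from first principles, not via the implementation's code paths

# two-sided Fisher exact p: enumerate all tables with the observed margins,
# compute each probability from log-binomial coefficients, and sum those not
# exceeding the observed probability (relative tolerance for float ties)
fisher_oracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  n <- r1 + r2
  lp <- function(x) lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(lp(xs))
  sum(probs[probs <= exp(lp(a)) * (1 + 1e-7)])
}

# enumeration of the Wilcoxon rank-sum null for two groups with no ties:
# all choose(n1+n2, n2) assignments of the combined ranks to the second group
wilcox_enum_greater <- function(x, y) {
  n <- length(x) + length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[(length(x) + 1):n])
  combos <- utils::combn(n, length(y))
  stats <- colSums(matrix(seq_len(n)[combos], nrow = length(y)))
  mean(stats >= w_obs)
}

# recovery-curve AUCell oracle: walk the ranking step by step
aucell_oracle <- function(expr, regulon, top_fraction = 0.05) {
  G <- length(expr)
  T_ <- ceiling(top_fraction * G)
  ord <- order(-expr, seq_along(expr))
  member <- names(expr)[ord] %in% regulon
  hits_cum <- cumsum(member)
  raw <- sum(hits_cum[seq_len(T_)])
  maxv <- sum(pmin(seq_len(T_), length(regulon)))
  raw / maxv
}

# closed-form hypergeometric upper tail via log-binomial coefficients
ora_oracle <- function(k, m, N, n) {
  if (m == 0 || k <= 0) {
    xs <- max(0, n - (N - m)):min(m, n)
  }
  xs <- max(k, max(0, n - (N - m))):min(m, n)
  if (k > min(m, n)) return(0)
  sum(exp(lchoose(m, xs) + lchoose(N - m, n - xs) - lchoose(N, n)))
}

# simple ARI re-export for readability in tests
ari <- function(a, b) cereFC:::adjusted_rand_index(a, b)

# wrap a replicates x genes matrix as a PseudobulkMatrix
as_pb <- function(Y, condition, mito = NULL) {
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("g%03d", seq_len(ncol(Y)))
  structure(list(
    counts = Y,
    meta = data.frame(group = "G", sample = "s",
                      condition = factor(condition, levels = c("HC", "CD", "TN")),
                      split = seq_len(nrow(Y))),
    var = data.frame(id = colnames(Y),
                     mito = mito %||% rep(FALSE, ncol(Y)))),
    class = c("PseudobulkMatrix", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
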