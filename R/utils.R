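# internal helpers shared across modules

# adjusted Rand index between two label vectors (chance-corrected agreement)
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (maxi - expected)
}

# mean silhouette width on a distance matrix for a label vector
mean_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  labels <- as.character(labels)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    others <- setdiff(unique(labels), labels[i])
    if (!length(others)) { s[i] <- 0; next }
    b <- min(vapply(others, function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# check a sparse graph is symmetric, zero-diagonal, weights in [0,1]
assert_connectivity_graph <- function(W, tol = 1e-12) {
  if (nrow(W) != ncol(W)) stop("graph must be square")
  if (any(abs(Matrix::diag(W)) > tol)) stop("graph has nonzero diagonal")
  if (max(abs(W - Matrix::t(W))) > tol) stop("graph is not symmetric")
  rng <- range(W@x, 0)
  if (rng[1] < -tol || rng[2] > 1 + tol) stop("graph weights outside [0,1]")
  invisible(W)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
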