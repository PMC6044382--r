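# Independent brute-force oracles used to validate the fast implementations.
# These deliberately take different computational routes than the package.

# KS enrichment by scanning every position of the ranked list: compares the
# empirical CDF of the tag positions against the uniform expectation at all
# n positions rather than only at the tag positions.
ks_oracle <- function(tag_positions, n) {
  v <- sort(tag_positions)
  t <- length(v)
  a <- -Inf
  b <- -Inf
  for (p in seq_len(n)) {
    le <- sum(v <= p)  # tags at or before p
    lt <- sum(v < p)   # tags strictly before p
    a <- max(a, le / t - p / n)
    b <- max(b, p / n - lt / t)
  }
  if (a >= b) a else -b
}

# c-index by explicit pairwise comparison of every (positive, negative) pair,
# ties counting one half, with the 0.5 floor.
c_index_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  max(wins / (length(pos) * length(neg)), 0.5)
}

# Youden-optimal cutoff by exhaustive threshold enumeration with explicit
# confusion-matrix counting; ties in J resolved towards the largest cutoff.
youden_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  best_j <- -Inf
  best_c <- NA_real_
  for (c0 in unique(scores)) {
    tp <- sum(scores >= c0 & labels)
    fn <- sum(scores < c0 & labels)
    tn <- sum(scores < c0 & !labels)
    fp <- sum(scores >= c0 & !labels)
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (j > best_j + 1e-12 || (abs(j - best_j) <= 1e-12 &&
                               (is.na(best_c) || c0 > best_c))) {
      best_j <- j
      best_c <- c0
    }
  }
  list(cutoff = best_c, youden_j = best_j)
}

# HITS by dense eigendecomposition: hub = principal eigenvector of W W',
# authority of W' W, rescaled so the maximum entry is 1.
hits_oracle <- function(W) {
  principal <- function(M) {
    e <- eigen(M, symmetric = TRUE)
    v <- e$vectors[, 1]
    v <- abs(v)  # Perron vector of a nonnegative matrix
    v / max(v)
  }
  list(hub = principal(W %*% t(W)), authority = principal(t(W) %*% W))
}

# Random weighted digraph adjacency matrix with at least one edge.
random_digraph <- function(n, p = 0.25) {
  repeat {
    W <- matrix(0, n, n)
    edges <- matrix(stats::runif(n * n) < p, n, n)
    diag(edges) <- FALSE
    W[edges] <- stats::runif(sum(edges), 0.1, 2)
    if (any(W > 0)) break
  }
  dimnames(W) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  W
}

# Rank by counting, for each gene, how many genes beat it (higher z; equal z
# and higher expr; equal both and earlier position).
rank_oracle <- function(z, expr = NULL) {
  n <- length(z)
  if (is.null(expr)) expr <- rep(0, n)
  r <- integer(n)
  for (i in seq_len(n)) {
    beats <- 0L
    for (j in seq_len(n)) {
      if (j == i) next
      if (z[j] > z[i] ||
          (z[j] == z[i] && expr[j] > expr[i]) ||
          (z[j] == z[i] && expr[j] == expr[i] && j < i)) {
        beats <- beats + 1L
      }
    }
    r[i] <- beats + 1L
  }
  r
}
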