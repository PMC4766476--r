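# Independent brute-force oracles used to validate the package's
# statistical primitives. These deliberately avoid the code paths (and
# library calls) they check.

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n)
# draws: the first K of N items are "annotated"; count draws with >= k.
hyper_enum <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Benjamini-Hochberg by threshold enumeration: every observed p-value is a
# candidate rejection threshold t with estimated FDR t * m / #(p <= t);
# q_i is the smallest such estimate over thresholds t >= p_i.
bh_brute <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(ts * m / vapply(ts, function(t) sum(p <= t), 0)))
  }, numeric(1))
}

# Naive agglomerative average-linkage clustering on a distance matrix:
# start from singletons, repeatedly merge the pair of clusters with the
# smallest mean pairwise distance (first pair in index order on ties),
# stop at k clusters. Returns a membership vector.
avg_linkage_brute <- function(d, k) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  while (length(clusters) > k) {
    best <- NULL
    best_val <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        val <- mean(d[clusters[[i]], clusters[[j]]])
        if (val < best_val - 1e-12) {
          best_val <- val
          best <- c(i, j)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  membership <- integer(nrow(d))
  for (i in seq_along(clusters)) membership[clusters[[i]]] <- i
  membership
}

# Two partitions are the same up to label permutation.
same_partition <- function(a, b) {
  identical(
    unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, 0))]),
    unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, 0))])
  )
}
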