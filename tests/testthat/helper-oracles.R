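# Independent oracles used to cross-check the implementation.  These are
# deliberately naive (loops, enumeration) and share no code with R/.

# Union-find connected components over an edge list.
uf_components <- function(M, edges) {
  parent <- seq_len(M)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- find(edges[i, 1]); b <- find(edges[i, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(M), find, integer(1))
  match(roots, unique(roots))
}

# O(n^2) silhouette, Euclidean, singletons scored 0.
brute_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    dmat[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(dmat[i, own])
    b <- Inf
    for (l in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(dmat[i, labels == l]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# ARI from explicit pair counting.
brute_ari <- function(a, b) {
  n <- length(a)
  s11 <- s10 <- s01 <- s00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (sa && !sb) s10 <- s10 + 1
    else if (!sa && sb) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  2 * (s11 * s00 - s10 * s01) /
    ((s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00))
}

# Rank-sum statistic computed independently (sort-based ranking) and the
# exact null distribution of W by enumeration of group assignments.
brute_ranksum_W <- function(x, y) {
  pooled <- c(x, y)
  ord <- order(pooled)
  r <- numeric(length(pooled))
  i <- 1
  while (i <= length(pooled)) {
    j <- i
    while (j < length(pooled) && pooled[ord[j + 1]] == pooled[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  sum(r[seq_along(x)])
}

enum_ranksum_null <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  apply(idx, 2, function(sel) brute_ranksum_W(pooled[sel], pooled[-sel]))
}

# All-pairs double-loop evaluation of the region-quality objective.
brute_objective <- function(regions, pcs, sigma) {
  K <- length(regions)
  if (K == 0) return(-Inf)
  cm <- suppressWarnings(stats::cor(t(pcs)))
  intra <- numeric(K)
  for (k in seq_len(K)) {
    idx <- regions[[k]]
    tot <- 0; cnt <- 0
    for (i in idx) for (j in idx) if (i != j) { tot <- tot + cm[i, j]; cnt <- cnt + 1 }
    intra[k] <- if (cnt > 0) tot / cnt else 0
  }
  inter <- 0
  if (K > 1) {
    vals <- c()
    for (a in seq_len(K - 1)) for (b in (a + 1):K) {
      tot <- 0; cnt <- 0
      for (i in regions[[a]]) for (j in regions[[b]]) { tot <- tot + cm[i, j]; cnt <- cnt + 1 }
      vals <- c(vals, tot / cnt)
    }
    inter <- mean(vals)
  }
  mean(intra) - inter + sigma * sum(lengths(regions)) / nrow(pcs)
}
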