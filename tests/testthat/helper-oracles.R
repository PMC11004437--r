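# Brute-force reference implementations, written independently of the
# package internals and kept deliberately naive (explicit loops, direct
# formulas). They are the oracles the fast implementations are checked
# against.

oracle_shannon <- function(counts) {
  p <- counts / sum(counts)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi)
  h
}

oracle_bray <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + min(x[i], y[i])
  1 - 2 * s / (sum(x) + sum(y))
}

# Spearman as Pearson on average ranks, by the definitional formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# one-factor pseudo-F and R2 by explicit pair loops
oracle_permanova <- function(d, groups) {
  n <- nrow(d)
  a <- length(unique(groups))
  ss_total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d[i, j]^2
  ss_total <- ss_total / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sg <- 0
    if (length(idx) > 1)
      for (i in idx) for (j in idx) if (i < j) sg <- sg + d[i, j]^2
    ssw <- ssw + sg / length(idx)
  }
  ssb <- ss_total - ssw
  list(f = (ssb / (a - 1)) / (ssw / (n - a)), r2 = ssb / ss_total)
}

# ANOSIM R by direct rank arithmetic over all pairs
oracle_anosim_r <- function(d, groups) {
  n <- nrow(d)
  vals <- c(); within <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    vals <- c(vals, d[i, j])
    within <- c(within, groups[i] == groups[j])
  }
  r <- rank(vals)
  (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
}

# Zi and Pi from an adjacency matrix and module labels, by loops
oracle_zipi <- function(adj, modules) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  k_own <- numeric(n)
  for (i in 1:n) k_own[i] <- sum(adj[i, modules == modules[i]])
  zi <- numeric(n); pi_v <- numeric(n)
  for (i in 1:n) {
    own <- which(modules == modules[i])
    mu <- mean(k_own[own]); sdv <- stats::sd(k_own[own])
    zi[i] <- if (length(own) < 2 || is.na(sdv) || sdv == 0) 0
             else (k_own[i] - mu) / sdv
    s <- 0
    for (m in unique(modules)) s <- s + (sum(adj[i, modules == m]) / deg[i])^2
    pi_v[i] <- 1 - s
  }
  list(zi = zi, pi = pi_v)
}

# weighted modularity Q by the definitional sum over modules
oracle_modularity <- function(edges, weights, modules) {
  total <- sum(weights)
  q <- 0
  for (m in unique(modules)) {
    e_m <- 0; d_m <- 0
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      if (modules[a] == m && modules[b] == m) e_m <- e_m + weights[k]
      if (modules[a] == m) d_m <- d_m + weights[k]
      if (modules[b] == m) d_m <- d_m + weights[k]
    }
    q <- q + e_m / total - (d_m / (2 * total))^2
  }
  q
}

# expected rarefied richness: hypergeometric inclusion probabilities
oracle_rarefied_richness <- function(counts, depth) {
  total <- sum(counts)
  sum(1 - exp(lchoose(total - counts, depth) - lchoose(total, depth)))
}

# every distinct two-group label split of the sample ids (for exhaustive
# permutation enumeration at small n)
all_balanced_splits <- function(n) {
  utils::combn(n, n / 2, simplify = FALSE)
}
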