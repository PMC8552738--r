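# Fixtures and independent brute-force oracles used across the suite.

toy_counts <- function() {
  tibble::tibble(
    feature_id = c("f1", "f2", "f3"),
    s1 = c(1, 2, 0),
    s2 = c(0, 5, 7)
  )
}

# Erdos-Renyi-style random simple graph as a cavenet_network (all rho = +1)
random_network <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
  ids <- sprintf("n%02d", 1:n)
  network_from_edges(tibble::tibble(
    feature_a = ids[pairs[keep, 1]],
    feature_b = ids[pairs[keep, 2]]
  ))
}

adjacency_of <- function(net) {
  a <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  a[a > 1] <- 1
  a
}

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix
oracle_shortest_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_apl <- function(adj) {
  d <- oracle_shortest_paths(adj)
  off <- d[upper.tri(d)]
  mean(off[is.finite(off)])
}

oracle_diameter <- function(adj) {
  d <- oracle_shortest_paths(adj)
  max(d[is.finite(d)])
}

# mean local clustering by direct triangle counting; degree<2 contributes 0
oracle_acc <- function(adj) {
  n <- nrow(adj)
  cc <- vapply(1:n, function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
  mean(cc)
}

# Zi/Pi by direct per-module tallies
oracle_zipi <- function(adj, membership) {
  n <- nrow(adj)
  mods <- sort(unique(membership))
  k_im <- sapply(mods, function(s) rowSums(adj[, membership == s, drop = FALSE]))
  if (is.null(dim(k_im))) k_im <- matrix(k_im, nrow = n)
  k_i <- rowSums(k_im)
  k_is <- k_im[cbind(1:n, match(membership, mods))]
  zi <- vapply(1:n, function(i) {
    same <- which(membership == membership[i])
    s <- stats::sd(k_is[same])
    if (length(same) < 2 || is.na(s) || s == 0) 0 else (k_is[i] - mean(k_is[same])) / s
  }, numeric(1))
  pi <- unname(1 - rowSums((k_im / pmax(k_i, 1))^2))
  pi[k_i == 0] <- 0
  list(zi = zi, pi = pi)
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# small random community spec used where full study scale is unnecessary
small_spec <- function(seed, within_module_rho = 0.85, ...) {
  syn_spec(n_features = 300, n_samples = 36, n_modules = 6, n_correlated = 120,
           n_connectors = 4, within_module_rho = within_module_rho,
           depth_range = c(4000, 5000), seed = seed, ...)
}
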