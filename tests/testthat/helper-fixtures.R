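# Shared fixtures and independent oracles, all built in code.

tiny_design <- function(...) {
  args <- utils::modifyList(
    list(n_taxa_pool = 40, groups = c(0, 100), stages = 2, replicates = 3,
         depth = 2000, seed = 42),
    list(...))
  do.call(sim_design, args)
}

tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_community(tiny_design())
    cache
  }
})

# 3-taxon distance matrix with d(A,B) = 2, d(A,C) = d(B,C) = 4
pd3 <- function() {
  matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

# ---- plain-R graph oracles (exhaustive-path computations, no igraph) ----

oracle_geodesic <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0; d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_mean_geodesic <- function(adj) {
  d <- oracle_geodesic(adj)[upper.tri(adj)]
  d <- d[is.finite(d)]
  if (!length(d)) NaN else mean(d)
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  loc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  mean(loc)
}

oracle_efficiency <- function(adj) {
  n <- nrow(adj)
  inv <- 1 / oracle_geodesic(adj)
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Newman Q of a given partition, by the direct formula
oracle_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(0)
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    e_c <- sum(adj[idx, idx]) / 2
    d_c <- sum(deg[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# all set partitions of 1..n as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1]] <<- prefix; return() }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

adjacency_from_code <- function(code, n, pairs) {
  bits <- as.integer(intToBits(code))[seq_len(nrow(pairs))]
  adj <- matrix(0L, n, n)
  adj[pairs] <- bits
  adj + t(adj)
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
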