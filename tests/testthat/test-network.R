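make_counts <- function(mat) {
  rownames(mat) <- paste0("s", seq_len(nrow(mat)))
  colnames(mat) <- paste0("t", seq_len(ncol(mat)))
  mat
}

test_that("the occupancy filter sits exactly on the 80% boundary", {
  n <- 18
  m <- matrix(10L, n, 5)
  m[15:18, 2] <- 0L   # 14/18 = 0.778 -> dropped
  m[16:18, 3] <- 0L   # 15/18 = 0.833 -> kept
  m <- make_counts(m)
  kept <- colnames(filter_for_network(m))
  expect_true("t1" %in% kept)
  expect_false("t2" %in% kept)
  expect_true("t3" %in% kept)
  expect_true(all(c("t4", "t5") %in% kept))

  full <- make_counts(matrix(5L, 10, 6))
  expect_equal(ncol(filter_for_network(full)), 6L)
  expect_error(filter_for_network(make_counts(matrix(5L, 4, 6))), ">= 5 samples")
  sparse <- make_counts(diag(10L) + 0L)
  expect_error(filter_for_network(sparse), "too sparse")
})

test_that("correlation networks threshold |r| with recorded signs", {
  set.seed(41)
  base <- rpois(18, 40) + 1
  m <- cbind(t1 = base, t2 = base * 3L, t3 = rpois(18, 40) + 1,
             t4 = rpois(18, 40) + 1, t5 = max(base) + 10L - base)
  rownames(m) <- paste0("s", 1:18)
  net <- correlation_network(m, st = 0.75)
  g <- net$graph
  e12 <- igraph::get_edge_ids(g, c("t1", "t2"))
  expect_gt(e12, 0)
  expect_equal(igraph::E(g)$sign[e12], 1L)
  e15 <- igraph::get_edge_ids(g, c("t1", "t5"))
  expect_gt(e15, 0)
  expect_equal(igraph::E(g)$sign[e15], -1L)

  expect_error(correlation_network(m, st = 1.5), "in \\(0, 1\\)")

  # a taxon constant on the relative-abundance scale (fixed share of a
  # fixed sequencing depth) has an undefined correlation and is dropped
  v <- sample(100:200, 18); w <- sample(50:120, 18)
  cm <- cbind(t1 = v, t2 = 400L - v, t3 = rep(50L, 18),
              t4 = w, t5 = 300L - w)
  rownames(cm) <- paste0("s", 1:18)
  expect_warning(net_c <- correlation_network(cm, st = 0.75), "constant")
  expect_false("t3" %in% igraph::V(net_c$graph)$name)
})

test_that("independent taxa give sparse networks and pruning is monotone", {
  set.seed(42)
  m <- make_counts(matrix(rpois(18 * 40, 50) + 1L, 18, 40))
  net <- correlation_network(m, st = 0.75)
  density <- igraph::ecount(net$graph) / choose(40, 2)
  expect_lt(density, 0.05)

  lo <- correlation_network(m, st = 0.55)
  hi <- correlation_network(m, st = 0.80)
  lo_edges <- apply(igraph::as_edgelist(lo$graph), 1, paste, collapse = "|")
  hi_edges <- apply(igraph::as_edgelist(hi$graph), 1, paste, collapse = "|")
  expect_true(all(hi_edges %in% lo_edges))
})

test_that("topology statistics match closed-form values on canonical graphs", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$module <- 1L
  st <- network_topology(tri)
  expect_equal(st$avg_connectivity, 2)
  expect_equal(st$avg_geodesic, 1)
  expect_equal(st$avg_clustering, 1)
  expect_equal(st$modularity, 0, tolerance = 1e-12)

  two_tri <- igraph::disjoint_union(igraph::make_full_graph(3),
                                    igraph::make_full_graph(3))
  st2 <- network_topology(two_tri)
  expect_equal(st2$modularity, 0.5, tolerance = 1e-12)
  expect_equal(st2$n_modules, 2L)

  # brute force over every partition of the 6 nodes confirms 0.5 is the max
  adj <- as.matrix(igraph::as_adjacency_matrix(two_tri))
  qs <- vapply(all_partitions(6), function(p) oracle_modularity(adj, p),
               numeric(1))
  expect_equal(max(qs), 0.5, tolerance = 1e-12)

  # avg connectivity identity 2E/N on arbitrary graphs
  set.seed(43)
  for (i in 1:10) {
    g <- igraph::sample_gnp(sample(5:30, 1), 0.3)
    st_i <- network_topology(g)
    expect_equal(st_i$avg_connectivity,
                 2 * igraph::ecount(g) / igraph::vcount(g))
  }
})

test_that("implementation agrees with exhaustive-path oracles on small graphs", {
  set.seed(44)
  pairs6 <- t(utils::combn(6, 2))
  for (code in sample(0:(2^15 - 1), 60)) {
    adj <- adjacency_from_code(code, 6, pairs6)
    g <- graph_from_adj(adj)
    st <- network_topology(g)
    o_geo <- oracle_mean_geodesic(adj)
    if (!is.nan(o_geo)) expect_equal(st$avg_geodesic, o_geo, tolerance = 1e-10)
    expect_equal(st$avg_clustering, oracle_clustering(adj), tolerance = 1e-10)
    if (sum(adj) > 0 && nrow(adj) >= 3) {
      expect_equal(net_vulnerability(g), {
        e0 <- oracle_efficiency(adj)
        drops <- vapply(1:6, function(i) {
          (e0 - oracle_efficiency(adj[-i, -i])) / e0
        }, numeric(1))
        max(drops)
      }, tolerance = 1e-10)
    }
  }
})

test_that("random nulls keep degrees and expose empirical clustering", {
  # two 6-cliques joined by one edge: far more clustered than degree-matched
  cl <- igraph::disjoint_union(igraph::make_full_graph(6),
                               igraph::make_full_graph(6))
  cl <- igraph::add_edges(cl, c(1, 7))
  nulls <- random_null(cl, n_rand = 100, seed = 3)
  emp <- network_topology(cl)$avg_clustering
  expect_gt(emp, nulls$clustering[["mean"]] + 2 * nulls$clustering[["sd"]])

  expect_identical(random_null(cl, n_rand = 20, seed = 9),
                   random_null(cl, n_rand = 20, seed = 9))

  rewired <- igraph::rewire(cl, igraph::keeping_degseq(niter = 10 * igraph::ecount(cl)))
  expect_identical(sort(igraph::degree(rewired)), sort(igraph::degree(cl)))

  expect_warning(n0 <- random_null(igraph::make_full_graph(5), n_rand = 10),
                 "complete graph")
  expect_equal(unname(n0$clustering["sd"]), 0)
})

test_that("robustness counts survivors exactly on solvable graphs", {
  k10 <- igraph::make_full_graph(10)
  expect_equal(net_robustness(k10, 0.5, n_rep = 20, seed = 1), 0.5)

  star <- igraph::make_star(10, mode = "undirected", center = 1)
  r <- net_robustness(star, 0.5, n_rep = 50, seed = 2, force_remove = 1)
  expect_equal(r, 0)  # hub loss cascades through every isolated survivor

  set.seed(5)
  g <- igraph::sample_gnp(40, 0.08)
  r_lo <- net_robustness(g, 0.3, n_rep = 200, seed = 3)
  r_hi <- net_robustness(g, 0.6, n_rep = 200, seed = 3)
  expect_gt(r_lo, r_hi)
  expect_lte(r_hi, 1 - 0.6 + 1e-12)
})

test_that("vulnerability matches hand arithmetic", {
  path3 <- igraph::make_graph(~ A - B, B - C)
  expect_equal(net_vulnerability(path3), 1)   # removing B disconnects A and C
  expect_equal(net_vulnerability(igraph::make_full_graph(6)), 0)
  expect_error(net_vulnerability(igraph::make_full_graph(2)), "< 3 nodes")
})

test_that("Zi-Pi roles follow the participation arithmetic", {
  # two triangles joined through node 1 -> 4 edges for node 1 if we add links
  g <- igraph::make_graph(~ a - b, a - c, b - c, d - e, d - f, e - f, a - d, a - e)
  igraph::V(g)$module <- c(1L, 1L, 1L, 2L, 2L, 2L)
  roles <- zi_pi(g)
  a_row <- roles[roles$taxon == "a", ]
  expect_equal(a_row$pi, 1 - 2 * 0.5^2)  # 4 links split 2/2 across modules
  b_row <- roles[roles$taxon == "b", ]
  expect_equal(b_row$pi, 0)              # all links inside its own module
  expect_true(all(roles$pi >= 0 & roles$pi <= 1))
  # node with degree equal to its module's mean within-degree
  sym <- igraph::make_full_graph(4)
  igraph::V(sym)$module <- 1L
  expect_true(all(zi_pi(sym)$zi == 0))
  expect_true(all(zi_pi(sym)$role == "peripheral"))
})
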