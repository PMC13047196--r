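test_that("Bray-Curtis matches hand arithmetic and stays in [0, 1]", {
  m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0), d = c(2, 0, 0))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 0.5)           # 1 - 2*1/4
  expect_equal(d["a", "c"], 0)             # identical rows
  expect_equal(d["b", "d"], 1)             # disjoint rows

  sim <- tiny_sim()
  dv <- bray_curtis(sim$counts)
  expect_true(all(dv >= 0 & dv <= 1))
  perm <- sample(ncol(sim$counts))
  expect_equal(as.matrix(bray_curtis(sim$counts[, perm])), as.matrix(dv),
               tolerance = 1e-12)

  expect_error(bray_curtis(rbind(a = c(1, 1), b = c(0, 0))), "degenerate")
})

test_that("PCoA recovers known geometry", {
  # four points on a line: the first axis is the line, up to sign
  pos <- c(0, 1, 3, 7)
  d <- dist(pos)
  ord <- pcoa_ord(d)
  expect_equal(abs(cor(ord$points[, 1], pos)), 1, tolerance = 1e-10)

  # equidistant points (regular simplex): equal positive eigenvalues,
  # proportion explained 1/(n-1) each
  d4 <- stats::as.dist(matrix(1, 4, 4) - diag(4))
  ord4 <- pcoa_ord(d4)
  pos_eig <- ord4$eigenvalues[ord4$eigenvalues > 1e-10]
  expect_equal(length(pos_eig), 3L)
  expect_true(all(abs(pos_eig - pos_eig[1]) < 1e-10))
  expect_equal(ord4$proportion_explained, rep(1 / 3, 3), tolerance = 1e-10)

  # Euclidean input is reproduced by the recovered coordinates
  set.seed(4)
  X <- matrix(rnorm(8 * 5), 8, 5)
  ordE <- pcoa_ord(dist(X))
  expect_lt(max(abs(dist(ordE$points) - dist(X))), 1e-8)

  bad <- matrix(c(0, 1, 2, 3, 0, 1, 2, 3, 0), 3, 3)
  expect_error(pcoa_ord(bad), "symmetric")
})

test_that("dissimilarity tests detect separation and respect sample order", {
  set.seed(21)
  X <- rbind(matrix(rnorm(10 * 4), 10, 4),
             matrix(rnorm(10 * 4, mean = 5), 10, 4))
  g <- rep(c("a", "b"), each = 10)
  d <- dist(X)
  expect_lte(permanova(d, g, n_perm = 999, seed = 1)$p, 0.001)
  expect_lte(anosim_test(d, g, n_perm = 999, seed = 1)$p, 0.001)
  expect_lte(mrpp_test(d, g, n_perm = 999, seed = 1)$p, 0.001)

  # permuting sample order leaves the statistics unchanged
  perm <- sample(20)
  dp <- dist(X[perm, ])
  expect_equal(permanova(dp, g[perm], 199, 1)$pseudo_F,
               permanova(d, g, 199, 1)$pseudo_F, tolerance = 1e-10)
  expect_equal(anosim_test(dp, g[perm], 199, 1)$R,
               anosim_test(d, g, 199, 1)$R, tolerance = 1e-10)
  expect_equal(mrpp_test(dp, g[perm], 199, 1)$delta,
               mrpp_test(d, g, 199, 1)$delta, tolerance = 1e-10)

  # p-values are valid permutation p-values (never 0)
  set.seed(22)
  dn <- dist(matrix(rnorm(12 * 3), 12, 3))
  gn <- rep(c("a", "b"), 6)
  expect_gte(permanova(dn, gn, 199, 3)$p, 1 / 200)
  expect_error(permanova(dn, rep("a", 12), 199, 1), "at least 2 groups")
})

test_that("core screen applies strict occupancy and inclusive abundance thresholds", {
  n <- 18
  counts <- matrix(0L, n, 4,
                   dimnames = list(paste0("s", 1:n), paste0("t", 1:4)))
  counts[, 1] <- 50L               # 18/18, abundant -> core
  counts[1:14, 2] <- 50L           # 14/18 = 0.778 -> excluded (strict > 0.8)
  counts[1:15, 3] <- 50L           # 15/18 = 0.833 -> occupancy ok
  counts[, 4] <- 1L                # 18/18 but rare
  # make taxon 4 fall below 0.1% of the group total
  counts[, 1] <- 2000L
  cs <- core_taxa(counts)
  rel4 <- sum(counts[, 4]) / sum(counts)
  expect_lt(rel4, 0.001)
  expect_true("t1" %in% cs$taxa)
  expect_false("t2" %in% cs$taxa)
  expect_true("t3" %in% cs$taxa)
  expect_false("t4" %in% cs$taxa)

  # monotone: raising either threshold never adds taxa
  sim <- tiny_sim()
  base <- core_taxa(sim$counts)$taxa
  expect_true(all(core_taxa(sim$counts, occupancy = 0.9)$taxa %in% base))
  expect_true(all(core_taxa(sim$counts, min_abund = 0.01)$taxa %in% base))
})
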