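test_that("betaMNTD matches hand arithmetic and its structural invariants", {
  pd <- pd3()
  expect_equal(bmntd(c(1, 0, 0), c(0, 1, 0), pd), 2)       # 0.5*(2+2)
  expect_equal(bmntd(c(1, 0, 0), c(0, 0, 1), pd), 4)
  expect_equal(bmntd(c(2, 1, 0), c(2, 1, 0), pd), 0)       # identical samples
  # branch-length scaling is linear
  expect_equal(bmntd(c(1, 0, 0), c(0, 1, 0), pd * 3), 6)

  set.seed(31)
  sim <- tiny_sim()
  comm <- sim$counts[1:5, 1:20]
  comm[comm == 0] <- 0L
  pd20 <- taxon_distance(sim$tree, colnames(comm))
  m <- bmntd_matrix(comm, pd20)
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_true(all(m >= 0))
  for (a in 1:4) for (b in (a + 1):5) {
    expect_equal(m[a, b], bmntd(comm[a, ], comm[b, ], pd20),
                 tolerance = 1e-12)
  }
})

test_that("betaMNTD agrees with an independent nearest-taxon implementation", {
  skip_if_not_installed("picante")
  sim <- tiny_sim()
  comm <- sim$counts[1:6, 1:25]
  pd <- taxon_distance(sim$tree, colnames(comm))
  ours <- bmntd_matrix(comm, pd)
  ref <- as.matrix(picante::comdistnt(comm, pd, abundance.weighted = TRUE))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("betaNTI degenerates to 0 with a warning on a star phylogeny", {
  star <- matrix(2, 4, 4); diag(star) <- 0
  rownames(star) <- colnames(star) <- paste0("t", 1:4)
  x <- c(3, 1, 0, 0); y <- c(0, 0, 2, 5)
  expect_warning(z <- bnti(x, y, star, n_null = 99, seed = 1), "degenerate")
  expect_equal(z, 0)
})

test_that("betaNTI is Monte-Carlo stable across seeds", {
  sim <- tiny_sim()
  comm <- sim$counts[c(1, 7), ]
  pd <- taxon_distance(sim$tree, colnames(comm))
  z1 <- bnti(comm[1, ], comm[2, ], pd, n_null = 999, seed = 1)
  z2 <- bnti(comm[1, ], comm[2, ], pd, n_null = 999, seed = 2)
  expect_lt(abs(z1 - z2), 0.5)
  expect_identical(z1, bnti(comm[1, ], comm[2, ], pd, n_null = 999, seed = 1))
})

test_that("Raup-Crick behaves at its anchor points", {
  # saturated occupancy: the generative process coincides with the null
  # assembly model, which is the regime where null consistency is meaningful
  set.seed(33)
  pool_w <- rlnorm(40, 0, 1)
  draw <- function() rmultinom(1, 3000, prob = pool_w)[, 1]
  comm <- t(replicate(20, draw()))
  colnames(comm) <- paste0("t", 1:40)
  rownames(comm) <- paste0("s", 1:20)
  occ <- colMeans(comm > 0)
  relab <- colSums(comm) / sum(comm)

  # identical pair: observed BC of 0 sits below essentially every null draw
  x <- comm[1, ]
  expect_lt(rc_bray(x, x, occ, relab, n_null = 199, seed = 1), -0.9)

  # independent draws from one pool: RC centred near 0 across pairs
  rc <- rc_bray_matrix(comm, n_null = 199, seed = 2)
  vals <- rc[upper.tri(rc)]
  expect_lt(abs(mean(vals)), 0.2)
  expect_true(all(vals >= -1 & vals <= 1))
})

test_that("the five-process classifier applies its strict thresholds", {
  expect_equal(as.character(classify_process(2.5, 0.99)), "variable_selection")
  expect_equal(as.character(classify_process(-2.5, 0)), "homogeneous_selection")
  expect_equal(as.character(classify_process(0.3, -0.99)), "homogenizing_dispersal")
  expect_equal(as.character(classify_process(0.3, 0.99)), "dispersal_limitation")
  expect_equal(as.character(classify_process(0, 0)), "undominated")
  # boundary values fall to the stochastic / undominated side
  expect_equal(as.character(classify_process(2, 0)), "undominated")
  expect_equal(as.character(classify_process(-2, 0)), "undominated")
  expect_equal(as.character(classify_process(0, 0.95)), "undominated")
  expect_equal(as.character(classify_process(0, -0.95)), "undominated")
})

test_that("assembly partition is a complete per-group partition with unit fractions", {
  sim <- tiny_sim()
  ap <- suppressWarnings(assembly_partition(sim$counts, sim$tree,
                                            groups = sim$metadata$group,
                                            n_null = 99, seed = 5))
  n_per_group <- table(sim$metadata$group)
  expect_equal(nrow(ap$pairs), sum(choose(n_per_group, 2)))
  expect_false(any(is.na(ap$pairs$process)))
  expect_true(all(abs(rowSums(ap$fractions) - 1) < 1e-9))
})

test_that("generating regimes are recovered from their assembly signatures", {
  run_regime <- function(regime, sel) {
    d <- sim_design(n_taxa_pool = 150, groups = c(0, 100), stages = 3,
                    replicates = 3, depth = 20000, selection_strength = sel,
                    dispersal_regime = regime, trait_signal = 1, seed = 17)
    sim <- simulate_community(d)
    suppressWarnings(assembly_partition(sim$counts, sim$tree, groups = NULL,
                                        n_null = 99, seed = 17))$fractions
  }
  fr_sel <- run_regime("neutral", 30)
  expect_equal(colnames(fr_sel)[which.max(fr_sel)], "variable_selection")

  fr_lim <- run_regime("limited", 0)
  expect_equal(colnames(fr_lim)[which.max(fr_lim)], "dispersal_limitation")

  fr_hom <- run_regime("homogenizing", 0)
  expect_gte(fr_hom[, "homogenizing_dispersal"] + fr_hom[, "undominated"], 0.6)
})
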