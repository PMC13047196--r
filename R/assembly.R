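# Phylogenetic null-model partitioning of community assembly.
#
# The turnover between every pair of samples is attributed to one of five
# ecological processes: variable selection (betaNTI > +2), homogeneous
# selection (betaNTI < -2), and -- for pairs with |betaNTI| < 2 -- dispersal
# limitation (RC_bray > +0.95), homogenizing dispersal (RC_bray < -0.95) or
# an undominated remainder.

#' Patristic distance matrix between taxa
#'
#' Pairwise sum of branch lengths along the tree, restricted (and ordered)
#' to the requested taxa.
#'
#' @param tree Rooted \code{phylo} with branch lengths.
#' @param taxa Taxon ids (must be tips); defaults to all tips.
#' @return Symmetric matrix of patristic distances.
#' @export
taxon_distance <- function(tree, taxa = tree$tip.label) {
  if (!all(taxa %in% tree$tip.label)) {
    stop("taxa missing from tree: ",
         paste(utils::head(setdiff(taxa, tree$tip.label), 5), collapse = ", "))
  }
  pd <- ape::cophenetic.phylo(tree)
  pd[taxa, taxa, drop = FALSE]
}

#' Between-sample mean nearest taxon distance (betaMNTD)
#'
#' Abundance-weighted: for each taxon present in one sample, the
#' phylogenetic distance to its nearest relative present in the other
#' sample, averaged with weights equal to relative abundances among present
#' taxa, then averaged over the two directions:
#' \deqn{0.5 \left[ \sum_i f_{xi} \min_{j: y_j > 0} d_{ij}
#'               + \sum_j f_{yj} \min_{i: x_i > 0} d_{ij} \right]}
#' Shared taxa contribute distance 0 (their nearest relative is themselves).
#'
#' @param x,y Abundance vectors aligned to the rows/columns of \code{pd}.
#' @param pd Taxon distance matrix covering all taxa present in x or y.
#' @return Non-negative scalar; 0 when the two samples share their taxa.
#' @export
bmntd <- function(x, y, pd) {
  px <- which(x > 0); py <- which(y > 0)
  if (!length(px) || !length(py)) stop("degenerate community: no taxa present")
  dx <- apply(pd[px, py, drop = FALSE], 1, min)
  dy <- apply(pd[px, py, drop = FALSE], 2, min)
  0.5 * (sum(x[px] / sum(x[px]) * dx) + sum(y[py] / sum(y[py]) * dy))
}

# Nearest-taxon distance profile: for each pool taxon i, min_j in P pd[i, j].
# Sharing these profiles across sample pairs is what makes the null loop
# affordable: one profile per sample per permutation instead of one matrix
# min per pair.
ntd_profiles <- function(comm, pd, perm = NULL) {
  if (!is.null(perm)) pd <- pd[perm, perm, drop = FALSE]
  out <- matrix(NA_real_, ncol(comm), nrow(comm))
  for (s in seq_len(nrow(comm))) {
    p <- which(comm[s, ] > 0)
    out[, s] <- do.call(pmin, c(as.data.frame(pd[, p, drop = FALSE]),
                                list(na.rm = FALSE)))
  }
  out
}

bmntd_from_profiles <- function(comm, profiles) {
  n <- nrow(comm)
  rel <- comm / rowSums(comm)
  pres <- comm > 0
  d <- matrix(0, n, n, dimnames = list(rownames(comm), rownames(comm)))
  for (a in seq_len(n - 1)) {
    pa <- which(pres[a, ])
    for (b in (a + 1):n) {
      pb <- which(pres[b, ])
      v <- 0.5 * (sum(rel[a, pa] * profiles[pa, b]) +
                  sum(rel[b, pb] * profiles[pb, a]))
      d[a, b] <- d[b, a] <- v
    }
  }
  d
}

#' All pairwise betaMNTD for a community matrix
#'
#' @param comm Samples x taxa abundance matrix.
#' @param pd Taxon distance matrix aligned to \code{colnames(comm)}.
#' @return Symmetric samples x samples matrix.
#' @export
bmntd_matrix <- function(comm, pd) {
  stopifnot(identical(colnames(comm), rownames(pd)))
  bmntd_from_profiles(comm, ntd_profiles(comm, pd))
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of betaMNTD against a taxa-shuffle null: taxon
#' labels are permuted across the tips of the distance matrix, randomizing
#' phylogenetic relationships while preserving each sample's abundances and
#' occupancy; \eqn{\beta NTI = (obs - \bar{null}) / sd(null)}. A null with
#' (numerically) zero spread — e.g. a star phylogeny, or two samples sharing
#' all their taxa — yields 0 with a warning.
#'
#' @inheritParams bmntd
#' @param n_null Number of null randomizations (>= 99).
#' @param seed Integer seed.
#' @return Scalar betaNTI.
#' @export
bnti <- function(x, y, pd, n_null = 999, seed = 1L) {
  if (n_null < 99) stop("n_null must be >= 99")
  comm <- rbind(x, y)
  colnames(comm) <- rownames(pd)
  bnti_matrix(comm, pd, n_null = n_null, seed = seed)[1, 2]
}

#' All pairwise betaNTI for a community matrix
#'
#' One taxa-shuffle permutation per null iteration is shared across all
#' sample pairs, as in the standard implementations of this null model.
#'
#' @inheritParams bmntd_matrix
#' @param n_null Number of null randomizations (>= 99).
#' @param seed Integer seed.
#' @return Symmetric samples x samples matrix of betaNTI values (diagonal 0).
#' @export
bnti_matrix <- function(comm, pd, n_null = 999, seed = 1L) {
  stopifnot(identical(colnames(comm), rownames(pd)))
  if (n_null < 99) stop("n_null must be >= 99")
  if (any(rowSums(comm > 0) == 0)) stop("degenerate community: no taxa present")
  n <- nrow(comm); nt <- ncol(comm)
  obs <- bmntd_matrix(comm, pd)
  set.seed(seed)
  ut <- upper.tri(obs)
  nulls <- matrix(NA_real_, n_null, sum(ut))
  for (k in seq_len(n_null)) {
    perm <- sample.int(nt)
    nulls[k, ] <- bmntd_from_profiles(comm, ntd_profiles(comm, pd, perm))[ut]
  }
  mu <- colMeans(nulls)
  sdv <- apply(nulls, 2, stats::sd)
  z <- (obs[ut] - mu) / sdv
  degen <- sdv < 1e-12
  if (any(degen)) {
    warning(sum(degen), " pair(s) with a degenerate (zero-spread) null; betaNTI set to 0")
    z[degen] <- 0
  }
  out <- matrix(0, n, n, dimnames = dimnames(obs))
  out[ut] <- z
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

# Draw one null community: the observed richness S is kept, species are
# drawn without replacement with probability proportional to pool occupancy,
# each drawn species is seeded with one individual, and the remaining
# N - S individuals are distributed multinomially proportional to pool
# relative abundance.
null_community <- function(S, N, occ, relab) {
  pool <- which(occ > 0)
  if (S > length(pool)) S <- length(pool)
  sp <- if (length(pool) == 1) pool else sample(pool, S, prob = occ[pool])
  counts <- numeric(length(occ))
  counts[sp] <- 1
  if (N > S) {
    p <- relab[sp]
    if (sum(p) <= 0) p <- rep(1, length(sp))
    counts[sp] <- counts[sp] + stats::rmultinom(1, N - S, prob = p)[, 1]
  }
  counts
}

bc_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)

#' Raup-Crick metric on Bray-Curtis dissimilarity
#'
#' Locates the observed Bray-Curtis dissimilarity of a sample pair within a
#' null distribution generated from the species pool: null communities keep
#' each sample's observed richness and total abundance, with membership
#' drawn proportional to pool occupancy and abundances filled proportional
#' to pool relative abundance. \eqn{RC = 2 (n_{<} + 0.5\, n_{=}) / n_{null} - 1},
#' clamped to [-1, 1].
#'
#' @param x,y Count vectors for the two samples.
#' @param pool_occ Pool occupancy per taxon (fraction of pool samples with
#'   the taxon present).
#' @param pool_relab Pool relative abundance per taxon.
#' @param n_null Number of null draws (>= 99).
#' @param seed Integer seed.
#' @return Scalar in [-1, 1].
#' @export
rc_bray <- function(x, y, pool_occ, pool_relab, n_null = 999, seed = 1L) {
  if (n_null < 99) stop("n_null must be >= 99")
  if (!any(pool_occ > 0)) stop("empty species pool")
  set.seed(seed)
  obs <- bc_pair(x, y)
  Sx <- sum(x > 0); Sy <- sum(y > 0)
  Nx <- sum(x); Ny <- sum(y)
  less <- 0; equal <- 0
  for (k in seq_len(n_null)) {
    b <- bc_pair(null_community(Sx, Nx, pool_occ, pool_relab),
                 null_community(Sy, Ny, pool_occ, pool_relab))
    if (b < obs - 1e-12) less <- less + 1
    else if (abs(b - obs) <= 1e-12) equal <- equal + 1
  }
  rc <- 2 * (less + 0.5 * equal) / n_null - 1
  max(-1, min(1, rc))
}

#' All pairwise Raup-Crick values for a community matrix
#'
#' The species pool (occupancy and relative abundance) is built from the
#' rows of \code{comm} — pass the samples of one group to use a group pool.
#' Each null iteration draws one null community per sample (richness and
#' total abundance preserved) and evaluates all pairwise Bray-Curtis
#' dissimilarities at once, so the null draws are shared across pairs.
#'
#' @param comm Samples x taxa count matrix.
#' @param n_null Number of null draws (>= 99).
#' @param seed Integer seed.
#' @return Symmetric samples x samples matrix of RC values (diagonal 0).
#' @export
rc_bray_matrix <- function(comm, n_null = 999, seed = 1L) {
  if (n_null < 99) stop("n_null must be >= 99")
  occ <- colMeans(comm > 0)
  if (!any(occ > 0)) stop("empty species pool")
  relab <- colSums(comm) / sum(comm)
  n <- nrow(comm)
  S <- rowSums(comm > 0); N <- rowSums(comm)
  obs <- as.matrix(vegan::vegdist(comm, method = "bray"))
  set.seed(seed)
  less <- matrix(0, n, n); equal <- matrix(0, n, n)
  nullm <- matrix(0, n, ncol(comm))
  for (k in seq_len(n_null)) {
    for (s in seq_len(n)) nullm[s, ] <- null_community(S[s], N[s], occ, relab)
    b <- as.matrix(vegan::vegdist(nullm, method = "bray"))
    less <- less + (b < obs - 1e-12)
    equal <- equal + (abs(b - obs) <= 1e-12)
  }
  rc <- 2 * (less + 0.5 * equal) / n_null - 1
  rc <- pmax(pmin(rc, 1), -1)
  diag(rc) <- 0
  dimnames(rc) <- list(rownames(comm), rownames(comm))
  rc
}

#' Classify pairwise turnover into five assembly processes
#'
#' betaNTI > +2: variable selection; betaNTI < -2: homogeneous selection;
#' otherwise RC > +0.95: dispersal limitation; RC < -0.95: homogenizing
#' dispersal; else undominated. Thresholds are strict, so |betaNTI| = 2 and
#' |RC| = 0.95 fall to the stochastic/undominated side.
#'
#' @param bnti Numeric vector of betaNTI values.
#' @param rc Numeric vector of RC values (same length).
#' @param bnti_thresh,rc_thresh Classification thresholds (defaults 2, 0.95).
#' @return Factor with levels \code{variable_selection},
#'   \code{homogeneous_selection}, \code{dispersal_limitation},
#'   \code{homogenizing_dispersal}, \code{undominated}.
#' @export
classify_process <- function(bnti, rc, bnti_thresh = 2, rc_thresh = 0.95) {
  stopifnot(length(bnti) == length(rc), all(is.finite(bnti)))
  out <- ifelse(bnti > bnti_thresh, "variable_selection",
         ifelse(bnti < -bnti_thresh, "homogeneous_selection",
         ifelse(rc > rc_thresh, "dispersal_limitation",
         ifelse(rc < -rc_thresh, "homogenizing_dispersal", "undominated"))))
  factor(out, levels = c("variable_selection", "homogeneous_selection",
                         "dispersal_limitation", "homogenizing_dispersal",
                         "undominated"))
}

#' Partition community assembly for a set of samples
#'
#' Runs betaNTI and Raup-Crick for every sample pair (within each group if
#' \code{groups} is given, following the convention of reporting per-group
#' process fractions) and classifies each pair.
#'
#' @param comm Samples x taxa count matrix.
#' @param tree Phylogeny covering the taxa.
#' @param groups Optional grouping vector (one per sample); when given,
#'   only within-group pairs are evaluated and fractions are per group.
#' @param n_null Null randomizations for both metrics.
#' @param seed Integer seed.
#' @param bnti_thresh,rc_thresh Classification thresholds.
#' @return Object of class \code{assembly_partition}: \code{pairs} (one row
#'   per pair: samples, group, bmntd_obs, bnti, rc_bray, process) and
#'   \code{fractions} (per group, one column per process, rows sum to 1).
#' @export
assembly_partition <- function(comm, tree, groups = NULL, n_null = 999,
                               seed = 1L, bnti_thresh = 2, rc_thresh = 0.95) {
  pd <- taxon_distance(tree, colnames(comm))
  if (is.null(groups)) groups <- rep("all", nrow(comm))
  groups <- as.character(groups)
  res <- NULL
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    sub <- comm[idx, , drop = FALSE]
    keep <- colSums(sub) > 0
    sub <- sub[, keep, drop = FALSE]
    z <- bnti_matrix(sub, pd[keep, keep], n_null = n_null, seed = seed)
    rc <- rc_bray_matrix(sub, n_null = n_null, seed = seed)
    obs <- bmntd_matrix(sub, pd[keep, keep])
    ut <- which(upper.tri(z), arr.ind = TRUE)
    res <- rbind(res, data.frame(
      sample_1 = rownames(sub)[ut[, 1]], sample_2 = rownames(sub)[ut[, 2]],
      group = g, bmntd_obs = obs[upper.tri(obs)], bnti = z[upper.tri(z)],
      rc_bray = rc[upper.tri(rc)], stringsAsFactors = FALSE))
  }
  if (is.null(res)) stop("design error: no group with >= 2 samples")
  res$process <- classify_process(res$bnti, res$rc_bray,
                                  bnti_thresh, rc_thresh)
  fr <- t(vapply(split(res$process, res$group),
                 function(p) as.vector(prop.table(table(p))),
                 numeric(nlevels(res$process))))
  colnames(fr) <- levels(res$process)
  structure(list(pairs = res, fractions = fr), class = "assembly_partition")
}

#' @export
print.assembly_partition <- function(x, ...) {
  cat("Assembly partition over", nrow(x$pairs), "sample pairs\n")
  print(round(x$fractions, 3))
  invisible(x)
}
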