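# Bray-Curtis dissimilarity, principal coordinates, the three permutation
# tests of group dissimilarity, and the core-taxon screen.

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(x, y) = 1 - 2 \sum_k \min(x_k, y_k) / (\sum_k x_k + \sum_k y_k)},
#' computed on the counts as given (use \code{relative = TRUE} to compute on
#' per-sample relative abundances instead).
#'
#' @param counts Samples x taxa matrix, positive row sums.
#' @param relative Compute on relative abundances instead of raw counts.
#' @return A \code{dist} object over samples.
#' @export
bray_curtis <- function(counts, relative = FALSE) {
  rs <- rowSums(counts)
  if (any(rs <= 0)) {
    stop("degenerate sample (zero total count): ",
         paste(rownames(counts)[rs <= 0], collapse = ", "))
  }
  if (relative) counts <- relative_abundance(counts)
  vegan::vegdist(counts, method = "bray")
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the double-centred Gower matrix of a dissimilarity.
#' Coordinates are returned for positive axes only; negative eigenvalues are
#' retained and reported, and the proportion explained is taken over the sum
#' of the positive eigenvalues.
#'
#' @param d A \code{dist} or symmetric hollow matrix over >= 3 samples.
#' @return List of class \code{pcoa_ord}: \code{points} (n x k),
#'   \code{eigenvalues} (all n, sorted decreasing),
#'   \code{proportion_explained} (length k), \code{n_negative}.
#' @export
pcoa_ord <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop("need at least 3 samples for ordination")
  if (max(abs(m - t(m))) > 1e-8 || max(abs(diag(m))) > 1e-12) {
    stop("contract violation: distance matrix must be symmetric and hollow")
  }
  n <- nrow(m)
  g <- -0.5 * m^2
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))  # now the double-centred Gower matrix
  eg <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-10
  pos <- which(eg$values > tol)
  pts <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]),
                                                  length(pos))
  rownames(pts) <- rownames(m)
  colnames(pts) <- paste0("PCo", seq_along(pos))
  structure(list(points = pts, eigenvalues = eg$values,
                 proportion_explained = eg$values[pos] / sum(eg$values[pos]),
                 n_negative = sum(eg$values < -tol)),
            class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat("PCoA:", nrow(x$points), "samples,", ncol(x$points),
      "positive axes (", x$n_negative, "negative eigenvalues )\n")
  cat("  first axes explain:",
      paste0(round(100 * utils::head(x$proportion_explained, 3), 1), "%",
             collapse = ", "), "\n")
  invisible(x)
}

#' Permutation tests of group dissimilarity
#'
#' PERMANOVA (pseudo-F), ANOSIM (R) and MRPP (delta, chance-corrected A),
#' all with the same label-permutation null and the valid permutation
#' p-value \eqn{(1 + \#\{stat_{perm} \ge stat_{obs}\}) / (1 + n_{perm})}.
#'
#' @param d Dissimilarity (\code{dist}) over samples.
#' @param groups Grouping factor (>= 2 levels).
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return \code{permanova}: list(pseudo_F, p); \code{anosim_test}:
#'   list(R, p); \code{mrpp_test}: list(delta, A, p).
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  check_grouping(groups, n_perm)
  df <- data.frame(g = factor(groups))
  set.seed(seed)
  fit <- vegan::adonis2(d ~ g, data = df, permutations = n_perm)
  list(pseudo_F = fit$F[1], p = fit$`Pr(>F)`[1])
}

#' @rdname permanova
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1L) {
  check_grouping(groups, n_perm)
  set.seed(seed)
  fit <- vegan::anosim(d, factor(groups), permutations = n_perm)
  list(R = unname(fit$statistic), p = fit$signif)
}

#' @rdname permanova
#' @export
mrpp_test <- function(d, groups, n_perm = 999, seed = 1L) {
  check_grouping(groups, n_perm)
  set.seed(seed)
  fit <- vegan::mrpp(d, factor(groups), permutations = n_perm)
  list(delta = fit$delta, A = fit$A, p = fit$Pvalue)
}

check_grouping <- function(groups, n_perm) {
  if (nlevels(factor(groups)) < 2) stop("design error: need at least 2 groups")
  if (n_perm < 99) stop("n_perm must be >= 99")
  invisible(TRUE)
}

#' Core-taxon screen within a group
#'
#' A taxon is core when its occupancy (fraction of the group's samples with
#' a nonzero count) strictly exceeds the occupancy threshold and its summed
#' relative abundance within the group (taxon total / grand total) is at
#' least the abundance threshold.
#'
#' @param counts Samples x taxa matrix restricted to one group (>= 2 rows).
#' @param occupancy Occupancy threshold, strict (default 0.8).
#' @param min_abund Within-group summed relative-abundance threshold,
#'   inclusive (default 0.001, i.e. 0.1\%).
#' @param group Optional group label carried into the result.
#' @return List of class \code{core_set}: \code{taxa}, \code{group},
#'   \code{occupancy}, \code{min_abund}.
#' @export
core_taxa <- function(counts, occupancy = 0.8, min_abund = 0.001,
                      group = NA) {
  if (nrow(counts) < 2) stop("design error: need >= 2 samples in the group")
  occ <- colMeans(counts > 0)
  rel <- colSums(counts) / sum(counts)
  keep <- occ > occupancy & rel >= min_abund
  structure(list(taxa = colnames(counts)[keep], group = group,
                 occupancy = occupancy, min_abund = min_abund),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat("Core set", if (!is.na(x$group)) paste0("(group ", x$group, ")"), ":",
      length(x$taxa), "taxa (occupancy >", x$occupancy,
      ", abundance >=", x$min_abund, ")\n")
  invisible(x)
}
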