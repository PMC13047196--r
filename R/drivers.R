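# Environmental drivers of community dissimilarity: partial Mantel tests
# and two-set variance partitioning.

#' Partial Mantel test of one environmental variable
#'
#' Correlates the community dissimilarity with the Euclidean distance on the
#' standardized focal variable, partialling out the Euclidean distance on a
#' standardized covariate block (first-order partial correlation of the
#' three distance vectors). With no covariates this reduces to the simple
#' Mantel test. Significance is by permutation of sample labels,
#' \eqn{p = (1 + n_{exceed}) / (1 + n_{perm})}.
#'
#' @param d_comm Community dissimilarity (\code{dist}) over samples.
#' @param env_focal Numeric vector, one value per sample (not constant).
#' @param env_covariates Optional numeric matrix/data.frame of covariates
#'   (one row per sample); NULL or zero columns gives the simple Mantel test.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @param variable Name carried into the result.
#' @return List of class \code{mantel_result}: \code{variable}, \code{r},
#'   \code{p}, \code{n_perm}, \code{covariates}.
#' @export
partial_mantel <- function(d_comm, env_focal, env_covariates = NULL,
                           n_perm = 999, seed = 1L, variable = "focal") {
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (stats::sd(env_focal) == 0) {
    stop("undefined distance: focal variable is constant")
  }
  d_focal <- stats::dist(scale(env_focal))
  set.seed(seed)
  if (is.null(env_covariates) || NCOL(env_covariates) == 0) {
    fit <- vegan::mantel(d_comm, d_focal, method = "pearson",
                         permutations = n_perm)
    covs <- character(0)
  } else {
    cov_m <- scale(as.matrix(env_covariates))
    cov_m <- cov_m[, apply(cov_m, 2, function(x) stats::sd(x) > 0),
                   drop = FALSE]
    if (ncol(cov_m) == 0) {
      fit <- vegan::mantel(d_comm, d_focal, method = "pearson",
                           permutations = n_perm)
      covs <- character(0)
    } else {
      fit <- vegan::mantel.partial(d_comm, d_focal, stats::dist(cov_m),
                                   method = "pearson", permutations = n_perm)
      covs <- colnames(cov_m)
      if (is.null(covs)) covs <- paste0("cov", seq_len(ncol(cov_m)))
    }
  }
  structure(list(variable = variable, r = unname(fit$statistic),
                 p = fit$signif, n_perm = n_perm, covariates = covs),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Partial Mantel [%s]: r = %.3f, p = %.4g (%d permutations, %d covariates)\n",
              x$variable, x$r, x$p, x$n_perm, length(x$covariates)))
  invisible(x)
}

#' Partial Mantel screen over an environmental table
#'
#' Runs \code{\link{partial_mantel}} for every column of \code{env},
#' partialling out the remaining columns as one block (or a single chosen
#' covariate per variable via \code{covariate}).
#'
#' @param d_comm Community dissimilarity over samples.
#' @param env data.frame of environmental variables (rows = samples).
#' @param covariate Optional single covariate column name to control for
#'   instead of the all-remaining-variables block.
#' @param n_perm,seed Passed through.
#' @return data.frame: \code{variable}, \code{r}, \code{p}.
#' @export
mantel_screen <- function(d_comm, env, covariate = NULL, n_perm = 999,
                          seed = 1L) {
  vars <- colnames(env)
  out <- lapply(vars, function(v) {
    covs <- if (is.null(covariate)) env[, setdiff(vars, v), drop = FALSE]
            else env[, setdiff(covariate, v), drop = FALSE]
    fit <- partial_mantel(d_comm, env[[v]], covs, n_perm = n_perm,
                          seed = seed, variable = v)
    data.frame(variable = v, r = fit$r, p = fit$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Variance partitioning between physical and chemical predictors
#'
#' Distance-based redundancy partitioning of the community dissimilarity
#' over two predictor sets: adjusted R-squared for each set and their union,
#' with pure and shared fractions by inclusion-exclusion. Negative adjusted
#' fractions are reported as-is (use \code{clamp = TRUE} for a display
#' variant clamped at zero); the residual is \eqn{1 - adjR^2(both)} so the
#' four reported fractions always sum to 1.
#'
#' @param d_comm Community dissimilarity (\code{dist}).
#' @param physical data.frame/matrix of the first predictor set.
#' @param chemical data.frame/matrix of the second predictor set.
#' @param clamp Clamp negative fractions to 0 for display (default FALSE).
#' @return List of class \code{vpa_result}: \code{fraction_physical_pure},
#'   \code{fraction_chemical_pure}, \code{fraction_shared}, \code{residual}.
#' @export
vpa <- function(d_comm, physical, chemical, clamp = FALSE) {
  if (NCOL(physical) == 0 || NCOL(chemical) == 0) {
    stop("both predictor sets must be non-empty")
  }
  n <- attr(stats::as.dist(d_comm), "Size")
  if (n < NCOL(physical) + NCOL(chemical) + 2) {
    stop("design error: need n >= total predictors + 2")
  }
  part <- vegan::varpart(stats::as.dist(d_comm), as.matrix(physical),
                         as.matrix(chemical))
  fr <- part$part$indfract$Adj.R.square
  lab <- rownames(part$part$indfract)
  pure1 <- grepl("X1\\s*\\|\\s*X2", lab)
  pure2 <- grepl("X2\\s*\\|\\s*X1", lab)
  resid <- grepl("Residual", lab)
  shared <- !(pure1 | pure2 | resid)
  stopifnot(sum(pure1) == 1, sum(pure2) == 1, sum(resid) == 1,
            sum(shared) == 1)
  out <- list(fraction_physical_pure = fr[pure1],
              fraction_shared = fr[shared],
              fraction_chemical_pure = fr[pure2],
              residual = fr[resid])
  if (clamp) {
    clamped <- lapply(out[1:3], function(v) max(v, 0))
    out[1:3] <- clamped
  }
  structure(out, class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, ...) {
  cat(sprintf("VPA: pure physical %.3f | shared %.3f | pure chemical %.3f | residual %.3f\n",
              x$fraction_physical_pure, x$fraction_shared,
              x$fraction_chemical_pure, x$residual))
  invisible(x)
}
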