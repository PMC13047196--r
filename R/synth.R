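#' Simulation design for a synthetic casing-soil community
#'
#' Bundles every knob of the synthetic-data generator: the regional taxon
#' pool, the sampling design (peat-proportion groups x growth stages x
#' replicates), sequencing depth, and the three levers that control which
#' assembly process dominates the simulated communities:
#' \code{selection_strength} (trait-based environmental filtering),
#' \code{dispersal_regime} (\code{"homogenizing"}, \code{"limited"} or
#' \code{"neutral"}) and \code{trait_signal} (Brownian rate of the habitat
#' optima along the phylogeny).
#'
#' The default design mirrors a five-level peat gradient sampled over six
#' growth stages with three replicates (90 samples) from a 300-taxon pool at
#' 20,000 reads per sample.
#'
#' @param n_taxa_pool Number of taxa in the regional pool (>= 4).
#' @param groups Ordered vector of group labels, interpreted as peat
#'   percentages.
#' @param stages Number of growth stages.
#' @param replicates Replicates per group-stage combination (>= 1).
#' @param depth Expected reads per sample (>= 10).
#' @param selection_strength Non-negative filtering strength; 0 disables
#'   selection.
#' @param dispersal_regime One of \code{"homogenizing"}, \code{"limited"},
#'   \code{"neutral"}.
#' @param trait_signal Non-negative Brownian variance rate of habitat optima.
#' @param stage_amplitude Drift of the latent environmental axis across
#'   growth stages, as a fraction of the full peat-gradient span (the
#'   within-group environmental variation that lets taxa co-vary).
#' @param regional_sigma Lognormal sd of the shared regional abundance
#'   weights (used by the homogenizing and limited regimes).
#' @param dispersal_sigma Lognormal sd of the per-sample weight jitter used
#'   by the limited regime.
#' @param noise_sd Relative sd of the Gaussian replicate noise on the
#'   physicochemical variables.
#' @param seed Integer seed; the whole simulation is deterministic given the
#'   design.
#' @return An object of class \code{sim_design} (a validated list).
#' @export
sim_design <- function(n_taxa_pool = 300,
                       groups = c(0, 20, 50, 70, 100),
                       stages = 6,
                       replicates = 3,
                       depth = 20000,
                       selection_strength = 0,
                       dispersal_regime = c("neutral", "homogenizing", "limited"),
                       trait_signal = 1,
                       stage_amplitude = 0.15,
                       regional_sigma = 1,
                       dispersal_sigma = 2,
                       noise_sd = 0.05,
                       seed = 1L) {
  dispersal_regime <- match.arg(dispersal_regime)
  if (n_taxa_pool < 4) stop("invalid design: n_taxa_pool must be >= 4")
  if (depth < 10) stop("invalid design: depth must be >= 10")
  if (length(groups) < 1) stop("invalid design: groups must be non-empty")
  if (replicates < 1) stop("invalid design: replicates must be >= 1")
  if (selection_strength < 0) stop("invalid design: selection_strength must be >= 0")
  if (trait_signal < 0) stop("invalid design: trait_signal must be >= 0")
  structure(list(
    n_taxa_pool = as.integer(n_taxa_pool), groups = groups,
    stages = as.integer(stages), replicates = as.integer(replicates),
    depth = as.integer(depth), selection_strength = selection_strength,
    dispersal_regime = dispersal_regime, trait_signal = trait_signal,
    stage_amplitude = stage_amplitude,
    regional_sigma = regional_sigma, dispersal_sigma = dispersal_sigma,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "sim_design")
}

#' Simulate a rooted phylogeny for the regional taxon pool
#'
#' Random rooted binary topology with strictly positive branch lengths; tips
#' are labelled \code{OTU_1 .. OTU_n}. Identical seeds give byte-identical
#' trees.
#'
#' @param n_taxa_pool Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An \code{ape} \code{phylo} object.
#' @export
simulate_tree <- function(n_taxa_pool, seed = 1L) {
  if (n_taxa_pool < 2) stop("invalid design: need at least 2 taxa to build a tree")
  set.seed(seed)
  tree <- ape::rtree(n_taxa_pool, rooted = TRUE)
  tree$tip.label <- paste0("OTU_", seq_len(n_taxa_pool))
  # rtree draws branch lengths from U(0,1); guard the open bound anyway
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  tree
}

#' Simulate habitat optima by Brownian motion along a phylogeny
#'
#' Each tip receives a niche optimum evolved from a root value of 0 by
#' Brownian motion with variance rate \code{trait_signal}; closely related
#' taxa therefore have similar optima, which is what makes environmental
#' selection leave a phylogenetic signature downstream. A rate of 0 returns
#' the root value for every tip.
#'
#' @param tree A rooted \code{phylo} with branch lengths.
#' @param trait_signal Non-negative Brownian variance rate.
#' @param seed Integer seed.
#' @return Named numeric vector of optima, one per tip.
#' @export
simulate_optima <- function(tree, trait_signal, seed = 1L) {
  if (is.null(tree$edge.length)) stop("invalid tree: branch lengths are required")
  if (trait_signal < 0) stop("trait_signal must be >= 0")
  ntip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  vals <- numeric(ntip + tree$Nnode)
  set.seed(seed)
  steps <- stats::rnorm(nrow(tree$edge), 0,
                        sqrt(trait_signal * tree$edge.length))
  for (k in seq_len(nrow(tree$edge))) {
    vals[tree$edge[k, 2L]] <- vals[tree$edge[k, 1L]] + steps[k]
  }
  stats::setNames(vals[seq_len(ntip)], tree$tip.label)
}

#' Simulate sample metadata along the peat gradient
#'
#' Produces one row per sample of the crossed design with physicochemical
#' variables that are noisy linear transforms of a single latent peat axis
#' (\code{env_axis}, the peat proportion rescaled to [0, 1]): total nitrogen
#' (TN), organic matter (OM), ammonium (NH4), total sulfur (TS) and moisture
#' increase with peat; bulk density and simulated unit weight decrease; pH
#' decreases (peat is acidic); nitrate (NO3) is independent of the gradient.
#'
#' @param design A \code{sim_design}.
#' @return A data.frame with columns \code{sample_id}, \code{group},
#'   \code{stage}, \code{replicate}, \code{env_axis} and the physicochemical
#'   variables.
#' @export
simulate_metadata <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      stage = seq_len(design$stages),
                      group = design$groups,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("group", "stage", "replicate")]
  n <- nrow(grid)
  # latent axis: group peat effect plus a centred drift across growth
  # stages, so samples within a group are not environmental clones
  z <- grid$group / max(design$groups, 1)
  if (design$stages > 1) {
    z <- z + design$stage_amplitude *
      (grid$stage - (design$stages + 1) / 2) / (design$stages - 1)
  }
  # (intercept, slope) per variable on the latent axis; slope sign encodes
  # the direction of the peat effect
  spec <- list(
    TN          = c(1.0,   2.0),
    NH4         = c(5.0,  15.0),
    NO3         = c(10.0,  0.0),
    AP          = c(30.0, 25.0),
    AK          = c(150, 100.0),
    TS          = c(0.2,   0.6),
    pH          = c(7.5,  -1.5),
    moisture    = c(30.0, 40.0),
    OM          = c(20.0, 40.0),
    density     = c(1.4,  -0.8),
    unit_weight = c(14.0, -6.0)
  )
  set.seed(design$seed + 1L)
  env <- lapply(spec, function(ab) {
    scale_ref <- if (ab[2] != 0) abs(ab[2]) else abs(ab[1])
    ab[1] + ab[2] * z + stats::rnorm(n, 0, design$noise_sd * scale_ref)
  })
  out <- data.frame(
    sample_id = sprintf("CT%s_S%d_R%d", grid$group, grid$stage, grid$replicate),
    group = grid$group, stage = grid$stage, replicate = grid$replicate,
    env_axis = z, as.data.frame(env), stringsAsFactors = FALSE
  )
  rownames(out) <- out$sample_id
  out
}

#' Simulate an OTU count table under a known assembly regime
#'
#' Per-sample multinomial sampling at the design depth from taxon weights
#' \eqn{w \propto \exp(-s\,(\mathrm{optimum} - e)^2)} where \eqn{s} is the
#' selection strength and \eqn{e} the sample's position on the latent peat
#' axis mapped onto the optimum scale. The dispersal regime modulates the
#' weights: \code{"homogenizing"} multiplies in one shared lognormal
#' regional abundance vector; \code{"limited"} additionally jitters it per
#' sample with a high-variance lognormal; \code{"neutral"} applies no
#' dispersal modulation.
#'
#' @param tree Pool phylogeny (tips = taxa).
#' @param optima Named optima as from \code{\link{simulate_optima}}.
#' @param metadata Metadata as from \code{\link{simulate_metadata}}.
#' @param design The \code{sim_design}.
#' @return Integer matrix (samples x taxa) with dimnames.
#' @export
simulate_counts <- function(tree, optima, metadata, design) {
  stopifnot(inherits(design, "sim_design"))
  if (!all(names(optima) %in% tree$tip.label)) {
    stop("all taxa in optima must be tips of the tree")
  }
  if (design$selection_strength < 0) stop("invalid design: negative selection_strength")
  taxa <- tree$tip.label
  optima <- optima[taxa]
  n_samp <- nrow(metadata)
  # map the [0,1] latent axis onto the span of the optima so that selection
  # is exercised across the whole trait range
  qs <- stats::quantile(optima, c(0.1, 0.9), names = FALSE)
  env <- qs[1] + metadata$env_axis * (qs[2] - qs[1])

  set.seed(design$seed + 2L)
  regional <- stats::rlnorm(length(taxa), 0, design$regional_sigma)
  counts <- matrix(0L, n_samp, length(taxa),
                   dimnames = list(metadata$sample_id, taxa))
  for (s in seq_len(n_samp)) {
    w <- exp(-design$selection_strength * (optima - env[s])^2)
    w <- switch(design$dispersal_regime,
      neutral      = w,
      homogenizing = w * regional,
      limited      = w * regional *
        stats::rlnorm(length(taxa), 0, design$dispersal_sigma)
    )
    if (!any(w > 0)) w[] <- 1  # numerically extinct weights: fall back to uniform
    counts[s, ] <- stats::rmultinom(1, design$depth, prob = w)[, 1]
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a full synthetic community data set
#'
#' Convenience wrapper running tree, optima, metadata and counts in sequence
#' from one design; everything is deterministic given \code{design$seed}.
#'
#' @param design A \code{sim_design}.
#' @return A list of class \code{sim_community} with elements \code{tree},
#'   \code{optima}, \code{metadata}, \code{counts}, \code{design}.
#' @export
simulate_community <- function(design = sim_design()) {
  stopifnot(inherits(design, "sim_design"))
  tree <- simulate_tree(design$n_taxa_pool, seed = design$seed)
  optima <- simulate_optima(tree, design$trait_signal, seed = design$seed + 3L)
  metadata <- simulate_metadata(design)
  counts <- simulate_counts(tree, optima, metadata, design)
  structure(list(tree = tree, optima = optima, metadata = metadata,
                 counts = counts, design = design),
            class = "sim_community")
}

#' @export
print.sim_community <- function(x, ...) {
  cat("Synthetic community:", nrow(x$counts), "samples x",
      ncol(x$counts), "taxa\n")
  cat("  groups:", paste(unique(x$metadata$group), collapse = ", "),
      "| regime:", x$design$dispersal_regime,
      "| selection:", x$design$selection_strength,
      "| trait signal:", x$design$trait_signal, "\n")
  invisible(x)
}
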