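# Correlation-threshold co-occurrence networks: construction, topology,
# random-graph nulls, robustness, vulnerability, and Zi-Pi node roles.

#' Occupancy filter for network construction
#'
#' Retains taxa whose occupancy strictly exceeds the threshold fraction of
#' the group's samples.
#'
#' @param counts Samples x taxa matrix restricted to one group (>= 5 rows).
#' @param occupancy Strict occupancy threshold (default 0.8).
#' @return The filtered count matrix.
#' @export
filter_for_network <- function(counts, occupancy = 0.8) {
  if (nrow(counts) < 5) stop("design error: need >= 5 samples in the group")
  keep <- colMeans(counts > 0) > occupancy
  if (sum(keep) < 3) stop("too sparse: fewer than 3 taxa pass the occupancy filter")
  counts[, keep, drop = FALSE]
}

#' Build a correlation-threshold ecological network
#'
#' Pairwise Pearson (or Spearman) correlation of log10(relative abundance +
#' pseudocount) across the group's samples; taxa pairs with |r| at or above
#' the threshold become edges, with the correlation sign recorded. Modules
#' are found by greedy modularity maximization on the unweighted, unsigned
#' graph. Constant taxa (undefined correlation) are dropped with a warning.
#'
#' @param counts Filtered samples x taxa matrix.
#' @param st Correlation threshold in (0, 1) (default 0.75).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param pseudocount Added to relative abundances before log10.
#' @param seed Seed for module-detection tie-breaking.
#' @return Object of class \code{eco_network}: \code{graph} (igraph, with
#'   edge attributes \code{r}, \code{sign} and vertex attributes
#'   \code{abundance}, \code{module}), plus the construction parameters.
#' @export
correlation_network <- function(counts, st = 0.75, method = "pearson",
                                pseudocount = 1e-6, seed = 1L) {
  if (st <= 0 || st >= 1) stop("st must be in (0, 1)")
  rel <- relative_abundance(counts)
  x <- log10(rel + pseudocount)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant taxa (undefined correlation)")
    x <- x[, sds > 0, drop = FALSE]
    rel <- rel[, sds > 0, drop = FALSE]
  }
  r <- stats::cor(x, method = method)
  adj <- (abs(r) >= st)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  rvals <- r[cbind(ends[, 1], ends[, 2])]
  igraph::E(g)$r <- rvals
  igraph::E(g)$sign <- ifelse(rvals >= 0, 1L, -1L)
  igraph::V(g)$abundance <- colMeans(rel)
  set.seed(seed)
  mods <- igraph::membership(igraph::cluster_fast_greedy(g))
  igraph::V(g)$module <- as.integer(mods)
  structure(list(graph = g, st = st, method = method,
                 pseudocount = pseudocount, seed = seed),
            class = "eco_network")
}

#' @export
print.eco_network <- function(x, ...) {
  g <- x$graph
  cat("Ecological network:", igraph::vcount(g), "nodes,",
      igraph::ecount(g), "edges (|r| >=", x$st, ",", x$method, ")\n")
  cat("  modules:", length(unique(igraph::V(g)$module)),
      "| positive edges:",
      if (igraph::ecount(g)) paste0(round(100 * mean(igraph::E(g)$sign > 0), 1), "%")
      else "-", "\n")
  invisible(x)
}

as_igraph <- function(net) {
  if (inherits(net, "eco_network")) net$graph else net
}

#' Topological statistics of an ecological network
#'
#' Average connectivity 2E/N, average geodesic distance over connected pairs
#' only, mean local clustering coefficient (nodes of degree < 2 contribute
#' 0), Newman modularity of the stored module partition, number of modules,
#' percentage of positive edges, and the R-squared of the least-squares
#' log(frequency) ~ log(degree) line over degrees with nonzero frequency
#' (the scale-free check).
#'
#' @param net An \code{eco_network} or plain igraph graph.
#' @return List of class \code{network_stats}.
#' @export
network_topology <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  if (n == 0) stop("empty network")
  mods <- if (!is.null(igraph::V(g)$module)) igraph::V(g)$module
          else as.integer(igraph::membership(igraph::cluster_fast_greedy(g)))
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  loc[igraph::degree(g) < 2] <- 0
  deg <- igraph::degree(g)
  tab <- table(deg[deg > 0])
  r2 <- NA_real_
  if (length(tab) >= 3) {
    fit <- stats::lm(log(as.vector(tab)) ~ log(as.numeric(names(tab))))
    r2 <- summary(fit)$r.squared
  }
  signs <- igraph::E(g)$sign
  structure(list(
    n_nodes = n, n_links = e, avg_connectivity = 2 * e / n,
    avg_geodesic = igraph::mean_distance(g, unconnected = TRUE),
    avg_clustering = mean(loc),
    modularity = if (e > 0) igraph::modularity(g, mods) else 0,
    n_modules = length(unique(mods)),
    pct_positive_links = if (!is.null(signs) && e > 0)
      100 * mean(signs > 0) else NA_real_,
    r2_powerlaw = r2
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("Nodes %d | links %d | avg connectivity %.3f\n",
              x$n_nodes, x$n_links, x$avg_connectivity))
  cat(sprintf("  geodesic %.3f | clustering %.3f | modularity %.3f (%d modules)\n",
              x$avg_geodesic, x$avg_clustering, x$modularity, x$n_modules))
  if (!is.na(x$pct_positive_links)) {
    cat(sprintf("  positive links %.1f%% | power-law R2 %s\n",
                x$pct_positive_links,
                ifelse(is.na(x$r2_powerlaw), "NA", sprintf("%.3f", x$r2_powerlaw))))
  }
  invisible(x)
}

#' Degree-preserving random-network null
#'
#' Rewires the empirical graph by degree-preserving edge swaps (10 x E swap
#' attempts per randomization), recomputes average geodesic distance, mean
#' clustering and modularity (with freshly detected modules) per
#' randomization, and returns their means and standard deviations. A graph
#' whose degree sequence admits no rewiring (e.g. a complete graph) returns
#' the empirical values with zero SD and a warning.
#'
#' @param net An \code{eco_network} or igraph graph.
#' @param n_rand Number of randomizations (>= 10).
#' @param seed Integer seed.
#' @return List with \code{geodesic}, \code{clustering}, \code{modularity},
#'   each a named vector \code{c(mean, sd)}.
#' @export
random_null <- function(net, n_rand = 100, seed = 1L) {
  if (n_rand < 10) stop("n_rand must be >= 10")
  g <- as_igraph(net)
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  if (e < 2 || e == n * (n - 1) / 2) {
    warning(if (e < 2) "fewer than 2 edges: rewiring cannot move any edge"
            else "complete graph: rewiring cannot move any edge")
    st <- network_topology(g)
    return(list(geodesic = c(mean = st$avg_geodesic, sd = 0),
                clustering = c(mean = st$avg_clustering, sd = 0),
                modularity = c(mean = st$modularity, sd = 0)))
  }
  set.seed(seed)
  res <- matrix(NA_real_, n_rand, 3)
  for (k in seq_len(n_rand)) {
    rg <- igraph::rewire(g, igraph::keeping_degseq(niter = max(10 * e, 100)))
    mods <- igraph::membership(igraph::cluster_fast_greedy(rg))
    loc <- igraph::transitivity(rg, type = "local", isolates = "zero")
    loc[igraph::degree(rg) < 2] <- 0
    res[k, ] <- c(igraph::mean_distance(rg, unconnected = TRUE),
                  mean(loc),
                  igraph::modularity(rg, mods))
  }
  list(geodesic = c(mean = mean(res[, 1]), sd = stats::sd(res[, 1])),
       clustering = c(mean = mean(res[, 2]), sd = stats::sd(res[, 2])),
       modularity = c(mean = mean(res[, 3]), sd = stats::sd(res[, 3])))
}

#' Network robustness to random node removal
#'
#' Per repetition, \code{floor(f * N)} nodes are removed uniformly at
#' random; with \code{cascade = TRUE} (default) nodes left without any edge
#' are then removed as secondary extinctions. Robustness is the mean
#' fraction of the original nodes remaining.
#'
#' @param net An \code{eco_network} or igraph graph.
#' @param removal_fraction Fraction of nodes removed, in (0, 1).
#' @param n_rep Number of repetitions.
#' @param seed Integer seed.
#' @param cascade Remove secondarily isolated nodes (default TRUE).
#' @param force_remove Optional vertex names/indices always included in the
#'   removed set (used to probe worst cases such as hub loss).
#' @return Mean proportion of nodes remaining, in [0, 1 - f].
#' @export
net_robustness <- function(net, removal_fraction = 0.5, n_rep = 100,
                           seed = 1L, cascade = TRUE, force_remove = NULL) {
  if (removal_fraction <= 0 || removal_fraction >= 1) {
    stop("removal_fraction must be in (0, 1)")
  }
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  k <- floor(removal_fraction * n)
  forced <- if (is.null(force_remove)) integer(0)
            else as.integer(igraph::V(g)[force_remove])
  if (length(forced) > k) stop("force_remove larger than the removal budget")
  set.seed(seed)
  remaining <- numeric(n_rep)
  for (rep in seq_len(n_rep)) {
    pool <- setdiff(seq_len(n), forced)
    drop <- c(forced, sample(pool, k - length(forced)))
    h <- igraph::delete_vertices(g, drop)
    if (cascade) {
      h <- igraph::delete_vertices(h, which(igraph::degree(h) == 0))
    }
    remaining[rep] <- igraph::vcount(h) / n
  }
  mean(remaining)
}

global_efficiency <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  d <- igraph::distances(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Network vulnerability
#'
#' Global efficiency is the mean over ordered node pairs of the inverse
#' shortest-path length (0 for disconnected pairs). Vulnerability is the
#' maximum relative drop in efficiency caused by deleting a single node:
#' \eqn{\max_i (E - E_{-i}) / E}.
#'
#' @param net An \code{eco_network} or igraph graph with >= 3 nodes.
#' @return Scalar vulnerability (a pure ratio).
#' @export
net_vulnerability <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n < 3) stop("vulnerability undefined for networks with < 3 nodes")
  e0 <- global_efficiency(g)
  if (e0 == 0) stop("vulnerability undefined for an edgeless network")
  drops <- vapply(seq_len(n), function(i) {
    (e0 - global_efficiency(igraph::delete_vertices(g, i))) / e0
  }, numeric(1))
  max(drops)
}

#' Zi-Pi node roles
#'
#' Within-module degree z-score \eqn{Z_i = (k_{i,within} - \bar{k}_{m}) /
#' sd(k_{m})} (0 when the module's spread is 0) and participation
#' coefficient \eqn{P_i = 1 - \sum_m (k_{i,m} / k_i)^2} (0 for isolated
#' nodes). Roles: network hubs (Zi > 2.5 and Pi > 0.62), module hubs
#' (Zi > 2.5, Pi <= 0.62), connectors (Zi <= 2.5, Pi > 0.62), the rest
#' peripheral.
#'
#' @param net An \code{eco_network} (modules must be present) or igraph
#'   graph with a \code{module} vertex attribute.
#' @return data.frame: \code{taxon}, \code{zi}, \code{pi}, \code{role}.
#' @export
zi_pi <- function(net) {
  g <- as_igraph(net)
  mods <- igraph::V(g)$module
  if (is.null(mods)) stop("modules have not been computed for this network")
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  mod_ids <- sort(unique(mods))
  # k[i, m]: edges from node i into module m
  kim <- vapply(mod_ids, function(m) rowSums(adj[, mods == m, drop = FALSE]),
                numeric(n))
  k_within <- kim[cbind(seq_len(n), match(mods, mod_ids))]
  zi <- numeric(n)
  for (m in mod_ids) {
    idx <- mods == m
    s <- stats::sd(k_within[idx])
    zi[idx] <- if (is.na(s) || s < 1e-12) 0
               else (k_within[idx] - mean(k_within[idx])) / s
  }
  pi <- ifelse(deg == 0, 0, 1 - rowSums((kim / pmax(deg, 1))^2))
  role <- ifelse(zi > 2.5 & pi > 0.62, "network_hub",
          ifelse(zi > 2.5, "module_hub",
          ifelse(pi > 0.62, "connector", "peripheral")))
  nm <- igraph::V(g)$name
  data.frame(taxon = if (is.null(nm)) as.character(seq_len(n)) else nm,
             zi = zi, pi = pi,
             role = factor(role, levels = c("network_hub", "module_hub",
                                            "connector", "peripheral")),
             row.names = NULL, stringsAsFactors = FALSE)
}
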