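# End-to-end orchestration: simulate or load, then run every analysis stage
# per group with one config, writing TSV/JSON outputs and a hashed manifest.

#' Build and validate a pipeline configuration
#'
#' Either \code{design} (a \code{\link{sim_design}}, for synthetic input) or
#' the three input paths must be supplied. Every threshold of the analysis
#' is validated here, before any computation.
#'
#' @param design Optional \code{sim_design} for synthetic input.
#' @param counts_path,metadata_path,tree_path Input files (used when
#'   \code{design} is NULL).
#' @param out_dir Output directory.
#' @param occupancy Occupancy threshold for the core screen and the network
#'   filter, in (0, 1).
#' @param core_abundance Core relative-abundance threshold, in (0, 1).
#' @param st Correlation threshold for network edges, in (0, 1).
#' @param bnti_thresh,rc_thresh Assembly classification thresholds (> 0;
#'   rc_thresh < 1).
#' @param zi_thresh,pi_thresh Zi-Pi role thresholds.
#' @param n_perm Permutations for dissimilarity and Mantel tests.
#' @param n_null Null randomizations for betaNTI and Raup-Crick.
#' @param n_rand Random-network randomizations.
#' @param n_rep_robustness Robustness repetitions.
#' @param seed Integer seed for every stochastic stage.
#' @return Validated list of class \code{run_config}.
#' @export
run_config <- function(design = NULL, counts_path = NULL,
                       metadata_path = NULL, tree_path = NULL,
                       out_dir = tempfile("micasa_run_"),
                       occupancy = 0.8, core_abundance = 0.001, st = 0.75,
                       bnti_thresh = 2, rc_thresh = 0.95,
                       zi_thresh = 2.5, pi_thresh = 0.62,
                       n_perm = 999, n_null = 199, n_rand = 50,
                       n_rep_robustness = 100, seed = 1L) {
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || x <= 0 || x >= 1) {
      stop("validation error: ", nm, " must be in (0, 1), got ", x)
    }
  }
  chk01(occupancy, "occupancy"); chk01(core_abundance, "core_abundance")
  chk01(st, "st"); chk01(rc_thresh, "rc_thresh")
  if (bnti_thresh <= 0) stop("validation error: bnti_thresh must be > 0")
  if (zi_thresh <= 0 || pi_thresh <= 0 || pi_thresh >= 1) {
    stop("validation error: zi/pi thresholds out of range")
  }
  if (n_perm < 99 || n_null < 99) stop("validation error: n_perm and n_null must be >= 99")
  if (is.null(design) &&
      (is.null(counts_path) || is.null(metadata_path) || is.null(tree_path))) {
    stop("validation error: supply a sim_design or all three input paths")
  }
  if (!is.null(design)) stopifnot(inherits(design, "sim_design"))
  structure(list(design = design, counts_path = counts_path,
                 metadata_path = metadata_path, tree_path = tree_path,
                 out_dir = out_dir, occupancy = occupancy,
                 core_abundance = core_abundance, st = st,
                 bnti_thresh = bnti_thresh, rc_thresh = rc_thresh,
                 zi_thresh = zi_thresh, pi_thresh = pi_thresh,
                 n_perm = n_perm, n_null = n_null, n_rand = n_rand,
                 n_rep_robustness = n_rep_robustness,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the inputs, then runs alpha diversity plus group
#' tests, Bray-Curtis beta structure (PCoA, PERMANOVA/ANOSIM/MRPP),
#' per-group core screens, per-group assembly partitioning, per-group
#' networks with topology, nulls, robustness, vulnerability and Zi-Pi, and
#' the environmental-driver stage (partial Mantel screen + VPA). All outputs
#' are written under \code{config$out_dir} together with the resolved config
#' and a manifest of output files with md5 content hashes; identical config
#' and seed give identical hashes.
#'
#' @param config A \code{\link{run_config}}.
#' @param quiet Suppress per-stage messages.
#' @return (Invisibly) the manifest: a named list of output paths and
#'   hashes, plus the in-memory stage results in \code{$results}.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[micasa] ", ...)
  t_all <- proc.time()[["elapsed"]]

  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$design)) {
      say("simulating community (seed ", config$seed, ")")
      sim <- simulate_community(config$design)
      counts <- sim$counts; metadata <- sim$metadata; tree <- sim$tree
    } else {
      say("loading inputs")
      counts <- read_count_table(config$counts_path)
      metadata <- read_metadata(config$metadata_path)
      tree <- read_tree(config$tree_path)
      metadata <- align_samples(counts, metadata, tree)
    }
    groups <- metadata$group
    env_cols <- intersect(c("TN", "NH4", "NO3", "AP", "AK", "TS", "pH",
                            "moisture", "OM", "density", "unit_weight"),
                          colnames(metadata))
    out <- list()

    stage <- "alpha"
    say("alpha diversity")
    alpha <- alpha_diversity(counts)
    tests <- lapply(c(richness = "richness", shannon = "shannon",
                      evenness = "evenness", chao1 = "chao1"),
                    function(v) {
                      gt <- group_anova(alpha[[v]], groups)
                      list(F = gt$F, p = gt$p)
                    })
    utils::write.table(alpha, file.path(config$out_dir, "alpha.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_out(tests, file.path(config$out_dir, "alpha_tests.json"))
    out$alpha <- alpha; out$alpha_tests <- tests

    stage <- "beta"
    say("beta structure")
    d <- bray_curtis(counts)
    ord <- pcoa_ord(d)
    beta <- list(
      permanova = permanova(d, groups, config$n_perm, config$seed),
      anosim = anosim_test(d, groups, config$n_perm, config$seed),
      mrpp = mrpp_test(d, groups, config$n_perm, config$seed),
      proportion_explained = ord$proportion_explained[1:2]
    )
    dm <- as.matrix(d)
    utils::write.table(
      data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
      file.path(config$out_dir, "bray_curtis.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = rownames(ord$points), ord$points,
                 check.names = FALSE),
      file.path(config$out_dir, "pcoa.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_out(beta, file.path(config$out_dir, "beta_tests.json"))
    out$beta <- beta; out$pcoa <- ord

    stage <- "core"
    say("core taxa")
    cores <- lapply(split(seq_len(nrow(counts)), groups), function(idx) {
      core_taxa(counts[idx, , drop = FALSE], config$occupancy,
                config$core_abundance, group = groups[idx[1]])
    })
    write_json_out(lapply(cores, function(cs) {
      list(group = cs$group, n_core = length(cs$taxa), taxa = cs$taxa)
    }), file.path(config$out_dir, "core.json"))
    out$cores <- cores

    stage <- "assembly"
    say("assembly partitioning (n_null = ", config$n_null, ")")
    asm <- suppressWarnings(assembly_partition(
      counts, tree, groups = groups, n_null = config$n_null,
      seed = config$seed, bnti_thresh = config$bnti_thresh,
      rc_thresh = config$rc_thresh))
    utils::write.table(asm$pairs, file.path(config$out_dir, "assembly_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_out(apply(asm$fractions, 1, as.list),
                   file.path(config$out_dir, "assembly_fractions.json"))
    out$assembly <- asm

    stage <- "network"
    say("networks per group")
    nets <- lapply(split(seq_len(nrow(counts)), groups), function(idx) {
      sub <- counts[idx, , drop = FALSE]
      filt <- filter_for_network(sub, config$occupancy)
      net <- suppressWarnings(correlation_network(filt, st = config$st,
                                                  seed = config$seed))
      stats <- network_topology(net)
      nulls <- random_null(net, n_rand = config$n_rand, seed = config$seed)
      list(net = net, stats = stats, nulls = nulls,
           robustness = net_robustness(net, 0.5, config$n_rep_robustness,
                                       seed = config$seed),
           vulnerability = if (igraph::ecount(net$graph) > 0 &&
                               igraph::vcount(net$graph) >= 3)
             net_vulnerability(net) else NA_real_,
           roles = zi_pi(net))
    })
    for (g in names(nets)) {
      utils::write.table(nets[[g]]$roles,
                         file.path(config$out_dir, paste0("roles_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_json_out(lapply(nets, function(x) {
      c(unclass(x$stats),
        list(robustness = x$robustness, vulnerability = x$vulnerability,
             random = x$nulls))
    }), file.path(config$out_dir, "network_stats.json"))
    out$networks <- nets

    stage <- "drivers"
    say("environmental drivers")
    env <- metadata[, env_cols, drop = FALSE]
    mant <- mantel_screen(d, env, n_perm = config$n_perm, seed = config$seed)
    phys <- intersect(c("pH", "TS", "moisture", "unit_weight", "density"),
                      env_cols)
    chem <- intersect(c("TN", "AK", "AP", "NH4", "NO3"), env_cols)
    vp <- vpa(d, env[, phys, drop = FALSE], env[, chem, drop = FALSE])
    utils::write.table(mant, file.path(config$out_dir, "mantel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_out(unclass(vp), file.path(config$out_dir, "vpa.json"))
    out$mantel <- mant; out$vpa <- vp
    out
  }, error = function(e) {
    stop("pipeline aborted in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  cfg <- config; cfg$design <- if (!is.null(config$design)) unclass(config$design)
  write_json_out(unclass(cfg), file.path(config$out_dir, "config.json"))
  files <- sort(setdiff(list.files(config$out_dir, full.names = TRUE),
                        file.path(config$out_dir, "manifest.json")))
  manifest <- list(files = lapply(stats::setNames(files, basename(files)),
                                  function(f) unname(tools::md5sum(f))),
                   seed = config$seed)
  write_json_out(manifest, file.path(config$out_dir, "manifest.json"))
  say("done in ", round(proc.time()[["elapsed"]] - t_all, 1), " s")
  manifest$results <- res
  invisible(manifest)
}
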