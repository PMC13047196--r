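# Alpha diversity per sample and group comparisons.

#' Alpha-diversity indices per sample
#'
#' Computes observed richness, bias-corrected Chao1
#' \eqn{S + F_1 (F_1 - 1) / (2 (F_2 + 1))} (with \eqn{F_1}, \eqn{F_2} the
#' singleton and doubleton counts), Shannon diversity \eqn{H = -\sum p \ln p}
#' (natural log), Pielou evenness \eqn{H / \ln S} (defined as 1 for a
#' single-taxon sample) and inverse Simpson \eqn{1 / \sum p^2}.
#'
#' @param counts Samples x taxa integer matrix, positive row sums.
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{richness}, \code{chao1}, \code{shannon}, \code{evenness},
#'   \code{inv_simpson}.
#' @export
alpha_diversity <- function(counts) {
  rs <- rowSums(counts)
  if (any(rs <= 0)) {
    stop("degenerate sample (zero total count): ",
         paste(rownames(counts)[rs <= 0], collapse = ", "))
  }
  richness <- rowSums(counts > 0)
  f1 <- rowSums(counts == 1)
  f2 <- rowSums(counts == 2)
  chao1 <- richness + f1 * (f1 - 1) / (2 * (f2 + 1))
  shannon <- vegan::diversity(counts, index = "shannon")  # natural log
  evenness <- ifelse(richness > 1, shannon / log(richness), 1)
  inv_simpson <- vegan::diversity(counts, index = "invsimpson")
  data.frame(
    sample_id = if (is.null(rownames(counts))) as.character(seq_len(nrow(counts)))
                else rownames(counts),
    richness = as.integer(richness), chao1 = chao1,
    shannon = as.numeric(shannon), evenness = as.numeric(evenness),
    inv_simpson = as.numeric(inv_simpson),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Classical one-way ANOVA followed by all pairwise Tukey honest significant
#' difference comparisons. When the within-group variance is numerically
#' zero but group means differ, the F statistic is unbounded; a p of 0 is
#' returned with a warning.
#'
#' @param values Numeric response, one per sample.
#' @param groups Grouping factor (>= 2 levels, each with >= 2 observations).
#' @return List with \code{F}, \code{p} and \code{tukey}, a data.frame of
#'   pairwise comparisons (\code{pair}, \code{diff}, \code{p_adj}).
#' @export
group_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("design error: need at least 2 groups")
  if (any(table(groups) < 2)) {
    stop("design error: every group needs at least 2 observations")
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  ssw <- tab["Residuals", "Sum Sq"]
  ssb <- tab["groups", "Sum Sq"]
  if (ssw < 1e-12 * max(ssb, 1)) {
    if (ssb > 0) {
      warning("degenerate within-group variance; p reported as 0")
      tk <- stats::TukeyHSD(fit)$groups
      return(list(F = Inf, p = 0,
                  tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                                     p_adj = tk[, "p adj"], row.names = NULL)))
    }
  }
  tk <- stats::TukeyHSD(fit)$groups
  list(F = tab["groups", "F value"], p = tab["groups", "Pr(>F)"],
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL))
}
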