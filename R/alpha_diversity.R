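#' Shannon entropy of a community
#'
#' H' = -sum(p_i log(p_i)) over taxa with positive proportion; zero-count
#' taxa contribute nothing.  Base-2 logs by default, so the unit is bits.
#'
#' @param counts nonnegative abundance vector.
#' @param log_base logarithm base (2 = bits).
#' @return Entropy value (>= 0).
#' @examples
#' shannon(c(1, 1, 1, 1))  # 2 bits
#' @export
shannon <- function(counts, log_base = 2) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative abundance")
  if (sum(counts) == 0) stop("all-zero abundance vector")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = log_base))
}

#' Pielou's evenness
#'
#' J = H' / log2(G_obs): Shannon entropy normalised by its maximum for the
#' observed number of taxa, so J lies in [0, 1].
#'
#' @param counts nonnegative abundance vector with at least two taxa
#'   observed (evenness is undefined for a single taxon).
#' @return Evenness in [0, 1].
#' @export
pielou <- function(counts) {
  g <- sum(counts > 0)
  if (g < 2) stop("Pielou's evenness requires at least 2 observed taxa")
  shannon(counts, log_base = 2) / log2(g)
}

#' Chao1 richness estimate
#'
#' Nonparametric extrapolation of total richness from the counts of
#' singleton (F1) and doubleton (F2) taxa: G_obs + F1^2 / (2 F2).  When no
#' doubletons are present the bias-corrected form G_obs + F1 (F1 - 1) / 2
#' is used.  The standard error follows the classical Chao (1987) variance
#' formulas.
#'
#' @param counts nonnegative integer abundance vector.
#' @return A list of class \code{chao1_estimate}: \code{G_obs}, \code{F1},
#'   \code{F2}, \code{estimate}, \code{se}.
#' @export
chao1 <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be nonnegative integers")
  g <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) {
    est <- g + f1^2 / (2 * f2)
    r <- f1 / f2
    v <- f2 * (r^2 / 2 + r^3 + r^4 / 4)
  } else {
    est <- g + f1 * (f1 - 1) / 2
    if (f1 > 0) {
      v <- f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * est)
    } else v <- 0
  }
  structure(list(G_obs = g, F1 = f1, F2 = f2,
                 estimate = est, se = sqrt(max(v, 0))),
            class = "chao1_estimate")
}

#' @export
print.chao1_estimate <- function(x, ...) {
  cat(sprintf("Chao1: %.1f +/- %.1f (observed %d, F1=%d, F2=%d)\n",
              x$estimate, x$se, x$G_obs, x$F1, x$F2))
  invisible(x)
}

#' Sampling coverage as a percentage of estimated richness
#'
#' round(100 * G_obs / Chao1), the conventional "percent complete" summary
#' of an inventory.
#'
#' @param G_obs observed taxon count.
#' @param chao1_estimate Chao1 richness (a number or a
#'   \code{chao1_estimate}).
#' @return Integer percent.
#' @examples
#' coverage_percent(92, 135)  # 68
#' @export
coverage_percent <- function(G_obs, chao1_estimate) {
  if (inherits(chao1_estimate, "chao1_estimate"))
    chao1_estimate <- chao1_estimate$estimate
  if (chao1_estimate <= 0) stop("Chao1 estimate must be positive")
  as.integer(round(100 * G_obs / chao1_estimate))
}

#' Rarefaction curve by Monte-Carlo subsampling
#'
#' Mean number of taxa observed in without-replacement subsamples at each
#' requested depth.
#'
#' @param counts nonnegative integer abundance vector.
#' @param depths increasing vector of subsample depths (max <= total reads).
#' @param iterations subsamples per depth.
#' @param seed integer seed.
#' @return Data.frame with columns \code{depth} and \code{mean_taxa}.
#' @export
rarefaction_curve <- function(counts, depths, iterations = 100, seed = NULL) {
  counts <- as.numeric(counts)
  n <- sum(counts)
  if (any(depths > n)) stop("depth exceeds total reads (", n, ")")
  if (any(depths < 1)) stop("depths must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  means <- vapply(depths, function(d) {
    mean(vapply(seq_len(iterations), function(i)
      sum(subsample_counts(counts, d) > 0), numeric(1)))
  }, numeric(1))
  data.frame(depth = depths, mean_taxa = means)
}

#' Per-site diversity summary
#'
#' Convenience wrapper computing observed richness, Shannon entropy,
#' Pielou's evenness, Chao1 (with SE) and coverage percent for every site
#' of a community table, optionally after dropping singletons (taxa seen
#' exactly once in a site) to gauge their influence.
#'
#' @param table a \code{community_table}.
#' @param drop_singletons logical; zero out within-site singleton taxa
#'   before computing the statistics.
#' @return Data.frame with one row per site.
#' @export
diversity_summary <- function(table, drop_singletons = FALSE) {
  stopifnot(inherits(table, "community_table"))
  rows <- lapply(rownames(table$counts), function(s) {
    v <- table$counts[s, ]
    if (drop_singletons) v[v == 1] <- 0L
    ch <- chao1(v)
    data.frame(site = s,
               reads = sum(v),
               G_obs = ch$G_obs,
               shannon = if (sum(v) > 0) shannon(v) else NA_real_,
               pielou = if (ch$G_obs >= 2) pielou(v) else NA_real_,
               chao1 = ch$estimate,
               chao1_se = ch$se,
               coverage_pct = if (ch$estimate > 0)
                 coverage_percent(ch$G_obs, ch$estimate) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
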