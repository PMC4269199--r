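# Synthetic-data generators.  Two community regimes are emulated:
#   "subsurface" - deeply sequenced sites sharing a large core of taxa with
#                  correlated abundances (pairwise Morisita dissimilarity low)
#   "spring"     - shallow, turnover-dominated sites, each dominated by its
#                  own private taxon plus many singletons (dissimilarity high)
# All generators are deterministic for a fixed seed.

#' Community generation scenario
#'
#' Bundles the parameters of \code{\link{generate_community}}.  The two
#' presets encode the study conditions of a thermal-spring/deep-subsurface
#' comparison: the subsurface preset has 7 sites sharing a 220-taxon core
#' out of 900 taxa at 14,000-23,400 reads per site; the spring preset has 6
#' shallow sites (120-800 reads), a single ubiquitous taxon, and per-site
#' dominant private taxa.
#'
#' @param preset \code{"subsurface"}, \code{"spring"} or \code{"custom"}.
#' @param ... overrides for individual fields: \code{n_sites},
#'   \code{n_taxa}, \code{core_size}, \code{reads_range},
#'   \code{core_mass} (probability mass carried by core taxa),
#'   \code{dominant_mass} (mass on each site's dominant private taxon),
#'   \code{sigma} (lognormal rank-abundance shape), \code{site_noise_sd}
#'   (lognormal sd of per-site jitter on core abundances),
#'   \code{ensure_core} (force every core taxon to be observed at every
#'   site).
#' @return A list of class \code{community_scenario}.
#' @export
community_scenario <- function(preset = c("subsurface", "spring", "custom"),
                               ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    subsurface = list(n_sites = 7, n_taxa = 900, core_size = 220,
                      reads_range = c(14000, 23400), core_mass = 0.85,
                      dominant_mass = 0, sigma = 0.8, site_noise_sd = 0.3,
                      ensure_core = TRUE, site_prefix = "sub"),
    spring = list(n_sites = 6, n_taxa = 300, core_size = 1,
                  reads_range = c(120, 800), core_mass = 0.02,
                  dominant_mass = 0.45, sigma = 1.2, site_noise_sd = 0.6,
                  ensure_core = FALSE, site_prefix = "spring"),
    custom = list(n_sites = 4, n_taxa = 100, core_size = 20,
                  reads_range = c(500, 1000), core_mass = 0.6,
                  dominant_mass = 0, sigma = 1, site_noise_sd = 0.3,
                  ensure_core = FALSE, site_prefix = "site"))
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
  base[names(over)] <- over
  if (base$core_size > base$n_taxa) stop("core_size exceeds n_taxa")
  if (base$core_mass + base$dominant_mass >= 1 && base$core_size < base$n_taxa)
    stop("core_mass + dominant_mass must leave mass for private taxa")
  structure(c(base, list(preset = preset)), class = "community_scenario")
}

#' Generate a synthetic community table
#'
#' Core taxa share a lognormal rank-abundance profile across all sites
#' (with per-site lognormal jitter); the remaining taxa are assigned to
#' sites as private taxa, optionally with one dominant private taxon per
#' site.  Read totals are drawn uniformly from \code{reads_range} and
#' counts by multinomial sampling, so configured totals are conserved
#' exactly.
#'
#' @param scenario a \code{\link{community_scenario}}.
#' @param seed integer seed (bit-reproducible output for a fixed seed).
#' @return A \code{community_table}.
#' @export
generate_community <- function(scenario = community_scenario(), seed = 1) {
  s <- scenario
  stopifnot(inherits(s, "community_scenario"))
  set.seed(seed)
  n_private <- s$n_taxa - s$core_size
  taxa <- c(if (s$core_size) paste0(s$site_prefix, "_core", seq_len(s$core_size)),
            if (n_private) paste0(s$site_prefix, "_priv", seq_len(n_private)))
  sites <- paste0(s$site_prefix, seq_len(s$n_sites))
  # disjoint private pools per site
  owner <- if (n_private) sample(rep_len(seq_len(s$n_sites), n_private))
           else integer(0)
  core_w <- if (s$core_size) stats::rlnorm(s$core_size, 0, s$sigma) else numeric(0)
  counts <- matrix(0L, s$n_sites, s$n_taxa, dimnames = list(sites, taxa))
  for (j in seq_len(s$n_sites)) {
    p <- numeric(s$n_taxa)
    if (s$core_size) {
      w <- core_w * stats::rlnorm(s$core_size, 0, s$site_noise_sd)
      p[seq_len(s$core_size)] <- s$core_mass * w / sum(w)
    }
    mine <- which(owner == j) + s$core_size
    if (length(mine)) {
      priv_mass <- 1 - s$core_mass
      if (s$dominant_mass > 0 && length(mine) > 1) {
        dom <- mine[1]
        p[dom] <- s$dominant_mass
        priv_mass <- priv_mass - s$dominant_mass
        mine <- mine[-1]
      }
      w <- stats::rlnorm(length(mine), 0, s$sigma)
      p[mine] <- priv_mass * w / sum(w)
    } else {
      p <- p / sum(p)
    }
    N <- sample(seq(s$reads_range[1], s$reads_range[2]), 1)
    x <- as.integer(stats::rmultinom(1, N, p))
    if (s$ensure_core && s$core_size) {
      # deep-sequencing guarantee: every core taxon observed at every site
      zero <- which(x[seq_len(s$core_size)] == 0L)
      for (z in zero) {
        top <- which.max(x)
        x[top] <- x[top] - 1L
        x[z] <- 1L
      }
    }
    counts[j, ] <- x
  }
  community_table(counts)
}

#' Generate environmental metadata with planted community drivers
#'
#' Planted variables are built from the principal-coordinate embedding of
#' the community dissimilarity matrix plus Gaussian noise, so that their
#' scaled Euclidean distances correlate with the community structure;
#' decoy variables are independent standard-normal noise.
#'
#' @param community_dissim symmetric community dissimilarity matrix.
#' @param variables names of all variables to emit.
#' @param planted subset of \code{variables} to tie to the community
#'   structure (one principal coordinate each).
#' @param noise_sd noise on planted variables, as a fraction of the
#'   coordinate's standard deviation (0 = perfect driver).
#' @param seed integer seed.
#' @return Data.frame with \code{site} plus one numeric column per
#'   variable; the planted subset is recorded in
#'   \code{attr(, "planted")}.
#' @export
generate_env <- function(community_dissim, variables,
                         planted = variables[seq_len(min(2, length(variables)))],
                         noise_sd = 0.2, seed = 1) {
  d <- as.matrix(community_dissim)
  if (!all(planted %in% variables)) stop("planted must be a subset of variables")
  n <- nrow(d)
  set.seed(seed)
  k <- length(planted)
  coords <- if (k > 0)
    suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k))
  else matrix(0, n, 0)
  out <- data.frame(site = rownames(d) %||% paste0("site", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (v in variables) {
    if (v %in% planted) {
      i <- match(v, planted)
      base <- coords[, min(i, ncol(coords))]
      out[[v]] <- base + stats::rnorm(n, 0, noise_sd * max(stats::sd(base), 1e-12))
    } else {
      out[[v]] <- stats::rnorm(n)
    }
  }
  attr(out, "planted") <- planted
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate aligned reads from planted haplotypes
#'
#' Reads are drawn from the haplotypes with the given mixture proportions;
#' independent per-base substitution errors (uniform over the three other
#' bases) are applied at non-gap positions.  Every read has abundance 1.
#'
#' @param haplotypes character vector of equal-length aligned sequences.
#' @param proportions mixture weights summing to 1.
#' @param n_reads number of reads to draw.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return A sequence record set with an \code{attr(, "haplotype")} integer
#'   vector recording each read's source.
#' @export
generate_reads <- function(haplotypes, proportions, n_reads,
                           error_rate = 0.01, seed = 1) {
  if (length(unique(nchar(haplotypes))) > 1)
    stop("haplotypes must have equal length")
  if (length(proportions) != length(haplotypes) ||
      abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0))
    stop("proportions must be a simplex over the haplotypes")
  set.seed(seed)
  src <- sample.int(length(haplotypes), n_reads, replace = TRUE,
                    prob = proportions)
  bases <- c("A", "C", "G", "T")
  reads <- vapply(src, function(h) {
    chars <- strsplit(haplotypes[h], "")[[1]]
    editable <- which(chars != "-")
    flip <- editable[stats::runif(length(editable)) < error_rate]
    for (pos in flip)
      chars[pos] <- sample(setdiff(bases, chars[pos]), 1)
    paste(chars, collapse = "")
  }, character(1))
  out <- sequence_set(sprintf("read%0*d", nchar(n_reads), seq_len(n_reads)),
                      reads)
  attr(out, "haplotype") <- src
  out
}

#' Combine two community tables over the union of their taxa
#'
#' Sites are stacked; taxa absent from one table get zero counts.
#'
#' @param x,y \code{community_table}s with disjoint site sets.
#' @return A \code{community_table}.
#' @export
combine_tables <- function(x, y) {
  stopifnot(inherits(x, "community_table"), inherits(y, "community_table"))
  if (length(intersect(rownames(x$counts), rownames(y$counts))))
    stop("site sets must be disjoint")
  taxa <- union(colnames(x$counts), colnames(y$counts))
  pad <- function(m) {
    out <- matrix(0L, nrow(m), length(taxa),
                  dimnames = list(rownames(m), taxa))
    out[, colnames(m)] <- m
    out
  }
  community_table(rbind(pad(x$counts), pad(y$counts)))
}
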