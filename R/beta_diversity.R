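#' Sorensen presence/absence similarity
#'
#' 2c / (a + b), where a and b are the numbers of taxa observed in each
#' sample and c the number observed in both.
#'
#' @param sample1,sample2 abundance vectors over a common taxon list.
#' @return List of class \code{presence_comparison}: \code{a}, \code{b},
#'   \code{c}, \code{sorensen}.
#' @examples
#' sorensen(c(1, 2, 0), c(0, 5, 3))  # a=2, b=2, c=1 -> 0.5
#' @export
sorensen <- function(sample1, sample2) {
  if (length(sample1) != length(sample2))
    stop("samples must share a common taxon list")
  p1 <- sample1 > 0
  p2 <- sample2 > 0
  a <- sum(p1); b <- sum(p2); c <- sum(p1 & p2)
  structure(list(a = a, b = b, c = c,
                 sorensen = sorensen_from_counts(a, b, c)),
            class = "presence_comparison")
}

#' Sorensen index from printed taxon counts
#'
#' Evaluates 2c / (a + b) directly from reported per-sample and shared
#' taxon counts, the form used when comparing published inventories.
#'
#' @param a,b taxon counts of the two samples.
#' @param c shared taxon count (c <= min(a, b)).
#' @return The index in [0, 1].
#' @examples
#' sorensen_from_counts(113, 119, 41)  # 0.3534...
#' @export
sorensen_from_counts <- function(a, b, c) {
  if (a + b == 0) stop("Sorensen undefined: both samples empty")
  if (c > min(a, b)) stop("shared count c exceeds min(a, b)")
  2 * c / (a + b)
}

#' Morisita abundance overlap and dissimilarity
#'
#' The classical Morisita index
#' C_lambda = 2 sum(n1i n2i) / ((lambda1 + lambda2) N1 N2) with
#' lambda_j = sum(n_ji (n_ji - 1)) / (N_j (N_j - 1)), computed on raw
#' integer counts.  It is chosen for between-site comparison because it is
#' robust to differences in sample size.  The dissimilarity is
#' 1 - C_lambda; because the classical form can slightly exceed 1 for small
#' samples, the dissimilarity is clamped at 0 (with a warning).
#'
#' @param sample1,sample2 nonnegative integer abundance vectors over a
#'   common taxon list; each must total at least 2 reads.
#' @return List of class \code{morisita_result}: \code{lambda1},
#'   \code{lambda2}, \code{cross_sum}, \code{C_lambda},
#'   \code{dissimilarity}.
#' @examples
#' morisita(c(9, 1), c(1, 9))$C_lambda  # 0.225
#' @export
morisita <- function(sample1, sample2) {
  if (length(sample1) != length(sample2))
    stop("samples must share a common taxon list")
  n1 <- as.numeric(sample1); n2 <- as.numeric(sample2)
  N1 <- sum(n1); N2 <- sum(n2)
  if (N1 < 2 || N2 < 2) stop("Morisita requires at least 2 reads per sample")
  l1 <- sum(n1 * (n1 - 1)) / (N1 * (N1 - 1))
  l2 <- sum(n2 * (n2 - 1)) / (N2 * (N2 - 1))
  if (l1 + l2 == 0)
    stop("Morisita undefined: both samples consist solely of singletons")
  cross <- sum(n1 * n2)
  cl <- 2 * cross / ((l1 + l2) * N1 * N2)
  dis <- 1 - cl
  if (dis < 0) {
    warning("Morisita overlap exceeds 1 (small-sample overshoot); ",
            "dissimilarity clamped to 0")
    dis <- 0
  }
  structure(list(lambda1 = l1, lambda2 = l2, cross_sum = cross,
                 C_lambda = cl, dissimilarity = dis),
            class = "morisita_result")
}

#' Pairwise community dissimilarity matrix
#'
#' Builds the symmetric site-by-site dissimilarity matrix used for
#' hierarchical clustering and matrix correlation: either the Morisita
#' dissimilarity (1 - C_lambda, clamped at 0) or the Sorensen complement
#' (1 - 2c/(a+b)).
#'
#' @param table a \code{community_table} with >= 2 sites (typically at
#'   genus rank).
#' @param metric \code{"morisita"} or \code{"sorensen"}.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = sites.
#' @export
dissimilarity_matrix <- function(table, metric = c("morisita", "sorensen")) {
  stopifnot(inherits(table, "community_table"))
  metric <- match.arg(metric)
  m <- table$counts
  if (nrow(m) < 2) stop("need at least 2 sites")
  sites <- rownames(m)
  out <- matrix(0, nrow(m), nrow(m), dimnames = list(sites, sites))
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    d <- switch(metric,
      morisita = suppressWarnings(morisita(m[i, ], m[j, ])$dissimilarity),
      sorensen = 1 - sorensen(m[i, ], m[j, ])$sorensen)
    out[i, j] <- out[j, i] <- d
  }
  out
}

#' Shared-taxon count matrix
#'
#' Off-diagonal cell [i, j] counts taxa present in both sites i and j; the
#' diagonal holds each site's observed taxon count.
#'
#' @param table a \code{community_table}.
#' @return Integer matrix, dimnames = sites.
#' @export
shared_taxa_matrix <- function(table) {
  stopifnot(inherits(table, "community_table"))
  pres <- table$counts > 0
  out <- pres %*% t(pres)
  storage.mode(out) <- "integer"
  out
}

#' Hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering (UPGMA average linkage by default) with a
#' deterministic lowest-index tie-break.  The return value is compatible
#' with \code{stats::hclust} consumers (\code{plot}, \code{cutree},
#' \code{ape::as.phylo}).
#'
#' @param dist symmetric dissimilarity matrix (or \code{dist}) with >= 2
#'   items.
#' @param linkage \code{"average"}, \code{"single"} or \code{"complete"}.
#' @return An \code{hclust}-class object.
#' @export
hierarchical_cluster <- function(dist,
                                 linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(dist)
  if (nrow(d) < 2) stop("need at least 2 items to cluster")
  if (any(d < 0)) stop("dissimilarities must be nonnegative")
  if (max(abs(d - t(d))) > 1e-12) stop("dissimilarity matrix must be symmetric")
  agglomerate(d, linkage = linkage)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths derive from the merge heights (ultrametric tree).
#'
#' @param hc an \code{hclust} object.
#' @param path optional file to write to.
#' @return The Newick string, invisibly if written to file.
#' @export
as_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
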