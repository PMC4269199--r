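#' Pairwise Pearson correlations across columns
#'
#' Pearson r and two-sided p-value (t distribution, n - 2 df) for every
#' unordered pair of columns of a sample-by-feature matrix, the screen used
#' to relate phylum relative abundances to environmental variables.
#' Missing values are handled pairwise-complete: each pair uses the samples
#' where both features are observed.  Zero-variance features are excluded
#' with a warning.
#'
#' @param mat numeric matrix or data.frame, samples in rows, features in
#'   columns (>= 3 complete samples per retained pair).
#' @return Data.frame of class \code{correlation_table} with columns
#'   \code{feature1}, \code{feature2}, \code{n}, \code{r}, \code{p}.
#' @export
pairwise_pearson <- function(mat) {
  m <- as.matrix(mat)
  if (!is.numeric(m)) stop("matrix must be numeric")
  if (nrow(m) < 3) stop("need at least 3 samples")
  keep <- apply(m, 2, function(col) stats::sd(col, na.rm = TRUE) > 0)
  keep[is.na(keep)] <- FALSE
  if (any(!keep))
    warning("excluding zero-variance feature(s): ",
            paste(colnames(m)[!keep], collapse = ", "))
  m <- m[, keep, drop = FALSE]
  nm <- colnames(m)
  if (length(nm) < 2) stop("fewer than 2 usable features")
  rows <- list()
  for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
    ok <- stats::complete.cases(m[, i], m[, j])
    n <- sum(ok)
    if (n < 3) {
      rows[[length(rows) + 1]] <- data.frame(
        feature1 = nm[i], feature2 = nm[j], n = n,
        r = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
      next
    }
    ct <- stats::cor.test(m[ok, i], m[ok, j], method = "pearson")
    rows[[length(rows) + 1]] <- data.frame(
      feature1 = nm[i], feature2 = nm[j], n = n,
      r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Multiple-testing adjusted q-values
#'
#' Benjamini-Hochberg step-up adjustment by default; \code{"storey"}
#' additionally rescales by a pi0 estimate (proportion of true nulls,
#' estimated as mean(p > lambda) / (1 - lambda) at a fixed lambda, capped
#' at 1).  Either way the adjustment preserves the ranking of the
#' p-values.
#'
#' @param pvals numeric p-values in [0, 1] (NAs passed through).
#' @param method \code{"bh"} or \code{"storey"}.
#' @param lambda tuning parameter for the Storey pi0 estimate.
#' @return Numeric q-values, same length/order as \code{pvals}.
#' @export
adjust_qvalues <- function(pvals, method = c("bh", "storey"), lambda = 0.5) {
  method <- match.arg(method)
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvals))
  q[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(pvals[ok] > lambda) / (1 - lambda))
    q[ok] <- pmin(1, q[ok] * pi0)
  }
  q
}

#' Filter a correlation table to significant pairs
#'
#' Applies the joint rule p < p_cut and q < q_cut (both defaulting to
#' 0.05), adding a q column if absent.
#'
#' @param table a \code{correlation_table} (output of
#'   \code{\link{pairwise_pearson}}); a \code{q} column is computed with
#'   \code{\link{adjust_qvalues}} if not already present.
#' @param p_cut,q_cut significance cutoffs.
#' @param method adjustment method when q must be computed.
#' @return The filtered table (possibly zero rows), with \code{q} and
#'   \code{significant} columns.
#' @export
significant_pairs <- function(table, p_cut = 0.05, q_cut = 0.05,
                              method = c("bh", "storey")) {
  stopifnot(is.data.frame(table))
  if (!"q" %in% names(table))
    table$q <- adjust_qvalues(table$p, method = method)
  table$significant <- !is.na(table$p) & !is.na(table$q) &
    table$p < p_cut & table$q < q_cut
  out <- table[table$significant, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate taxon relative abundances with environmental variables
#'
#' End-to-end screen: join a site-by-taxon relative-abundance matrix
#' (typically from \code{\link{mean_relative_abundance}} at phylum rank)
#' with environmental columns, compute all pairwise Pearson correlations,
#' adjust, and flag significance.
#'
#' @param relabund numeric site-by-taxon proportion matrix.
#' @param env site metadata data.frame aligned with \code{relabund} rows.
#' @param variables environmental column names to include.
#' @param method q-value method.
#' @param p_cut,q_cut significance cutoffs.
#' @return Full correlation table restricted to taxon-by-environment pairs,
#'   with \code{q} and \code{significant} columns.
#' @export
taxon_env_correlation <- function(relabund, env, variables,
                                  method = c("bh", "storey"),
                                  p_cut = 0.05, q_cut = 0.05) {
  ev <- as.matrix(env[, variables, drop = FALSE])
  if (nrow(ev) != nrow(relabund))
    stop("relabund and env must describe the same sites")
  joint <- cbind(relabund, ev)
  tbl <- suppressWarnings(pairwise_pearson(joint))
  taxa <- colnames(relabund)
  cross <- (tbl$feature1 %in% taxa) != (tbl$feature2 %in% taxa)
  tbl <- tbl[cross, , drop = FALSE]
  tbl$q <- adjust_qvalues(tbl$p, method = method)
  tbl$significant <- !is.na(tbl$p) & !is.na(tbl$q) &
    tbl$p < p_cut & tbl$q < q_cut
  rownames(tbl) <- NULL
  tbl
}
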