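# small builders shared across test files

make_table <- function(counts, sites = NULL, taxa = NULL, taxonomy = NULL) {
  m <- as.matrix(counts)
  rownames(m) <- sites %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- taxa %||% paste0("t", seq_len(ncol(m)))
  community_table(m, taxonomy = taxonomy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_seqs <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# independent eachgap distance oracle written as a direct column-by-column
# trace of the definition (kept naive on purpose)
oracle_eachgap <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  first <- function(x) min(which(x != "-")); last <- function(x) max(which(x != "-"))
  lo <- max(first(a), first(b)); hi <- min(last(a), last(b))
  num <- 0; den <- 0
  for (k in lo:hi) {
    if (a[k] == "-" && b[k] == "-") next
    den <- den + 1
    if (a[k] != b[k]) num <- num + 1
  }
  num / den
}

# brute-force average-linkage agglomeration oracle: recompute the mean
# inter-cluster distance from the raw matrix at every step
oracle_average_linkage <- function(d, threshold) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  repeat {
    if (length(clusters) == 1) break
    best <- NULL; best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h - 1e-12) { best_h <- h; best <- c(i, j) }
    }
    if (best_h > threshold + 1e-12) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  membership <- integer(nrow(d))
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  membership
}

# partition equality up to label renaming
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
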