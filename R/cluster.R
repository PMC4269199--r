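# Agglomerative clustering engine shared by the community dendrogram and the
# OTU clustering routines.  Deterministic: when several pairs attain the
# minimum criterion, the pair with the lowest (row, column) index merges
# first.  Returns a stats::hclust-compatible object so cutree(), plot() and
# ape::as.phylo() work on it.

agglomerate <- function(d, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("clustering requires at least 2 items")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("item", 1:n)
  labels <- rownames(d)
  cd <- d
  diag(cd) <- Inf
  size <- rep(1, n)
  id <- -(1:n)          # hclust convention: negative = singleton leaf
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  members <- as.list(1:n)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- cd[idx, idx, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)
    # lowest-index tie-break: smallest row, then smallest column, i < j
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- idx[best[1]]; j <- idx[best[2]]
    h <- cd[i, j]
    pair <- sort(c(id[i], id[j]))
    merge[step, ] <- pair
    height[step] <- h
    # Lance-Williams update into slot i
    for (k in idx) {
      if (k == i || k == j) next
      cd[i, k] <- cd[k, i] <- switch(linkage,
        average  = (cd[i, k] * size[i] + cd[j, k] * size[j]) /
                   (size[i] + size[j]),
        single   = min(cd[i, k], cd[j, k]),
        complete = max(cd[i, k], cd[j, k]))
    }
    size[i] <- size[i] + size[j]
    members[[i]] <- c(members[[i]], members[[j]])
    id[i] <- step
    active[j] <- FALSE
    cd[j, ] <- cd[, j] <- Inf
  }
  ord <- leaf_order(merge, n)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = linkage,
                 call = match.call(), dist.method = "user"),
            class = "hclust")
}

# Leaf ordering for plotting: depth-first traversal of the merge tree.
leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

# Cut an hclust-style tree so that items joined at height <= h share a
# cluster; returns an integer membership vector named by labels.
cut_at <- function(hc, h) {
  k <- sum(hc$height > h + 1e-12) + 1
  stats::cutree(hc, k = k)
}
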