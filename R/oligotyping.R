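#' Per-position Shannon entropy profile of an alignment
#'
#' Entropy (bits) of the abundance-weighted symbol distribution at every
#' alignment column.  Positions where sequencing noise dominates show
#' entropy near or below ~0.2 bits; genuine strain-level variation stands
#' out as high-entropy columns.  Gaps count as a fifth symbol by default
#' (indel variation is real signal in alignments); set
#' \code{include_gaps = FALSE} to score only residue variation.
#'
#' @param records aligned sequence record set with abundances.
#' @param include_gaps treat '-' as a symbol (default) or drop gap
#'   characters from each column's distribution.
#' @return Data.frame with columns \code{position} (1-based) and
#'   \code{entropy} (bits).
#' @export
entropy_profile <- function(records, include_gaps = TRUE) {
  if (nrow(records) == 0) stop("empty alignment")
  if (length(unique(nchar(records$seq))) > 1)
    stop("sequences must be aligned to equal length")
  chars <- do.call(rbind, strsplit(toupper(records$seq), ""))
  w <- records$abundance
  ent <- apply(chars, 2, function(col) {
    keep <- if (include_gaps) rep(TRUE, length(col)) else col != "-"
    if (!any(keep)) return(0)
    tab <- tapply(w[keep], col[keep], sum)
    shannon(tab)
  })
  data.frame(position = seq_along(ent), entropy = as.numeric(ent))
}

#' Select component positions from an entropy profile
#'
#' Either every position whose entropy exceeds a noise cutoff
#' (\code{mode = "threshold"}, default cutoff 0.2 bits), or the \code{c}
#' highest-entropy positions (\code{mode = "top_c"}, ties resolved toward
#' the lower index).
#'
#' @param profile output of \code{\link{entropy_profile}}.
#' @param mode \code{"threshold"} or \code{"top_c"}.
#' @param entropy_cutoff noise floor for threshold mode, bits.
#' @param c number of components for top_c mode.
#' @return Sorted integer vector of 1-based positions.
#' @export
select_components <- function(profile, mode = c("threshold", "top_c"),
                              entropy_cutoff = 0.2, c = NULL) {
  mode <- match.arg(mode)
  if (mode == "threshold")
    return(profile$position[profile$entropy > entropy_cutoff])
  if (is.null(c)) stop("top_c mode requires c")
  if (c > nrow(profile)) stop("c exceeds alignment length")
  ord <- order(-profile$entropy, profile$position)
  sort(profile$position[ord[seq_len(c)]])
}

#' Decompose an alignment into oligotypes
#'
#' Each read is keyed by its residues at the selected component positions;
#' keys are aggregated by abundance, and keys below the minimum
#' substantive abundance M are set aside as probable noise.  Retained
#' oligotypes are sorted by descending abundance.
#'
#' @param records aligned sequence record set.
#' @param components 1-based component positions (nonempty, within the
#'   alignment).
#' @param M minimum substantive abundance: oligotypes with total abundance
#'   < M are filtered out.
#' @return List of class \code{oligotype_set}: \code{components},
#'   \code{oligotypes} and \code{filtered} (data.frames with
#'   \code{oligotype}, \code{abundance}), \code{M}, \code{total_abundance}.
#'   Retained + filtered abundance always equals the input total.
#' @export
decompose <- function(records, components, M = 20) {
  if (length(components) == 0) stop("no component positions given")
  len <- unique(nchar(records$seq))
  if (length(len) > 1) stop("sequences must be aligned to equal length")
  if (any(components < 1 | components > len))
    stop("component positions outside the alignment")
  chars <- do.call(rbind, strsplit(toupper(records$seq), ""))
  key <- apply(chars[, components, drop = FALSE], 1, paste, collapse = "")
  ab <- tapply(records$abundance, key, sum)
  df <- data.frame(oligotype = names(ab), abundance = as.integer(ab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$abundance, df$oligotype), ]
  rownames(df) <- NULL
  keep <- df$abundance >= M
  structure(list(components = sort(components),
                 oligotypes = df[keep, , drop = FALSE],
                 filtered = df[!keep, , drop = FALSE],
                 M = M,
                 total_abundance = sum(records$abundance)),
            class = "oligotype_set")
}

#' @export
print.oligotype_set <- function(x, ...) {
  cat("oligotype_set: ", nrow(x$oligotypes), " oligotypes (M = ", x$M,
      ") over positions ", paste(x$components, collapse = ", "), "\n",
      sep = "")
  if (nrow(x$oligotypes))
    print(utils::head(x$oligotypes, 10), row.names = FALSE)
  invisible(x)
}

#' One-pass oligotyping pipeline
#'
#' Convenience wrapper: entropy profile, component selection, and
#' decomposition in one supervised pass.
#'
#' @param records aligned sequence record set.
#' @param c number of components (top_c selection); if NULL, threshold
#'   selection at \code{entropy_cutoff} is used.
#' @param M minimum substantive abundance.
#' @param entropy_cutoff noise floor for threshold selection.
#' @return An \code{oligotype_set} (with the profile attached as
#'   \code{profile}).
#' @export
oligotype <- function(records, c = NULL, M = 20, entropy_cutoff = 0.2) {
  prof <- entropy_profile(records)
  comp <- if (is.null(c))
    select_components(prof, mode = "threshold", entropy_cutoff = entropy_cutoff)
  else select_components(prof, mode = "top_c", c = c)
  out <- decompose(records, comp, M = M)
  out$profile <- prof
  out
}
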