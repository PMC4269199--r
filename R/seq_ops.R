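# Sequence record sets are plain data.frames with columns
#   id        character, unique
#   seq       character, DNA over {A,C,G,T,N,-}
#   abundance positive integer (reads collapsed into the record)
# built by sequence_set() and the FASTA reader.

#' Construct a sequence record set
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of sequences (upper-cased on input).
#' @param abundance positive integer abundances (default 1 each).
#' @return Data.frame with columns \code{id}, \code{seq}, \code{abundance}.
#' @export
sequence_set <- function(id, seq, abundance = rep(1L, length(seq))) {
  if (length(id) != length(seq) || length(seq) != length(abundance))
    stop("id, seq and abundance must have equal length")
  if (anyDuplicated(id)) stop("duplicate sequence ids")
  seq <- toupper(as.character(seq))
  if (any(nchar(seq) == 0)) stop("empty sequence")
  if (any(grepl("[^ACGTN-]", seq))) stop("sequence contains invalid characters")
  if (any(abundance < 1)) stop("abundances must be >= 1")
  data.frame(id = as.character(id), seq = seq,
             abundance = as.integer(abundance), stringsAsFactors = FALSE)
}

#' Read sequences with abundances from FASTA
#'
#' Abundance is parsed from a \code{;size=N} suffix in the header (1 when
#' absent), the convention used by dereplication tools.
#'
#' @param path FASTA file.
#' @return A sequence record set (see \code{\link{sequence_set}}).
#' @export
read_fasta_abund <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  size <- rep(1L, length(ss))
  has <- grepl(";size=\\d+", headers)
  size[has] <- as.integer(sub(".*;size=(\\d+).*", "\\1", headers[has]))
  ids <- sub(";size=\\d+.*", "", headers)
  ids <- sub("\\s.*$", "", ids)
  sequence_set(ids, as.character(ss), size)
}

#' Write sequences with abundances to FASTA
#'
#' @param records a sequence record set.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_fasta_abund <- function(records, path) {
  ss <- Biostrings::BStringSet(records$seq)
  names(ss) <- paste0(records$id, ";size=", records$abundance)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Dereplicate sequences
#'
#' \code{"full"} mode merges exact duplicates; \code{"prefix"} mode (the
#' derep_prefix convention) additionally merges any sequence that is an
#' exact prefix of a longer retained sequence.  Abundances are summed into
#' the retained record (the longest, then most abundant, then
#' lexicographically-smallest-id candidate) and the output is sorted by
#' descending abundance (ties by id).
#'
#' @param records a sequence record set (unaligned).
#' @param mode \code{"prefix"} or \code{"full"}.
#' @return A dereplicated sequence record set; total abundance conserved.
#' @export
dereplicate <- function(records, mode = c("prefix", "full")) {
  mode <- match.arg(mode)
  # collapse exact duplicates first
  agg <- stats::aggregate(abundance ~ seq, data = records, FUN = sum)
  rep_id <- vapply(agg$seq, function(s) {
    cand <- records[records$seq == s, ]
    cand <- cand[order(-cand$abundance, cand$id), ]
    cand$id[1]
  }, character(1))
  df <- data.frame(id = rep_id, seq = agg$seq, abundance = agg$abundance,
                   stringsAsFactors = FALSE)
  if (mode == "prefix" && nrow(df) > 1) {
    df <- df[order(-nchar(df$seq), -df$abundance, df$id), ]
    retained <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      hosts <- which(retained & nchar(df$seq) > nchar(df$seq[i]) &
                       startsWith(df$seq, df$seq[i]))
      if (length(hosts)) {
        # longest, most abundant, smallest-id host absorbs the prefix
        h <- hosts[order(-nchar(df$seq[hosts]), -df$abundance[hosts],
                         df$id[hosts])][1]
        df$abundance[h] <- df$abundance[h] + df$abundance[i]
      } else retained[i] <- TRUE
    }
    df <- df[retained, ]
  }
  df <- df[order(-df$abundance, df$id), ]
  rownames(df) <- NULL
  df
}

# first/last non-gap position of an aligned character vector
nongap_range <- function(chars) {
  ng <- which(chars != "-")
  if (!length(ng)) c(NA_integer_, NA_integer_) else range(ng)
}

#' Pairwise distance between aligned sequences (eachgap, terminal gaps
#' ignored)
#'
#' The comparable span excludes terminal gap runs (leading/trailing gaps
#' of either sequence).  Within the span, any column where the residues
#' differ counts as one difference — a gap aligned to a base counts, a
#' gap-gap column is excluded from both numerator and denominator.
#' Distance = differences / compared columns.
#'
#' @param s1,s2 aligned sequences of equal length.
#' @return Distance fraction in [0, 1].
#' @examples
#' pairwise_distance("ACG-T", "ACGAT")  # 0.2
#' @export
pairwise_distance <- function(s1, s2) {
  if (nchar(s1) != nchar(s2)) stop("aligned sequences must have equal length")
  c1 <- strsplit(toupper(s1), "")[[1]]
  c2 <- strsplit(toupper(s2), "")[[1]]
  r1 <- nongap_range(c1); r2 <- nongap_range(c2)
  if (any(is.na(c(r1, r2)))) stop("all-gap sequence")
  span <- max(r1[1], r2[1]):min(r1[2], r2[2])
  if (span[1] > span[length(span)]) stop("no comparable columns")
  a <- c1[span]; b <- c2[span]
  comparable <- !(a == "-" & b == "-")
  n_comp <- sum(comparable)
  if (n_comp == 0) stop("no comparable columns")
  sum(a[comparable] != b[comparable]) / n_comp
}

#' All-pairs eachgap distance matrix
#'
#' @param records sequence record set of aligned sequences.
#' @return Symmetric numeric matrix, dimnames = record ids.
#' @export
distance_matrix <- function(records) {
  n <- nrow(records)
  chars <- do.call(rbind, strsplit(toupper(records$seq), ""))
  rngs <- t(apply(chars, 1, nongap_range))
  out <- matrix(0, n, n, dimnames = list(records$id, records$id))
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    span <- max(rngs[i, 1], rngs[j, 1]):min(rngs[i, 2], rngs[j, 2])
    a <- chars[i, span]; b <- chars[j, span]
    comparable <- !(a == "-" & b == "-")
    out[i, j] <- out[j, i] <- sum(a[comparable] != b[comparable]) /
      sum(comparable)
  }
  out
}

# mismatching columns between two equal-length aligned strings
count_diffs <- function(s1, s2) {
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  sum(c1 != c2)
}

#' Abundance-greedy preclustering of aligned sequences
#'
#' Denoising pass before OTU clustering ("pseudo-single-linkage"): records
#' are processed in descending abundance (ties by id); each record merges
#' into the first already-retained record within \code{max_diffs}
#' mismatching columns, adding its abundance, and is otherwise retained.
#' Greedy, so unlike true single linkage a chain A-B-C does not collapse
#' into one record unless C is itself close to A.
#'
#' @param records aligned, abundance-annotated sequence record set.
#' @param max_diffs maximum mismatching columns for a merge.
#' @return Precluster-reduced sequence record set (abundance conserved).
#' @export
precluster <- function(records, max_diffs = 2) {
  df <- records[order(-records$abundance, records$id), ]
  retained <- integer(0)
  for (i in seq_len(nrow(df))) {
    merged <- FALSE
    for (r in retained) {
      if (count_diffs(df$seq[i], df$seq[r]) <= max_diffs) {
        df$abundance[r] <- df$abundance[r] + df$abundance[i]
        merged <- TRUE
        break
      }
    }
    if (!merged) retained <- c(retained, i)
  }
  out <- df[retained, ]
  rownames(out) <- NULL
  out
}

#' Average-linkage OTU clustering of aligned sequences
#'
#' Agglomerative average-linkage clustering on the eachgap distance matrix,
#' cut at \code{threshold} (0.03 ~ 97\% identity by convention).  Each OTU
#' is represented by its most abundant member (ties by id).
#'
#' @param records aligned sequence record set.
#' @param threshold distance cut.
#' @param linkage linkage method.
#' @return List of class \code{otu_set}: \code{clusters} (list of member-id
#'   vectors), \code{representatives} (character vector of ids, one per
#'   cluster), \code{threshold}, \code{membership} (named integer vector).
#' @export
cluster_otus <- function(records, threshold = 0.03,
                         linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (nrow(records) == 0) stop("no sequences to cluster")
  if (length(unique(nchar(records$seq))) > 1)
    stop("sequences must be aligned to equal length")
  if (nrow(records) == 1) {
    membership <- setNames(1L, records$id)
  } else {
    d <- distance_matrix(records)
    hc <- agglomerate(d, linkage = linkage)
    membership <- cut_at(hc, threshold)
  }
  clusters <- split(names(membership), membership)
  reps <- vapply(clusters, function(ids) {
    sub <- records[match(ids, records$id), ]
    sub$id[order(-sub$abundance, sub$id)][1]
  }, character(1))
  structure(list(clusters = unname(clusters),
                 representatives = unname(reps),
                 threshold = threshold,
                 membership = membership),
            class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat("otu_set: ", length(x$clusters), " OTUs at threshold ", x$threshold,
      " (", sum(sizes == 1), " singleton clusters)\n", sep = "")
  invisible(x)
}

#' Representative sequences of an OTU set
#'
#' One record per OTU: the most abundant member, carrying the OTU's total
#' abundance.
#'
#' @param otus an \code{otu_set}.
#' @param records the sequence record set the OTUs were built from.
#' @return Sequence record set of representatives.
#' @export
otu_representatives <- function(otus, records) {
  stopifnot(inherits(otus, "otu_set"))
  rows <- lapply(seq_along(otus$clusters), function(i) {
    ids <- otus$clusters[[i]]
    sub <- records[match(ids, records$id), ]
    rep <- sub[order(-sub$abundance, sub$id), ][1, ]
    rep$abundance <- sum(sub$abundance)
    rep
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-site shared OTUs from per-site representatives
#'
#' Implements the representative-based shared-OTU procedure for datasets
#' too large to cluster jointly: (1) each site's OTUs are reduced to their
#' most abundant representative, (2) representatives are pooled across
#' sites, (3) identical sequences are dereplicated, (4) the pooled set —
#' whose alignment must already be consistent across sites — is (5)
#' clustered at a tight final threshold (default 0.0049); clusters
#' containing representatives from more than one site are shared OTUs.
#'
#' @param rep_sets named list (one element per site) of representative
#'   sequence record sets, all aligned to the same length.
#' @param final_threshold distance cut for the pooled clustering.
#' @return List with \code{presence} (cluster-by-site logical matrix),
#'   \code{clusters} (pooled member ids per cluster), \code{shared}
#'   (indices of clusters spanning >= 2 sites).
#' @export
shared_otus <- function(rep_sets, final_threshold = 0.0049) {
  if (is.null(names(rep_sets)) || any(names(rep_sets) == ""))
    stop("rep_sets must be a named list (one element per site)")
  pooled <- do.call(rbind, lapply(names(rep_sets), function(s) {
    df <- rep_sets[[s]]
    df$site <- s
    df$id <- paste(s, df$id, sep = "|")
    df
  }))
  if (length(unique(nchar(pooled$seq))) > 1)
    stop("representatives must be aligned to a common length across sites")
  # dereplicate identical sequences, remembering contributing sites
  key <- pooled$seq
  uniq <- !duplicated(key)
  derep <- pooled[uniq, c("id", "seq"), drop = FALSE]
  derep$abundance <- as.integer(tapply(pooled$abundance, key, sum)[derep$seq])
  site_of <- split(pooled$site, key)
  otus <- cluster_otus(derep[, c("id", "seq", "abundance")],
                       threshold = final_threshold)
  sites <- names(rep_sets)
  presence <- t(vapply(otus$clusters, function(ids) {
    seqs <- derep$seq[match(ids, derep$id)]
    got <- unique(unlist(site_of[seqs]))
    sites %in% got
  }, logical(length(sites))))
  colnames(presence) <- sites
  rownames(presence) <- paste0("OTU", seq_len(nrow(presence)))
  list(presence = presence,
       clusters = otus$clusters,
       shared = which(rowSums(presence) >= 2))
}

#' Ungapped k-mismatch read mapping
#'
#' Reports every ungapped placement of each query on each reference with at
#' most \code{max_mismatches} Hamming mismatches, on both strands (the
#' reverse complement of the query is searched and flagged).  Offsets are
#' 1-based positions in the reference.
#'
#' @param queries,references sequence record sets (gap-free).
#' @param max_mismatches allowed mismatches (0 and 2 are the conventional
#'   strict/lenient settings).
#' @return Data.frame with columns \code{query}, \code{reference},
#'   \code{offset} (1-based start), \code{strand} ("+"/"-"),
#'   \code{mismatches}; zero rows when nothing maps.
#' @export
kmismatch_map <- function(queries, references, max_mismatches = 0) {
  hits <- list()
  for (qi in seq_len(nrow(queries))) {
    q <- queries$seq[qi]
    variants <- c("+" = q,
                  "-" = as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(q))))
    for (ri in seq_len(nrow(references))) {
      ref <- Biostrings::DNAString(references$seq[ri])
      if (nchar(q) > length(ref)) next
      for (strand in names(variants)) {
        pat <- Biostrings::DNAString(variants[[strand]])
        m <- Biostrings::matchPattern(pat, ref,
                                      max.mismatch = max_mismatches,
                                      with.indels = FALSE, fixed = TRUE)
        if (length(m) == 0) next
        starts <- Biostrings::start(m)
        mm <- Biostrings::neditStartingAt(pat, ref, starting.at = starts,
                                          fixed = TRUE)
        hits[[length(hits) + 1]] <- data.frame(
          query = queries$id[qi], reference = references$id[ri],
          offset = starts, strand = strand, mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(query = character(0), reference = character(0),
                      offset = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Screen a genus-level table for potential contaminant genera
#'
#' Summarises, per site, how many of the listed contaminant genera are
#' observed and what fraction of the site's reads they carry.
#'
#' @param table a \code{community_table} at genus rank (taxon names are
#'   genus names).
#' @param contaminant_genera character vector of genus names.
#' @return Data.frame with columns \code{site}, \code{n_contaminant_genera},
#'   \code{contaminant_abundance} (proportion of reads).
#' @export
contaminant_screen <- function(table, contaminant_genera) {
  stopifnot(inherits(table, "community_table"))
  hit <- colnames(table$counts) %in% contaminant_genera
  tot <- site_totals(table)
  data.frame(
    site = rownames(table$counts),
    n_contaminant_genera = as.integer(
      rowSums(table$counts[, hit, drop = FALSE] > 0)),
    contaminant_abundance = ifelse(tot > 0,
      rowSums(table$counts[, hit, drop = FALSE]) / tot, 0),
    stringsAsFactors = FALSE)
}
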