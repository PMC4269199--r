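#' Construct a site-by-taxon community table
#'
#' The central container of the package: a nonnegative integer count matrix
#' with sites as rows and taxa as columns, optionally annotated with a
#' taxonomy table giving rank labels (phylum ... genus) per taxon.
#'
#' @param counts numeric matrix (coercible) of nonnegative integer counts,
#'   sites in rows, taxa in columns; both dimensions must carry unique names.
#' @param taxonomy optional data.frame of rank labels, one row per taxon
#'   (rownames matching \code{colnames(counts)}), columns named after ranks
#'   such as \code{"phylum"}, \code{"class"}, \code{"genus"}.
#' @return An object of class \code{community_table}: a list with elements
#'   \code{counts} (integer matrix) and \code{taxonomy} (data.frame or NULL).
#'   Per-site read totals are available via \code{site_totals()}.
#' @examples
#' ct <- community_table(matrix(c(5L, 0L, 3L, 2L), 2,
#'   dimnames = list(c("s1", "s2"), c("gA", "gB"))))
#' site_totals(ct)
#' @export
community_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    rownames(counts) <- paste0("site", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate site identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (length(counts) > 0) {
    if (any(is.na(counts))) stop("counts must not contain missing values")
    if (any(counts < 0)) stop("negative count in community table")
    if (any(abs(counts - round(counts)) > 1e-8))
      stop("non-integer count in community table")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    missing_tax <- setdiff(colnames(counts), rownames(taxonomy))
    if (length(missing_tax))
      stop("taxa missing from taxonomy: ", paste(missing_tax, collapse = ", "))
    taxonomy <- taxonomy[colnames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat("community_table: ", nrow(x$counts), " sites x ", ncol(x$counts),
      " taxa (", sum(x$counts), " reads)\n", sep = "")
  if (!is.null(x$taxonomy))
    cat("taxonomy ranks: ", paste(colnames(x$taxonomy), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Per-site read totals
#'
#' @param table a \code{community_table}.
#' @return Named integer vector of row sums (total reads per site).
#' @export
site_totals <- function(table) {
  stopifnot(inherits(table, "community_table"))
  if (nrow(table$counts) == 0) return(setNames(integer(0), character(0)))
  rowSums(table$counts)
}

#' Read a community table from TSV
#'
#' Expects a tab-delimited file with a header of taxon identifiers and one
#' row per site (first column = site id); set \code{sites_in_rows = FALSE}
#' for the transposed layout.
#'
#' @param path path to a UTF-8, tab-delimited file.
#' @param sites_in_rows logical; orientation of the file.
#' @param taxonomy optional taxonomy data.frame passed to
#'   \code{\link{community_table}}.
#' @return A validated \code{community_table}.
#' @export
read_community_table <- function(path, sites_in_rows = TRUE, taxonomy = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1) stop("community table file has no columns: ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) > 0 && !is.numeric(m))
    stop("non-numeric cell in community table: ", path)
  rownames(m) <- ids
  if (!sites_in_rows) m <- t(m)
  community_table(m, taxonomy = taxonomy)
}

#' Write a community table to TSV
#'
#' Inverse of \code{\link{read_community_table}}; round-trips counts exactly.
#'
#' @param table a \code{community_table}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_community_table <- function(table, path) {
  stopifnot(inherits(table, "community_table"))
  df <- data.frame(site = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a degrees-minutes-seconds coordinate
#'
#' Accepts the typography found in field tables: degree sign, prime or ASCII
#' apostrophe for minutes, double prime or ASCII quote for seconds, optional
#' internal whitespace, decimal seconds, and an optional hemisphere letter
#' suffix.  Southern and western hemispheres yield negative decimal degrees.
#'
#' @param x character vector of DMS strings, e.g. \code{"23°39′31″"}.
#' @param hemisphere "N", "S", "E" or "W"; overridden by a trailing
#'   hemisphere letter inside the string itself.
#' @return Numeric vector of signed decimal degrees.
#' @examples
#' parse_dms("23°39′31″", hemisphere = "S")  # -23.65861
#' @export
parse_dms <- function(x, hemisphere = "N") {
  vapply(as.character(x), function(s) {
    raw <- s
    s <- trimws(s)
    hemi <- toupper(hemisphere)
    suffix <- regmatches(s, regexpr("[NSEWnsew]\\s*$", s))
    if (length(suffix) && nzchar(suffix)) {
      hemi <- toupper(trimws(suffix))
      s <- sub("[NSEWnsew]\\s*$", "", s)
    }
    pat <- paste0("^\\s*([0-9]+(?:\\.[0-9]+)?)\\s*°\\s*",
                  "(?:([0-9]+(?:\\.[0-9]+)?)\\s*[′'´`]\\s*)?",
                  "(?:([0-9]+(?:\\.[0-9]+)?)\\s*[″\"′']{1,2}\\s*)?$")
    m <- regmatches(s, regexec(pat, s))[[1]]
    if (length(m) == 0)
      stop("unparseable DMS coordinate: '", raw, "'")
    num <- function(v) if (is.na(v) || v == "") 0 else as.numeric(v)
    deg <- num(m[2]) + num(m[3]) / 60 + num(m[4]) / 3600
    if (hemi %in% c("S", "W")) deg <- -deg
    deg
  }, numeric(1), USE.NAMES = FALSE)
}

# Parse a numeric cell that may be a range "a-b" (any dash typography), a
# censored bound ("<x", ">x", "<d.l.") or missing ("n.a.", "").  Returns
# list(min, max, mid).  Bounds keep the printed bound as the value.
parse_numeric_cell <- function(s) {
  s <- trimws(as.character(s))
  if (is.na(s) || s == "" || s %in% c("n.a.", "na", "NA", "n.d.") ||
      grepl("d\\.l\\.", s))
    return(list(min = NA_real_, max = NA_real_, mid = NA_real_))
  s <- gsub("[<>]", "", s)
  s <- gsub("[–—]", "-", s)
  # a range has a dash that is not a leading sign or exponent sign
  parts <- strsplit(s, "(?<=[0-9.])-", perl = TRUE)[[1]]
  vals <- suppressWarnings(as.numeric(parts))
  if (any(is.na(vals)))
    return(list(min = NA_real_, max = NA_real_, mid = NA_real_))
  list(min = min(vals), max = max(vals), mid = mean(range(vals)))
}

#' Read site metadata (coordinates and geochemistry) from TSV
#'
#' Reads a tab-delimited table with one row per site.  Coordinate columns
#' (recognised by a name containing "lat"/"lon") are parsed from DMS text;
#' the hemisphere is taken from a parenthesised letter in the column name
#' (e.g. \code{"Latitude (S)"}) or a suffix in the cell.  Any other column
#' that parses as a number, range (\code{"63-67"}) or censored bound is
#' converted to its numeric midpoint, with \code{<column>_min} and
#' \code{<column>_max} columns added wherever at least one cell was a range.
#' Cells reading \code{"n.a."} or \code{"<d.l."} become \code{NA}; censored
#' bounds (\code{">1862"}, \code{"<1e-4"}) keep the printed bound as the
#' value.
#'
#' @param path path to a tab-delimited file.
#' @return A data.frame with a \code{site} column, signed decimal
#'   \code{latitude}/\code{longitude}, and numeric environmental columns.
#' @export
read_site_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!nrow(df)) stop("empty metadata table: ", path)
  out <- data.frame(site = as.character(df[[1]]), stringsAsFactors = FALSE)
  if (anyDuplicated(out$site)) stop("duplicate site identifiers in ", path)
  for (j in seq_along(df)[-1]) {
    nm <- names(df)[j]
    col <- df[[j]]
    if (grepl("lat", nm, ignore.case = TRUE)) {
      hemi <- if (grepl("\\(S\\)", nm)) "S" else "N"
      vals <- tryCatch(parse_dms(col, hemisphere = hemi),
                       error = function(e) stop("column '", nm, "': ",
                                                conditionMessage(e)))
      out$latitude <- vals
      if (any(abs(vals) > 90)) stop("latitude out of range in column ", nm)
    } else if (grepl("lon", nm, ignore.case = TRUE)) {
      hemi <- if (grepl("\\(W\\)", nm)) "W" else "E"
      vals <- tryCatch(parse_dms(col, hemisphere = hemi),
                       error = function(e) stop("column '", nm, "': ",
                                                conditionMessage(e)))
      out$longitude <- vals
      if (any(abs(vals) > 180)) stop("longitude out of range in column ", nm)
    } else {
      parsed <- lapply(col, parse_numeric_cell)
      mid <- vapply(parsed, `[[`, numeric(1), "mid")
      lo <- vapply(parsed, `[[`, numeric(1), "min")
      hi <- vapply(parsed, `[[`, numeric(1), "max")
      clean <- make.names(nm)
      out[[clean]] <- mid
      if (any(hi > lo, na.rm = TRUE)) {
        out[[paste0(clean, "_min")]] <- lo
        out[[paste0(clean, "_max")]] <- hi
      }
    }
  }
  out
}

#' Aggregate a community table to a coarser taxonomic rank
#'
#' Sums counts within each group at the requested rank.  With
#' \code{split_proteobacteria = TRUE} (mirroring the common display
#' convention for this dominant phylum), taxa whose phylum is Proteobacteria
#' are grouped by their class instead of the phylum label.
#'
#' @param table a \code{community_table} whose taxonomy carries the
#'   requested rank.
#' @param rank name of a taxonomy column, e.g. \code{"phylum"}.
#' @param split_proteobacteria logical; see above (requires a
#'   \code{"class"} rank when set).
#' @return A \code{community_table} whose taxa are the rank groups.
#' @export
aggregate_rank <- function(table, rank, split_proteobacteria = FALSE) {
  stopifnot(inherits(table, "community_table"))
  if (is.null(table$taxonomy) || !rank %in% colnames(table$taxonomy))
    stop("taxonomy rank '", rank, "' not available")
  labels <- as.character(table$taxonomy[[rank]])
  bad <- colnames(table$counts)[is.na(labels) | labels == ""]
  if (length(bad))
    stop("taxa with missing '", rank, "' label: ", paste(bad, collapse = ", "))
  if (split_proteobacteria) {
    if (!all(c("phylum", "class") %in% colnames(table$taxonomy)))
      stop("split_proteobacteria requires 'phylum' and 'class' ranks")
    is_proteo <- table$taxonomy$phylum == "Proteobacteria"
    labels[is_proteo] <- as.character(table$taxonomy$class[is_proteo])
  }
  groups <- unique(labels)
  agg <- vapply(groups, function(g)
    rowSums(table$counts[, labels == g, drop = FALSE]),
    numeric(nrow(table$counts)))
  if (nrow(table$counts) == 1) agg <- matrix(agg, nrow = 1,
                                             dimnames = list(rownames(table$counts), groups))
  community_table(agg)
}

# Subsample a single count vector to exactly `depth` reads without
# replacement (multivariate hypergeometric draw).
subsample_counts <- function(counts, depth) {
  n <- sum(counts)
  if (depth > n) stop("subsample depth exceeds available reads")
  if (depth == n) return(counts)
  drawn <- sample.int(n, depth)
  breaks <- c(0L, cumsum(counts))
  tabulate(findInterval(drawn, breaks, left.open = TRUE), nbins = length(counts))
}

#' Rarefy a community table to a fixed depth
#'
#' Subsamples every site, without replacement, to exactly \code{depth} reads.
#'
#' @param table a \code{community_table} with all row sums >= \code{depth}.
#' @param depth target reads per site.
#' @param seed integer seed for the random draw.
#' @return A \code{community_table} with every row sum equal to \code{depth}.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  stopifnot(inherits(table, "community_table"))
  tot <- site_totals(table)
  short <- names(tot)[tot < depth]
  if (length(short))
    stop("depth ", depth, " exceeds reads at site(s): ",
         paste(short, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  out <- t(apply(table$counts, 1, subsample_counts, depth = depth))
  dimnames(out) <- dimnames(table$counts)
  community_table(out, taxonomy = table$taxonomy)
}

#' Mean relative abundance under repeated subsampling
#'
#' Computes relative abundances robust to unequal sequencing depth: every
#' site is repeatedly subsampled without replacement to a common depth equal
#' to \code{floor(fraction * min(site_totals(table)))}, converted to
#' proportions, and the per-cell mean over iterations is returned.  The
#' defaults (85\% of the smallest sample, 1,000 iterations) are the
#' conventional choice for small amplicon surveys.
#'
#' @param table a \code{community_table} with all site totals > 0.
#' @param fraction proportion of the smallest site total used as common
#'   depth.
#' @param iterations number of subsampling iterations.
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @return Numeric site-by-taxon matrix of mean proportions; rows sum to 1.
#' @export
mean_relative_abundance <- function(table, fraction = 0.85, iterations = 1000,
                                    seed = NULL) {
  stopifnot(inherits(table, "community_table"))
  tot <- site_totals(table)
  if (any(tot == 0)) stop("all site totals must be positive")
  depth <- floor(fraction * min(tot))
  if (depth < 1) stop("subsample depth is 0; increase fraction or read counts")
  if (!is.null(seed)) set.seed(seed)
  acc <- matrix(0, nrow(table$counts), ncol(table$counts),
                dimnames = dimnames(table$counts))
  for (i in seq_len(iterations)) {
    sub <- t(apply(table$counts, 1, subsample_counts, depth = depth))
    acc <- acc + sub / depth
  }
  acc / iterations
}
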