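#' Great-circle distance matrix from coordinates
#'
#' Pairwise haversine distances, in kilometres, on a sphere of the given
#' radius (mean Earth radius by default).
#'
#' @param coords data.frame with \code{latitude} and \code{longitude}
#'   columns in signed decimal degrees; rownames or a \code{site} column
#'   name the sites.
#' @param radius_km sphere radius in km.
#' @return Symmetric numeric matrix of distances in km.
#' @export
great_circle_matrix <- function(coords, radius_km = 6371.0) {
  if (!all(c("latitude", "longitude") %in% names(coords)))
    stop("coords needs 'latitude' and 'longitude' columns")
  if (any(abs(coords$latitude) > 90) || any(abs(coords$longitude) > 180))
    stop("coordinates out of range")
  sites <- if ("site" %in% names(coords)) as.character(coords$site)
           else rownames(coords)
  ll <- cbind(coords$longitude, coords$latitude)
  n <- nrow(ll)
  out <- matrix(0, n, n, dimnames = list(sites, sites))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) {
      d <- geosphere::distHaversine(ll[i, ], ll[j, ], r = radius_km)
      out[i, j] <- out[j, i] <- d
    }
  }
  out
}

#' Centre and scale environmental variables
#'
#' Each selected column is centred to mean 0 and scaled to unit sample
#' standard deviation (n - 1 denominator), the standard preprocessing
#' before building environmental distance matrices.
#'
#' @param env data.frame of site metadata (one row per site; a \code{site}
#'   column, if present, names the rows).
#' @param variables character vector of column names to use.
#' @return Numeric site-by-variable matrix of z-scores.
#' @export
scale_variables <- function(env, variables) {
  missing_v <- setdiff(variables, names(env))
  if (length(missing_v))
    stop("variables not found: ", paste(missing_v, collapse = ", "))
  sites <- if ("site" %in% names(env)) as.character(env$site) else rownames(env)
  m <- as.matrix(env[, variables, drop = FALSE])
  if (!is.numeric(m)) stop("selected variables must be numeric")
  rownames(m) <- sites
  for (v in variables) {
    col <- m[, v]
    if (any(is.na(col)))
      stop("missing value in variable '", v, "' at site(s): ",
           paste(sites[is.na(col)], collapse = ", "))
    if (stats::sd(col) == 0) stop("zero-variance variable: '", v, "'")
  }
  scale(m)[, , drop = FALSE]
}

#' Euclidean distance matrix over scaled variables
#'
#' @param scaled numeric site-by-variable matrix (no missing values).
#' @return Symmetric numeric distance matrix.
#' @export
euclidean_env_distance <- function(scaled) {
  if (any(is.na(scaled))) stop("scaled matrix must not contain missing values")
  as.matrix(stats::dist(scaled))
}

#' Correlation between two distance matrices
#'
#' Pearson correlation between the vectorised matrices — by default the
#' strictly upper triangles, which avoids double-counting pairs and the
#' zero diagonal; \code{mode = "full"} correlates the whole matrices for
#' compatibility with spreadsheet-style whole-matrix correlation.
#'
#' @param m1,m2 symmetric matrices over the same sites in the same order.
#' @param mode \code{"upper"} or \code{"full"}.
#' @return List with \code{pcc} (Pearson r) and \code{r2}.
#' @export
matrix_correlation <- function(m1, m2, mode = c("upper", "full")) {
  mode <- match.arg(mode)
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2))) stop("matrices must have identical dimensions")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("matrices must cover the same sites in the same order")
  v1 <- if (mode == "upper") m1[upper.tri(m1)] else as.vector(m1)
  v2 <- if (mode == "upper") m2[upper.tri(m2)] else as.vector(m2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("matrix correlation undefined for constant entries")
  r <- stats::cor(v1, v2)
  list(pcc = r, r2 = r^2)
}

#' Exhaustive best-subset search of environmental variables
#'
#' For every nonempty subset of the named variables: scale the columns,
#' build the Euclidean distance matrix, and correlate it (Pearson, upper
#' triangle) with the community dissimilarity matrix.  Returns the full
#' ranking and the maximising subset.  Subsets are enumerated by size then
#' lexicographically; ties in correlation resolve toward the smaller
#' (earlier-enumerated) subset.
#'
#' @param env site metadata data.frame (rows aligned with
#'   \code{community_dissim}).
#' @param variables variable names to search over (k <= \code{max_vars}).
#' @param community_dissim symmetric community dissimilarity matrix.
#' @param mode vectorisation mode passed to
#'   \code{\link{matrix_correlation}}.
#' @param max_vars guard on the exhaustive 2^k - 1 enumeration.
#' @return List of class \code{bioenv_result}: \code{ranking} (data.frame
#'   of subset, size, pcc, r2, sorted by decreasing pcc), \code{best_subset},
#'   \code{best_pcc}, \code{best_r2}, \code{n_subsets}.
#' @export
bioenv <- function(env, variables, community_dissim,
                   mode = c("upper", "full"), max_vars = 20) {
  mode <- match.arg(mode)
  k <- length(variables)
  if (k < 1) stop("need at least one variable")
  if (k > max_vars)
    stop("k = ", k, " exceeds the exhaustive-search guard (", max_vars,
         "); raise max_vars explicitly to override")
  scaled <- scale_variables(env, variables)
  if (nrow(scaled) != nrow(as.matrix(community_dissim)))
    stop("env sites and dissimilarity matrix disagree in size")
  subsets <- unlist(lapply(seq_len(k), function(sz)
    utils::combn(variables, sz, simplify = FALSE)), recursive = FALSE)
  res <- lapply(subsets, function(vs) {
    d <- euclidean_env_distance(scaled[, vs, drop = FALSE])
    mc <- matrix_correlation(d, as.matrix(community_dissim), mode = mode)
    data.frame(subset = paste(vs, collapse = "+"), size = length(vs),
               pcc = mc$pcc, r2 = mc$r2, stringsAsFactors = FALSE)
  })
  ranking <- do.call(rbind, res)
  ord <- order(-ranking$pcc, seq_len(nrow(ranking)))  # stable: ties keep
  ranking <- ranking[ord, ]                           # enumeration order
  rownames(ranking) <- NULL
  best <- ranking[1, ]
  structure(list(ranking = ranking,
                 best_subset = strsplit(best$subset, "+", fixed = TRUE)[[1]],
                 best_pcc = best$pcc, best_r2 = best$r2,
                 n_subsets = nrow(ranking)),
            class = "bioenv_result")
}

#' @export
print.bioenv_result <- function(x, ...) {
  cat("bioenv: ", x$n_subsets, " subsets evaluated\n", sep = "")
  cat("best subset:", paste(x$best_subset, collapse = " + "), "\n")
  cat(sprintf("PCC = %.4f, R2 = %.4f\n", x$best_pcc, x$best_r2))
  invisible(x)
}

#' Geothermal circulation-depth estimate from water temperature
#'
#' Minimum depth of groundwater circulation implied by a spring's water
#' temperature: (water temperature - mean annual surface temperature) /
#' geothermal gradient.  The two gradients bound the plausible range, so
#' the hotter gradient gives the shallower (minimum) depth.  Defaults are
#' typical of stable continental crust: 20 degC surface temperature and a
#' 20-30 degC/km gradient.
#'
#' @param water_temp water temperature in degC; a length-2 vector is taken
#'   as a (min, max) range and its midpoint used.
#' @param surface_temp mean annual surface temperature, degC.
#' @param gradient_low,gradient_high geothermal gradient bounds, degC/km.
#' @return List of class \code{depth_estimate}: \code{water_temp} (scalar
#'   used), \code{depth_min_m}, \code{depth_max_m} (nearest metre).
#' @examples
#' estimate_depth(58)  # 1267-1900 m
#' @export
estimate_depth <- function(water_temp, surface_temp = 20,
                           gradient_low = 20, gradient_high = 30) {
  if (length(water_temp) == 2) water_temp <- mean(water_temp)
  if (gradient_low <= 0 || gradient_high <= 0) stop("gradients must be positive")
  if (water_temp < surface_temp)
    stop("water temperature below surface temperature: no depth implied")
  dt <- water_temp - surface_temp
  structure(list(water_temp = water_temp,
                 surface_temp = surface_temp,
                 gradient_low = gradient_low, gradient_high = gradient_high,
                 depth_min_m = round(dt / gradient_high * 1000),
                 depth_max_m = round(dt / gradient_low * 1000)),
            class = "depth_estimate")
}

#' @export
print.depth_estimate <- function(x, ...) {
  cat(sprintf("estimated circulation depth: %d-%d m (water %.1f degC)\n",
              x$depth_min_m, x$depth_max_m, x$water_temp))
  invisible(x)
}
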