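#' Gower dissimilarity on a tri-state trait matrix
#'
#' For binary traits with explicit unknowns the Gower coefficient reduces to
#' the mean absolute difference over the traits whose state is known in both
#' rows (pairwise deletion, no imputation). Shared absence counts as
#' agreement (symmetric treatment); set `asymmetric = TRUE` for a
#' Jaccard-like variant in which jointly absent traits are dropped from the
#' comparison.
#'
#' @param x a [trait_matrix()] or a plain 0/1/NA matrix.
#' @param asymmetric drop 0-0 matches from the comparable set (default
#'   `FALSE`).
#' @return A [dist_matrix()] with metric `"gower"`.
#' @export
gower_distance <- function(x, asymmetric = FALSE) {
  vals <- if (inherits(x, "trait_matrix")) x$values else as.matrix(x)
  if (nrow(vals) < 2L) stop("need at least 2 rows", call. = FALSE)
  known <- !is.na(vals)
  v0 <- vals; v0[!known] <- 0L
  storage.mode(v0) <- "double"
  storage.mode(known) <- "double"
  # |x_i - x_j| over known-known pairs, vectorized:
  # sum |xi - xj| = xi(1-xj) + xj(1-xi) restricted to jointly known traits
  both_known <- known %*% t(known)
  cross <- v0 %*% t(v0)                   # jointly present count
  pres_i <- (v0 * known) %*% t(known)     # present in i, known in j
  mism <- pres_i + t(pres_i) - 2 * cross  # present in exactly one
  denom <- both_known
  if (asymmetric) denom <- denom - (both_known - pres_i - t(pres_i) + cross)
  if (any(denom[upper.tri(denom)] <= 0)) {
    idx <- which(denom <= 0 & upper.tri(denom), arr.ind = TRUE)[1, ]
    stop(sprintf("no jointly known traits for pair (%s, %s)",
                 rownames(vals)[idx[1]], rownames(vals)[idx[2]]),
         call. = FALSE)
  }
  d <- mism / denom
  diag(d) <- 0
  dimnames(d) <- list(rownames(vals), rownames(vals))
  dist_matrix(d, metric = "gower")
}

#' Euclidean distance in shape space
#'
#' Pairwise Euclidean distances over all retained principal-component
#' scores. Since the full PC basis is an orthogonal rotation of the centered
#' coefficient space, these equal the distances between centered coefficient
#' rows.
#'
#' @param space a [pca_shapespace()] result, or a plain score matrix.
#' @return A [dist_matrix()] with metric `"euclidean_pc"`.
#' @export
shape_distance <- function(space) {
  scores <- if (inherits(space, "shape_space")) space$scores else as.matrix(space)
  d <- as.matrix(stats::dist(scores))
  dist_matrix(d, metric = "euclidean_pc")
}

#' Great-circle distances between sites or NAC regional centroids
#'
#' Haversine distances in kilometres (sphere radius 6371.0088 km). In
#' `"regional_centroid"` mode each NAC is first reduced to the arithmetic
#' mean of its site coordinates in decimal degrees ("mean site
#' coordinates"), and distances are computed between those centroids.
#'
#' @param points data frame with columns `lat`, `lon` (decimal degrees,
#'   WGS84) and an id column (`site_id` or first column) used for labels.
#' @param mode `"site"` or `"regional_centroid"`.
#' @param nac_index for centroid mode: character vector, one NAC id per row
#'   of `points`.
#' @return A [dist_matrix()] with metric `"haversine_km"`.
#' @export
geo_distance <- function(points, mode = c("site", "regional_centroid"),
                         nac_index = NULL) {
  mode <- match.arg(mode)
  points <- as.data.frame(points)
  if (!all(c("lat", "lon") %in% names(points))) {
    stop("points needs lat and lon columns", call. = FALSE)
  }
  if (any(abs(points$lat) > 90) || any(abs(points$lon) > 180)) {
    stop("coordinates outside valid decimal-degree ranges", call. = FALSE)
  }
  if (mode == "regional_centroid") {
    if (is.null(nac_index) || length(nac_index) != nrow(points)) {
      stop("centroid mode needs one nac_index entry per point", call. = FALSE)
    }
    lat <- tapply(points$lat, nac_index, mean)
    lon <- tapply(points$lon, nac_index, mean)
    labs <- names(lat)
    coords <- cbind(lon = as.numeric(lon), lat = as.numeric(lat))
  } else {
    labs <- if ("site_id" %in% names(points)) {
      as.character(points$site_id)
    } else {
      as.character(points[[1]])
    }
    coords <- cbind(lon = points$lon, lat = points$lat)
  }
  km <- geosphere::distm(coords, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = 6371.0088)
  })
  dimnames(km) <- list(labs, labs)
  dist_matrix(km, metric = "haversine_km")
}

#' Chronological distance between single-slice observations
#'
#' Maps time-slices I..IV to ranks 1..4 and returns the absolute rank
#' difference as a proxy for chronological distance. Observations spanning
#' several slices must be excluded beforehand (they are not expanded for
#' this test).
#'
#' @param slices named character vector of single time-slice tokens, one per
#'   observation; names are the observation labels.
#' @return A [dist_matrix()] with metric `"timeslice"`.
#' @export
timeslice_distance <- function(slices) {
  if (is.null(names(slices))) names(slices) <- as.character(seq_along(slices))
  multi <- grepl("|", slices, fixed = TRUE)
  if (any(multi)) {
    stop("multi-slice observation(s) present: ",
         paste(names(slices)[multi], collapse = ", "), call. = FALSE)
  }
  rk <- match(slices, time_slice_levels())
  if (any(is.na(rk))) {
    stop("unknown time-slice token(s): ",
         paste(slices[is.na(rk)], collapse = ", "), call. = FALSE)
  }
  d <- abs(outer(rk, rk, "-"))
  dimnames(d) <- list(names(slices), names(slices))
  dist_matrix(d, metric = "timeslice")
}
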