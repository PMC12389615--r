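#' NPP-weighted gravity center of a raster field
#'
#' X = sum(A_j X_j) / sum(A_j) and likewise Y, with A_j the pixel value
#' and (X_j, Y_j) the pixel-centre coordinates in projected metres.
#' Negative weights are rejected; the centroid of a nonnegative field lies
#' inside the convex hull of its positive-weight pixel centres.
#'
#' @param npp a [grid] of nonnegative weights (typically annual NPP).
#' @param epoch optional year label carried through to the result.
#' @return list `x`, `y` (metres), `epoch`, `total_weight`, `crs`.
#' @export
weighted_centroid <- function(npp, epoch = NA_integer_) {
  v <- npp$values
  if (any(v < 0, na.rm = TRUE)) stop("negative weights not allowed")
  w <- sum(v, na.rm = TRUE)
  if (!is.finite(w) || w <= 0)
    stop("need at least one unmasked pixel with positive weight")
  ctr <- pixel_centers(npp)
  ok <- !is.na(v)
  list(x = sum(v[ok] * ctr$x[ok]) / w,
       y = sum(v[ok] * ctr$y[ok]) / w,
       epoch = epoch, total_weight = w, crs = npp$crs)
}

#' Migration step between two gravity centers
#'
#' Planar Euclidean distance in metres and compass azimuth in degrees
#' clockwise from north (0 = due north, 90 = due east), from `c1` to `c2`.
#'
#' @param c1,c2 centroids from [weighted_centroid()] in the same CRS.
#' @return list `from_epoch`, `to_epoch`, `distance_m`, `azimuth_deg`.
#' @export
migration <- function(c1, c2) {
  if (!identical(c1$crs, c2$crs))
    stop("centroids are in different CRS: ", c1$crs, " vs ", c2$crs)
  dx <- c2$x - c1$x; dy <- c2$y - c1$y
  dist <- sqrt(dx^2 + dy^2)
  az <- if (dist == 0) 0 else (atan2(dx, dy) * 180 / pi) %% 360
  list(from_epoch = c1$epoch, to_epoch = c2$epoch,
       distance_m = dist, azimuth_deg = az)
}

#' Gravity-center trajectory over a cube of epochs
#' @param cube annual [raster_cube] (e.g. NPP at selected epochs).
#' @return list `centroids` (data.frame epoch/x/y/total_weight) and
#'   `steps` (data.frame from/to/distance_m/azimuth_deg).
#' @export
gravity_trajectory <- function(cube) {
  cents <- lapply(seq_along(cube$layers), function(i)
    weighted_centroid(cube$layers[[i]], cube$years[i]))
  cdf <- data.frame(epoch = vapply(cents, `[[`, 0, "epoch"),
                    x = vapply(cents, `[[`, 0, "x"),
                    y = vapply(cents, `[[`, 0, "y"),
                    total_weight = vapply(cents, `[[`, 0, "total_weight"))
  steps <- NULL
  if (length(cents) > 1L) {
    st <- lapply(seq_len(length(cents) - 1L), function(i)
      migration(cents[[i]], cents[[i + 1L]]))
    steps <- data.frame(
      from_epoch = vapply(st, `[[`, 0, "from_epoch"),
      to_epoch = vapply(st, `[[`, 0, "to_epoch"),
      distance_m = vapply(st, `[[`, 0, "distance_m"),
      azimuth_deg = vapply(st, `[[`, 0, "azimuth_deg"))
  }
  list(centroids = cdf, steps = steps)
}
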