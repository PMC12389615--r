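#' The six land-use classes
#' @export
LANDUSE_CLASSES <- c("farmland", "woodland", "grassland", "water_body",
                     "unused_land", "construction_land")

#' Land-use transition matrix between two epochs
#'
#' Cross-tabulates aligned categorical grids into a 6x6 matrix of areas
#' (km2): entry (i, j) is the area that was class i at the first epoch and
#' class j at the second. Pixels masked in either epoch are excluded from
#' both marginals, so row sums are the epoch-a class areas, column sums
#' the epoch-b class areas, and the grand total the common unmasked area.
#'
#' @param lu_a,lu_b aligned [grid]s coded 1-6.
#' @param epoch_pair optional c(year_a, year_b) label.
#' @return list `area_km2` (6x6 matrix, dimnames = class names),
#'   `classes`, `epoch_pair`.
#' @export
transition_matrix <- function(lu_a, lu_b, epoch_pair = c(NA, NA)) {
  stop_unless_aligned(lu_a, lu_b)
  a <- as.vector(lu_a$values); b <- as.vector(lu_b$values)
  ok <- !is.na(a) & !is.na(b)
  codes <- sort(unique(c(a[ok], b[ok])))
  bad <- setdiff(codes, seq_along(LANDUSE_CLASSES))
  if (length(bad))
    stop("unknown land-use class code(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(a[ok], levels = 1:6), factor(b[ok], levels = 1:6))
  m <- matrix(as.numeric(tab), 6, 6,
              dimnames = list(from = LANDUSE_CLASSES, to = LANDUSE_CLASSES))
  m <- m * pixel_area_km2(lu_a)
  list(area_km2 = m, classes = LANDUSE_CLASSES, epoch_pair = epoch_pair)
}

#' Mean NPP per land-use class
#'
#' @param npp NPP [grid].
#' @param lu aligned land-use [grid] coded 1-6.
#' @return named numeric vector (gC m-2 yr-1); `NA` for empty classes.
#' @export
class_mean_npp <- function(npp, lu) {
  stop_unless_aligned(npp, lu)
  v <- as.vector(npp$values); c <- as.vector(lu$values)
  ok <- !is.na(v) & !is.na(c)
  out <- rep(NA_real_, 6)
  agg <- tapply(v[ok], factor(c[ok], levels = 1:6), mean)
  out[seq_along(agg)] <- as.numeric(agg)
  stats::setNames(out, LANDUSE_CLASSES)
}

#' NPP change attributed to land-use transitions
#'
#' Each off-diagonal transition i -> j contributes
#' area_km2 x 1e6 m2/km2 x (mean_j - mean_i) gC m-2 x 1e-12 TgC.
#' Two attribution conventions are emitted: `dest` credits the
#' contribution to the destination class j (so converting unused land to
#' grassland credits grassland), `source` debits the source class i. Their
#' per-class vectors differ but both sum to the same global delta.
#'
#' @param tm transition matrix from [transition_matrix()].
#' @param means per-class mean NPP (gC m-2 yr-1) as from
#'   [class_mean_npp()].
#' @return list: `per_class` data.frame (class, gain_area_km2,
#'   loss_area_km2, mean_npp, net_delta_TgC_dest, net_delta_TgC_source),
#'   `total_delta_TgC`.
#' @export
npp_change_from_transitions <- function(tm, means) {
  m <- tm$area_km2
  off <- m; diag(off) <- 0
  active <- which(rowSums(off) + colSums(off) > 0)
  if (any(is.na(means[active])))
    stop("missing mean NPP for transitioning class(es): ",
         paste(names(means)[active][is.na(means[active])], collapse = ", "))
  contrib <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) if (i != j && m[i, j] > 0)
    contrib[i, j] <- m[i, j] * 1e6 * (means[j] - means[i]) * 1e-12
  dest <- colSums(contrib)   # credited to destination class
  src <- rowSums(contrib)    # debited from source class
  per_class <- data.frame(
    class = LANDUSE_CLASSES,
    gain_area_km2 = colSums(m) - diag(m),
    loss_area_km2 = rowSums(m) - diag(m),
    mean_npp = as.numeric(means),
    net_delta_TgC_dest = dest,
    net_delta_TgC_source = src)
  list(per_class = per_class, total_delta_TgC = sum(contrib))
}

#' Zonal statistics of NPP over integer band codes
#'
#' Generic band summary used for elevation and slope belts: per band, the
#' mean NPP and pixel count.
#'
#' @param npp NPP [grid].
#' @param zones aligned [grid] of integer band codes.
#' @param band_edges optional numeric vector echoed in the output (the
#'   edges that produced the codes).
#' @return data.frame with band, mean_npp, n_pixels (and attribute
#'   `band_edges`).
#' @export
zonal_mean <- function(npp, zones, band_edges = NULL) {
  stop_unless_aligned(npp, zones)
  v <- as.vector(npp$values); z <- as.vector(zones$values)
  ok <- !is.na(v) & !is.na(z)
  bands <- sort(unique(z[ok]))
  mean_npp <- vapply(bands, function(b) mean(v[ok & z == b]), 0)
  n <- vapply(bands, function(b) sum(ok & z == b), 0L)
  out <- data.frame(band = bands, mean_npp = mean_npp, n_pixels = n)
  attr(out, "band_edges") <- band_edges
  out
}

#' Cut a continuous grid into integer bands
#' @param g a [grid].
#' @param edges increasing numeric vector of band edges; values are
#'   assigned by left-closed, right-open intervals, last interval closed.
#' @return a [grid] of integer band codes 1..(length(edges)-1).
#' @export
band_grid <- function(g, edges) {
  codes <- cut_lco(as.vector(g$values), edges)
  grid_like(g, codes)
}

# left-closed/right-open cut with closed last bin; NA outside range
cut_lco <- function(x, edges) {
  k <- length(edges) - 1L
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[idx < 1L | idx > k] <- NA_integer_
  idx
}
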