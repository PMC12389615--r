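#' Georeferenced raster grid
#'
#' A `grid` is the basic spatial unit of the package: a numeric matrix of
#' pixel values (row 1 = northernmost row), a square pixel size in metres,
#' the coordinates of the lower-left corner of the extent, and a label for a
#' *projected, metric* CRS. Nodata pixels are `NA` in `values`. Geographic
#' (degree-based) coordinate systems are rejected because every downstream
#' statistic (pixel areas in km2, centroid migration distances in metres)
#' is planar.
#'
#' @param values numeric matrix; `NA` marks nodata.
#' @param xll,yll coordinates (m) of the lower-left corner of the extent.
#' @param cellsize pixel edge length in metres; must be > 0.
#' @param crs text label of the projected CRS (e.g. "World_Mercator").
#'   Labels containing "longlat", "4326" or "WGS84-geographic" are refused.
#' @return an object of class `grid`.
#' @export
grid <- function(values, xll = 0, yll = 0, cellsize = 500,
                 crs = "World_Mercator") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || !is.finite(cellsize) ||
      cellsize <= 0)
    stop("cellsize must be a single positive number (metres)")
  assert_metric_crs(crs)
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize), crs = crs),
    class = "grid"
  )
}

assert_metric_crs <- function(crs) {
  if (!is.character(crs) || length(crs) != 1L || !nzchar(crs))
    stop("crs must be a non-empty string")
  if (grepl("longlat|4326|geographic", crs, ignore.case = TRUE))
    stop("geographic (degree) CRS '", crs,
         "' rejected: a projected metric CRS is required")
  invisible(crs)
}

#' @export
print.grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid> %d x %d px, %g m cells, CRS %s\n",
              nrow(v), ncol(v), x$cellsize, x$crs))
  cat(sprintf("  extent x [%g, %g] y [%g, %g] m; %d nodata px\n",
              x$xll, x$xll + ncol(v) * x$cellsize,
              x$yll, x$yll + nrow(v) * x$cellsize, sum(is.na(v))))
  invisible(x)
}

#' @export
dim.grid <- function(x) dim(x$values)

#' Pixel area in km2
#' @param g a [grid].
#' @return scalar area of one pixel in km2.
#' @export
pixel_area_km2 <- function(g) g$cellsize^2 / 1e6

#' Pixel-centre coordinates
#'
#' Matrices of x (easting) and y (northing) coordinates of every pixel
#' centre, in the grid's projected metres. Row 1 is the northernmost row.
#' @param g a [grid].
#' @return list with matrices `x` and `y` shaped like `g$values`.
#' @export
pixel_centers <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  xs <- g$xll + (seq_len(nc) - 0.5) * g$cellsize
  ys <- g$yll + (nr - seq_len(nr) + 0.5) * g$cellsize  # row 1 = north
  list(x = matrix(xs, nr, nc, byrow = TRUE),
       y = matrix(ys, nr, nc))
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol && identical(a$crs, b$crs)
}

stop_unless_aligned <- function(a, b, what = "grids") {
  if (!same_geometry(a, b))
    stop(what, " must share shape, transform and CRS")
  invisible(TRUE)
}

#' Read an ESRI ASCII grid
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/`
#' `cellsize/NODATA_value` header followed by row-major values, north row
#' first). An optional sidecar `<path>.crs` holds the projected-CRS label;
#' without one the label defaults to "World_Mercator". Values equal to the
#' declared nodata value come back as `NA`.
#'
#' @param path path to a `.asc` file.
#' @return a [grid].
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- character(0); vals_start <- 0L
  meta <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("malformed ASCII grid (no data rows): ", path)
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      meta[[tolower(parts[1])]] <- as.numeric(parts[2])
    } else {
      first_row <- as.numeric(parts); break
    }
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(meta)))
    stop("ASCII grid header incomplete (missing transform) in ", path)
  nc <- as.integer(meta$ncols); nr <- as.integer(meta$nrows)
  rest <- scan(con, what = double(), quiet = TRUE)
  vals <- c(first_row, rest)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(meta$nodata_value)) m[m == meta$nodata_value] <- NA
  crs <- "World_Mercator"
  sidecar <- paste0(path, ".crs")
  if (file.exists(sidecar)) crs <- trimws(readLines(sidecar, n = 1L))
  grid(m, xll = meta$xllcorner, yll = meta$yllcorner,
       cellsize = meta$cellsize, crs = crs)
}

#' Write an ESRI ASCII grid
#'
#' Integer-valued layers round-trip exactly; continuous layers are written
#' with 15 significant digits (beyond 32-bit float precision). The CRS label
#' goes to a `<path>.crs` sidecar. Nodata pixels are written as -9999.
#'
#' @param g a [grid].
#' @param path output path (`.asc` by convention); parent dir must exist.
#' @param digits significant digits for continuous values.
#' @export
write_grid <- function(g, path, digits = 15) {
  stopifnot(inherits(g, "grid"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  v <- g$values
  nodata <- -9999
  if (any(v[!is.na(v)] == nodata)) nodata <- min(v, na.rm = TRUE) - 1e6
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xll),
    sprintf("yllcorner %.10g", g$yll),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %.10g", nodata))
  vv <- v; vv[is.na(vv)] <- nodata
  rows <- apply(vv, 1L, function(r) paste(formatC(r, digits = digits,
                                                  format = "g"),
                                          collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(g$crs, paste0(path, ".crs"))
  invisible(path)
}

#' Align grids onto a target geometry
#'
#' Resamples each grid onto the shape/transform of `target`. `nearest`
#' picks the source pixel whose centre is nearest to each target centre
#' (required for categorical layers); `bilinear` interpolates from the four
#' surrounding source centres, with nodata propagating (any NA corner masks
#' the result). Grids must share the target's CRS label.
#'
#' @param grids a [grid] or list of grids.
#' @param target a [grid] supplying the output geometry.
#' @param method "nearest" or "bilinear".
#' @param categorical logical, recycled over `grids`; `bilinear` on a
#'   categorical layer is an error.
#' @return list of aligned grids (a bare grid in, a bare grid out).
#' @export
align_grids <- function(grids, target, method = c("nearest", "bilinear"),
                        categorical = FALSE) {
  method <- match.arg(method)
  single <- inherits(grids, "grid")
  if (single) grids <- list(grids)
  categorical <- rep_len(categorical, length(grids))
  out <- lapply(seq_along(grids), function(i) {
    g <- grids[[i]]
    if (!identical(g$crs, target$crs))
      stop("CRS mismatch: ", g$crs, " vs ", target$crs)
    if (categorical[i] && method == "bilinear")
      stop("bilinear resampling requested for a categorical layer")
    if (same_geometry(g, target)) return(g)
    resample_one(g, target, method)
  })
  if (single) out[[1]] else out
}

resample_one <- function(g, target, method) {
  tc <- pixel_centers(target)
  nrs <- nrow(g$values); ncs <- ncol(g$values)
  # fractional source indices of the target centres
  fc <- (tc$x - g$xll) / g$cellsize + 0.5            # 1-based col
  fr <- nrs - (tc$y - g$yll) / g$cellsize + 0.5      # 1-based row
  if (method == "nearest") {
    ri <- pmin(pmax(round(fr), 1L), nrs)
    ci <- pmin(pmax(round(fc), 1L), ncs)
    vals <- g$values[cbind(as.vector(ri), as.vector(ci))]
    out <- matrix(vals, nrow(target$values), ncol(target$values))
  } else {
    r0 <- pmin(pmax(floor(fr), 1L), nrs); r1 <- pmin(r0 + 1L, nrs)
    c0 <- pmin(pmax(floor(fc), 1L), ncs); c1 <- pmin(c0 + 1L, ncs)
    wr <- pmin(pmax(fr - r0, 0), 1); wc <- pmin(pmax(fc - c0, 0), 1)
    v <- g$values
    v00 <- v[cbind(as.vector(r0), as.vector(c0))]
    v01 <- v[cbind(as.vector(r0), as.vector(c1))]
    v10 <- v[cbind(as.vector(r1), as.vector(c0))]
    v11 <- v[cbind(as.vector(r1), as.vector(c1))]
    vals <- (1 - wr) * ((1 - wc) * v00 + wc * v01) +
      wr * ((1 - wc) * v10 + wc * v11)
    out <- matrix(vals, nrow(target$values), ncol(target$values))
  }
  grid(out, xll = target$xll, yll = target$yll,
       cellsize = target$cellsize, crs = target$crs)
}

#' Aggregate a grid to a coarser resolution
#'
#' Blocks of `factor` x `factor` pixels collapse to one output pixel whose
#' size is `factor` times the input size. `mean` ignores nodata cells within
#' the block (all-nodata block -> NA); `mode` is for categorical layers and
#' breaks ties deterministically toward the lowest class id.
#'
#' @param g a [grid].
#' @param factor integer >= 1.
#' @param stat "mean" or "mode".
#' @return a coarser [grid].
#' @export
aggregate_grid <- function(g, factor, stat = c("mean", "mode")) {
  stat <- match.arg(stat)
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  nr <- nrow(g$values); nc <- ncol(g$values)
  if (factor > nr || factor > nc)
    stop("aggregation factor ", factor, " exceeds grid extent ",
         nr, "x", nc)
  if (factor == 1L) return(g)
  nro <- nr %/% factor; nco <- nc %/% factor
  v <- g$values[seq_len(nro * factor), seq_len(nco * factor), drop = FALSE]
  # index of output block for each retained input pixel
  bi <- rep(seq_len(nro), each = factor)
  bj <- rep(seq_len(nco), each = factor)
  block <- outer(bi, bj, function(i, j) (j - 1L) * nro + i)
  if (stat == "mean") {
    sums <- tapply(as.vector(v), as.vector(block),
                   function(z) if (all(is.na(z))) NA_real_ else
                     mean(z, na.rm = TRUE))
    out <- matrix(as.numeric(sums[as.character(seq_len(nro * nco))]),
                  nro, nco)
  } else {
    modes <- tapply(as.vector(v), as.vector(block), mode_lowest)
    out <- matrix(as.numeric(modes[as.character(seq_len(nro * nco))]),
                  nro, nco)
  }
  # north edge of retained area stays at the grid's north edge
  ytop <- g$yll + nr * g$cellsize
  grid(out, xll = g$xll, yll = ytop - nro * factor * g$cellsize,
       cellsize = g$cellsize * factor, crs = g$crs)
}

mode_lowest <- function(z) {
  z <- z[!is.na(z)]
  if (!length(z)) return(NA_real_)
  tab <- table(z)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  min(cand)  # deterministic tie-break: lowest class id
}

#' Time-indexed stack of aligned grids
#'
#' @param layers list of mutually aligned [grid]s.
#' @param years integer vector, one per layer.
#' @param months optional integer vector (1-12), one per layer, for monthly
#'   cubes. (year, month) pairs must be strictly increasing with no
#'   duplicates.
#' @return an object of class `raster_cube`.
#' @export
raster_cube <- function(layers, years, months = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  if (length(years) != length(layers))
    stop("years must have one entry per layer")
  for (g in layers[-1]) stop_unless_aligned(layers[[1]], g, "cube layers")
  key <- if (is.null(months)) years else years * 12 + months
  if (any(diff(key) <= 0)) stop("time index must be strictly increasing")
  structure(list(layers = layers, years = as.integer(years),
                 months = if (is.null(months)) NULL else as.integer(months)),
            class = "raster_cube")
}

#' @export
length.raster_cube <- function(x) length(x$layers)

#' @export
print.raster_cube <- function(x, ...) {
  cat(sprintf("<raster_cube> %d layers (%s), %s\n", length(x$layers),
              if (is.null(x$months)) "annual" else "monthly",
              paste(range(x$years), collapse = "-")))
  invisible(x)
}

#' Stack a cube into a pixels x time matrix
#' @param cube a [raster_cube].
#' @return numeric matrix, one column per layer, pixels in column-major
#'   order of the grid matrix.
#' @export
cube_matrix <- function(cube) {
  m <- vapply(cube$layers, function(g) as.vector(g$values),
              numeric(length(cube$layers[[1]]$values)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  m
}

cube_template <- function(cube) cube$layers[[1]]

grid_like <- function(template, values) {
  grid(matrix(values, nrow(template$values), ncol(template$values)),
       xll = template$xll, yll = template$yll,
       cellsize = template$cellsize, crs = template$crs)
}

#' Subset a cube by year (and optionally month)
#' @param cube a [raster_cube].
#' @param years years to keep.
#' @return a [raster_cube].
#' @export
cube_subset <- function(cube, years) {
  keep <- cube$years %in% years
  if (!any(keep)) stop("no layers in requested years")
  raster_cube(cube$layers[keep], cube$years[keep],
              if (is.null(cube$months)) NULL else cube$months[keep])
}

#' Maximum-value composite of sub-period layers
#'
#' Collapses several layers observed within one month (e.g. 16-day NDVI)
#' into a single monthly layer by the per-pixel maximum. A pixel is nodata
#' only where *all* contributing layers are nodata.
#'
#' @param layers non-empty list of aligned [grid]s.
#' @return a [grid].
#' @export
monthly_max_composite <- function(layers) {
  if (!length(layers)) stop("no layers to composite")
  for (g in layers[-1]) stop_unless_aligned(layers[[1]], g)
  acc <- layers[[1]]$values
  for (g in layers[-1]) {
    v <- g$values
    take <- is.na(acc) | (!is.na(v) & v > acc)
    acc[take] <- v[take]
  }
  grid_like(layers[[1]], acc)
}

#' Per-pixel arithmetic between aligned grids
#' @param a,b grids with identical geometry (`b` may be a scalar).
#' @param op a binary function such as `+`.
#' @return a [grid]; nodata propagates (NA in either operand -> NA).
#' @export
grid_map2 <- function(a, b, op) {
  if (inherits(b, "grid")) {
    stop_unless_aligned(a, b)
    grid_like(a, op(a$values, b$values))
  } else grid_like(a, op(a$values, b))
}

#' Total unmasked area of a grid in km2
#' @param g a [grid].
#' @export
unmasked_area_km2 <- function(g) sum(!is.na(g$values)) * pixel_area_km2(g)
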