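#' Default vegetation-class parameter table for the CASA model
#'
#' One row per vegetation class: maximum light-use efficiency `eps_max`
#' (gC per MJ APAR) and the class-specific NDVI range used to rescale NDVI
#' onto FPAR. The values follow the China calibration of the improved CASA
#' model that is standard in the regional NPP literature; they are shipped
#' as an editable table, not as facts about any particular study area.
#' Simple-ratio bounds are derived from the NDVI bounds through the SR
#' transform so the two FPAR routes are internally consistent.
#'
#' Classes: 1 farmland, 2 woodland, 3 grassland, 4 water body,
#' 5 unused land, 6 construction land.
#'
#' @return data.frame with columns class_id, name, eps_max, ndvi_min,
#'   ndvi_max, sr_min, sr_max.
#' @export
default_veg_params <- function() {
  p <- data.frame(
    class_id = 1:6,
    name = c("farmland", "woodland", "grassland", "water_body",
             "unused_land", "construction_land"),
    eps_max = c(0.542, 0.692, 0.542, 0.542, 0.542, 0.542),
    ndvi_min = rep(0.023, 6),
    ndvi_max = c(0.634, 0.738, 0.634, 0.634, 0.634, 0.634)
  )
  p$sr_min <- (1 + p$ndvi_min) / (1 - p$ndvi_min)
  p$sr_max <- (1 + p$ndvi_max) / (1 - p$ndvi_max)
  validate_veg_params(p)
  p
}

validate_veg_params <- function(p) {
  stopifnot(all(c("class_id", "eps_max", "ndvi_min", "ndvi_max") %in%
                  names(p)))
  if (any(p$eps_max <= 0 | p$eps_max > 2))
    stop("eps_max must lie in (0, 2] gC/MJ")
  if (any(p$ndvi_min >= p$ndvi_max)) stop("ndvi_min must be < ndvi_max")
  if (is.null(p$sr_min)) p$sr_min <- (1 + p$ndvi_min) / (1 - p$ndvi_min)
  if (is.null(p$sr_max)) p$sr_max <- (1 + p$ndvi_max) / (1 - p$ndvi_max)
  if (any(p$sr_min >= p$sr_max)) stop("sr_min must be < sr_max")
  invisible(p)
}

#' FPAR bounds used throughout the CASA model
#' @export
FPAR_MAX <- 0.95
#' @rdname FPAR_MAX
#' @export
FPAR_MIN <- 0.001

#' Simple ratio SR = (1 + NDVI) / (1 - NDVI)
#'
#' NDVI is clipped at 0.997 first so the transform stays finite; negative
#' NDVI passes through (the FPAR rescale floors such pixels anyway).
#'
#' @param ndvi a [grid] of NDVI values.
#' @return a [grid] of simple-ratio values.
#' @export
sr_index <- function(ndvi) {
  v <- pmin(ndvi$values, 0.997)
  grid_like(ndvi, (1 + v) / (1 - v))
}

rescale_by_class <- function(x, vegtype, lo_by_class, hi_by_class,
                             class_ids) {
  cls <- vegtype$values
  present <- sort(unique(as.vector(cls[!is.na(cls)])))
  missing <- setdiff(present, class_ids)
  if (length(missing))
    stop("no CASA parameters for vegetation class id(s): ",
         paste(missing, collapse = ", "))
  idx <- match(as.vector(cls), class_ids)
  lo <- matrix(lo_by_class[idx], nrow(cls), ncol(cls))
  hi <- matrix(hi_by_class[idx], nrow(cls), ncol(cls))
  f <- (x$values - lo) / (hi - lo) * (FPAR_MAX - FPAR_MIN) + FPAR_MIN
  pmin(pmax(f, FPAR_MIN), FPAR_MAX)
}

#' FPAR from NDVI (per-class linear rescale)
#'
#' NDVI is rescaled linearly from the class interval
#' \[ndvi_min, ndvi_max\] onto \[0.001, 0.95\] and clipped to that range.
#' Negative NDVI maps to the FPAR floor.
#'
#' @param ndvi NDVI [grid].
#' @param vegtype categorical [grid] of vegetation class ids.
#' @param params parameter table as from [default_veg_params()].
#' @return FPAR [grid] in \[0.001, 0.95\].
#' @export
fpar_from_ndvi <- function(ndvi, vegtype, params = default_veg_params()) {
  stop_unless_aligned(ndvi, vegtype)
  params <- validate_veg_params(params)
  f <- rescale_by_class(ndvi, vegtype, params$ndvi_min, params$ndvi_max,
                        params$class_id)
  f[!is.na(ndvi$values) & ndvi$values < 0] <- FPAR_MIN
  grid_like(ndvi, f)
}

#' FPAR from the simple ratio (per-class linear rescale)
#' @inheritParams fpar_from_ndvi
#' @param sr simple-ratio [grid] from [sr_index()].
#' @return FPAR [grid] in \[0.001, 0.95\].
#' @export
fpar_from_sr <- function(sr, vegtype, params = default_veg_params()) {
  stop_unless_aligned(sr, vegtype)
  params <- validate_veg_params(params)
  grid_like(sr, rescale_by_class(sr, vegtype, params$sr_min, params$sr_max,
                                 params$class_id))
}

#' Averaged FPAR
#'
#' The NDVI-based and SR-based FPAR estimates bracket the truth from
#' opposite sides; their arithmetic mean has the smallest error, so the
#' model uses the average.
#'
#' @param fpar_ndvi,fpar_sr aligned FPAR [grid]s.
#' @return FPAR [grid].
#' @export
fpar_combined <- function(fpar_ndvi, fpar_sr) {
  grid_map2(fpar_ndvi, fpar_sr, function(a, b) (a + b) / 2)
}

#' Absorbed photosynthetically active radiation
#'
#' APAR = FPAR x SOL x 0.5, where 0.5 is the fraction of total solar
#' radiation in the photosynthetically active 0.4-0.7 um band.
#'
#' @param fpar FPAR [grid].
#' @param sol total solar radiation [grid], MJ m-2 month-1; must be >= 0.
#' @return APAR [grid], MJ m-2 month-1.
#' @export
apar <- function(fpar, sol) {
  if (any(sol$values < 0, na.rm = TRUE))
    stop("negative solar radiation values")
  grid_map2(fpar, sol, function(f, s) f * s * 0.5)
}

#' Optimal growth temperature per pixel
#'
#' Topt is the multi-year mean temperature of the calendar month in which
#' the multi-year mean NDVI peaks (the paper-standard proxy for the
#' temperature during peak vegetation activity). Ties break to the
#' earliest month.
#'
#' @param ndvi_cube,temp_cube monthly [raster_cube]s over the same months.
#' @return a [grid] of Topt in degrees C.
#' @export
optimal_temperature <- function(ndvi_cube, temp_cube) {
  if (is.null(ndvi_cube$months) || is.null(temp_cube$months))
    stop("monthly cubes required")
  if (length(ndvi_cube) != length(temp_cube))
    stop("cubes must cover the same months")
  nm <- cube_matrix(ndvi_cube)   # pixels x layers
  tm <- cube_matrix(temp_cube)
  mon <- ndvi_cube$months
  npx <- nrow(nm)
  ndvi_mean <- sapply(1:12, function(m) {
    cols <- which(mon == m)
    if (!length(cols)) return(rep(NA_real_, npx))
    rowMeans(nm[, cols, drop = FALSE], na.rm = TRUE)
  })
  temp_mean <- sapply(1:12, function(m) {
    cols <- which(mon == m)
    if (!length(cols)) return(rep(NA_real_, npx))
    rowMeans(tm[, cols, drop = FALSE], na.rm = TRUE)
  })
  if (is.null(dim(ndvi_mean))) ndvi_mean <- matrix(ndvi_mean, nrow = 1L)
  if (is.null(dim(temp_mean))) temp_mean <- matrix(temp_mean, nrow = 1L)
  ndvi_mean[is.nan(ndvi_mean)] <- NA
  temp_mean[is.nan(temp_mean)] <- NA
  topt <- rep(NA_real_, npx)
  ok <- rowSums(!is.na(ndvi_mean)) > 0
  best <- apply(ndvi_mean[ok, , drop = FALSE], 1L,
                which.max)  # earliest month on ties
  topt[ok] <- temp_mean[cbind(which(ok), best)]
  grid_like(cube_template(ndvi_cube), topt)
}

#' Temperature stress scalars
#'
#' Canonical light-use-efficiency closures:
#' Te1 = 0.8 + 0.02 Topt - 0.0005 Topt^2 (floored at 0, and set to 0 in
#' months with T <= -10 C, when growth is shut down);
#' Te2 = 1.1814 / ((1 + exp(0.2 (Topt - 10 - T))) (1 + exp(0.3 (-Topt - 10 + T)))),
#' a double-logistic penalty for months much colder or hotter than Topt.
#'
#' @param topt Topt [grid] from [optimal_temperature()].
#' @param temp monthly mean temperature [grid], degrees C.
#' @return list of grids `t1` and `t2`.
#' @export
temperature_stress <- function(topt, temp) {
  stop_unless_aligned(topt, temp)
  to <- topt$values; tm <- temp$values
  t1 <- pmax(0.8 + 0.02 * to - 0.0005 * to^2, 0)
  t1[!is.na(tm) & tm <= -10] <- 0
  t2 <- 1.1814 / ((1 + exp(0.2 * (to - 10 - tm))) *
                    (1 + exp(0.3 * (-to - 10 + tm))))
  t1[is.na(tm) | is.na(to)] <- NA
  t2[is.na(tm) | is.na(to)] <- NA
  list(t1 = grid_like(topt, t1), t2 = grid_like(topt, t2))
}

# Thornthwaite heat index and exponent per pixel from 12 multi-month mean
# temperatures; used by the potential-ET closure below.
thornthwaite_pet <- function(temp_month, heat_index) {
  a <- 6.75e-7 * heat_index^3 - 7.71e-5 * heat_index^2 +
    1.792e-2 * heat_index + 0.49239
  t <- pmax(temp_month, 0)
  pet <- ifelse(heat_index > 0, 16 * (10 * t / heat_index)^a, 0)
  pet[t <= 0] <- 0
  pet
}

#' Water stress scalar (monthly cube)
#'
#' We = 0.5 + 0.5 E/Ep clipped to \[0.5, 1\], with estimated actual
#' evapotranspiration E from the regional evapotranspiration closure
#' (precipitation P and net radiation Rn):
#' E = P Rn (P^2 + Rn^2 + P Rn) / ((P + Rn)(P^2 + Rn^2)),
#' Rn = sqrt(Ep0 P) (0.369 + 0.598 sqrt(Ep0 / P)),
#' and potential evapotranspiration Ep = (E + Ep0)/2 where Ep0 is the
#' Thornthwaite monthly potential ET. Where Ep = 0 (frozen/arid months)
#' We falls back to the drought floor 0.5. The solar-radiation cube is
#' accepted for interface compatibility; the closure itself is driven by
#' precipitation and temperature.
#'
#' @param precip_cube,temp_cube monthly [raster_cube]s (mm, degrees C).
#' @param sol_cube optional monthly radiation cube (unused by the closure).
#' @return monthly [raster_cube] of We in \[0.5, 1\].
#' @export
water_stress <- function(precip_cube, temp_cube, sol_cube = NULL) {
  if (length(precip_cube) != length(temp_cube))
    stop("precipitation and temperature cubes must cover the same months")
  pm <- cube_matrix(precip_cube); tm <- cube_matrix(temp_cube)
  mon <- temp_cube$months
  # per-pixel Thornthwaite heat index from multi-year monthly mean temps
  tmean <- sapply(1:12, function(m) {
    cols <- which(mon == m)
    if (!length(cols)) return(rep(0, nrow(tm)))
    rowMeans(tm[, cols, drop = FALSE], na.rm = TRUE)
  })
  if (is.null(dim(tmean))) tmean <- matrix(tmean, nrow = 1L)
  tmean[is.nan(tmean)] <- 0
  heat <- rowSums(pmax(tmean / 5, 0)^1.514)
  out <- matrix(NA_real_, nrow(pm), ncol(pm))
  for (j in seq_len(ncol(pm))) {
    P <- pm[, j]; Tt <- tm[, j]
    ep0 <- thornthwaite_pet(Tt, heat)
    Pp <- pmax(P, 0)
    rn <- ifelse(Pp > 0 & ep0 > 0,
                 sqrt(ep0 * Pp) * (0.369 + 0.598 * sqrt(ep0 / Pp)), 0)
    denom <- (Pp + rn) * (Pp^2 + rn^2)
    E <- ifelse(denom > 0,
                Pp * rn * (Pp^2 + rn^2 + Pp * rn) / denom, 0)
    Ep <- (E + ep0) / 2
    w <- ifelse(Ep > 0, 0.5 + 0.5 * E / Ep, 0.5)
    w <- pmin(pmax(w, 0.5), 1)
    w[is.na(P) | is.na(Tt)] <- NA
    out[, j] <- w
  }
  tpl <- cube_template(precip_cube)
  raster_cube(lapply(seq_len(ncol(out)),
                     function(j) grid_like(tpl, out[, j])),
              precip_cube$years, precip_cube$months)
}

#' Monthly NPP from assembled CASA components
#'
#' NPP = APAR x Te1 x Te2 x We x eps_max(class); nonnegative wherever
#' radiation is nonnegative, nodata wherever any input is nodata.
#'
#' @param apar_g APAR [grid].
#' @param t1,t2 temperature-stress grids.
#' @param w water-stress [grid].
#' @param vegtype vegetation class [grid].
#' @param params parameter table (eps_max per class).
#' @return NPP [grid], gC m-2 month-1.
#' @export
monthly_npp <- function(apar_g, t1, t2, w, vegtype,
                        params = default_veg_params()) {
  params <- validate_veg_params(params)
  idx <- match(as.vector(vegtype$values), params$class_id)
  emax <- matrix(params$eps_max[idx], nrow(vegtype$values),
                 ncol(vegtype$values))
  grid_like(apar_g, apar_g$values * t1$values * t2$values * w$values * emax)
}

#' Annual NPP as the sum of twelve monthly layers
#' @param monthly_cube a monthly [raster_cube] holding exactly 12 layers
#'   of one calendar year.
#' @return annual NPP [grid], gC m-2 yr-1.
#' @export
annual_npp <- function(monthly_cube) {
  if (length(monthly_cube) != 12L)
    stop("annual_npp needs exactly 12 monthly layers, got ",
         length(monthly_cube))
  m <- cube_matrix(monthly_cube)
  grid_like(cube_template(monthly_cube), rowSums(m))
}

#' Run the full CASA chain for a span of years
#'
#' Convenience driver: computes Topt once from the whole record, then for
#' every month FPAR (both routes, averaged), APAR, the stress scalars and
#' monthly NPP, and sums to annual NPP per year.
#'
#' @param ndvi_cube,sol_cube,temp_cube,precip_cube monthly cubes over the
#'   same (year, month) index.
#' @param vegtype vegetation class [grid].
#' @param params CASA parameter table.
#' @return list: `annual` (annual [raster_cube] of NPP), `monthly`
#'   (monthly NPP [raster_cube]), `topt` ([grid]).
#' @export
casa_npp <- function(ndvi_cube, sol_cube, temp_cube, precip_cube, vegtype,
                     params = default_veg_params()) {
  n <- length(ndvi_cube)
  if (length(sol_cube) != n || length(temp_cube) != n ||
      length(precip_cube) != n)
    stop("all driver cubes must cover the same months")
  topt <- optimal_temperature(ndvi_cube, temp_cube)
  wcube <- water_stress(precip_cube, temp_cube, sol_cube)
  monthly <- vector("list", n)
  for (i in seq_len(n)) {
    ndvi <- ndvi_cube$layers[[i]]
    f <- fpar_combined(fpar_from_ndvi(ndvi, vegtype, params),
                       fpar_from_sr(sr_index(ndvi), vegtype, params))
    ap <- apar(f, sol_cube$layers[[i]])
    ts <- temperature_stress(topt, temp_cube$layers[[i]])
    monthly[[i]] <- monthly_npp(ap, ts$t1, ts$t2, wcube$layers[[i]],
                                vegtype, params)
  }
  mcube <- raster_cube(monthly, ndvi_cube$years, ndvi_cube$months)
  yrs <- unique(ndvi_cube$years)
  ann <- lapply(yrs, function(y) annual_npp(cube_subset(mcube, y)))
  list(annual = raster_cube(ann, yrs), monthly = mcube, topt = topt)
}

#' Regional NPP summary: mean areal density and total carbon
#'
#' Total NPP in TgC = sum(pixel NPP gC m-2 x pixel area m2) x 1e-12.
#'
#' @param npp annual NPP [grid], gC m-2 yr-1.
#' @return list `mean_gC_m2` and `total_TgC`.
#' @export
regional_npp_summary <- function(npp) {
  v <- npp$values
  area_m2 <- npp$cellsize^2
  list(mean_gC_m2 = mean(v, na.rm = TRUE),
       total_TgC = sum(v * area_m2, na.rm = TRUE) * 1e-12)
}
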