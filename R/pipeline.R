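#' Regression validation of estimated NPP against a reference product
#'
#' Pools per-pixel, per-year pairs (estimate on the x-axis, reference on
#' the y-axis by default, matching the usual product-validation
#' orientation) and reports the OLS slope, intercept, R-squared, slope
#' p-value and the difference of the two means.
#'
#' @param est_cube,ref_cube aligned annual [raster_cube]s on the same
#'   years.
#' @param ref_on_y logical; set `FALSE` to regress estimate on reference.
#' @return list slope, intercept, r_squared, p_value, mean_est, mean_ref,
#'   mean_difference (|mean_ref - mean_est|), n_pairs.
#' @export
validate_against_reference <- function(est_cube, ref_cube,
                                       ref_on_y = TRUE) {
  if (length(est_cube) != length(ref_cube) ||
      !all(est_cube$years == ref_cube$years))
    stop("cubes must cover the same years")
  x <- as.vector(cube_matrix(est_cube))
  y <- as.vector(cube_matrix(ref_cube))
  ok <- is.finite(x) & is.finite(y)
  if (!any(ok)) stop("no overlapping unmasked pairs")
  x <- x[ok]; y <- y[ok]
  if (!ref_on_y) { tmp <- x; x <- y; y <- tmp }
  fit <- stats::lm(y ~ x)
  # a perfect fit (identity validation) is legitimate here
  sm <- suppressWarnings(summary(fit))
  p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  me <- if (ref_on_y) mean(x) else mean(y)
  mr <- if (ref_on_y) mean(y) else mean(x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p_value = p,
       mean_est = me, mean_ref = mr,
       mean_difference = abs(mr - me), n_pairs = length(x))
}

#' Run the full synthetic-scenario analysis pipeline
#'
#' Stages, in dependency order: synthesize -> casa -> trend -> gravity ->
#' pcorr -> landuse -> opgd -> validate. Each stage can be toggled;
#' disabling one makes dependents fail with a stage-named error. With an
#' `outdir`, per-stage CSV summaries (and key rasters as ASCII grids) are
#' written and listed in the returned manifest; without one the results
#' stay in memory.
#'
#' @param cfg a [scenario_config()].
#' @param stages character vector of stages to run.
#' @param outdir optional output directory (created if missing).
#' @param epochs years used for the gravity / land-use epoch analyses
#'   (default: first, middle and last scenario years).
#' @param opgd_scales_px aggregation factors (pixels) for OPGD scale
#'   selection.
#' @return named list of stage results plus `manifest` (data.frame of
#'   written files, if any).
#' @export
run_pipeline <- function(cfg = scenario_config(),
                         stages = c("synthesize", "casa", "trend",
                                    "gravity", "pcorr", "landuse", "opgd",
                                    "validate"),
                         outdir = NULL,
                         epochs = NULL,
                         opgd_scales_px = c(6L, 8L, 10L, 12L, 16L, 20L)) {
  res <- list()
  files <- character(0)
  emit <- function(obj, name) {
    if (is.null(outdir)) return(invisible(NULL))
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    path <- file.path(outdir, name)
    if (inherits(obj, "grid")) write_grid(obj, path)
    else utils::write.csv(obj, path, row.names = FALSE)
    files <<- c(files, path)
  }
  need <- function(stage, dep) {
    if (is.null(res[[dep]]))
      stop("stage '", stage, "' needs disabled/failed stage '", dep, "'")
  }
  if (is.null(epochs))
    epochs <- unique(cfg$years[c(1, ceiling(length(cfg$years) / 2),
                                 length(cfg$years))])

  if ("synthesize" %in% stages) {
    res$synthesize <- generate_scenario(cfg)
    emit(data.frame(parameter = c("seed", "strata_q_target", "npp_trend",
                                  "ndvi_trend",
                                  paste0("pcor_", names(cfg$partial_corr_targets))),
                    value = c(cfg$seed, cfg$strata_q_target,
                              cfg$npp_trend[1], cfg$ndvi_trend,
                              unname(cfg$partial_corr_targets))),
         "truth_manifest.csv")
  }
  if ("casa" %in% stages) {
    need("casa", "synthesize")
    s <- res$synthesize
    res$casa <- casa_npp(s$ndvi, s$climate$solrad, s$climate$temp,
                         s$climate$precip, s$static$vegtype)
    summ <- do.call(rbind, lapply(seq_along(res$casa$annual$layers),
      function(i) {
        rs <- regional_npp_summary(res$casa$annual$layers[[i]])
        data.frame(year = res$casa$annual$years[i],
                   mean_gC_m2 = rs$mean_gC_m2, total_TgC = rs$total_TgC)
      }))
    res$casa$summary <- summ
    emit(summ, "casa_summary.csv")
  }
  if ("trend" %in% stages) {
    need("trend", "casa")
    res$trend <- trend_map(res$casa$annual)
    res$trend$summary <- series_summary(res$casa$summary$mean_gC_m2)
    grades <- do.call(rbind, lapply(seq_along(res$casa$annual$layers),
      function(i) data.frame(year = res$casa$annual$years[i],
                             t(grade_proportions(
                               res$casa$annual$layers[[i]])))))
    res$trend$grades <- grades
    emit(res$trend$slope, "slope.asc")
    emit(res$trend$class, "trend_class.asc")
    emit(grades, "grades.csv")
  }
  if ("gravity" %in% stages) {
    need("gravity", "casa")
    cube <- cube_subset(res$casa$annual, epochs)
    res$gravity <- gravity_trajectory(cube)
    emit(res$gravity$centroids, "centroids.csv")
    if (!is.null(res$gravity$steps)) emit(res$gravity$steps,
                                          "migrations.csv")
  }
  if ("pcorr" %in% stages) {
    need("pcorr", "synthesize")
    s <- res$synthesize
    ann <- annualize_drivers(s$climate)
    res$pcorr <- pixelwise_partial_cor(s$climate$npp_response, ann$precip,
                                       ann$temp, ann$solrad)
    res$pcorr$sig <- lapply(res$pcorr$r, classify_pcor_significance,
                            n_years = res$pcorr$n_years)
    emit(data.frame(factor = names(res$pcorr$regional_mean_r),
                    mean_r = unname(res$pcorr$regional_mean_r),
                    series_r = unname(res$pcorr$regional_series_r)),
         "pcorr_summary.csv")
  }
  if ("landuse" %in% stages) {
    need("landuse", "casa")
    s <- res$synthesize
    lu <- res$synthesize$landuse
    e2 <- range(epochs)
    lu_a <- lu$layers[[match(e2[1], lu$years)]]
    lu_b <- lu$layers[[match(e2[2], lu$years)]]
    tm <- transition_matrix(lu_a, lu_b, e2)
    npp_a <- res$casa$annual$layers[[match(e2[1],
                                           res$casa$annual$years)]]
    means <- class_mean_npp(npp_a, lu_a)
    ledger <- npp_change_from_transitions(tm, means)
    zb <- band_grid(s$static$elevation,
                    seq(min(s$static$elevation$values),
                        max(s$static$elevation$values), length.out = 7))
    res$landuse <- list(transition = tm, class_means = means,
                        ledger = ledger,
                        zonal = zonal_mean(npp_a, zb))
    emit(as.data.frame(tm$area_km2),
         sprintf("transitions_%d_%d.csv", e2[1], e2[2]))
    emit(ledger$per_class, sprintf("ledger_%d_%d.csv", e2[1], e2[2]))
    emit(res$landuse$zonal, "zonal.csv")
  }
  if ("opgd" %in% stages) {
    need("opgd", "synthesize")
    s <- res$synthesize
    y <- s$static$q_response
    factors <- list(vegtype = s$static$vegtype,
                    soil_moisture = s$static$soil_moisture,
                    elevation = s$static$elevation,
                    gdp = s$static$gdp)
    types <- c(vegtype = "categorical", soil_moisture = "continuous",
               elevation = "continuous", gdp = "continuous")
    sel <- select_scale(y, factors, types, opgd_scales_px,
                        scale_labels = opgd_scales_px * cfg$cellsize_m /
                          1000)
    samples <- detector_samples(y, factors, types, sel$best_px)
    det <- factor_detector(samples, types)
    inter <- interaction_matrix(samples, det)
    res$opgd <- list(scale = sel, factors = det, interactions = inter)
    emit(sel$q_table, "scale_selection.csv")
    emit(det, "factor_q.csv")
    emit(inter, "interaction_matrix.csv")
  }
  if ("validate" %in% stages) {
    need("validate", "casa")
    # synthetic stand-in reference: the scenario's NPP-response cube
    ref <- res$synthesize$climate$npp_response
    res$validate <- validate_against_reference(res$casa$annual, ref)
    emit(data.frame(metric = names(res$validate),
                    value = unlist(res$validate)), "validation.csv")
  }
  res$manifest <- if (length(files)) data.frame(file = files) else
    data.frame(file = character(0))
  res
}

#' Annual aggregates of the monthly climate cubes
#'
#' Precipitation and radiation are summed over months, temperature is
#' averaged — the aggregation convention used before correlating annual
#' NPP with its drivers.
#'
#' @param climate list with monthly cubes `precip`, `temp`, `solrad`
#'   (as from [generate_climate_cubes()]).
#' @return list of annual cubes precip/temp/solrad.
#' @export
annualize_drivers <- function(climate) {
  agg <- function(cube, fun) {
    yrs <- unique(cube$years)
    tpl <- cube_template(cube)
    m <- cube_matrix(cube)
    raster_cube(lapply(yrs, function(y)
      grid_like(tpl, apply(m[, cube$years == y, drop = FALSE], 1, fun))),
      yrs)
  }
  list(precip = agg(climate$precip, sum),
       temp = agg(climate$temp, mean),
       solrad = agg(climate$solrad, sum))
}
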