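#' Synthetic study-scenario configuration
#'
#' Describes a fully synthetic arid-region scenario with known,
#' recoverable structure: raster geometry, time span, trends, the
#' NPP-driver partial-correlation targets, the latent-strata variance
#' share, and a land-use transition plan. All downstream stages are
#' tested by recovering these numbers.
#'
#' Defaults state the scenario the package treats as its reference world:
#' 120 x 120 pixels of 500 m, 20 years, an NPP interannual trend of
#' 2.47 gC m-2 yr-2, NPP-driver partial correlations (0.30, 0.17, 0.09)
#' for (precipitation, temperature, radiation), strata explaining half
#' the response variance on 8-pixel (4 km) blocks, and a land-use plan
#' dominated by grassland-to-farmland conversion partly offset by
#' unused-land-to-grassland restoration.
#'
#' @param nrow,ncol grid shape in pixels.
#' @param cellsize_m pixel edge (metres).
#' @param years inclusive year range.
#' @param seed integer RNG seed; a fixed seed gives identical rasters.
#' @param n_veg_classes number of latent vegetation classes/strata.
#' @param npp_trend interannual NPP trend, gC m-2 yr-1 per yr (scalar or
#'   nrow x ncol matrix).
#' @param ndvi_trend interannual trend of annual-max NDVI, NDVI yr-1.
#' @param partial_corr_targets length-3 vector in (-1, 1): target
#'   second-order partial correlations of annual NPP with precipitation,
#'   temperature and solar radiation (each controlling the other two).
#' @param strata_q_target share in \[0, 1\] of response variance explained
#'   by the latent strata.
#' @param strata_block_px block edge of the latent strata in pixels (the
#'   injected signal scale).
#' @param transition_plan data.frame(from, to, area_km2, epoch) of planned
#'   land-use conversions (class codes 1-6, epoch = first year the new
#'   class applies).
#' @param npp_noise_sd,precip_sd,temp_sd,solrad_sd interannual standard
#'   deviations of the four annual variables (gC m-2, mm, degC, MJ m-2).
#' @param precip_trend,temp_trend,solrad_trend annual linear trends of
#'   the drivers (mm yr-1, degC yr-1, MJ m-2 yr-1).
#' @param ndvi_noise_sd monthly NDVI noise sd.
#' @param ndvi_precip_weight,ndvi_temp_weight monotone response weights of
#'   NDVI to standardized growing-season precipitation / temperature.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(nrow = 120, ncol = 120, cellsize_m = 500,
                            years = 2001:2020, seed = 42L,
                            n_veg_classes = 6L,
                            npp_trend = 2.47, ndvi_trend = 0.002,
                            partial_corr_targets = c(precip = 0.30,
                                                     temp = 0.17,
                                                     solrad = 0.09),
                            strata_q_target = 0.5,
                            strata_block_px = 8L,
                            transition_plan = data.frame(
                              from = c(3L, 5L),
                              to = c(1L, 3L),
                              area_km2 = c(400, 150),
                              epoch = c(2010L, 2010L)),
                            npp_noise_sd = 20, precip_sd = 40,
                            temp_sd = 0.8, solrad_sd = 150,
                            precip_trend = 1.5, temp_trend = 0.03,
                            solrad_trend = 3,
                            ndvi_noise_sd = 0.02,
                            ndvi_precip_weight = 0.05,
                            ndvi_temp_weight = 0.02) {
  stopifnot(length(partial_corr_targets) == 3L)
  if (any(abs(partial_corr_targets) >= 1))
    stop("partial_corr_targets must lie in (-1, 1)")
  if (strata_q_target < 0 || strata_q_target > 1)
    stop("strata_q_target must lie in [0, 1]")
  cfg <- list(nrow = as.integer(nrow), ncol = as.integer(ncol),
              cellsize_m = cellsize_m, years = as.integer(years),
              seed = as.integer(seed),
              n_veg_classes = as.integer(n_veg_classes),
              npp_trend = npp_trend, ndvi_trend = ndvi_trend,
              partial_corr_targets = partial_corr_targets,
              strata_q_target = strata_q_target,
              strata_block_px = as.integer(strata_block_px),
              transition_plan = transition_plan,
              npp_noise_sd = npp_noise_sd, precip_sd = precip_sd,
              temp_sd = temp_sd, solrad_sd = solrad_sd,
              precip_trend = precip_trend, temp_trend = temp_trend,
              solrad_trend = solrad_trend,
              ndvi_noise_sd = ndvi_noise_sd,
              ndvi_precip_weight = ndvi_precip_weight,
              ndvi_temp_weight = ndvi_temp_weight)
  class(cfg) <- "scenario_config"
  cfg
}

# Evaluate expr under a temporary RNG state derived from seed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

blank_grid <- function(cfg, fill = 0) {
  grid(matrix(fill, cfg$nrow, cfg$ncol), xll = 0, yll = 0,
       cellsize = cfg$cellsize_m, crs = "World_Mercator")
}

# row gradient in [0, 1]: 0 at the north edge (row 1), 1 at the south
south_gradient <- function(cfg) {
  matrix(rep((seq_len(cfg$nrow) - 1) / max(cfg$nrow - 1, 1), cfg$ncol),
         cfg$nrow, cfg$ncol)
}

#' Correlation structure implied by the partial-correlation targets
#'
#' The 4x4 correlation matrix of (NPP, precip, temp, solrad) is built
#' from a precision matrix with unit diagonal, off-diagonal entries
#' -target between NPP and each driver, and 0 between drivers (i.e. the
#' drivers are conditionally independent of each other given the rest).
#' By the precision-matrix identity, the partial correlation of NPP with
#' driver i given the other two is then exactly `targets[i]`. The matrix
#' is positive definite iff the squared targets sum below 1.
#'
#' @param targets length-3 numeric in (-1, 1).
#' @return 4x4 correlation matrix (order: npp, precip, temp, solrad).
#' @export
pcor_target_cor_matrix <- function(targets) {
  a <- as.numeric(targets)
  if (sum(a^2) >= 1) {
    worst <- which.max(abs(a))
    stop("partial-correlation targets are infeasible (precision matrix ",
         "not positive definite); largest offender: ",
         c("precip", "temp", "solrad")[worst], " = ", a[worst])
  }
  P <- diag(4)
  P[1, 2:4] <- P[2:4, 1] <- -a
  S <- solve(P)
  stats::cov2cor(S)
}

#' Generate monthly climate cubes plus the jointly-drawn NPP response
#'
#' Monthly precipitation, temperature and solar radiation cubes with
#' (a) a north-south spatial gradient, (b) a sinusoidal seasonal cycle,
#' (c) a linear interannual trend and (d) pixel-level Gaussian interannual
#' anomalies. The annual aggregates (precip/solrad sums, temp mean) are
#' drawn *jointly with an annual NPP-response anomaly* from the 4-variate
#' Gaussian implied by [pcor_target_cor_matrix()], so the second-order
#' partial correlations between the returned `npp_response` cube and the
#' drivers are known analytically. The linear trends are folded into the
#' construction: the noise covariance is the target covariance minus the
#' trend outer product over the year design, so the *raw* 20-year series
#' (trend included) still carry the prescribed correlation structure.
#'
#' @param cfg a [scenario_config()].
#' @return list of cubes `precip` (mm/month), `temp` (degC), `solrad`
#'   (MJ m-2/month) — monthly — and `npp_response` (annual, gC m-2 yr-1).
#' @export
generate_climate_cubes <- function(cfg) {
  ny <- length(cfg$years)
  npx <- cfg$nrow * cfg$ncol
  R <- pcor_target_cor_matrix(cfg$partial_corr_targets)
  sds <- c(cfg$npp_noise_sd, cfg$precip_sd, cfg$temp_sd, cfg$solrad_sd)
  Sigma_tot <- diag(sds) %*% R %*% diag(sds)
  tcent <- seq_len(ny) - mean(seq_len(ny))
  var_t <- sum(tcent^2) / (ny - 1)
  trends <- c(cfg$npp_trend[1], cfg$precip_trend, cfg$temp_trend,
              cfg$solrad_trend)
  Sigma_noise <- Sigma_tot - tcrossprod(trends) * var_t
  ch <- tryCatch(chol(Sigma_noise), error = function(e)
    stop("interannual trends too large for the prescribed correlation ",
         "structure (noise covariance not positive definite)"))
  g <- south_gradient(cfg)
  # spatial mean fields: wetter/warmer toward the south (mountain side)
  precip_mean <- 180 + 140 * g           # mm / yr
  temp_mean <- 9 - 4 * g                 # degC annual mean
  sol_mean <- 5600 - 400 * g             # MJ m-2 / yr
  npp_mean <- 110 + 80 * g               # gC m-2 / yr response baseline
  trend_field <- if (is.matrix(cfg$npp_trend)) cfg$npp_trend
  else matrix(cfg$npp_trend, cfg$nrow, cfg$ncol)

  Z <- with_seed(cfg$seed, matrix(stats::rnorm(npx * ny * 4), ncol = 4))
  E <- Z %*% ch  # rows: pixel-year draws; cols: npp, precip, temp, solrad
  dim_idx <- function(k) matrix(E[, k], npx, ny)
  annual <- list(
    npp = matrix(npp_mean, npx, ny) + outer(as.vector(trend_field), tcent) +
      dim_idx(1),
    precip = matrix(precip_mean, npx, ny) +
      outer(rep(cfg$precip_trend, npx), tcent) + dim_idx(2),
    temp = matrix(temp_mean, npx, ny) +
      outer(rep(cfg$temp_trend, npx), tcent) + dim_idx(3),
    solrad = matrix(sol_mean, npx, ny) +
      outer(rep(cfg$solrad_trend, npx), tcent) + dim_idx(4))
  annual$precip <- pmax(annual$precip, 0)
  annual$solrad <- pmax(annual$solrad, 0)

  tpl <- blank_grid(cfg)
  # seasonal shapes: weights (sum 1) for the flux variables, additive
  # sinusoid for temperature
  m <- 1:12
  wp <- (1 + 0.9 * sin(2 * pi * (m - 4) / 12)); wp <- wp / sum(wp)
  ws <- (1 + 0.6 * sin(2 * pi * (m - 3) / 12)); ws <- ws / sum(ws)
  tamp <- 14  # degC seasonal half-amplitude
  tshape <- tamp * sin(2 * pi * (m - 4) / 12)  # sums to zero over 12 months

  mk_cube <- function(build) {
    layers <- list(); yy <- integer(0); mm <- integer(0)
    for (yi in seq_len(ny)) for (mo in 1:12) {
      layers[[length(layers) + 1L]] <- grid_like(tpl, build(yi, mo))
      yy <- c(yy, cfg$years[yi]); mm <- c(mm, mo)
    }
    raster_cube(layers, yy, mm)
  }
  precip_cube <- mk_cube(function(yi, mo) annual$precip[, yi] * wp[mo])
  sol_cube <- mk_cube(function(yi, mo) annual$solrad[, yi] * ws[mo])
  temp_cube <- mk_cube(function(yi, mo) annual$temp[, yi] + tshape[mo])
  npp_cube <- raster_cube(lapply(seq_len(ny), function(yi)
    grid_like(tpl, annual$npp[, yi])), cfg$years)
  list(precip = precip_cube, temp = temp_cube, solrad = sol_cube,
       npp_response = npp_cube)
}

#' Generate a monthly NDVI cube responding to climate
#'
#' NDVI follows a growing-season bell (peak in July) whose amplitude
#' responds monotonically (stated positive weights) to the standardized
#' annual precipitation and temperature anomalies of the pixel, carries a
#' linear interannual trend of `cfg$ndvi_trend` on the annual maximum, and
#' receives Gaussian monthly noise. Values are clipped to \[-0.1, 0.95\].
#' With both response weights zero ("all-desert" scenario) and zero noise
#' the cube is constant at its baseline seasonal cycle.
#'
#' @param cfg a [scenario_config()].
#' @param temp_cube,precip_cube monthly cubes from
#'   [generate_climate_cubes()].
#' @return monthly NDVI [raster_cube].
#' @export
generate_ndvi_cube <- function(cfg, temp_cube, precip_cube) {
  stop_unless_aligned(cube_template(temp_cube), cube_template(precip_cube),
                      "driver cubes")
  ny <- length(cfg$years)
  npx <- cfg$nrow * cfg$ncol
  P <- cube_matrix(precip_cube); Tm <- cube_matrix(temp_cube)
  mon <- precip_cube$months
  p_ann <- sapply(seq_len(ny), function(yi)
    rowSums(P[, mon %in% 1:12 & precip_cube$years == cfg$years[yi],
              drop = FALSE]))
  t_ann <- sapply(seq_len(ny), function(yi)
    rowMeans(Tm[, temp_cube$years == cfg$years[yi], drop = FALSE]))
  p_std <- (p_ann - rowMeans(p_ann)) / cfg$precip_sd
  t_std <- (t_ann - rowMeans(t_ann)) / cfg$temp_sd
  g <- south_gradient(cfg)
  base <- as.vector(0.08 + 0.10 * g)      # dormant-season background
  amp <- as.vector(0.15 + 0.45 * g)       # peak-season greenness
  m <- 1:12
  season <- exp(-((m - 7) / 2.2)^2)       # growing-season bell, peak July
  tcent <- seq_len(ny) - mean(seq_len(ny))
  noise <- with_seed(cfg$seed + 1L,
                     array(stats::rnorm(npx * ny * 12, sd = cfg$ndvi_noise_sd),
                           dim = c(npx, ny, 12)))
  tpl <- blank_grid(cfg)
  layers <- list(); yy <- integer(0); mm <- integer(0)
  for (yi in seq_len(ny)) {
    peak <- amp + cfg$ndvi_precip_weight * p_std[, yi] +
      cfg$ndvi_temp_weight * t_std[, yi] + cfg$ndvi_trend * tcent[yi]
    for (mo in 1:12) {
      v <- base + season[mo] * peak + noise[, yi, mo]
      layers[[length(layers) + 1L]] <- grid_like(tpl,
                                                 pmin(pmax(v, -0.1), 0.95))
      yy <- c(yy, cfg$years[yi]); mm <- c(mm, mo)
    }
  }
  raster_cube(layers, yy, mm)
}

#' Generate static layers with a controllable strata signal
#'
#' The vegetation-type grid is a blocky latent stratification
#' (`strata_block_px` blocks, classes 1..n_veg_classes) constructed so
#' that the strata explain *exactly* `strata_q_target` of the variance of
#' the returned `q_response` field: the response is a·(stratum mean) +
#' b·(within-stratum-centred noise), whose between/within sum-of-squares
#' split is exact by construction. Elevation is a smooth south-rising
#' field; slope and aspect come from its finite differences; soil
#' moisture tracks the response (a correlated factor); GDP and population
#' density are smooth lognormal surfaces.
#'
#' @param cfg a [scenario_config()].
#' @return list of grids: vegtype, elevation, slope, aspect,
#'   soil_moisture, gdp, popdens, q_response.
#' @export
generate_static_layers <- function(cfg) {
  nr <- cfg$nrow; nc <- cfg$ncol; npx <- nr * nc
  bp <- cfg$strata_block_px
  tpl <- blank_grid(cfg)
  res <- with_seed(cfg$seed + 2L, {
    # blocky strata
    nbr <- ceiling(nr / bp); nbc <- ceiling(nc / bp)
    block_class <- matrix(sample.int(cfg$n_veg_classes, nbr * nbc,
                                     replace = TRUE), nbr, nbc)
    strata <- block_class[cbind(rep((seq_len(nr) - 1) %/% bp + 1, nc),
                                rep((seq_len(nc) - 1) %/% bp + 1,
                                    each = nr))]
    strata <- matrix(strata, nr, nc)
    # exact-q response: a * between-component + b * within-component
    mu <- stats::rnorm(cfg$n_veg_classes)
    mvec <- mu[as.vector(strata)]
    e <- stats::rnorm(npx)
    f <- factor(as.vector(strata))
    e <- e - stats::ave(e, f)              # centre noise within strata
    mvec <- mvec - mean(mvec)
    ssm <- sum(mvec^2); sse <- sum(e^2)
    qt <- cfg$strata_q_target
    a <- if (ssm > 0) sqrt(qt / ssm) else 0
    b <- if (sse > 0) sqrt((1 - qt) / sse) else 0
    resp_std <- a * mvec + b * e           # realized q is exactly qt
    response <- 150 + 60 * resp_std / stats::sd(resp_std)
    # smooth elevation: ramp + low-frequency random cosines
    rg <- south_gradient(cfg)
    cg <- matrix(rep((seq_len(nc) - 1) / max(nc - 1, 1), each = nr), nr, nc)
    elev <- 500 + 2200 * rg
    for (i in 1:4) {
      fr <- stats::runif(2, 0.5, 2.5); ph <- stats::runif(2, 0, 2 * pi)
      elev <- elev + 120 * cos(2 * pi * fr[1] * rg + ph[1]) *
        cos(2 * pi * fr[2] * cg + ph[2])
    }
    soil <- 0.15 + 0.05 * resp_std + stats::rnorm(npx, sd = 0.03)
    gdp <- exp(stats::rnorm(npx, mean = 3, sd = 0.6) + 1.5 * (1 - rg))
    pop <- exp(stats::rnorm(npx, mean = 2, sd = 0.5) + 1.2 * (1 - rg))
    list(strata = strata, response = response, elev = elev,
         soil = soil, gdp = gdp, pop = pop)
  })
  elev <- res$elev
  # finite-difference slope/aspect (degrees); edges replicated
  dzdx <- (elev[, c(2:nc, nc)] - elev[, c(1, 1:(nc - 1))]) /
    (2 * cfg$cellsize_m)
  dzdy <- (elev[c(1, 1:(nr - 1)), ] - elev[c(2:nr, nr), ]) /
    (2 * cfg$cellsize_m)  # y increases northward = decreasing row
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  aspect <- (atan2(dzdx, dzdy) * 180 / pi) %% 360
  list(vegtype = grid_like(tpl, res$strata),
       elevation = grid_like(tpl, elev),
       slope = grid_like(tpl, slope),
       aspect = grid_like(tpl, aspect),
       soil_moisture = grid_like(tpl, res$soil),
       gdp = grid_like(tpl, res$gdp),
       popdens = grid_like(tpl, res$pop),
       q_response = grid_like(tpl, res$response))
}

#' Generate an annual land-use series executing a transition plan
#'
#' Starts from the scenario's vegetation-type map (classes 1-6) and, for
#' each planned transition, converts exactly floor(area / pixel area)
#' pixels of the source class to the destination class from the epoch
#' year onward. Pixel choice is a seeded deterministic sample within the
#' source class, so the realized transition matrix equals the plan
#' exactly.
#'
#' @param cfg a [scenario_config()].
#' @param vegtype optional starting land-use [grid] (default: the
#'   scenario's vegetation-type layer).
#' @return annual categorical [raster_cube] over `cfg$years`.
#' @export
generate_landuse_series <- function(cfg, vegtype = NULL) {
  if (is.null(vegtype)) vegtype <- generate_static_layers(cfg)$vegtype
  tpl <- blank_grid(cfg)
  px_area <- cfg$cellsize_m^2 / 1e6
  lu <- vegtype$values
  plan <- cfg$transition_plan
  maps <- list()
  cur <- lu
  conversions <- with_seed(cfg$seed + 3L, {
    if (is.null(plan) || !nrow(plan)) list() else
      lapply(seq_len(nrow(plan)), function(i) {
        n_need <- floor(plan$area_km2[i] / px_area)
        src <- which(as.vector(lu) == plan$from[i])
        # pixels already claimed by earlier plan rows are unavailable
        src
        list(row = plan[i, ], n = n_need,
             order = sample(src, length(src)))
      })
  })
  claimed <- integer(0)
  for (ci in seq_along(conversions)) {
    cv <- conversions[[ci]]
    avail <- setdiff(cv$order, claimed)
    if (length(avail) < cv$n)
      stop("transition plan row ", ci, " requests ", cv$n,
           " pixels of class ", cv$row$from, " but only ", length(avail),
           " are available")
    conversions[[ci]]$pixels <- avail[seq_len(cv$n)]
    claimed <- c(claimed, conversions[[ci]]$pixels)
  }
  for (yi in seq_along(cfg$years)) {
    cur <- lu
    for (cv in conversions)
      if (cfg$years[yi] >= cv$row$epoch) cur[cv$pixels] <- cv$row$to
    maps[[yi]] <- grid_like(tpl, cur)
  }
  raster_cube(maps, cfg$years)
}

#' Generate the complete synthetic scenario
#'
#' Convenience wrapper running every generator under the config's seed
#' and returning all layers plus a ground-truth manifest.
#'
#' @param cfg a [scenario_config()].
#' @return list: `climate` (precip/temp/solrad/npp_response cubes),
#'   `ndvi` (monthly cube), `static` (static layer list), `landuse`
#'   (annual cube), `truth` (list of generator parameters a downstream
#'   stage should recover).
#' @export
generate_scenario <- function(cfg) {
  climate <- generate_climate_cubes(cfg)
  ndvi <- generate_ndvi_cube(cfg, climate$temp, climate$precip)
  static <- generate_static_layers(cfg)
  landuse <- generate_landuse_series(cfg, static$vegtype)
  truth <- list(partial_corr_targets = cfg$partial_corr_targets,
                npp_trend = cfg$npp_trend, ndvi_trend = cfg$ndvi_trend,
                strata_q_target = cfg$strata_q_target,
                strata_block_px = cfg$strata_block_px,
                transition_plan = cfg$transition_plan)
  list(climate = climate, ndvi = ndvi, static = static, landuse = landuse,
       truth = truth)
}
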