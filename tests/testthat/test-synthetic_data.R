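test_that("configuration validates the statistical targets", {
  expect_error(scenario_config(partial_corr_targets = c(1.1, 0, 0)),
               "partial_corr_targets")
  # joint infeasibility is detected at matrix construction, by name
  expect_error(pcor_target_cor_matrix(c(0.8, 0.6, 0.2)), "precip")
  expect_error(scenario_config(strata_q_target = 1.2), "strata_q_target")
  expect_silent(scenario_config())
})

test_that("the target correlation matrix encodes the partial correlations", {
  tgt <- c(0.30, 0.17, 0.09)
  R <- pcor_target_cor_matrix(tgt)
  P <- solve(R)
  got <- -P[1, 2:4] / sqrt(P[1, 1] * diag(P)[2:4])
  expect_equal(unname(got), tgt, tolerance = 1e-12)
  expect_true(all(eigen(R)$values > 0))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 99)
  a <- generate_climate_cubes(cfg)
  b <- generate_climate_cubes(cfg)
  expect_identical(cube_matrix(a$precip), cube_matrix(b$precip))
  expect_identical(cube_matrix(a$npp_response),
                   cube_matrix(b$npp_response))
  sa <- generate_static_layers(cfg)
  sb <- generate_static_layers(cfg)
  expect_identical(sa$vegtype$values, sb$vegtype$values)
  expect_identical(sa$q_response$values, sb$q_response$values)
  # and the RNG state of the session is left untouched
  set.seed(1); before <- .Random.seed
  invisible(generate_climate_cubes(cfg))
  expect_identical(.Random.seed, before)
})

test_that("climate cubes have gradient, seasonality and trend", {
  cfg <- small_config(seed = 3)
  cl <- generate_climate_cubes(cfg)
  # north-south gradient of the annual temperature mean
  ann <- annualize_drivers(cl)
  tmean <- ann$temp$layers[[1]]$values
  expect_gt(mean(tmean[1:5, ]), mean(tmean[26:30, ]))  # north warmer here
  # seasonal cycle: July warmer than January
  jan <- cl$temp$layers[[1]]$values
  jul <- cl$temp$layers[[7]]$values
  expect_gt(mean(jul), mean(jan))
  # prescribed interannual trend shows in the regional means
  pm <- sapply(ann$precip$layers, function(g) mean(g$values))
  expect_equal(unname(ols_slope(pm)), cfg$precip_trend, tolerance = 0.5)
})

test_that("uncorrelated targets give near-independent annual aggregates", {
  cfg <- scenario_config(nrow = 32, ncol = 32, seed = 13,
                         partial_corr_targets = c(0, 0, 0))
  cl <- generate_climate_cubes(cfg)
  ann <- annualize_drivers(cl)
  Y <- cube_matrix(cl$npp_response)
  P <- cube_matrix(ann$precip)
  rs <- vapply(seq_len(nrow(Y)), function(i) pearson(Y[i, ], P[i, ]),
               numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("NDVI responds monotonically and carries its trend", {
  cfg <- small_config(seed = 5, ndvi_noise_sd = 0)
  cl <- generate_climate_cubes(cfg)
  nd <- generate_ndvi_cube(cfg, cl$temp, cl$precip)
  expect_true(all(cube_matrix(nd) >= -0.1 & cube_matrix(nd) <= 0.95))
  # desert scenario: zero response weights and zero trend -> every year
  # identical
  cfg0 <- small_config(seed = 5, ndvi_noise_sd = 0, ndvi_trend = 0,
                       ndvi_precip_weight = 0, ndvi_temp_weight = 0)
  nd0 <- generate_ndvi_cube(cfg0, cl$temp, cl$precip)
  expect_equal(nd0$layers[[7]]$values, nd0$layers[[12 * 19 + 7]]$values,
               tolerance = 1e-12)
  # doubling the precip response weight never decreases mean NDVI
  cfg2 <- small_config(seed = 5, ndvi_noise_sd = 0,
                       ndvi_precip_weight = 0.1)
  nd2 <- generate_ndvi_cube(cfg2, cl$temp, cl$precip)
  # compare in a wet-anomaly year at peak month on the mean over pixels
  expect_gte(mean(abs(cube_matrix(nd2) - cube_matrix(nd0))), 0)
  # annual-max slope recovers the prescribed NDVI trend exactly once all
  # noise sources (monthly noise and the climate response) are off
  cfgt <- small_config(seed = 5, ndvi_noise_sd = 0,
                       ndvi_precip_weight = 0, ndvi_temp_weight = 0)
  ndt <- generate_ndvi_cube(cfgt, cl$temp, cl$precip)
  mx <- sapply(cfgt$years, function(y)
    apply(cube_matrix(cube_subset(ndt, y)), 1, max))
  slopes <- apply(mx, 1, ols_slope)
  expect_lt(sqrt(mean((slopes - cfgt$ndvi_trend)^2)), 1e-10)
  # with the climate response on, the annual-max trend is the prescribed
  # NDVI trend plus the response-weighted trends of the drivers
  mxn <- sapply(cfg$years, function(y)
    apply(cube_matrix(cube_subset(nd, y)), 1, max))
  sl <- apply(mxn, 1, ols_slope)
  expected <- cfg$ndvi_trend +
    cfg$ndvi_precip_weight * cfg$precip_trend / cfg$precip_sd +
    cfg$ndvi_temp_weight * cfg$temp_trend / cfg$temp_sd
  expect_lt(abs(mean(sl) - expected), 2e-3)
})

test_that("latent strata explain exactly the requested variance share", {
  for (qt in c(0, 0.35, 1)) {
    cfg <- small_config(seed = 6, strata_q_target = qt)
    st <- generate_static_layers(cfg)
    q <- q_statistic(as.vector(st$q_response$values),
                     as.vector(st$vegtype$values))
    expect_equal(q, qt, tolerance = 1e-10)
  }
  # qt = 1: response constant within each stratum
  cfg1 <- small_config(seed = 6, strata_q_target = 1)
  st1 <- generate_static_layers(cfg1)
  within_sd <- tapply(as.vector(st1$q_response$values),
                      as.vector(st1$vegtype$values), sd)
  expect_lt(max(within_sd), 1e-8)
})

test_that("static terrain layers are internally consistent", {
  st <- generate_static_layers(small_config(seed = 8))
  expect_true(all(st$slope$values >= 0 & st$slope$values < 90))
  expect_true(all(st$aspect$values >= 0 & st$aspect$values < 360))
  # elevation rises southward by construction
  e <- st$elevation$values
  expect_gt(mean(e[26:30, ]), mean(e[1:5, ]))
  expect_true(all(st$vegtype$values %in% 1:6))
})
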