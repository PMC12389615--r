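veg1 <- function(nr = 1, nc = 1) tiny_grid(matrix(3, nr, nc))  # grassland

test_that("simple ratio transform matches direct evaluation", {
  nd <- tiny_grid(matrix(c(0, 0.5, -0.2), 1, 3))
  sr <- sr_index(nd)
  expect_equal(as.vector(sr$values), c(1, 3, 0.8 / 1.2),
               tolerance = 1e-12)  # (1 - 0.2)/(1 + 0.2)
  # clipping keeps the transform finite at NDVI -> 1
  expect_true(is.finite(sr_index(tiny_grid(matrix(0.9999, 1, 1)))$values))
})

test_that("FPAR rescales hit the documented endpoints and midpoint", {
  p <- default_veg_params()
  pr <- p[p$class_id == 3, ]
  nd <- tiny_grid(matrix(c(pr$ndvi_min, pr$ndvi_max,
                           (pr$ndvi_min + pr$ndvi_max) / 2, -0.05), 1, 4))
  f <- fpar_from_ndvi(nd, veg1(1, 4), p)
  expect_equal(as.vector(f$values),
               c(0.001, 0.95, (0.95 + 0.001) / 2, 0.001),
               tolerance = 1e-12)
  sr <- tiny_grid(matrix(c(pr$sr_min, pr$sr_max,
                           (pr$sr_min + pr$sr_max) / 2), 1, 3))
  fs <- fpar_from_sr(sr, veg1(1, 3), p)
  expect_equal(as.vector(fs$values), c(0.001, 0.95, (0.95 + 0.001) / 2),
               tolerance = 1e-12)
  # FPAR clipped into [0.001, 0.95] for any NDVI
  wild <- fpar_from_ndvi(tiny_grid(matrix(seq(-1, 1, length = 16), 4, 4)),
                         veg1(4, 4), p)
  expect_true(all(wild$values >= 0.001 & wild$values <= 0.95))
  expect_error(fpar_from_ndvi(nd, tiny_grid(matrix(99, 1, 4)), p),
               "99")
})

test_that("combined FPAR is the mean and APAR is linear in SOL", {
  a <- const_grid(0.001); b <- const_grid(0.95)
  expect_equal(fpar_combined(a, b)$values[1, 1], 0.4755)
  expect_identical(fpar_combined(a, a)$values, a$values)
  f <- const_grid(0.5); s <- const_grid(100)
  expect_equal(apar(f, s)$values[1, 1], 25)
  expect_equal(apar(f, grid_map2(s, 2, `*`))$values[1, 1], 50)
  expect_equal(apar(f, const_grid(0))$values[1, 1], 0)
  expect_error(apar(f, const_grid(-1)), "negative")
})

test_that("optimal temperature picks the NDVI-peak month (earliest tie)", {
  nr <- 1; nc <- 2
  mk_cube <- function(vals_by_month) {
    layers <- list(); yy <- integer(0); mm <- integer(0)
    for (y in 1:2) for (m in 1:12) {
      layers[[length(layers) + 1L]] <- tiny_grid(
        matrix(vals_by_month[[m]], nr, nc))
      yy <- c(yy, 2000L + y); mm <- c(mm, m)
    }
    raster_cube(layers, yy, mm)
  }
  ndvi_m <- as.list(c(rep(0.1, 6), 0.8, rep(0.1, 5)))   # July peak
  temp_m <- as.list(1:12 * 2)
  topt <- optimal_temperature(mk_cube(ndvi_m), mk_cube(temp_m))
  expect_equal(as.vector(topt$values), c(14, 14))  # July temp
  # constant NDVI: tie-break to month 1
  flat <- optimal_temperature(mk_cube(as.list(rep(0.3, 12))),
                              mk_cube(temp_m))
  expect_equal(flat$values[1, 1], 2)
})

test_that("temperature stress matches the adopted closed forms", {
  topt <- const_grid(20)
  ts <- temperature_stress(topt, const_grid(20))
  expect_equal(ts$t1$values[1, 1], 0.8 + 0.4 - 0.2, tolerance = 1e-12)
  expect_equal(ts$t2$values[1, 1],
               1.1814 / ((1 + exp(-2)) * (1 + exp(-3))),
               tolerance = 1e-12)
  # deep-frost shutdown and the nonnegativity floor
  frost <- temperature_stress(topt, const_grid(-30))
  expect_equal(frost$t1$values[1, 1], 0)
  cold_opt <- temperature_stress(const_grid(-50), const_grid(5))
  expect_equal(cold_opt$t1$values[1, 1], 0)
})

test_that("water stress is bounded and hits its analytic limits", {
  yrs <- rep(2001L, 12); mos <- 1:12
  mk <- function(x) raster_cube(lapply(1:12, function(i)
    const_grid(x[i], 1, 1)), yrs, mos)
  # wet warm months: We approaches 1; bone-dry months: floor 0.5
  wet <- water_stress(mk(rep(120, 12)), mk(rep(18, 12)))
  expect_true(all(wet$layers[[7]]$values >= 0.5 &
                    wet$layers[[7]]$values <= 1))
  dry <- water_stress(mk(rep(0, 12)), mk(rep(18, 12)))
  expect_equal(dry$layers[[7]]$values[1, 1], 0.5)
  frozen <- water_stress(mk(rep(10, 12)), mk(rep(-15, 12)))
  expect_equal(frozen$layers[[1]]$values[1, 1], 0.5)  # Ep = 0 fallback
  # monotone: more precipitation never dries the stress term
  w1 <- water_stress(mk(rep(30, 12)), mk(rep(15, 12)))
  w2 <- water_stress(mk(rep(90, 12)), mk(rep(15, 12)))
  expect_true(all(w2$layers[[6]]$values >= w1$layers[[6]]$values - 1e-12))
})

test_that("monthly NPP composes the factors and annual NPP sums 12 months", {
  p <- default_veg_params()
  f <- const_grid(0.95); s <- const_grid(100)
  one <- const_grid(1)
  npp <- monthly_npp(apar(f, s), one, one, one, veg1(4, 4), p)
  expect_equal(npp$values[1, 1], 0.95 * 100 * 0.5 * 0.542,
               tolerance = 1e-12)
  # halving eps_max halves NPP
  p2 <- p; p2$eps_max <- p2$eps_max / 2
  expect_equal(monthly_npp(apar(f, s), one, one, one, veg1(4, 4),
                           p2)$values[1, 1], npp$values[1, 1] / 2)
  # SOL = 0 month gives exactly zero NPP
  expect_true(all(monthly_npp(apar(f, const_grid(0)), one, one, one,
                              veg1(4, 4), p)$values == 0))
  # annual total = sum of months, invariant to month order
  vals <- rnorm(12, 10, 2)
  mk_ann <- function(v) raster_cube(lapply(v, const_grid),
                                    rep(2001L, 12), 1:12)
  expect_equal(annual_npp(mk_ann(vals))$values[1, 1], sum(vals))
  expect_error(annual_npp(raster_cube(lapply(1:3, const_grid),
                                      rep(2001L, 3), 1:3)), "12")
})

test_that("regional totals convert to TgC by the hand-summed 3x3 fixture", {
  v <- matrix(c(100, 200, 300, 0, 50, NA, 10, 20, 30), 3, 3)
  g <- tiny_grid(v, cellsize = 500)
  s <- regional_npp_summary(g)
  expect_equal(s$total_TgC, sum(v, na.rm = TRUE) * 500^2 * 1e-12)
  expect_equal(s$mean_gC_m2, mean(v, na.rm = TRUE))
})

test_that("full CASA chain returns nonnegative NPP over a small scenario", {
  cfg <- small_config(seed = 5)
  sc <- generate_scenario(cfg)
  out <- casa_npp(sc$ndvi, sc$climate$solrad, sc$climate$temp,
                  sc$climate$precip, sc$static$vegtype)
  expect_equal(length(out$annual), length(cfg$years))
  expect_true(all(out$annual$layers[[1]]$values >= 0, na.rm = TRUE))
  expect_equal(out$annual$layers[[3]]$values,
               annual_npp(cube_subset(out$monthly,
                                      cfg$years[3]))$values)
})
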