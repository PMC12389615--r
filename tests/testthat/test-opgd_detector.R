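test_that("q-statistic equals the brute-force variance decomposition", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(c(50, 200, 500), 1)
    y <- rnorm(n); s <- sample(1:6, n, replace = TRUE)
    expect_equal(q_statistic(y, s), q_bruteforce(y, s),
                 tolerance = 1e-12)
  }
  # single stratum: q = 0; constant-within-strata: q = 1
  y <- rnorm(30)
  expect_equal(q_statistic(y, rep(1, 30)), 0)
  ystep <- rep(c(1, 5, 9), each = 10)
  expect_equal(q_statistic(ystep, rep(1:3, each = 10)), 1)
  expect_error(q_statistic(rep(2, 10), rep(1:2, 5)), "variance is zero")
  # affine invariance of q
  s <- sample(1:4, 100, replace = TRUE); y <- rnorm(100)
  expect_equal(q_statistic(y, s), q_statistic(-3.2 * y + 7, s),
               tolerance = 1e-12)
  # exact SST = SSW + SSB reconstruction
  st <- casanpp:::stratified_stats(y, s)
  ssb <- sum(st$n_h * (st$mean_h - mean(y))^2)
  expect_equal(st$ssw + ssb, st$sst, tolerance = 1e-10)
})

test_that("small strata are dropped with a message", {
  y <- c(rnorm(20), 5)
  s <- c(rep(1:2, 10), 99)
  expect_message(q_statistic(y, s), "dropping")
})

test_that("q significance is monotone and calibrated at the edges", {
  y <- rnorm(100); s <- rep(1:4, 25)
  r <- suppressMessages(q_significance(y, s))
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  # strong signal: tiny p
  ysig <- rep(c(0, 10), each = 50) + rnorm(100, sd = 0.1)
  rs <- q_significance(ysig, rep(c(1, 2), each = 50))
  expect_lt(rs$p_value, 1e-6)
  # q -> p monotone at fixed N, L (central F mode)
  p_of <- function(shift) {
    yy <- rep(c(0, shift), each = 50) + rnorm(100, sd = 1)
    q_significance(yy, rep(c(1, 2), each = 50), central = TRUE)$p_value
  }
  set.seed(5)
  expect_lt(p_of(3), p_of(0.2))
})

test_that("discretization methods produce their documented edges", {
  # equal interval on [0, 10], k = 5
  lab <- discretize(seq(0, 10, length = 101), "equal_interval", 5)
  expect_equal(attr(lab, "edges"), seq(0, 10, by = 2))
  # quantile on 100 distinct uniforms: 25 per bin
  set.seed(44)
  x <- runif(100)
  labq <- discretize(x, "quantile", 4)
  expect_true(all(table(labq) == 25))
  # natural breaks split the obvious two clusters
  labj <- discretize(c(1, 1, 1, 9, 9, 9), "natural_breaks", 2)
  expect_equal(as.vector(table(labj)), c(3, 3))
  e <- attr(labj, "edges")
  expect_true(e[2] > 1 && e[2] < 9)
  # geometric interval edges are a geometric progression on positives
  labg <- discretize(exp(seq(0, 4, length = 50)), "geometric_interval", 4)
  eg <- attr(labg, "edges")
  expect_equal(diff(log(eg)), rep(diff(log(eg))[1], 4), tolerance = 1e-9)
  # std_dev cuts at mean +/- s*sd
  xs <- rnorm(1000)
  labs_ <- discretize(xs, "std_dev", 4)
  expect_equal(attr(labs_, "edges")[2:4],
               mean(xs) + sd(xs) * c(-1, 0, 1), tolerance = 1e-12)
  expect_warning(discretize(rep(2, 10), "quantile", 3), "constant")
  # bins are left-closed right-open, last closed
  lab2 <- discretize(c(0, 2, 4, 6, 8, 10), "equal_interval", 5)
  expect_equal(as.integer(lab2), c(1L, 2L, 3L, 4L, 5L, 5L))
})

test_that("Jenks DP equals exhaustive search over split points", {
  sse_of <- function(v) sum((v - mean(v))^2)
  set.seed(45)
  for (i in 1:10) {
    x <- sort(c(rnorm(8), rnorm(7, 6)))
    # exhaustive k = 2: best single split
    best <- Inf
    for (s in 1:(length(x) - 1))
      best <- min(best, sse_of(x[1:s]) + sse_of(x[(s + 1):length(x)]))
    e <- jenks_breaks(x, 2)
    got <- sse_of(x[x < e[2]]) + sse_of(x[x >= e[2]])
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("optimal discretization recovers a 3-level step construction", {
  set.seed(46)
  # three well-separated x clusters, y an exact 3-level step of cluster:
  # every k = 3 method that isolates the clusters reaches q = 1, and the
  # fewer-bins tie-break settles on k = 3
  cl <- sample(1:3, 600, replace = TRUE)
  x <- c(0.1, 0.5, 0.9)[cl] + runif(600, -0.02, 0.02)
  y <- c(10, 20, 40)[cl]
  opt <- optimize_discretization(y, x)
  expect_equal(opt$best_k, 3)
  expect_gt(opt$q, 0.99)
  # returned q equals direct q of the returned labelling
  expect_equal(opt$q, suppressMessages(q_statistic(y, opt$labels)),
               tolerance = 1e-12)
  # independence: all q small, tie-break yields small k
  ynull <- rnorm(600)
  optn <- optimize_discretization(ynull, x)
  expect_lt(optn$q, 0.05)
})

test_that("null calibration: E[q] is about (L-1)/(N-1)", {
  set.seed(47)
  L <- 5; N <- 200
  qs <- replicate(400, q_statistic(rnorm(N), sample(1:L, N, TRUE)))
  se <- sd(qs) / sqrt(length(qs))
  expect_lt(abs(mean(qs) - (L - 1) / (N - 1)), 4 * se + 0.002)
})

test_that("interaction detector categorizes against the q1+q2 benchmark", {
  set.seed(48)
  n <- 1200
  a <- sample(1:3, n, TRUE); b <- sample(1:3, n, TRUE)
  # additive independent construction: q12 near q1 + q2
  y <- c(0, 2, 4)[a] + c(0, 3, 6)[b] + rnorm(n, sd = 0.8)
  r <- interaction_detector(y, a, b)
  expect_gte(r$q12, max(r$q1, r$q2))
  expect_lt(abs(r$q12 - (r$q1 + r$q2)), 0.05)
  expect_true(r$category %in% c("bifactor_enhance", "independent",
                                "nonlinear_enhance"))
  # intersection with a single-stratum factor is the identity (edge case)
  expect_message(r1 <- interaction_detector(y, a, rep(1L, n)),
                 "edge case")
  expect_equal(r1$q12, r1$q1, tolerance = 1e-12)
  # refinement monotonicity on random instances without dropped strata
  viol <- 0
  for (i in 1:100) {
    yy <- rnorm(300)
    aa <- sample(1:3, 300, TRUE); bb <- sample(1:4, 300, TRUE)
    rr <- interaction_detector(yy, aa, bb)
    if (rr$q12 < max(rr$q1, rr$q2) - 1e-12) viol <- viol + 1
  }
  expect_equal(viol, 0)
})

test_that("scale selection and factor detection recover injected strata", {
  cfg <- scenario_config(nrow = 60, ncol = 60, seed = 9,
                         strata_q_target = 0.6, strata_block_px = 8L)
  st <- generate_static_layers(cfg)
  factors <- list(vegtype = st$vegtype, soil = st$soil_moisture,
                  elev = st$elevation)
  types <- c(vegtype = "categorical", soil = "continuous",
             elev = "continuous")
  sel <- select_scale(st$q_response, factors, types,
                      scales_px = c(4L, 8L, 12L),
                      scale_labels = c(2, 4, 6))
  expect_equal(sel$best_px, 8L)  # the injected block scale
  samples <- detector_samples(st$q_response, factors, types, sel$best_px)
  det <- factor_detector(samples, types)
  expect_identical(det$factor[1], "vegtype")
  expect_gt(det$q[1], 0.9)
  expect_true(all(det$q >= 0 & det$q <= 1))
  # a factor that exactly reproduces a discrete response scores q = 1
  ystep <- rep(c(10, 20, 30), each = 50)
  dfc <- data.frame(y = ystep, copy = ystep)
  det2 <- factor_detector(dfc, c(copy = "categorical"))
  expect_equal(det2$q[1], 1)
  im <- interaction_matrix(samples, det)
  expect_true(all(im$category %in% INTERACTION_CATEGORIES))
  expect_true(all(im$q12 <= 1 & im$q12 >= 0))
})
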