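# Small in-code fixtures shared across the suite.

tiny_grid <- function(values, cellsize = 500) {
  grid(values, xll = 0, yll = 0, cellsize = cellsize,
       crs = "World_Mercator")
}

const_grid <- function(x, nr = 4, nc = 4, cellsize = 500) {
  tiny_grid(matrix(x, nr, nc), cellsize)
}

# annual cube from a pixels-x-years matrix of values
cube_from_matrix <- function(m, nr, nc, years = NULL, cellsize = 500) {
  if (is.null(years)) years <- seq_len(ncol(m)) + 2000L
  raster_cube(lapply(seq_len(ncol(m)), function(j)
    tiny_grid(matrix(m[, j], nr, nc), cellsize)), years)
}

# small, fast scenario used where full size is not needed
small_config <- function(seed = 1, ...) {
  args <- list(...)
  if (!("transition_plan" %in% names(args)))
    args$transition_plan <- data.frame(from = 3L, to = 1L, area_km2 = 25,
                                       epoch = 2010L)
  do.call(scenario_config,
          c(list(nrow = 30, ncol = 30, seed = seed), args))
}

# independent oracle: partial correlation from the precision matrix of
# the 4x4 correlation matrix (r_ij = -p_ij / sqrt(p_ii p_jj))
pcor_precision_oracle <- function(y, x1, x2, x3) {
  R <- stats::cor(cbind(y, x1, x2, x3))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# independent oracle: q as 1 - SSW/SST by explicit group-by
q_bruteforce <- function(y, strata) {
  sst <- sum((y - mean(y))^2)
  ssw <- sum(unlist(lapply(split(y, strata),
                           function(v) sum((v - mean(v))^2))))
  1 - ssw / sst
}

# independent oracle: Mann-Kendall S by explicit pair enumeration
mk_s_bruteforce <- function(y) {
  n <- length(y); s <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) s <- s + sign(y[j] - y[i])
  s
}
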