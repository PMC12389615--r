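#' Pearson product-moment correlation
#'
#' Thin, contract-checked wrapper used by the partial-correlation
#' recursion: requires n >= 3 paired finite values and nonzero variance in
#' both series, returning `NA` otherwise (a masked pixel downstream).
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in \[-1, 1\] or `NA`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

first_order_pcor <- function(r_ab, r_ac, r_bc) {
  den <- sqrt((1 - r_ac^2) * (1 - r_bc^2))
  if (!is.finite(den) || den == 0) return(NA_real_)
  (r_ab - r_ac * r_bc) / den
}

#' Second-order partial correlation by the first-order recursion
#'
#' R_y1.23 = (R_y1.2 - R_y3.2 R_13.2) / sqrt((1 - R_y3.2^2)(1 - R_13.2^2)),
#' where each first-order coefficient is itself built from the pairwise
#' Pearson correlations. Perfectly collinear controls make an intermediate
#' denominator vanish and yield `NA`.
#'
#' @param y response series; `x1` target factor; `x2`, `x3` controls.
#' @return partial correlation of y and x1 given (x2, x3), or `NA`.
#' @export
partial_cor2 <- function(y, x1, x2, x3) {
  ok <- is.finite(y) & is.finite(x1) & is.finite(x2) & is.finite(x3)
  if (sum(ok) < 5L) return(NA_real_)
  y <- y[ok]; x1 <- x1[ok]; x2 <- x2[ok]; x3 <- x3[ok]
  r_y1 <- pearson(y, x1); r_y2 <- pearson(y, x2); r_y3 <- pearson(y, x3)
  r_12 <- pearson(x1, x2); r_13 <- pearson(x1, x3); r_23 <- pearson(x2, x3)
  if (anyNA(c(r_y1, r_y2, r_y3, r_12, r_13, r_23))) return(NA_real_)
  ry1_2 <- first_order_pcor(r_y1, r_y2, r_12)
  ry3_2 <- first_order_pcor(r_y3, r_y2, r_23)
  r13_2 <- first_order_pcor(r_13, r_12, r_23)
  if (anyNA(c(ry1_2, ry3_2, r13_2))) return(NA_real_)
  first_order_pcor(ry1_2, ry3_2, r13_2)
}

#' Pixelwise partial correlation of annual NPP with three climate drivers
#'
#' For each pixel, correlates the n-year NPP series with each driver while
#' controlling for the other two (second-order partial correlation). Also
#' reports two regional summaries: the mean of the per-pixel coefficients
#' and the partial correlation of the regional-mean series (the two
#' readings of a single "regional coefficient").
#'
#' @param npp_cube annual NPP [raster_cube].
#' @param precip_cube,temp_cube,solrad_cube annual driver cubes on the
#'   same years.
#' @return list: `r` (named list of grids precip/temp/solrad), `n_years`,
#'   `regional_mean_r`, `regional_series_r`.
#' @export
pixelwise_partial_cor <- function(npp_cube, precip_cube, temp_cube,
                                  solrad_cube) {
  n <- length(npp_cube)
  if (length(precip_cube) != n || length(temp_cube) != n ||
      length(solrad_cube) != n)
    stop("all cubes must cover the same years")
  Y <- cube_matrix(npp_cube)
  X <- list(precip = cube_matrix(precip_cube),
            temp = cube_matrix(temp_cube),
            solrad = cube_matrix(solrad_cube))
  order3 <- list(precip = c("precip", "temp", "solrad"),
                 temp = c("temp", "precip", "solrad"),
                 solrad = c("solrad", "precip", "temp"))
  tpl <- cube_template(npp_cube)
  rgrids <- list(); rmean <- c(); rser <- c()
  for (f in names(order3)) {
    o <- order3[[f]]
    rv <- vapply(seq_len(nrow(Y)), function(p)
      partial_cor2(Y[p, ], X[[o[1]]][p, ], X[[o[2]]][p, ], X[[o[3]]][p, ]),
      numeric(1))
    rgrids[[f]] <- grid_like(tpl, rv)
    rmean[f] <- mean(rv, na.rm = TRUE)
    rser[f] <- partial_cor2(colMeans(Y, na.rm = TRUE),
                            colMeans(X[[o[1]]], na.rm = TRUE),
                            colMeans(X[[o[2]]], na.rm = TRUE),
                            colMeans(X[[o[3]]], na.rm = TRUE))
  }
  list(r = rgrids, n_years = n, regional_mean_r = rmean,
       regional_series_r = rser)
}

#' Significance classes for partial-correlation maps
#' @export
PCOR_CLASSES <- c("SNC", "NSNC", "NSPC", "SPC")

#' Classify partial-correlation significance (four-way map legend)
#'
#' t = r sqrt((n - 2 - k)/(1 - r^2)) with k = 2 controls, df = n - 4,
#' two-sided p. Classes: SPC significant positive, NSPC nonsignificant
#' positive, SNC significant negative, NSNC nonsignificant negative
#' (r = 0 counts as nonsignificant positive; |r| = 1 is significant by
#' convention).
#'
#' @param r a [grid] (or numeric vector) of partial correlations.
#' @param n_years series length per pixel.
#' @param alpha significance level (default 0.05).
#' @return same shape as `r`: codes 1-4 in the order SNC, NSNC, NSPC, SPC
#'   when `r` is a grid (with `class_labels` attribute), labels when a
#'   vector.
#' @export
classify_pcor_significance <- function(r, n_years, alpha = 0.05) {
  k <- 2L
  df <- n_years - 2L - k
  if (df < 1L) stop("need n_years > ", 2L + k, " for the t-test")
  val <- if (inherits(r, "grid")) r$values else r
  p <- rep(NA_real_, length(val))
  ok <- is.finite(val)
  tstat <- abs(val[ok]) * sqrt(df / pmax(1 - val[ok]^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(tstat, df, lower.tail = FALSE)
  p[ok & abs(val) >= 1] <- 0
  lab <- rep(NA_character_, length(val))
  lab[ok & val < 0 & p < alpha] <- "SNC"
  lab[ok & val < 0 & p >= alpha] <- "NSNC"
  lab[ok & val >= 0 & p >= alpha] <- "NSPC"
  lab[ok & val >= 0 & p < alpha] <- "SPC"
  if (inherits(r, "grid")) {
    g <- grid_like(r, match(lab, PCOR_CLASSES))
    attr(g, "class_labels") <- PCOR_CLASSES
    g
  } else lab
}
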