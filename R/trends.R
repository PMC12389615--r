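#' Closed-form OLS slope against time index 1..n
#'
#' slope = (n * sum(i * y_i) - sum(i) * sum(y_i)) /
#'         (n * sum(i^2) - (sum i)^2)
#'
#' @param series numeric vector (one pixel's annual values, time-ordered).
#' @return slope per time step; `NA` if fewer than 3 finite values.
#' @export
ols_slope <- function(series) {
  y <- as.numeric(series)
  if (sum(is.finite(y)) < 3L || anyNA(y)) return(NA_real_)
  n <- length(y)
  i <- seq_len(n)
  (n * sum(i * y) - sum(i) * sum(y)) / (n * sum(i^2) - sum(i)^2)
}

#' Mann-Kendall trend statistics
#'
#' S is the sum over all ordered pairs (i < j) of sign(y_j - y_i).
#' Var(S) uses the standard tie-corrected form
#' \[n(n-1)(2n+5) - sum_g t_g (t_g - 1)(2 t_g + 5)\] / 18 over tie groups
#' g of size t_g, and Z is the three-branch standardized statistic
#' ((S - 1)/sqrt(Var) if S > 0, 0 if S = 0, (S + 1)/sqrt(Var) if S < 0).
#'
#' @param series numeric vector, length >= 4.
#' @return list with `S`, `varS`, `Z`.
#' @export
mann_kendall <- function(series) {
  y <- as.numeric(series)
  n <- length(y)
  if (n < 4L) stop("Mann-Kendall needs n >= 4")
  if (anyNA(y)) return(list(S = NA_integer_, varS = NA_real_, Z = NA_real_))
  s <- 0L
  for (i in seq_len(n - 1L))
    s <- s + sum(sign(y[(i + 1L):n] - y[i]))
  ties <- table(y)
  ties <- ties[ties > 1L]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (s > 0) (s - 1) / sqrt(varS)
  else if (s < 0) (s + 1) / sqrt(varS)
  else 0
  if (!is.finite(z)) z <- 0  # all-equal series: varS = 0, S = 0
  list(S = as.integer(s), varS = varS, Z = z)
}

#' Five-class trend significance labels
#' @export
TREND_CLASSES <- c("ESR", "SR", "NSC", "SI", "ESI")

#' Classify a (slope, Z) pair into the five-class trend scheme
#'
#' ESR: slope < 0 and Z < -2.58; SR: slope < 0 and -2.58 <= Z < -1.96;
#' NSC: |Z| <= 1.96; SI: slope > 0 and 1.96 < Z <= 2.58; ESI: slope > 0
#' and Z > 2.58. Sign-inconsistent combinations (significant Z with an
#' opposite-sign or zero slope, possible with ties) fall back to NSC, the
#' only class defined without a slope-sign condition.
#'
#' @param slope,z numeric scalars or vectors.
#' @return character vector of class labels.
#' @export
classify_trend <- function(slope, z) {
  out <- rep(NA_character_, length(slope))
  ok <- is.finite(slope) & is.finite(z)
  cl <- rep("NSC", sum(ok))
  s <- slope[ok]; zz <- z[ok]
  cl[s < 0 & zz < -2.58] <- "ESR"
  cl[s < 0 & zz >= -2.58 & zz < -1.96] <- "SR"
  cl[s > 0 & zz > 1.96 & zz <= 2.58] <- "SI"
  cl[s > 0 & zz > 2.58] <- "ESI"
  out[ok] <- cl
  out
}

#' Per-pixel trend and Mann-Kendall significance maps
#'
#' @param annual_cube annual NPP [raster_cube] (n years >= 4).
#' @return list of grids `slope`, `z`, plus `class` ([grid] coded 1-5 in
#'   the order ESR, SR, NSC, SI, ESI) and `class_labels`.
#' @export
trend_map <- function(annual_cube) {
  m <- cube_matrix(annual_cube)
  slope <- apply(m, 1L, ols_slope)
  z <- apply(m, 1L, function(y) {
    if (anyNA(y)) return(NA_real_)
    mann_kendall(y)$Z
  })
  lab <- classify_trend(slope, z)
  code <- match(lab, TREND_CLASSES)
  tpl <- cube_template(annual_cube)
  list(slope = grid_like(tpl, slope), z = grid_like(tpl, z),
       class = grid_like(tpl, code), class_labels = TREND_CLASSES)
}

#' NPP grade boundaries (gC m-2 yr-1)
#' @export
NPP_GRADE_EDGES <- c(0, 100, 200, 300, 400, Inf)

#' Area proportion of each NPP grade
#'
#' Grades are the half-open intervals \[0,100), \[100,200), \[200,300),
#' \[300,400) and \[400, Inf) gC m-2 yr-1; a value exactly on an edge
#' counts in the upper grade. Proportions are over unmasked pixels and sum
#' to 1.
#'
#' @param npp annual NPP [grid].
#' @return named numeric vector of 5 proportions.
#' @export
grade_proportions <- function(npp) {
  v <- npp$values[!is.na(npp$values)]
  if (!length(v)) stop("empty grid: no unmasked pixels")
  b <- cut(v, NPP_GRADE_EDGES, right = FALSE,
           labels = c("0-100", "100-200", "200-300", "300-400", ">400"),
           include.lowest = TRUE)
  tab <- table(b) / length(v)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Scalar summary of an annual-mean series
#'
#' Reports the headline numbers used to describe a regional NPP record:
#' endpoints, mean, extremes, relative change 100 (last - first)/first in
#' percent, the max-above-mean and mean-above-min anomalies, OLS slope,
#' and the slope's R-squared and p-value.
#'
#' @param annual_means numeric vector (length >= 2) of yearly regional
#'   means.
#' @return named list.
#' @export
series_summary <- function(annual_means) {
  y <- as.numeric(annual_means)
  if (length(y) < 2L) stop("need at least two annual values")
  n <- length(y)
  first <- y[1]; last <- y[n]
  rel <- if (first == 0) NA_real_ else 100 * (last - first) / first
  slope <- ols_slope(y)
  r2 <- NA_real_; p <- NA_real_
  if (n >= 3L && stats::sd(y) > 0) {
    fit <- stats::lm(y ~ seq_len(n))
    sm <- summary(fit)
    r2 <- sm$r.squared
    p <- sm$coefficients[2, 4]
  }
  list(first = first, last = last, mean = mean(y), max = max(y),
       min = min(y), relative_change_pct = rel,
       max_minus_mean = max(y) - mean(y),
       mean_minus_min = mean(y) - min(y),
       slope = slope, r_squared = r2, p_value = p)
}
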