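#' Geodetector q-statistic
#'
#' q = 1 - sum_h N_h sigma2_h / (N sigma2): one minus the ratio of the
#' within-stratum to the total variance of the response over a spatial
#' stratification. Population (denominator-N) variances are used so that
#' the decomposition SST = SSW + SSB is exact and q is exactly the
#' between-strata variance share. Strata with fewer than `min_stratum`
#' samples are dropped from both numerator and denominator (with a
#' message), the only mechanism by which interaction "weakening" can
#' occur.
#'
#' @param y numeric response values.
#' @param strata stratum labels (any atomic type); NA pairs are dropped.
#' @param min_stratum minimum samples per retained stratum (default 2).
#' @return q in \[0, 1\].
#' @export
q_statistic <- function(y, strata, min_stratum = 2L) {
  stratified_stats(y, strata, min_stratum)$q
}

stratified_stats <- function(y, strata, min_stratum = 2L) {
  ok <- is.finite(y) & !is.na(strata)
  y <- y[ok]; strata <- strata[ok]
  sizes <- table(strata)
  drop <- names(sizes)[sizes < min_stratum]
  if (length(drop)) {
    message("q_statistic: dropping ", length(drop),
            " stratum/strata with < ", min_stratum, " samples")
    keep <- !(strata %in% drop)
    y <- y[keep]; strata <- strata[keep]
  }
  N <- length(y)
  if (N < 2L) stop("q-statistic needs at least 2 samples after filtering")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("q-statistic undefined: response variance is zero")
  f <- factor(strata)
  nh <- as.numeric(table(f))
  mh <- as.numeric(tapply(y, f, mean))
  ssw <- sum(tapply(y, f, function(v) sum((v - mean(v))^2)))
  list(q = 1 - ssw / sst, N = N, L = nlevels(f), n_h = nh,
       mean_h = mh, sst = sst, ssw = ssw, var_pop = sst / N)
}

#' Significance of a q value (noncentral-F test)
#'
#' F = ((N - L)/(L - 1)) q/(1 - q) compared against a noncentral
#' F(L-1, N-L; lambda) with
#' lambda = (sum N_h ybar_h^2 - (sum sqrt(N_h) ybar_h)^2 / N) / sigma2,
#' the canonical geodetector derivation. `central = TRUE` falls back to
#' the plain ANOVA F test. q = 1 gives p = 0 by convention.
#'
#' @param y,strata as in [q_statistic()].
#' @param central logical; use the central F distribution instead.
#' @param min_stratum passed through to the stratified decomposition.
#' @return list `q`, `F`, `p_value`, `N`, `L`.
#' @export
q_significance <- function(y, strata, central = FALSE, min_stratum = 2L) {
  st <- stratified_stats(y, strata, min_stratum)
  q <- st$q; N <- st$N; L <- st$L
  if (L < 2L) return(list(q = q, F = NA_real_, p_value = 1, N = N, L = L))
  if (q >= 1) return(list(q = q, F = Inf, p_value = 0, N = N, L = L))
  Fv <- (N - L) / (L - 1) * q / (1 - q)
  if (central) {
    p <- stats::pf(Fv, L - 1, N - L, lower.tail = FALSE)
  } else {
    lambda <- (sum(st$n_h * st$mean_h^2) -
                 sum(sqrt(st$n_h) * st$mean_h)^2 / N) / st$var_pop
    p <- stats::pf(Fv, L - 1, N - L, ncp = lambda, lower.tail = FALSE)
  }
  list(q = q, F = Fv, p_value = p, N = N, L = L)
}

#' Discretization methods available to the optimal-parameter search
#' @export
DISC_METHODS <- c("equal_interval", "natural_breaks", "quantile",
                  "geometric_interval", "std_dev")

#' Discretize a continuous variable into k strata
#'
#' Methods: `equal_interval` splits the data span linearly;
#' `quantile` places edges at k-quantiles (type 7); `natural_breaks` is
#' the exact Fisher-Jenks dynamic program minimizing within-class sum of
#' squares; `geometric_interval` places edges in geometric progression
#' over the (positively shifted) span with closed-form ratio
#' (max/min)^(1/k); `std_dev` cuts at mean + s*sd for s stepping by 1,
#' centred on the mean, trimmed to the data range. Bins are left-closed /
#' right-open, last bin closed. Duplicate edges (heavily tied data)
#' collapse with a message, yielding fewer strata than requested.
#'
#' @param x numeric values.
#' @param method one of [DISC_METHODS].
#' @param k requested number of strata (>= 2).
#' @return integer stratum labels (NA where x is NA) with attributes
#'   `edges` and `method`.
#' @export
discretize <- function(x, method = DISC_METHODS, k = 3L) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  v <- x[is.finite(x)]
  if (!length(v)) stop("no finite values to discretize")
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    warning("constant variable: single stratum returned")
    lab <- ifelse(is.finite(x), 1L, NA_integer_)
    attr(lab, "edges") <- c(lo, hi); attr(lab, "method") <- method
    return(lab)
  }
  edges <- switch(method,
    equal_interval = seq(lo, hi, length.out = k + 1L),
    quantile = as.numeric(stats::quantile(v, probs = seq(0, 1,
                                                         length.out = k + 1L),
                                          type = 7)),
    natural_breaks = jenks_breaks(v, k),
    geometric_interval = geometric_edges(lo, hi, k),
    std_dev = {
      cuts <- mean(v) + stats::sd(v) * (seq_len(k - 1L) - k / 2)
      c(lo, cuts[cuts > lo & cuts < hi], hi)
    })
  edges <- unique(edges)
  if (length(edges) < k + 1L && method != "std_dev")
    message("discretize: ", method, " produced ", length(edges) - 1L,
            " strata instead of ", k, " (tied data)")
  lab <- cut_lco(x, edges)
  attr(lab, "edges") <- edges
  attr(lab, "method") <- method
  lab
}

geometric_edges <- function(lo, hi, k) {
  shift <- if (lo <= 0) 1 - lo else 0
  a <- lo + shift; b <- hi + shift
  r <- (b / a)^(1 / k)
  a * r^(0:k) - shift
}

#' Fisher-Jenks natural breaks (exact dynamic program)
#'
#' Minimizes the total within-class sum of squared deviations over all
#' partitions of the sorted values into k contiguous classes. Exact and
#' deterministic; for very long vectors the input is first thinned to a
#' deterministic quantile subsample (`max_n`), standard practice for
#' one-dimensional classification.
#'
#' @param x numeric values (finite).
#' @param k number of classes.
#' @param max_n subsample size cap for the DP (default 3000).
#' @return numeric vector of k + 1 edges spanning \[min(x), max(x)\].
#' @export
jenks_breaks <- function(x, k, max_n = 3000L) {
  v <- sort(x[is.finite(x)])
  n <- length(v)
  if (n > max_n)
    v <- as.numeric(stats::quantile(v, probs = seq(0, 1,
                                                   length.out = max_n),
                                    type = 7))
  n <- length(v)
  if (k >= n) return(unique(c(v[1], v, v[n])))
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  sse <- function(i, j) {  # vectorized over i
    len <- j - i + 1
    s <- cs[j] - c(0, cs)[i]
    s2 <- cs2[j] - c(0, cs2)[i]
    s2 - s^2 / len
  }
  D <- matrix(Inf, k, n)       # D[c, j] = best SSE of v[1..j] in c classes
  B <- matrix(1L, k, n)        # start index of last class
  D[1, ] <- sse(rep(1L, n), seq_len(n))
  if (k > 1) for (c in 2:k) {
    for (j in c:n) {
      i <- c:j                 # last class = v[i..j]
      tot <- D[c - 1, i - 1L] + sse(i, j)
      best <- which.min(tot)
      D[c, j] <- tot[best]
      B[c, j] <- i[best]
    }
  }
  # recover class boundaries
  edges <- numeric(k + 1L)
  edges[k + 1L] <- v[n]
  j <- n
  for (c in k:1) {
    i <- B[c, j]
    edges[c] <- if (c == 1L) v[1] else (v[i - 1L] + v[i]) / 2
    j <- i - 1L
  }
  edges
}

#' Optimal discretization of one factor
#'
#' Evaluates q for every (method, k) combination and returns the argmax.
#' Ties break toward fewer bins, then toward the method order of
#' [DISC_METHODS].
#'
#' @param y response values.
#' @param x continuous factor values.
#' @param methods discretization methods to try.
#' @param k_range candidate bin counts (default 3:8).
#' @return list `best_method`, `best_k`, `q`, `labels`, `table`
#'   (data.frame of all combinations).
#' @export
optimize_discretization <- function(y, x, methods = DISC_METHODS,
                                    k_range = 3:8) {
  rows <- list(); labs <- list()
  for (m in methods) for (k in k_range) {
    lab <- suppressMessages(suppressWarnings(discretize(x, m, k)))
    q <- tryCatch(suppressMessages(q_statistic(y, lab)),
                  error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(method = m, k = k, q = q)
    labs[[paste(m, k)]] <- lab
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$q))) stop("all discretization combinations degenerate")
  # argmax q; ties -> fewer bins, then method order as listed
  tab$mord <- match(tab$method, DISC_METHODS)
  o <- order(-tab$q, tab$k, tab$mord)
  best <- tab[o[1], ]
  list(best_method = best$method, best_k = best$k, q = best$q,
       labels = labs[[paste(best$method, best$k)]],
       table = tab[, c("method", "k", "q")])
}

#' Build geodetector samples from grids at an analysis scale
#'
#' Aggregates the response and every factor to the analysis scale (mean
#' for continuous layers, mode for categorical) and keeps cells where the
#' response and all factors are defined: each retained cell is one sample.
#'
#' @param y_grid response [grid] at base resolution.
#' @param factors named list of factor [grid]s.
#' @param types named character vector, "continuous" or "categorical"
#'   per factor.
#' @param factor_px aggregation factor in pixels (>= 1).
#' @return data.frame with column `y` plus one column per factor.
#' @export
detector_samples <- function(y_grid, factors, types, factor_px = 1L) {
  ya <- aggregate_grid(y_grid, factor_px, "mean")
  cols <- list(y = as.vector(ya$values))
  for (f in names(factors)) {
    stat <- if (types[[f]] == "categorical") "mode" else "mean"
    cols[[f]] <- as.vector(aggregate_grid(factors[[f]], factor_px,
                                          stat)$values)
  }
  df <- as.data.frame(cols)
  df[stats::complete.cases(df), , drop = FALSE]
}

#' Optimal spatial scale by the 90 percent quantile of q
#'
#' For each candidate scale, every factor's q is optimized (continuous
#' factors via [optimize_discretization()], categorical used as-is); the
#' scale whose 90% quantile of q across factors (linear-interpolation
#' quantile) is largest wins.
#'
#' @inheritParams detector_samples
#' @param scales_px integer aggregation factors to evaluate.
#' @param scale_labels optional labels (e.g. km) for the scales.
#' @param k_range bin counts for the discretization search.
#' @return list `best_scale` (label), `best_px`, `q90` (per scale),
#'   `q_table` (long data.frame scale x factor q).
#' @export
select_scale <- function(y_grid, factors, types, scales_px,
                         scale_labels = scales_px, k_range = 3:8) {
  if (length(factors) < 2L) stop("need at least 2 factors")
  rows <- list()
  for (si in seq_along(scales_px)) {
    df <- detector_samples(y_grid, factors, types, scales_px[si])
    for (f in names(factors)) {
      q <- if (types[[f]] == "categorical")
        suppressMessages(q_statistic(df$y, df[[f]]))
      else
        optimize_discretization(df$y, df[[f]], k_range = k_range)$q
      rows[[length(rows) + 1L]] <-
        data.frame(scale = scale_labels[si], px = scales_px[si],
                   factor = f, q = q)
    }
  }
  tab <- do.call(rbind, rows)
  q90 <- tapply(tab$q, tab$scale, stats::quantile, probs = 0.9, type = 7,
                na.rm = TRUE)
  q90 <- q90[as.character(unique(tab$scale))]
  best <- which.max(q90)
  list(best_scale = names(q90)[best],
       best_px = scales_px[match(names(q90)[best],
                                 as.character(scale_labels))],
       q90 = q90, q_table = tab)
}

#' Factor detection at a fixed analysis scale
#'
#' Per-factor explanatory power q with optimal discretization parameters
#' (categorical factors bypass the search), noncentral-F significance,
#' sorted by decreasing q.
#'
#' @param samples data.frame from [detector_samples()].
#' @param types named type vector ("continuous"/"categorical").
#' @param k_range bin counts for the discretization search.
#' @return data.frame factor/q/p_value/best_method/best_k, plus a list
#'   attribute `labels` holding each factor's stratum labels.
#' @export
factor_detector <- function(samples, types, k_range = 3:8) {
  fs <- setdiff(names(samples), "y")
  out <- list(); labs <- list()
  for (f in fs) {
    x <- samples[[f]]
    if (all(is.na(x))) next
    if (types[[f]] == "categorical") {
      lab <- x
      sig <- suppressMessages(q_significance(samples$y, lab))
      out[[f]] <- data.frame(factor = f, q = sig$q, p_value = sig$p_value,
                             best_method = "categorical", best_k = NA)
    } else {
      opt <- optimize_discretization(samples$y, x, k_range = k_range)
      lab <- opt$labels
      sig <- suppressMessages(q_significance(samples$y, lab))
      out[[f]] <- data.frame(factor = f, q = opt$q, p_value = sig$p_value,
                             best_method = opt$best_method,
                             best_k = opt$best_k)
    }
    labs[[f]] <- as.integer(lab)
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$q), ]
  rownames(res) <- NULL
  attr(res, "labels") <- labs
  res
}

#' Interaction categories of the geodetector
#' @export
INTERACTION_CATEGORIES <- c("nonlinear_weaken", "single_weaken",
                            "bifactor_enhance", "independent",
                            "nonlinear_enhance")

#' Interaction detection between two stratified factors
#'
#' q12 is the q-statistic of the cross-classification (pairwise label
#' intersection). Category, with tolerance `tol` on the additivity check:
#' nonlinear_weaken if q12 < min(q1, q2); single_weaken if
#' min <= q12 < max; bifactor_enhance if max < q12 < q1 + q2;
#' independent if q12 = q1 + q2; nonlinear_enhance if q12 > q1 + q2.
#' q12 exactly equal to max(q1, q2) (e.g. one factor is a single stratum,
#' making the intersection the other factor) is an edge case reported as
#' single_weaken with a message.
#'
#' @param y response values.
#' @param lab1,lab2 stratum labels of the two factors on the same samples.
#' @param tol additivity tolerance (default 1e-9).
#' @return list `q1`, `q2`, `q12`, `category`.
#' @export
interaction_detector <- function(y, lab1, lab2, tol = 1e-9) {
  ok <- is.finite(y) & !is.na(lab1) & !is.na(lab2)
  y <- y[ok]; lab1 <- lab1[ok]; lab2 <- lab2[ok]
  q1 <- suppressMessages(q_statistic(y, lab1))
  q2 <- suppressMessages(q_statistic(y, lab2))
  inter <- interaction(lab1, lab2, drop = TRUE)
  sizes <- table(inter)
  if (all(sizes < 2L))
    stop("cross-classification has only singleton strata; use coarser bins")
  q12 <- suppressMessages(q_statistic(y, inter))
  lo <- min(q1, q2); hi <- max(q1, q2); s <- q1 + q2
  category <- if (lo <= tol && abs(q12 - hi) <= tol) {
    message("interaction_detector: q12 equals max(q1, q2) (edge case)")
    "single_weaken"
  }
  else if (abs(q12 - s) <= tol) "independent"
  else if (q12 > s) "nonlinear_enhance"
  else if (q12 > hi) "bifactor_enhance"
  else if (abs(q12 - hi) <= tol) {
    message("interaction_detector: q12 equals max(q1, q2) (edge case)")
    "single_weaken"
  }
  else if (q12 >= lo) "single_weaken"
  else "nonlinear_weaken"
  list(q1 = q1, q2 = q2, q12 = q12, category = category)
}

#' All pairwise interactions for a detected factor set
#' @param samples data.frame from [detector_samples()].
#' @param detection result of [factor_detector()] (supplies the stratum
#'   labels).
#' @return data.frame factor_1/factor_2/q1/q2/q12/category.
#' @export
interaction_matrix <- function(samples, detection) {
  labs <- attr(detection, "labels")
  fs <- detection$factor
  rows <- list()
  for (i in seq_along(fs)) for (j in seq_along(fs)) if (i < j) {
    r <- tryCatch(
      interaction_detector(samples$y, labs[[fs[i]]], labs[[fs[j]]]),
      error = function(e) NULL)
    if (is.null(r)) next
    rows[[length(rows) + 1L]] <-
      data.frame(factor_1 = fs[i], factor_2 = fs[j], q1 = r$q1, q2 = r$q2,
                 q12 = r$q12, category = r$category)
  }
  do.call(rbind, rows)
}
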