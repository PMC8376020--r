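#' Scale a concentration vector to z-scores
#'
#' Subtracts the mean and divides by the sample standard deviation
#' (n - 1 denominator). This is the scaling applied to each solute before
#' plotting against subwatershed area and before variance-changepoint
#' detection, so that solutes with different absolute concentrations are
#' comparable.
#'
#' @param values Numeric vector, length >= 2, no missing values.
#' @return Numeric vector with mean 0 and sample standard deviation 1.
#' @export
scale_concentrations <- function(values) {
  if (length(values) < 2L) {
    stop("scale_concentrations: need at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("scale_concentrations: non-finite values", call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) {
    stop("degenerate series: zero variance", call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Order scaled concentrations by subwatershed area
#'
#' Builds the area-ordered, z-scored series on which variance changepoints
#' are detected. Sites missing the solute are dropped; the scaling is applied
#' after sorting, over the full retained set. Ties in area are broken by
#' `site_id` lexicographic order (C collation) so results are deterministic.
#' Point-source sites encoded with `area_km2 = 0` sort first.
#'
#' By default all seasons and networks in `x` are pooled into one series per
#' solute; pass `season` and/or `network` to scale within a subset instead.
#'
#' @param x A `site_table`.
#' @param solute One solute name.
#' @param season,network Optional subset before ordering.
#' @return A `scaled_series`: list with `solute`, `values` (z-scores),
#'   `areas_km2`, `site_ids`, `seasons`, `n`.
#' @export
order_by_area <- function(x, solute, season = NULL, network = NULL) {
  solute <- match_vocabulary(solute, site_solutes(x), "solute")
  x <- filter_sites(x, season = season, network = network)
  keep <- !is.na(x[[solute]])
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 4L) {
    stop(sprintf("order_by_area: fewer than 4 usable sites for %s", solute),
         call. = FALSE)
  }
  ord <- order(x$area_km2, xtfrm(x$site_id), method = "radix")
  x <- x[ord, , drop = FALSE]
  structure(
    list(solute = solute,
         values = scale_concentrations(x[[solute]]),
         areas_km2 = x$area_km2,
         site_ids = x$site_id,
         seasons = x$season,
         n = nrow(x)),
    class = "scaled_series")
}

#' @export
print.scaled_series <- function(x, ...) {
  cat(sprintf("<scaled_series> %s: n = %d, area %.3g-%.3g km2\n",
              x$solute, x$n, min(x$areas_km2), max(x$areas_km2)))
  invisible(x)
}

#' Cost of one segment under the variance-change model
#'
#' The series is z-scored, so the segment mean is fixed at 0 and the only
#' segment parameter is its variance. The cost is twice the negative
#' log-likelihood of a zero-mean normal with the segment's maximum-likelihood
#' variance: `m * (log(2*pi) + log(sigma2) + 1)` with
#' `sigma2 = max(mean(values^2), var_floor)`. The floor keeps the cost finite
#' on all-zero segments.
#'
#' @param values Numeric vector (one segment).
#' @param var_floor Lower bound on the variance estimate. Default `1e-8`.
#' @return The segment cost (scalar).
#' @export
segment_cost <- function(values, var_floor = 1e-8) {
  m <- length(values)
  sigma2 <- max(sum(values^2) / m, var_floor)
  m * (log(2 * pi) + log(sigma2) + 1)
}

# Penalty per changepoint. "bic": 2 log n (two parameters per added segment:
# its variance and the changepoint location). "mbic": 3/2 log n per
# changepoint plus a log(segment length / n) term folded into each segment's
# cost (Zhang-Siegmund modified BIC).
resolve_penalty <- function(penalty, n) {
  if (is.numeric(penalty)) {
    list(name = "manual", beta = as.numeric(penalty), mbic = FALSE)
  } else {
    penalty <- match.arg(penalty, c("bic", "mbic"))
    switch(penalty,
           bic = list(name = "bic", beta = 2 * log(n), mbic = FALSE),
           mbic = list(name = "mbic", beta = 1.5 * log(n), mbic = TRUE))
  }
}

# Shared result assembly: segment variances + areas at changepoints.
build_changepoint_result <- function(x, cps, F_total, pen, min_seg,
                                     var_floor, areas, series = NULL) {
  n <- length(x)
  bounds <- c(0L, cps, n)
  seg_var <- vapply(seq_len(length(bounds) - 1L), function(i) {
    seg <- x[(bounds[i] + 1L):bounds[i + 1L]]
    max(sum(seg^2) / length(seg), var_floor)
  }, numeric(1))
  structure(
    list(changepoints = cps,
         changepoint_areas_km2 = if (is.null(areas)) rep(NA_real_, length(cps))
                                 else areas[cps],
         segment_variances = seg_var,
         penalty = pen$name,
         penalty_value = pen$beta,
         cost_total = F_total,
         min_seg = min_seg,
         n = n,
         solute = if (is.null(series)) NULL else series$solute,
         boundary_convention = "last index of left segment (1-based)"),
    class = "changepoint_result")
}

#' @export
print.changepoint_result <- function(x, ...) {
  cat(sprintf(
    "<changepoint_result>%s n = %d, penalty = %s (%.4g), %d changepoint(s)\n",
    if (is.null(x$solute)) "" else paste0(" ", x$solute, ":"),
    x$n, x$penalty, x$penalty_value, length(x$changepoints)))
  if (length(x$changepoints) > 0L) {
    cat("  indices:", paste(x$changepoints, collapse = ", "), "\n")
    if (!all(is.na(x$changepoint_areas_km2))) {
      cat("  areas (km2):",
          paste(signif(x$changepoint_areas_km2, 4), collapse = ", "), "\n")
    }
  }
  cat("  segment variances:",
      paste(signif(x$segment_variances, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Detect variance changepoints with PELT
#'
#' Pruned exact linear time search for the segmentation of an area-ordered,
#' z-scored series that minimises total segment cost (see [segment_cost()])
#' plus `penalty` per changepoint. The dynamic program is
#' `F(t) = min_s F(s) + C(s+1..t) + beta`, with candidate start points `s`
#' pruned when `F(s) + C(s+1..t) > F(t)`; because the cost is a minimised
#' negative log-likelihood (and the MBIC length correction is subadditive),
#' pruning is exact and the result is identical to exhaustive optimal
#' partitioning ([brute_force_changepoints()]).
#'
#' Changepoints are reported 1-based as the last index of each left segment;
#' the "area" of a changepoint is the subwatershed area at that index (the
#' boundary convention is recorded in the result).
#'
#' @param series A `scaled_series` from [order_by_area()], or a plain numeric
#'   vector (areas then unknown).
#' @param penalty `"bic"` (default, `2 log n` per changepoint), `"mbic"`
#'   (`1.5 log n` plus segment-length corrections), or a manual non-negative
#'   number.
#' @param min_seg Minimum segment length, default 2 (a variance needs at
#'   least two points).
#' @param var_floor Variance floor passed to the cost. Default `1e-8`.
#' @return A `changepoint_result`.
#' @export
pelt_changepoints <- function(series, penalty = "bic", min_seg = 2L,
                              var_floor = 1e-8) {
  x <- if (inherits(series, "scaled_series")) series$values else series
  areas <- if (inherits(series, "scaled_series")) series$areas_km2 else NULL
  n <- length(x)
  min_seg <- as.integer(min_seg)
  if (min_seg < 1L) stop("min_seg must be >= 1", call. = FALSE)
  if (n < 2L * min_seg) {
    stop(sprintf("pelt_changepoints: n = %d too small for min_seg = %d",
                 n, min_seg), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("pelt_changepoints: non-finite values", call. = FALSE)
  }
  pen <- resolve_penalty(penalty, n)

  css <- cumsum(x^2)
  log2pi1 <- log(2 * pi) + 1
  segcost <- function(i, j) {
    m <- j - i + 1L
    sigma2 <- max((css[j] - if (i > 1L) css[i - 1L] else 0) / m, var_floor)
    cost <- m * (log2pi1 + log(sigma2))
    if (pen$mbic) cost + log(m / n) else cost
  }

  F <- c(-pen$beta, rep(Inf, n))          # F[s + 1] holds F(s)
  last <- integer(n + 1L)
  cand <- 0L
  # A candidate marked prunable at time t0 is dominated only for times
  # T >= t0 + min_seg (the domination path uses t0 as a changepoint, which
  # needs a full segment after it), so removal is lagged accordingly.
  pruned_at <- rep(Inf, n + 1L)           # pruned_at[s + 1] = marking time
  for (t in seq.int(min_seg, n)) {
    cand <- cand[pruned_at[cand + 1L] + min_seg - 1L >= t]
    eligible <- cand[cand <= t - min_seg]
    if (length(eligible) > 0L) {
      vals <- vapply(eligible,
                     function(s) F[s + 1L] + segcost(s + 1L, t) + pen$beta,
                     numeric(1))
      best <- which.min(vals)             # ties -> smallest s (deterministic)
      F[t + 1L] <- vals[best]
      last[t + 1L] <- eligible[best]
      newly <- eligible[vals - pen$beta > F[t + 1L]]
      pruned_at[newly + 1L] <- pmin(pruned_at[newly + 1L], t)
    }
    cand <- c(cand, t)
  }

  cps <- integer()
  t <- n
  while (t > 0L) {
    s <- last[t + 1L]
    if (s > 0L) cps <- c(s, cps)
    t <- s
  }
  build_changepoint_result(x, cps, F[n + 1L], pen, min_seg, var_floor,
                           areas, if (inherits(series, "scaled_series")) series)
}

#' Exhaustive optimal-partitioning oracle
#'
#' Computes the globally optimal segmentation by dynamic programming over
#' every admissible split point, with no pruning. Same objective as
#' [pelt_changepoints()]; used as an independent correctness check. Guarded
#' to `n <= 40`.
#'
#' @inheritParams pelt_changepoints
#' @return A `changepoint_result`.
#' @export
brute_force_changepoints <- function(series, penalty = "bic", min_seg = 2L,
                                     var_floor = 1e-8) {
  x <- if (inherits(series, "scaled_series")) series$values else series
  areas <- if (inherits(series, "scaled_series")) series$areas_km2 else NULL
  n <- length(x)
  if (n > 40L) stop("oracle limit: n > 40", call. = FALSE)
  min_seg <- as.integer(min_seg)
  if (n < 2L * min_seg) {
    stop(sprintf("brute_force_changepoints: n = %d too small for min_seg = %d",
                 n, min_seg), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("brute_force_changepoints: non-finite values", call. = FALSE)
  }
  pen <- resolve_penalty(penalty, n)
  log2pi1 <- log(2 * pi) + 1

  # Cost computed from scratch per segment (no prefix sums, no sharing with
  # the PELT fast path).
  cost_of <- function(i, j) {
    seg <- x[i:j]
    m <- length(seg)
    cost <- m * (log2pi1 + log(max(mean(seg^2), var_floor)))
    if (pen$mbic) cost + log(m / n) else cost
  }

  F <- c(-pen$beta, rep(Inf, n))
  last <- integer(n + 1L)
  for (t in seq.int(min_seg, n)) {
    starts <- c(0L, seq_len(max(0L, t - min_seg)))
    starts <- starts[starts == 0L | starts >= min_seg]
    for (s in starts) {
      v <- F[s + 1L] + cost_of(s + 1L, t) + pen$beta
      if (v < F[t + 1L]) {
        F[t + 1L] <- v
        last[t + 1L] <- s
      }
    }
  }
  cps <- integer()
  t <- n
  while (t > 0L) {
    s <- last[t + 1L]
    if (s > 0L) cps <- c(s, cps)
    t <- s
  }
  build_changepoint_result(x, cps, F[n + 1L], pen, min_seg, var_floor,
                           areas, if (inherits(series, "scaled_series")) series)
}

#' Tidy a changepoint result
#'
#' @param x A `changepoint_result`.
#' @return A tibble with one row per segment: `solute`, `segment_id`,
#'   `segment_start`, `segment_end`, `segment_variance`, plus the changepoint
#'   index/area ending the segment (`NA` for the final segment), the penalty
#'   and `n`.
#' @export
tidy_changepoints <- function(x) {
  k <- length(x$changepoints)
  bounds <- c(0L, x$changepoints, x$n)
  tibble::tibble(
    solute = x$solute %||% NA_character_,
    segment_id = seq_len(k + 1L),
    segment_start = bounds[seq_len(k + 1L)] + 1L,
    segment_end = bounds[-1L],
    segment_variance = x$segment_variances,
    changepoint_index = c(x$changepoints, NA_integer_),
    changepoint_area_km2 = c(x$changepoint_areas_km2, NA_real_),
    penalty = x$penalty,
    penalty_value = x$penalty_value,
    n = x$n)
}
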