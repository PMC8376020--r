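#' Spearman rank correlation between two seasons' concentrations
#'
#' Pearson correlation of average ranks (ties receive mean ranks); with no
#' ties this equals `1 - 6 * sum(d^2) / (n * (n^2 - 1))`. A rho near 1 means
#' the spatial pattern of sources and sinks is stable between the two
#' sampling dates.
#'
#' @param x,y Numeric vectors of equal length `>= 3`, finite, each with at
#'   least two distinct values.
#' @return Scalar rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    stop("spearman_rho: unequal lengths", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("spearman_rho: need at least 3 paired values", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("spearman_rho: non-finite values", call. = FALSE)
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

season_pairs <- function() {
  list(c("Spring", "Summer"), c("Summer", "Fall"), c("Spring", "Fall"))
}

#' Spatial persistence of concentration rankings across seasons
#'
#' For each (group, solute, season pair) computes Spearman's rho over the
#' sites observed (non-missing) in both seasons. Pairing is by `site_id`;
#' replicate samples within a season must be aggregated upstream (see
#' [read_site_table()]). Groups with fewer than `min_overlap` overlapping
#' sites, or with constant concentrations in either season, are reported
#' with `rho = NA` and a reason rather than silently dropped.
#'
#' @param x A `site_table` with at least two seasons.
#' @param min_overlap Minimum overlapping sites per comparison; default 5
#'   (rank correlations on fewer points are uninformative).
#' @param group Grouping column, `"category"` (default, pooling networks
#'   within a category) or `"network"`.
#' @return Tibble: group key, `solute`, `season_pair`, `rho`, `n_overlap`,
#'   `reason` (`NA` when rho is available).
#' @export
persistence_matrix <- function(x, min_overlap = 5L, group = "category") {
  group <- match.arg(group, c("category", "network"))
  seasons_present <- intersect(watershed_seasons(), unique(x$season))
  if (length(seasons_present) < 2L) {
    stop("persistence_matrix: need at least two seasons", call. = FALSE)
  }
  solutes <- site_solutes(x)
  pairs <- Filter(function(p) all(p %in% seasons_present), season_pairs())

  rows <- list()
  for (g in unique(x[[group]])) {
    xg <- x[x[[group]] == g, , drop = FALSE]
    for (s in solutes) {
      for (p in pairs) {
        a <- xg[xg$season == p[1], c("site_id", s)]
        b <- xg[xg$season == p[2], c("site_id", s)]
        m <- merge(a, b, by = "site_id", suffixes = c("_1", "_2"))
        v1 <- m[[paste0(s, "_1")]]
        v2 <- m[[paste0(s, "_2")]]
        ok <- !is.na(v1) & !is.na(v2)
        n_overlap <- sum(ok)
        rho <- NA_real_
        reason <- NA_character_
        if (n_overlap < min_overlap) {
          reason <- "insufficient overlap"
        } else if (length(unique(v1[ok])) < 2L ||
                   length(unique(v2[ok])) < 2L) {
          reason <- "constant concentrations"
        } else {
          rho <- spearman_rho(v1[ok], v2[ok])
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          !!group := g, solute = s,
          season_pair = paste(p, collapse = "-"),
          rho = rho, n_overlap = n_overlap, reason = reason)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Summarise persistence: mean and range of rho per group and solute
#'
#' Mean and (min, max) of the available season-pair rho values, mirroring
#' the usual points-with-range display. Groups where every pair is missing
#' are omitted with a warning.
#'
#' @param results Output of [persistence_matrix()].
#' @return Tibble: group key, `solute`, `mean_rho`, `rho_min`, `rho_max`,
#'   `n_pairs`.
#' @export
persistence_summary <- function(results) {
  group <- setdiff(names(results),
                   c("solute", "season_pair", "rho", "n_overlap", "reason"))[1]
  avail <- results[!is.na(results$rho), , drop = FALSE]
  dropped <- dplyr::anti_join(
    unique(results[, c(group, "solute")]),
    unique(avail[, c(group, "solute")]),
    by = c(group, "solute"))
  if (nrow(dropped) > 0L) {
    warning(sprintf(
      "persistence_summary: no usable season pairs for %d group(s), omitted",
      nrow(dropped)), call. = FALSE)
  }
  if (nrow(avail) == 0L) {
    return(tibble::tibble(!!group := character(), solute = character(),
                          mean_rho = numeric(), rho_min = numeric(),
                          rho_max = numeric(), n_pairs = integer()))
  }
  avail |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group, "solute")))) |>
    dplyr::summarise(
      mean_rho = mean(.data$rho),
      rho_min = min(.data$rho),
      rho_max = max(.data$rho),
      n_pairs = dplyr::n(),
      .groups = "drop")
}
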