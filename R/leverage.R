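#' Subwatershed leverage on outlet flux
#'
#' Leverage measures how much of the solute flux at a network outlet a
#' subwatershed can account for, assuming uniform specific discharge across
#' the watershed:
#'
#' `leverage_conc = (c_sub - c_out) * (a_sub / a_out)`   (mg/L), and
#' `leverage_pct  = 100 * leverage_conc / c_out`         (% of outlet flux).
#'
#' Values above +100% mark highly influential (critical source) areas: the
#' subwatershed delivers more solute than leaves the outlet altogether,
#' which is possible because material is retained or removed in transit.
#'
#' @param c_sub Subwatershed concentration(s), mg/L, `>= 0` (vectorised).
#' @param c_out Outlet concentration, mg/L, `> 0` (scalar).
#' @param a_sub Subwatershed area(s), km2, in `[0, a_out]` (vectorised).
#' @param a_out Outlet watershed area, km2, `> 0` (scalar).
#' @return A tibble with `leverage_conc`, `leverage_pct`, `influence_class`.
#' @export
compute_leverage <- function(c_sub, c_out, a_sub, a_out) {
  if (length(c_out) != 1L || length(a_out) != 1L) {
    stop("compute_leverage: c_out and a_out must be scalars", call. = FALSE)
  }
  if (is.na(c_out) || c_out <= 0) {
    stop("undefined leverage (zero outlet concentration)", call. = FALSE)
  }
  if (a_out <= 0) stop("compute_leverage: a_out must be > 0", call. = FALSE)
  if (any(a_sub < 0 | a_sub > a_out)) {
    stop("compute_leverage: a_sub must lie in [0, a_out]", call. = FALSE)
  }
  if (any(!is.na(c_sub) & c_sub < 0)) {
    stop("compute_leverage: negative subwatershed concentration",
         call. = FALSE)
  }
  leverage_conc <- (c_sub - c_out) * (a_sub / a_out)
  leverage_pct <- 100 * leverage_conc / c_out
  tibble::tibble(
    leverage_conc = leverage_conc,
    leverage_pct = leverage_pct,
    influence_class = classify_influence(leverage_pct))
}

#' Classify a leverage percentage into influence classes
#'
#' Strict thresholds: `|pct| < 25` is `low_moderate`; `pct > 100` is
#' `highly_influential_positive` (a critical source area); `pct < -100` is
#' `highly_influential_negative` (the symmetric sink case, an extension of
#' the usual source-only reading); everything else, boundaries included, is
#' `intermediate`.
#'
#' @param leverage_pct Numeric vector of leverage percentages.
#' @return Factor with levels `low_moderate`, `intermediate`,
#'   `highly_influential_positive`, `highly_influential_negative`.
#' @export
classify_influence <- function(leverage_pct) {
  if (any(!is.finite(leverage_pct))) {
    stop("classify_influence: non-finite leverage", call. = FALSE)
  }
  cls <- ifelse(abs(leverage_pct) < 25, "low_moderate",
         ifelse(leverage_pct > 100, "highly_influential_positive",
         ifelse(leverage_pct < -100, "highly_influential_negative",
                "intermediate")))
  factor(cls, levels = c("low_moderate", "intermediate",
                         "highly_influential_positive",
                         "highly_influential_negative"))
}

# Resolve the outlet row index of one network subset.
resolve_outlet <- function(sub, outlet_rule) {
  idx <- which(sub$is_outlet)
  if (length(idx) == 1L) return(idx)
  if (length(idx) > 1L) {
    stop(sprintf("no single outlet: network %s has %d flagged outlets",
                 sub$network[1], length(idx)), call. = FALSE)
  }
  if (identical(outlet_rule, "flagged")) {
    stop(sprintf("no single outlet: network %s has no flagged outlet",
                 sub$network[1]), call. = FALSE)
  }
  # max_area fallback; area ties broken by site_id for determinism
  ord <- order(-sub$area_km2, xtfrm(sub$site_id), method = "radix")
  ord[1]
}

#' Per-site leverage for every network in a table
#'
#' Computes leverage of each non-outlet site on its network outlet, for one
#' solute and season. The outlet itself is included with leverage 0 by
#' definition. Sites missing the solute are dropped (pairwise deletion).
#'
#' Valley tributaries do not converge to a single outlet within a network
#' (many discharge directly into the lake), so their presence is an error:
#' exclude them first with [exclude_valley_tributaries()] (or pass
#' `allow_valley = TRUE` to accept a per-network max-area pseudo-outlet,
#' clearly an extension of the standard analysis).
#'
#' @param x A `site_table`.
#' @param solute One solute name.
#' @param season One season token.
#' @param outlet_rule `"flagged"` uses the `is_outlet` flag and falls back to
#'   `"max_area"` only if that rule is given instead.
#' @param allow_valley Permit `ValleyTributaries` rows (default `FALSE`).
#' @return Tibble: `network`, `site_id`, `category`, `solute`, `season`,
#'   `area_km2`, `leverage_conc`, `leverage_pct`, `influence_class`,
#'   `is_outlet`.
#' @export
network_leverage <- function(x, solute, season,
                             outlet_rule = c("flagged", "max_area"),
                             allow_valley = FALSE) {
  outlet_rule <- match.arg(outlet_rule)
  solute <- match_vocabulary(solute, site_solutes(x), "solute")
  x <- filter_sites(x, season = season)
  if (!allow_valley && any(x$category == "ValleyTributaries")) {
    stop(paste("no single outlet: ValleyTributaries sites do not converge",
               "to a network outlet; exclude them first",
               "(exclude_valley_tributaries())"), call. = FALSE)
  }
  if (nrow(x) == 0L) {
    stop(sprintf("network_leverage: no records for season %s", season),
         call. = FALSE)
  }
  out <- lapply(split(seq_len(nrow(x)), x$network), function(rows) {
    sub <- x[rows, , drop = FALSE]
    o <- resolve_outlet(sub, outlet_rule)
    outlet_id <- sub$site_id[o]
    c_out <- sub[[solute]][o]
    a_out <- sub$area_km2[o]
    if (is.na(c_out) || c_out <= 0) {
      stop(sprintf(
        "undefined leverage (zero outlet concentration): network %s, %s, %s",
        sub$network[1], solute, season), call. = FALSE)
    }
    keep <- !is.na(sub[[solute]])
    keep[o] <- TRUE
    sub <- sub[keep, , drop = FALSE]
    o <- which(sub$site_id == outlet_id)[1]
    lev <- compute_leverage(sub[[solute]], c_out, sub$area_km2, a_out)
    lev$leverage_conc[o] <- 0
    lev$leverage_pct[o] <- 0
    lev$influence_class[o] <- classify_influence(0)
    tibble::tibble(
      network = sub$network,
      site_id = sub$site_id,
      category = sub$category,
      solute = solute,
      season = season,
      area_km2 = sub$area_km2,
      lev,
      is_outlet = seq_len(nrow(sub)) == o)
  })
  dplyr::bind_rows(out)
}

#' Leverage across all solutes and seasons of a table
#'
#' Convenience wrapper looping [network_leverage()] over every solute and
#' season present; (solute, season, network) combinations whose outlet
#' concentration is missing or zero are skipped with a warning rather than
#' aborting the whole sweep.
#'
#' @inheritParams network_leverage
#' @param solutes,seasons Subsets to run; defaults: everything present.
#' @return Combined tibble as in [network_leverage()].
#' @export
leverage_table <- function(x, solutes = site_solutes(x),
                           seasons = intersect(watershed_seasons(),
                                               unique(x$season)),
                           outlet_rule = c("flagged", "max_area"),
                           allow_valley = FALSE) {
  outlet_rule <- match.arg(outlet_rule)
  grid <- expand.grid(solute = solutes, season = seasons,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    tryCatch(
      network_leverage(x, grid$solute[i], grid$season[i],
                       outlet_rule = outlet_rule, allow_valley = allow_valley),
      error = function(e) {
        if (grepl("ValleyTributaries", conditionMessage(e))) stop(e)
        warning(sprintf("skipping %s/%s: %s", grid$solute[i], grid$season[i],
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
  })
  dplyr::bind_rows(out)
}

#' Summarise leverage by group: mean, class fractions, direction
#'
#' Group means of leverage are read as network-scale mass balance under the
#' convention of the survey methodology: a positive mean implies net removal
#' within the surface-water network (tributaries carry more solute than is
#' accounted for at the outlet), a negative mean implies net production.
#' Note the original figure caption uses the opposite wording; this package
#' follows the methods-text convention and documents the discrepancy rather
#' than reconciling it silently.
#'
#' Outlet rows (leverage 0 by definition) are excluded from summaries when
#' an `is_outlet` column is present.
#'
#' @param records A tibble of leverage records ([network_leverage()]).
#' @param group_by Grouping columns, default `c("category", "season",
#'   "solute")`.
#' @param tol Dead band around 0 for the `neutral` direction. Default 0.
#' @return Tibble with group keys, `n`, `mean_leverage_pct`,
#'   `fraction_low_moderate`, `fraction_highly_influential`, `direction`.
#' @export
summarize_leverage <- function(records,
                               group_by = c("category", "season", "solute"),
                               tol = 0) {
  stopifnot(all(group_by %in% names(records)))
  if ("is_outlet" %in% names(records)) {
    records <- records[!records$is_outlet, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    warning("summarize_leverage: no non-outlet records", call. = FALSE)
    return(tibble::tibble())
  }
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_leverage_pct = mean(.data$leverage_pct),
      fraction_low_moderate = mean(abs(.data$leverage_pct) < 25),
      fraction_highly_influential = mean(abs(.data$leverage_pct) > 100),
      .groups = "drop") |>
    dplyr::mutate(
      direction = ifelse(.data$mean_leverage_pct > tol, "removal",
                  ifelse(.data$mean_leverage_pct < -tol, "production",
                         "neutral")))
}
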