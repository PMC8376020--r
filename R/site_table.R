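#' Site tables of synoptic observations
#'
#' A `site_table` is a tibble with one row per site x season observation and
#' a fixed column contract: `site_id`, `network`, `category`, `area_km2`,
#' `season`, the four land-cover fractions (`forest`, `developed`,
#' `impervious`, `herbaceous`), one concentration column (mg/L) per solute,
#' and a logical `is_outlet` flag. Missing concentrations are `NA` and are
#' never imputed; each downstream metric drops them pairwise.
#'
#' Subwatershed area 0 is allowed: it encodes point sources (wastewater
#' outfalls, field drains) that deliver solute without a contributing area.
#'
#' @param x A data frame with the columns above.
#' @param solutes Character vector of solute columns present in `x`.
#'   Defaults to the intersection of `watershed_solutes()` with `names(x)`.
#' @return A validated `site_table`.
#' @seealso [read_site_table()], [validate_site_table()]
#' @export
as_site_table <- function(x, solutes = NULL) {
  x <- tibble::as_tibble(x)
  if (is.null(solutes)) {
    solutes <- intersect(watershed_solutes(), names(x))
  }
  required <- c("site_id", "network", "category", "area_km2", "season", solutes)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (length(solutes) == 0L) {
    stop("schema error: no solute columns present", call. = FALSE)
  }
  for (lc in land_cover_classes()) {
    if (!lc %in% names(x)) x[[lc]] <- NA_real_
  }
  if (!"is_outlet" %in% names(x)) x$is_outlet <- FALSE
  x$site_id <- as.character(x$site_id)
  x$network <- as.character(x$network)
  x$category <- match_vocabulary(x$category, watershed_categories(), "category")
  x$season <- match_vocabulary(x$season, watershed_seasons(), "season",
                               extra = "Mean")
  x$area_km2 <- as.numeric(x$area_km2)
  x$is_outlet <- as.logical(x$is_outlet)
  x$is_outlet[is.na(x$is_outlet)] <- FALSE
  canon <- c("site_id", "network", "category", "area_km2", "season",
             land_cover_classes(), solutes, "is_outlet")
  x <- x[, c(canon, setdiff(names(x), canon))]
  out <- structure(x,
                   solutes = solutes,
                   class = c("site_table", class(tibble::tibble())))
  validate_site_table(out, action = "error")
  out
}

#' Validate a site table against its invariants
#'
#' Checks: non-negative areas and concentrations, land-cover fractions in
#' `[0, 1]`, at most one outlet per (network, season), unique (site_id,
#' season) pairs. Hard violations (negative values, bad fractions) are
#' errors with row numbers; duplicates and multiple outlets are reported as
#' warnings because replicate volunteer samples are legitimately passed
#' through by the reader (aggregate them explicitly, e.g. with
#' `aggregate_duplicates = "mean"`).
#'
#' @param x A `site_table`.
#' @param action `"error"` to abort on hard violations, `"report"` to return
#'   diagnostics only.
#' @return (Invisibly) a list with character vectors `errors` and `warnings`.
#' @export
validate_site_table <- function(x, action = c("error", "report")) {
  action <- match.arg(action)
  solutes <- site_solutes(x)
  errors <- character()
  warnings <- character()

  bad_area <- which(is.na(x$area_km2) | x$area_km2 < 0)
  if (length(bad_area) > 0L) {
    errors <- c(errors, sprintf(
      "validation error: negative or missing area_km2 in row(s) %s",
      paste(bad_area, collapse = ", ")))
  }
  for (s in solutes) {
    bad <- which(!is.na(x[[s]]) & x[[s]] < 0)
    if (length(bad) > 0L) {
      errors <- c(errors, sprintf(
        "validation error: negative %s concentration in row(s) %s",
        s, paste(bad, collapse = ", ")))
    }
  }
  for (lc in land_cover_classes()) {
    bad <- which(!is.na(x[[lc]]) & (x[[lc]] < 0 | x[[lc]] > 1))
    if (length(bad) > 0L) {
      errors <- c(errors, sprintf(
        "validation error: %s fraction outside [0, 1] in row(s) %s",
        lc, paste(bad, collapse = ", ")))
    }
  }

  dup <- duplicated(x[, c("site_id", "season")])
  if (any(dup)) {
    warnings <- c(warnings, sprintf(
      "duplicate (site_id, season) in row(s) %s (replicate samples?)",
      paste(which(dup), collapse = ", ")))
  }
  n_outlets <- table(paste(x$network[x$is_outlet], x$season[x$is_outlet]))
  if (any(n_outlets > 1L)) {
    warnings <- c(warnings, sprintf(
      "more than one flagged outlet for: %s",
      paste(names(n_outlets)[n_outlets > 1L], collapse = ", ")))
  }

  if (action == "error" && length(errors) > 0L) {
    stop(paste(errors, collapse = "\n"), call. = FALSE)
  }
  invisible(list(errors = errors, warnings = warnings))
}

#' @rdname as_site_table
#' @export
site_solutes <- function(x) {
  s <- attr(x, "solutes")
  if (is.null(s)) intersect(watershed_solutes(), names(x)) else s
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf(
    "<site_table> %d observations, %d sites, %d network(s), %d solute(s)\n",
    nrow(x), length(unique(x$site_id)), length(unique(x$network)),
    length(site_solutes(x))))
  NextMethod()
}

#' Read a long-format synoptic site table from CSV
#'
#' The canonical layout is long: one row per site x season, columns
#' `site_id, network, category, area_km2, season, forest, developed,
#' impervious, herbaceous`, then one column per solute (mg/L); empty cells
#' are missing values. Wide-by-season files (solute columns named
#' `<solute>_<season>`) are normalised on load with `wide_seasons = TRUE`.
#' Category and season tokens are matched case-insensitively and written
#' back in canonical form.
#'
#' @param path Path to a CSV file (RFC 4180, UTF-8, header row).
#' @param solutes Solute columns to read; default: any of
#'   `watershed_solutes()` found in the header.
#' @param wide_seasons Set `TRUE` for wide-by-season input.
#' @param aggregate_duplicates `"none"` passes replicate (site_id, season)
#'   rows through untouched (with a validation warning); `"mean"` averages
#'   their concentrations.
#' @return A validated [as_site_table()] object. Validation warnings are
#'   attached as `attr(x, "validation_warnings")`.
#' @export
read_site_table <- function(path, solutes = NULL,
                            wide_seasons = FALSE,
                            aggregate_duplicates = c("none", "mean")) {
  aggregate_duplicates <- match.arg(aggregate_duplicates)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  if (wide_seasons) {
    raw <- widen_to_long(raw, solutes)
  }
  if (is.null(solutes)) {
    solutes <- intersect(watershed_solutes(), names(raw))
  }
  tbl <- as_site_table(raw, solutes = solutes)

  if (aggregate_duplicates == "mean") {
    tbl <- aggregate_replicates(tbl)
  }
  diag <- validate_site_table(tbl, action = "report")
  attr(tbl, "validation_warnings") <- diag$warnings
  tbl
}

# Pivot <solute>_<season> columns into long layout.
widen_to_long <- function(raw, solutes) {
  if (is.null(solutes)) solutes <- watershed_solutes()
  pat <- sprintf("^(%s)_(%s)$",
                 paste(solutes, collapse = "|"),
                 paste(watershed_seasons(), collapse = "|"))
  wide_cols <- grep(pat, names(raw), value = TRUE)
  if (length(wide_cols) == 0L) {
    stop("schema error: wide_seasons = TRUE but no <solute>_<season> columns found",
         call. = FALSE)
  }
  long <- tidyr::pivot_longer(raw, cols = dplyr::all_of(wide_cols),
                              names_to = c("solute", "season"),
                              names_pattern = pat,
                              values_to = "conc")
  tidyr::pivot_wider(long, names_from = "solute", values_from = "conc")
}

# Average replicate (site_id, season) rows; site covariates from first row.
aggregate_replicates <- function(tbl) {
  solutes <- site_solutes(tbl)
  agg <- tbl |>
    dplyr::group_by(.data$site_id, .data$season) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c("network", "category")), dplyr::first),
      dplyr::across(dplyr::all_of(c("area_km2", land_cover_classes())),
                    dplyr::first),
      dplyr::across(dplyr::all_of(solutes),
                    ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
      is_outlet = any(.data$is_outlet),
      .groups = "drop")
  as_site_table(agg, solutes = solutes)
}

#' Write a site table back to CSV with a JSON metadata sidecar
#'
#' @param x A `site_table`.
#' @param path Output CSV path. The sidecar, if requested, is written to
#'   `paste0(path, ".json")` and records the solute list, record count and
#'   any validation warnings.
#' @param sidecar Write the JSON sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(x, path, sidecar = TRUE) {
  readr::write_csv(tibble::as_tibble(x), path, na = "")
  if (sidecar) {
    meta <- list(
      solutes = site_solutes(x),
      n_records = nrow(x),
      n_sites = length(unique(x$site_id)),
      validation_warnings = as.character(
        attr(x, "validation_warnings") %||% character())
    )
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Subset a site table by category, network or season
#'
#' Filters compose: `filter_sites(filter_sites(x, category = a), season = b)`
#' equals `filter_sites(x, category = a, season = b)`. Tokens are validated
#' against the vocabulary; unknown tokens are an error. An empty result is
#' allowed.
#'
#' @param x A `site_table`.
#' @param category,season Keep only these canonical tokens (vectors allowed).
#' @param network Keep only these networks.
#' @param drop_category,drop_season Remove these tokens instead.
#' @return A `site_table` subset preserving row order.
#' @export
filter_sites <- function(x, category = NULL, network = NULL, season = NULL,
                         drop_category = NULL, drop_season = NULL) {
  keep <- rep(TRUE, nrow(x))
  if (!is.null(category)) {
    category <- match_vocabulary(category, watershed_categories(), "category")
    keep <- keep & x$category %in% category
  }
  if (!is.null(drop_category)) {
    drop_category <- match_vocabulary(drop_category, watershed_categories(),
                                      "category")
    keep <- keep & !(x$category %in% drop_category)
  }
  if (!is.null(network)) {
    unknown <- setdiff(network, unique(x$network))
    if (length(unknown) > 0L) {
      stop(sprintf("unknown network token(s): %s",
                   paste(sQuote(unknown), collapse = ", ")), call. = FALSE)
    }
    keep <- keep & x$network %in% network
  }
  if (!is.null(season)) {
    season <- match_vocabulary(season, watershed_seasons(), "season",
                               extra = "Mean")
    keep <- keep & x$season %in% season
  }
  if (!is.null(drop_season)) {
    drop_season <- match_vocabulary(drop_season, watershed_seasons(), "season",
                                    extra = "Mean")
    keep <- keep & !(x$season %in% drop_season)
  }
  out <- x[keep, , drop = FALSE]
  attr(out, "solutes") <- site_solutes(x)
  out
}

#' Exclude Valley tributaries sites
#'
#' Named filter for the standard leverage-analysis exclusion: Valley
#' tributaries do not converge within a network to a single outlet (many
#' discharge directly into the lake), so subwatershed leverage is undefined
#' for them.
#'
#' @param x A `site_table`.
#' @return `x` without `ValleyTributaries` rows.
#' @export
exclude_valley_tributaries <- function(x) {
  filter_sites(x, drop_category = "ValleyTributaries")
}

#' Average concentrations across seasons
#'
#' Collapses a site table to one record per site; each solute concentration
#' becomes the arithmetic mean over the seasons where it was observed
#' (missing values skipped, never imputed). The season field is set to
#' `"Mean"`. Sites observed in a single season pass through unchanged.
#'
#' @param x A non-empty `site_table`.
#' @return A `site_table` with one row per `site_id`.
#' @export
season_mean <- function(x) {
  if (nrow(x) == 0L) stop("season_mean: empty site table", call. = FALSE)
  solutes <- site_solutes(x)
  out <- x |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c("network", "category")), dplyr::first),
      dplyr::across(dplyr::all_of(c("area_km2", land_cover_classes())),
                    dplyr::first),
      dplyr::across(dplyr::all_of(solutes),
                    ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
      is_outlet = any(.data$is_outlet),
      .groups = "drop") |>
    dplyr::mutate(season = "Mean")
  as_site_table(out, solutes = solutes)
}
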