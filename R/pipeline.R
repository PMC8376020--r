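#' Run the full synoptic analysis pipeline
#'
#' Wires the stages together in the survey's analysis order:
#' simulate (optional) -> validate -> changepoints -> leverage ->
#' persistence -> models. Every stage writes a tidy CSV into `out_dir`, and
#' a `manifest.json` records the configuration hash, seed, package version,
#' penalty formula, per-stage status and warnings - enough to re-run the
#' deterministic stages bit-identically. An empty `stages` vector gives a
#' validation-only run (the manifest is still written).
#'
#' @param input A path to a site-table CSV, a `site_table`, or a
#'   [watershed_config()] (which triggers the simulate stage).
#' @param out_dir Output directory; created if needed.
#' @param stages Stages to run, a subset of
#'   `c("changepoints", "leverage", "persistence", "models")` (validation
#'   always runs; simulation runs iff `input` is a config).
#' @param penalty,min_seg Changepoint options (see [pelt_changepoints()]).
#' @param min_overlap Persistence option (see [persistence_matrix()]).
#' @param outlet_rule Leverage option (see [network_leverage()]).
#' @param exclude_valley Apply the Valley-tributaries exclusion before the
#'   leverage stage (default `TRUE`; turning it off makes the leverage stage
#'   fail, by design, when valley sites are present).
#' @param candidates Model-stage candidate predictors (see [best_subset()]).
#' @param seed Seed recorded in the manifest and used for any simulation.
#' @return (Invisibly) the manifest list; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(input, out_dir,
                         stages = c("changepoints", "leverage",
                                    "persistence", "models"),
                         penalty = "bic", min_seg = 2L, min_overlap = 5L,
                         outlet_rule = "flagged", exclude_valley = TRUE,
                         candidates = c("season", land_cover_classes()),
                         seed = 1L) {
  known <- c("changepoints", "leverage", "persistence", "models")
  if (!all(stages %in% known)) {
    stop(sprintf("unknown stage(s): %s",
                 paste(setdiff(stages, known), collapse = ", ")),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    package = "synopticr",
    version = as.character(utils::packageVersion("synopticr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    stages = as.list(stages),
    options = list(penalty = penalty, min_seg = min_seg,
                   min_overlap = min_overlap, outlet_rule = outlet_rule,
                   exclude_valley = exclude_valley,
                   candidates = candidates),
    penalty_formula = switch(as.character(penalty[1]),
                             bic = "2 * log(n) per changepoint",
                             mbic = paste("1.5 * log(n) per changepoint +",
                                          "log(segment length / n) per segment"),
                             sprintf("manual beta = %s", penalty[1])),
    stage_status = list(),
    warnings = list())
  finish <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stage_status[[name]] <<- paste("error:", conditionMessage(res))
      finish()
      stop(sprintf("stage %s failed: %s", name, conditionMessage(res)),
           call. = FALSE)
    }
    manifest$stage_status[[name]] <<- "ok"
    res
  }

  # -- simulate / load -------------------------------------------------------
  truth <- NULL
  if (inherits(input, "watershed_config")) {
    sim <- run_stage("simulate", simulate_watershed(input))
    table <- sim$table
    truth <- sim$truth
    manifest$input <- "simulated"
    manifest$simulate_seed <- input$seed
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  } else if (inherits(input, "site_table")) {
    table <- input
    manifest$input <- "in-memory site_table"
  } else {
    table <- run_stage("read", read_site_table(input))
    manifest$input <- as.character(input)
  }
  manifest$config_hash <- rlang::hash(list(tibble::as_tibble(table),
                                           manifest$options, seed))

  # -- validate (always) -----------------------------------------------------
  diag <- run_stage("validate", validate_site_table(table, action = "report"))
  manifest$warnings$validate <- diag$warnings
  write_site_table(table, file.path(out_dir, "sites.csv"))
  manifest$n_records <- nrow(table)

  solutes <- site_solutes(table)

  if ("changepoints" %in% stages) {
    cp <- run_stage("changepoints", {
      dplyr::bind_rows(lapply(solutes, function(s) {
        tidy_changepoints(pelt_changepoints(
          order_by_area(table, s), penalty = penalty, min_seg = min_seg))
      }))
    })
    readr::write_csv(cp, file.path(out_dir, "changepoints.csv"))
  }

  if ("leverage" %in% stages) {
    lev <- run_stage("leverage", {
      tab <- if (exclude_valley) exclude_valley_tributaries(table) else table
      leverage_table(tab, outlet_rule = outlet_rule)
    })
    readr::write_csv(lev, file.path(out_dir, "leverage.csv"))
    readr::write_csv(summarize_leverage(lev),
                     file.path(out_dir, "leverage_summary.csv"))
  }

  if ("persistence" %in% stages) {
    per <- run_stage("persistence",
                     persistence_matrix(table, min_overlap = min_overlap))
    readr::write_csv(per, file.path(out_dir, "persistence.csv"))
    readr::write_csv(suppressWarnings(persistence_summary(per)),
                     file.path(out_dir, "persistence_summary.csv"))
  }

  if ("models" %in% stages) {
    fits <- run_stage("models", {
      lapply(solutes, function(s) best_subset(table, s,
                                              candidates = candidates))
    })
    models <- dplyr::bind_rows(lapply(fits, function(f) {
      tibble::tibble(
        solute = f$response,
        model = if (length(f$predictors) == 0L) "(intercept)" else
          paste(f$predictors, collapse = " + "),
        r_squared = f$r_squared, aicc = f$aicc, n = f$n)
    }))
    audit <- dplyr::bind_rows(lapply(fits, function(f)
      dplyr::mutate(f$audit, solute = f$response, .before = 1)))
    readr::write_csv(models, file.path(out_dir, "models.csv"))
    readr::write_csv(audit, file.path(out_dir, "models_audit.csv"))
  }

  finish()
  invisible(manifest)
}
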