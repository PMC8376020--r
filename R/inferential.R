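#' Factorial ANOVA on solute concentration
#'
#' Fixed-effects linear model with the listed factors (main effects; add the
#' interaction with `interaction = TRUE`, e.g. for a season-by-category
#' test), summarised with Type-II sums of squares.
#'
#' @param x A `site_table` or data frame.
#' @param response Response column (a solute).
#' @param factors Character vector of factor columns (e.g. `"season"`,
#'   `"category"`); each must have at least two levels with at least two
#'   observations.
#' @param interaction Include the two-way interaction(s)? Default `FALSE`.
#' @return Tibble: `term`, `f_stat`, `df`, `df_resid`, `p_value`.
#' @export
solute_anova <- function(x, response, factors, interaction = FALSE) {
  df <- as.data.frame(x)[, c(response, factors)]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    tab <- table(df[[f]])
    if (length(tab) < 2L) {
      stop(sprintf("solute_anova: factor %s has a single level", f),
           call. = FALSE)
    }
    if (any(tab < 2L)) {
      stop(sprintf("solute_anova: factor %s has level(s) with < 2 observations: %s",
                   f, paste(names(tab)[tab < 2L], collapse = ", ")),
           call. = FALSE)
    }
  }
  if (interaction && length(factors) >= 2L) {
    cells <- table(df[factors])
    if (any(cells == 0L)) {
      empty <- which(cells == 0L, arr.ind = TRUE)
      lab <- apply(empty, 1L, function(i)
        paste(mapply(function(d, j) dimnames(cells)[[d]][j],
                     seq_along(factors), i), collapse = " x "))
      stop(sprintf("solute_anova: empty cell(s) with interaction requested: %s",
                   paste(lab, collapse = "; ")), call. = FALSE)
    }
  }
  op <- if (interaction) " * " else " + "
  fml <- stats::reformulate(paste(factors, collapse = op), response)
  fit <- stats::lm(fml, data = df)
  terms_lab <- attr(stats::terms(fit), "term.labels")
  if (stats::var(df[[response]]) < .Machine$double.eps) {
    # constant response: no variance to attribute, F = 0 and p = 1
    return(tibble::tibble(
      term = terms_lab, f_stat = 0, df = NA_integer_,
      df_resid = stats::df.residual(fit), p_value = 1))
  }
  aov2 <- car::Anova(fit, type = 2)
  terms <- rownames(aov2)
  resid_row <- terms == "Residuals"
  tibble::tibble(
    term = terms[!resid_row],
    f_stat = aov2$`F value`[!resid_row],
    df = aov2$Df[!resid_row],
    df_resid = aov2$Df[resid_row],
    p_value = aov2$`Pr(>F)`[!resid_row])
}

#' Tukey honest significant difference post-hoc comparisons
#'
#' Studentized-range adjusted p-values for all pairwise level differences of
#' one factor, after a one-way ANOVA.
#'
#' @inheritParams solute_anova
#' @param factor_col The factor whose levels are compared.
#' @return Tibble: `contrast`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(x, response, factor_col) {
  df <- as.data.frame(x)[, c(response, factor_col)]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df[[factor_col]] <- factor(df[[factor_col]])
  tab <- table(df[[factor_col]])
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("tukey_hsd: every level needs >= 2 observations and >= 2 levels",
         call. = FALSE)
  }
  fit <- stats::aov(stats::reformulate(factor_col, response), data = df)
  th <- stats::TukeyHSD(fit)[[factor_col]]
  tibble::tibble(
    contrast = rownames(th),
    diff = th[, "diff"],
    lwr = th[, "lwr"],
    upr = th[, "upr"],
    p_adj = th[, "p adj"])
}

#' Second-order (small-sample) Akaike Information Criterion
#'
#' `AICc = -2 * logL + 2k + 2k(k + 1) / (n - k - 1)`, defined only for
#' `n > k + 1`; converges to AIC as `n` grows.
#'
#' @param log_likelihood Maximised log-likelihood.
#' @param k Number of estimated parameters (count the residual variance).
#' @param n Number of observations.
#' @return Scalar AICc.
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1) {
    stop("AICc undefined: n <= k + 1", call. = FALSE)
  }
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets regression selected by AICc
#'
#' Fits an ordinary-least-squares model for every subset of the candidate
#' predictors (including the intercept-only model; `2^p` fits) and returns
#' the subset with the smallest AICc. `season` enters as a categorical
#' predictor (two dummy columns, counted accordingly in `k`); land-cover
#' candidates are numeric fractions. Ties are broken toward fewer
#' predictors, then lexicographically, so selection is deterministic and
#' invariant to predictor order. Collinear subsets (any aliased coefficient)
#' are skipped with a warning.
#'
#' Note on model family: the survey methodology names generalized least
#' squares but specifies no correlation or variance structure; this
#' implementation uses OLS (the identity-structure GLS special case).
#'
#' @param x A `site_table` or data frame.
#' @param response Response column (a solute), mg/L.
#' @param candidates Candidate predictor columns. Default: season and the
#'   four land-cover fractions.
#' @param log_response Model `log(response)` instead (strictly positive
#'   responses only). Default `FALSE`.
#' @return A `model_fit`: list with `response`, `predictors`,
#'   `coefficients`, `r_squared`, `aicc`, `n`, the fitted `lm` and an
#'   `audit` tibble of every subset's AICc.
#' @export
best_subset <- function(x, response,
                        candidates = c("season", land_cover_classes()),
                        log_response = FALSE) {
  if (length(candidates) > 10L) {
    stop("best_subset: more than 10 candidates (exhaustive search)",
         call. = FALSE)
  }
  df <- as.data.frame(x)[, c(response, candidates)]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10L) {
    stop("best_subset: fewer than 10 complete cases", call. = FALSE)
  }
  if ("season" %in% candidates) df$season <- factor(df$season)
  if (log_response) {
    if (any(df[[response]] <= 0)) {
      stop("best_subset: log_response requires positive concentrations",
           call. = FALSE)
    }
    df[[response]] <- log(df[[response]])
  }
  n <- nrow(df)
  candidates <- sort(candidates)          # canonical order: order-invariant

  p <- length(candidates)
  subsets <- lapply(seq_len(2^p) - 1L, function(mask) {
    candidates[bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0L]
  })

  fits <- vector("list", length(subsets))
  audit <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    preds <- subsets[[i]]
    fml <- if (length(preds) == 0L) {
      stats::reformulate("1", response)
    } else {
      stats::reformulate(preds, response)
    }
    fit <- stats::lm(fml, data = df)
    if (anyNA(stats::coef(fit))) {
      warning(sprintf("best_subset: collinear subset skipped: {%s}",
                      paste(preds, collapse = ", ")), call. = FALSE)
      next
    }
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")                   # coefficients + residual variance
    a <- aicc(as.numeric(ll), k, n)
    fits[[i]] <- fit
    audit[[i]] <- tibble::tibble(
      subset = paste(preds, collapse = "+"),
      n_predictors = length(preds),
      k = k,
      aicc = a,
      r_squared = summary(fit)$r.squared)
  }
  audit <- dplyr::bind_rows(audit)
  if (nrow(audit) == 0L) {
    stop("best_subset: no estimable subset", call. = FALSE)
  }
  ord <- order(audit$aicc, audit$n_predictors, xtfrm(audit$subset),
               method = "radix")
  best_row <- audit[ord[1], ]
  best_preds <- if (nzchar(best_row$subset)) {
    strsplit(best_row$subset, "+", fixed = TRUE)[[1]]
  } else {
    character()
  }
  best_idx <- which(vapply(subsets, function(s)
    identical(sort(s), sort(best_preds)), logical(1)))
  fit <- fits[[best_idx]]
  structure(
    list(response = response,
         predictors = best_preds,
         coefficients = stats::coef(fit),
         r_squared = best_row$r_squared,
         aicc = best_row$aicc,
         n = n,
         fit = fit,
         audit = audit[order(audit$aicc), ]),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  terms <- if (length(x$predictors) == 0L) "(intercept only)" else {
    signs <- vapply(x$predictors, function(p) {
      cf <- x$coefficients[startsWith(names(x$coefficients), p)]
      if (all(cf >= 0)) "+" else if (all(cf < 0)) "-" else "+/-"
    }, character(1))
    paste(sprintf("%s%s", signs, x$predictors), collapse = " ")
  }
  cat(sprintf("<model_fit> %s ~ %s\n  R^2 = %.3f, AICc = %.2f, n = %d\n",
              x$response, terms, x$r_squared, x$aicc, x$n))
  invisible(x)
}
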