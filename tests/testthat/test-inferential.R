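test_that("one-way F equals the squared pooled t for two balanced groups", {
  set.seed(12)
  df <- data.frame(
    DOC = c(rnorm(15, 2), rnorm(15, 3)),
    category = rep(c("MixedDammed", "MountainUrban"), each = 15))
  a <- solute_anova(df, "DOC", "category")
  tt <- t.test(DOC ~ category, data = df, var.equal = TRUE)
  expect_equal(a$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("anova degenerates sensibly and enforces its preconditions", {
  df <- data.frame(DOC = rep(2, 12),
                   season = rep(c("Spring", "Summer", "Fall"), 4))
  a <- solute_anova(df, "DOC", "season")
  expect_true(is.na(a$f_stat) || a$f_stat < 1e-10)
  one <- data.frame(DOC = rnorm(5), season = c("Spring", rep("Summer", 4)))
  expect_error(solute_anova(one, "DOC", "season"), "< 2 observations")
  single <- data.frame(DOC = rnorm(5), season = "Spring")
  expect_error(solute_anova(single, "DOC", "season"), "single level")
})

test_that("interaction requests fail on empty cells, naming the cell", {
  df <- expand.grid(season = c("Spring", "Summer"),
                    category = c("MixedDammed", "MountainUrban"),
                    rep = 1:3)
  df$DOC <- rnorm(nrow(df))
  df <- df[!(df$season == "Spring" & df$category == "MountainUrban"), ]
  expect_error(solute_anova(df, "DOC", c("season", "category"),
                            interaction = TRUE),
               "empty cell.*Spring.*MountainUrban")
})

test_that("Tukey HSD reduces to the anova p with two levels and enumerates pairs", {
  set.seed(4)
  df <- data.frame(DOC = rnorm(24, rep(c(1, 2), each = 12)),
                   category = rep(c("MixedDammed", "MountainUrban"), each = 12))
  th <- tukey_hsd(df, "DOC", "category")
  a <- solute_anova(df, "DOC", "category")
  expect_equal(nrow(th), 1)
  expect_equal(th$p_adj, a$p_value, tolerance = 1e-8)
  # four levels -> six pairwise comparisons
  df4 <- data.frame(DOC = rnorm(40), f = rep(letters[1:4], each = 10))
  expect_equal(nrow(tukey_hsd(df4, "DOC", "f")), 6)
  # identical group means -> adjusted p near 1
  dfe <- data.frame(DOC = rep(c(1, 1.0000001), 20),
                    f = rep(letters[1:4], each = 10))
  expect_true(all(tukey_hsd(dfe, "DOC", "f")$p_adj > 0.99))
})

test_that("AICc follows its closed form and limits", {
  expect_equal(aicc(-10, 2, 10), 20 + 4 + 12 / 7)
  expect_equal(aicc(-10, 0, 10), 20)            # k = 0 reduces to -2 logL
  # large-n limit approaches AIC
  expect_equal(aicc(-10, 3, 1e7), -2 * -10 + 6, tolerance = 1e-5)
  expect_error(aicc(-10, 9, 10), "AICc undefined")
})

test_that("best_subset enumerates every subset and recovers a planted predictor", {
  sk <- generate_network(watershed_config(seed = 2, n_sites = 120))
  df <- sk$sites[, c("forest", "developed", "impervious", "herbaceous")]
  df$season <- rep(watershed_seasons(), length.out = nrow(df))
  withr::with_seed(8, {
    df$TDN <- 3 * df$impervious + rnorm(nrow(df), 0, 0.03)
  })
  fit <- best_subset(df, "TDN")
  expect_equal(nrow(fit$audit), 32)             # 2^5 subsets
  expect_true("impervious" %in% fit$predictors)
  expect_gt(fit$coefficients[["impervious"]], 0)
  expect_gt(fit$r_squared, 0.9)
})

test_that("best_subset is invariant to candidate order and ties go to parsimony", {
  sk <- generate_network(watershed_config(seed = 9, n_sites = 80))
  df <- sk$sites[, c("forest", "developed", "impervious", "herbaceous")]
  df$season <- rep(watershed_seasons(), length.out = nrow(df))
  withr::with_seed(21, df$Cl <- 40 + 10 * df$herbaceous + rnorm(nrow(df), 0, 1))
  f1 <- best_subset(df, "Cl",
                    candidates = c("season", "forest", "developed",
                                   "impervious", "herbaceous"))
  f2 <- best_subset(df, "Cl",
                    candidates = c("herbaceous", "impervious", "developed",
                                   "forest", "season"))
  expect_identical(f1$predictors, f2$predictors)
  expect_equal(f1$aicc, f2$aicc)
})

test_that("nested models never increase in fit: RSS is monotone in the audit", {
  sk <- generate_network(watershed_config(seed = 13, n_sites = 60))
  df <- sk$sites[, c("forest", "developed", "impervious", "herbaceous")]
  withr::with_seed(3, df$DOC <- 2 + df$forest + rnorm(nrow(df), 0, 0.5))
  fit <- best_subset(df, "DOC",
                     candidates = c("forest", "developed", "impervious"))
  # R^2 of the full model is at least that of every subset
  full <- fit$audit$r_squared[fit$audit$n_predictors == 3]
  expect_true(all(full >= fit$audit$r_squared - 1e-12))
})

test_that("collinear subsets are skipped with a warning", {
  df <- data.frame(forest = runif(30), developed = runif(30))
  df$impervious <- df$developed              # exact collinearity
  df$DOC <- rnorm(30)
  w <- capture_warnings(
    fit <- best_subset(df, "DOC",
                       candidates = c("forest", "developed", "impervious")))
  expect_match(w, "collinear", all = FALSE)
  expect_lt(nrow(fit$audit), 8)
})
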