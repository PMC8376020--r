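test_that("the generator is deterministic under seed and changes with it", {
  cfg <- watershed_config(seed = 42, n_sites = 60)
  t1 <- simulate_watershed(cfg)$table
  t2 <- simulate_watershed(cfg)$table
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
  t3 <- simulate_watershed(watershed_config(seed = 43, n_sites = 60))$table
  expect_identical(names(t3), names(t1))       # schema stable
  expect_false(identical(t3$DOC, t1$DOC))      # values differ
})

test_that("outlet areas equal the sum of their network's leaf areas", {
  sk <- generate_network(watershed_config(seed = 8))
  sites <- sk$sites
  for (net in unique(sites$network[sites$is_outlet])) {
    s <- sites[sites$network == net, ]
    expect_equal(s$area_km2[s$is_outlet],
                 sum(s$area_km2[s$is_leaf]), tolerance = 1e-12)
  }
  # internal areas are sums of their children
  with_parent <- sites[!is.na(sites$parent), ]
  child_sums <- tapply(with_parent$area_km2, with_parent$parent, sum)
  internal <- sites[sites$site_id %in% names(child_sums), ]
  expect_equal(as.vector(child_sums[internal$site_id]), internal$area_km2,
               tolerance = 1e-12)
})

test_that("generated tables pass validation with zero warnings", {
  for (s in c(1, 17)) {
    tbl <- simulate_watershed(watershed_config(seed = s))$table
    diag <- validate_site_table(tbl, action = "report")
    expect_length(diag$errors, 0)
    expect_length(diag$warnings, 0)
  }
})

test_that("valley tributaries networks have no outlet and break leverage", {
  sim <- simulate_watershed(watershed_config(seed = 4))
  valley <- filter_sites(sim$table, category = "ValleyTributaries")
  expect_gt(nrow(valley), 0)
  expect_false(any(valley$is_outlet))
  expect_error(network_leverage(sim$table, "TDN", "Spring"),
               "no single outlet")
})

test_that("conservative routing with no noise collapses to the baseline", {
  sp <- default_solute_params()
  sp$eta_sd <- 0
  sp$eps_sd <- 0
  sp$coef_forest <- 0
  sp$coef_developed <- 0
  sp$coef_impervious <- 0
  sp$coef_herbaceous <- 0
  cfg <- watershed_config(seed = 5, n_sites = 40, solute_params = sp,
                          hourglass = FALSE, conservative_routing = TRUE,
                          season_factors = c(Spring = 1, Summer = 1, Fall = 1))
  sim <- simulate_watershed(cfg)
  expect_equal(unique(round(sim$table$DOC, 12)), 3.5)
  lev <- leverage_table(exclude_valley_tributaries(sim$table),
                        solutes = "DOC", seasons = "Spring")
  expect_true(all(abs(lev$leverage_pct) < 1e-9))
})

test_that("conservative routing conserves mass exactly despite noise", {
  sim <- simulate_watershed(watershed_config(seed = 6,
                                             conservative_routing = TRUE))
  leaves <- sim$skeleton$sites$site_id[sim$skeleton$sites$is_leaf]
  lev <- leverage_table(exclude_valley_tributaries(sim$table))
  sums <- lev[lev$site_id %in% leaves, ] |>
    dplyr::group_by(.data$network, .data$solute, .data$season) |>
    dplyr::summarise(s = sum(.data$leverage_conc), .groups = "drop")
  expect_equal(nrow(sums), 4 * 6 * 3)  # every network x solute x season
  expect_lt(max(abs(sums$s)), 1e-9)
})

test_that("ground truth records planted structure consistent with the table", {
  sim <- simulate_watershed(watershed_config(seed = 10))
  expect_true(all(sim$truth$planted_source_sites %in% sim$table$site_id))
  expect_gt(length(sim$truth$planted_source_sites), 0)
  expect_setequal(names(sim$truth$true_predictor_subsets),
                  watershed_solutes())
  expect_true(all(c("season", "impervious") %in%
                    sim$truth$true_predictor_subsets$TDN))
  # conservative-ion rank share exceeds the reactive nutrients' share
  expect_gt(sim$truth$true_rank_share[["Cl"]],
            sim$truth$true_rank_share[["PO4"]])
})

test_that("the hourglass flag controls small/large-area variance inflation", {
  hits <- 0
  for (s in 1:6) {
    sim <- simulate_watershed(watershed_config(seed = s))
    for (sol in c("Cl", "SO4")) {
      ser <- order_by_area(sim$table, sol)
      dec <- cut(seq_along(ser$values), 10, labels = FALSE)
      v <- tapply(ser$values, dec, var)
      hits <- hits + (v[[1]] > mean(v[4:7]) && v[[10]] > mean(v[4:7]))
    }
  }
  expect_gte(hits, 10)  # 12 seed x solute combinations
  # with hourglass off, the small-area arm loses its inflation
  off <- simulate_watershed(watershed_config(seed = 1, hourglass = FALSE))
  on <- simulate_watershed(watershed_config(seed = 1, hourglass = TRUE))
  v_of <- function(sim) {
    ser <- order_by_area(sim$table, "Cl")
    dec <- cut(seq_along(ser$values), 10, labels = FALSE)
    tapply(ser$values, dec, var)[[1]]
  }
  expect_gt(v_of(on), v_of(off))
})

test_that("planted variance regimes are recovered by the changepoint stage", {
  sk <- generate_network(watershed_config(seed = 5, n_sites = 100))
  areas <- sort(sk$sites$area_km2)
  b <- sqrt(areas[50] * areas[51])
  hits <- vapply(1:40, function(s) {
    pl <- plant_variance_regime(sk, b, c(0.3, 3), seed = 100 + s)
    cp <- pelt_changepoints(order_by_area(pl$table, "DOC"))
    length(cp$changepoints) >= 1 &&
      min(abs(cp$changepoints - pl$truth$boundary_index)) <= 3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # sd ratio 1: mostly no changepoints
  fp <- vapply(1:40, function(s) {
    pl <- plant_variance_regime(sk, b, c(1, 1), seed = 500 + s)
    length(pelt_changepoints(order_by_area(pl$table, "DOC"))$changepoints) > 0
  }, logical(1))
  expect_lte(mean(fp), 0.15)
  # two planted boundaries -> two recovered changepoints
  b2 <- c(sqrt(areas[33] * areas[34]), sqrt(areas[66] * areas[67]))
  two <- vapply(1:40, function(s) {
    pl <- plant_variance_regime(sk, b2, c(0.2, 2.5, 0.2), seed = 900 + s)
    cp <- pelt_changepoints(order_by_area(pl$table, "DOC"))
    length(cp$changepoints) == 2 &&
      all(abs(cp$changepoints - pl$truth$boundary_index) <= 3)
  }, logical(1))
  expect_gte(mean(two), 0.85)
  expect_error(plant_variance_regime(sk, 1e6, c(1, 2)), "outside")
})
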