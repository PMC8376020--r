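test_that("z-scaling centres, scales and rejects degenerate input", {
  expect_equal(scale_concentrations(c(2, 4, 6)), c(-1, 0, 1))
  z <- scale_concentrations(1:5)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(z[1], -2 / sqrt(2.5))
  expect_error(scale_concentrations(c(5, 5, 5)), "degenerate series")
  expect_error(scale_concentrations(3), "at least 2")
  expect_error(scale_concentrations(c(1, NA, 2)), "non-finite")
})

test_that("area ordering sorts ascending, breaks ties by site id, drops nulls", {
  df <- tibble::as_tibble(tiny_table())[1:3, ]
  df <- rbind(df, df, df)  # 9 rows; make them distinct sites
  df$site_id <- c("C", "B", "A", "F", "E", "D", "I", "H", "G")
  df$season <- "Spring"
  df$area_km2 <- c(10, 1, 5, 7, 7, 0, 3, 20, 2)
  df$is_outlet <- FALSE
  df$DOC <- c(1, 2, 3, 4, 5, 6, 7, 8, NA)
  tbl <- as_site_table(df)
  ser <- order_by_area(tbl, "DOC")
  expect_false(is.unsorted(ser$areas_km2))
  expect_equal(ser$site_ids[1], "D")                # area 0 sorts first
  tied <- ser$site_ids[ser$areas_km2 == 7]
  expect_equal(tied, c("E", "F"))                   # tie broken by id
  expect_false("G" %in% ser$site_ids)               # null dropped
  expect_equal(mean(ser$values), 0, tolerance = 1e-12)
  expect_equal(sd(ser$values), 1, tolerance = 1e-12)
  expect_error(order_by_area(tbl[1:3, ], "DOC"), "fewer than 4")
})

test_that("segment cost follows the zero-mean gaussian formula", {
  expect_equal(segment_cost(c(1, -1)), 2 * (log(2 * pi) + 1))
  # variance floor keeps all-zero segments finite
  expect_equal(segment_cost(c(0, 0)), 2 * (log(2 * pi) + log(1e-8) + 1))
  # doubling values adds 2m log 2
  x <- c(0.3, -1.2, 0.8, 0.1)
  expect_equal(segment_cost(2 * x) - segment_cost(x), 2 * 4 * log(2))
})

test_that("PELT finds the planted variance break in the 12-point worked series", {
  x <- c(0.10, -0.12, 0.05, -0.07, 0.11, -0.09,
         2.0, -1.6, 1.9, -2.1, 2.4, -1.8)
  res <- pelt_changepoints(x, penalty = "bic")
  expect_equal(res$changepoints, 6L)  # last index of the quiet left segment
  expect_length(res$segment_variances, 2)
  expect_lt(res$segment_variances[1], res$segment_variances[2])
  oracle <- brute_force_changepoints(x, penalty = "bic")
  expect_identical(res$changepoints, oracle$changepoints)
  expect_equal(res$cost_total, oracle$cost_total)
})

test_that("PELT equals the exhaustive oracle across random series and penalties", {
  set.seed(421)
  for (i in 1:80) {
    n <- sample(8:30, 1)
    x <- rnorm(n, 0, sample(c(0.2, 1, 3), 1))
    if (runif(1) < 0.5) {
      k <- sample(2:(n - 2), 1)
      x[1:k] <- x[1:k] * sample(c(0.1, 5), 1)
    }
    for (pen in list("bic", "mbic", 3)) {
      p <- pelt_changepoints(x, pen)
      b <- brute_force_changepoints(x, pen)
      expect_identical(p$changepoints, b$changepoints)
      expect_equal(p$cost_total, b$cost_total, tolerance = 1e-10)
    }
  }
})

test_that("the number of changepoints is non-increasing in the manual penalty", {
  set.seed(7)
  x <- c(rnorm(30, 0, 0.2), rnorm(30, 0, 2), rnorm(30, 0, 0.5))
  ks <- vapply(c(0.5, 2, 5, 10, 20, 50, 200),
               function(b) length(pelt_changepoints(x, b)$changepoints),
               integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("changepoints are invariant to shifting raw concentrations", {
  df <- tibble::as_tibble(tiny_table())
  set.seed(11)
  df <- do.call(rbind, replicate(10, df, simplify = FALSE))
  df$site_id <- sprintf("S%02d", seq_len(nrow(df)))
  df$season <- "Spring"
  df$is_outlet <- FALSE
  df$area_km2 <- sort(exp(runif(nrow(df), 0, 6)))
  df$DOC <- c(rnorm(30, 5, 0.1), rnorm(30, 5, 2))
  tbl <- as_site_table(df)
  shifted <- df
  shifted$DOC <- shifted$DOC + 100
  r1 <- pelt_changepoints(order_by_area(tbl, "DOC"))
  r2 <- pelt_changepoints(order_by_area(as_site_table(shifted), "DOC"))
  expect_identical(r1$changepoints, r2$changepoints)
  expect_equal(r1$segment_variances, r2$segment_variances)
})

test_that("the oracle refuses large series and enforces minimum length", {
  expect_error(brute_force_changepoints(rnorm(41)), "oracle limit")
  expect_error(pelt_changepoints(rnorm(3), min_seg = 2), "too small")
  expect_error(pelt_changepoints(c(1, NA, 2, 4)), "non-finite")
})

test_that("tidy_changepoints reports one row per segment with its boundary area", {
  sk <- generate_network(watershed_config(seed = 31, n_sites = 60))
  pl <- plant_variance_regime(sk, boundaries_km2 = 30, sds = c(0.2, 2),
                              seed = 5)
  ser <- order_by_area(pl$table, "DOC")
  res <- pelt_changepoints(ser)
  td <- tidy_changepoints(res)
  expect_equal(nrow(td), length(res$changepoints) + 1L)
  expect_true(all(is.na(td$changepoint_index[nrow(td)])))
  if (length(res$changepoints) > 0) {
    expect_equal(td$changepoint_area_km2[1],
                 ser$areas_km2[res$changepoints[1]])
  }
})
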