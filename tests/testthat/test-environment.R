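test_that("climate rate is the OLS temperature slope", {
  expect_identical(climate_rate(rep(9.5, 12)), 0)
  expect_equal(climate_rate(10 + 0.02 * (0:19)), 0.02, tolerance = 1e-12)
  set.seed(3)
  x <- 1:15; y <- rnorm(15, 8, 1)
  oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(climate_rate(y), oracle, tolerance = 1e-12)
  expect_error(climate_rate(c(1, NA, 3)), "missing")
  expect_error(climate_rate(c(1, 2, 3), years = c(1, 2, 4)), "missing years")
})

test_that("land-use rate is the mean annual difference (endpoint identity)", {
  expect_identical(landuse_rate(rep(0.4, 8)), 0)
  expect_equal(landuse_rate(c(0.2, 0.3, 0.4)), 0.1)
  set.seed(4)
  for (i in 1:10) {
    f <- runif(sample(3:30, 1))
    expect_equal(landuse_rate(f), (f[length(f)] - f[1]) / (length(f) - 1),
                 tolerance = 1e-12)
  }
  expect_error(landuse_rate(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("lag windows offset the monitoring span without changing its length", {
  expect_identical(lag_window(c(1990, 2000), 5), c(1985, 1995))
  expect_identical(lag_window(c(1990, 2000), 0), c(1990, 2000))
  # 49-year lag from 1950 lands exactly on the 1901 coverage limit
  expect_identical(lag_window(c(1950, 1960), 49, env_start = 1901), c(1901, 1911))
  expect_error(lag_window(c(1950, 1960), 50, env_start = 1901), "1900")
})

test_that("generation lags convert to whole years by round-half-up", {
  expect_identical(generations_to_years(2, 25), 50L)  # African elephant
  expect_identical(generations_to_years(2, 1), 2L)    # Eurasian pygmy shrew
  expect_identical(generations_to_years(0.3, 1), 0L)
  expect_identical(generations_to_years(0.5, 1), 1L)  # half rounds up
  expect_identical(generations_to_years(1.25, 2), 3L)
  expect_error(generations_to_years(-1, 5), "positive")
})

test_that("lag grids cross every driver combination without duplicates", {
  g <- lag_grid("bird", "years")
  expect_identical(nrow(g), 2500L)
  expect_identical(anyDuplicated(g), 0L)
  reduced <- lag_grid("bird", "years", year_lags = 0:10)
  expect_identical(nrow(reduced), 121L)
  expect_identical(length(generation_grid("bird")), 29L)
  expect_identical(length(generation_grid("mammal")), 21L)
  expect_error(lag_grid("bird", "years", year_lags = c(-1, 0)), "non-negative")
})

test_that("driver rates honour lags, currencies and coverage limits", {
  sim <- small_sim()
  tr <- sim$trends
  meta <- sim$populations$meta
  env <- sim$environment
  r0 <- driver_rates(tr, meta, env, 0, 0)
  # lag 0 equals unlagged rates recomputed by hand for one population
  i <- 1
  s <- env[env$location_key == meta$location_key[match(tr$population_id[i],
                                                       meta$population_id)] &
             env$scenario == "historical", ]
  s <- s[order(s$year), ]
  win <- s$year >= tr$start_year[i] & s$year <= tr$end_year[i]
  expect_equal(r0$CC[i], climate_rate(s$temperature_C[win]), tolerance = 1e-12)
  expect_equal(r0$LUC[i], landuse_rate(s$anthro_fraction[win]), tolerance = 1e-12)
  # brute-force window oracle at a non-zero lag
  r5 <- driver_rates(tr, meta, env, 5, 3)
  win5 <- s$year >= tr$start_year[i] - 5 & s$year <= tr$end_year[i] - 5
  win3 <- s$year >= tr$start_year[i] - 3 & s$year <= tr$end_year[i] - 3
  expect_equal(r5$CC[i], climate_rate(s$temperature_C[win5]), tolerance = 1e-12)
  expect_equal(r5$LUC[i], landuse_rate(s$anthro_fraction[win3]), tolerance = 1e-12)
  # generation currency equals year currency run with the converted lags,
  # population by population
  gl <- meta$generation_length_y[match(tr$population_id, meta$population_id)]
  mult <- 1.3
  rg <- driver_rates(tr, meta, env, mult, mult, currency = "generations")
  expect_identical(rg$cc_lag_years, generations_to_years(mult, gl))
  for (j in unique(rg$cc_lag_years)) {
    idx <- which(rg$cc_lag_years == j)
    ry <- driver_rates(tr[idx, , drop = FALSE], meta, env, j, j)
    expect_equal(rg$CC[idx], ry$CC, tolerance = 1e-12)
    expect_equal(rg$LUC[idx], ry$LUC, tolerance = 1e-12)
  }
  # windows before coverage abort with the limiting year reported
  expect_error(driver_rates(tr, meta, env, 60, 0), "before environmental coverage")
})
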