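test_that("index path follows the decadal closed form", {
  expect_equal(index_path(c(0, 0, 0))$index, c(1, 1, 1, 1))
  expect_equal(index_path(0.01)$index[2], 10^0.1, tolerance = 1e-12)
  # multiplicative symmetry: equal and opposite decades cancel
  expect_equal(index_path(c(0.01, -0.01))$index[3], 1, tolerance = 1e-12)
  # splitting a decade's trend into equal sub-periods leaves the end value
  expect_equal(index_path(0.02, step = 10)$index[2],
               index_path(c(0.02, 0.02), step = 5)$index[3], tolerance = 1e-12)
  expect_error(index_path(c(0.01, NA)), "non-finite")
})

test_that("hierarchical averaging is unweighted at each level", {
  # two species in one realm: 3 populations at 0.1 average to 0.1, then with
  # the 0.3 species the class value is 0.2
  h <- hierarchical_average(c(0.1, 0.1, 0.1, 0.3),
                            species = c("a", "a", "a", "b"),
                            realm = rep("Palearctic", 4))
  expect_equal(h$class, 0.2)
  expect_equal(hierarchical_average(0.05, "a", "r")$class, 0.05)
  # order invariance and boundedness
  set.seed(8)
  lam <- rnorm(30, 0, 0.05)
  sp <- sample(letters[1:6], 30, TRUE)
  rl <- sample(c("r1", "r2"), 30, TRUE)
  o <- sample(30)
  expect_equal(hierarchical_average(lam, sp, rl)$class,
               hierarchical_average(lam[o], sp[o], rl[o])$class,
               tolerance = 1e-12)
  expect_gte(hierarchical_average(lam, sp, rl)$class, min(lam))
  expect_lte(hierarchical_average(lam, sp, rl)$class, max(lam))
})

test_that("model averaging requires aligned, normalized weights", {
  expect_equal(model_average_trend(0.02, 1), 0.02)
  expect_equal(model_average_trend(c(0, 0.04), c(0.75, 0.25)), 0.01)
  expect_error(model_average_trend(c(0, 1), c(0.6, 0.6)), "sum to 1")
  expect_error(model_average_trend(c(0, 1), 1), "one weight per")
})

test_that("lock-in classification follows the lagged-window arithmetic", {
  expect_identical(dependence_classification(30, 30, c(2010, 2020)),
                   c(cc = "fully", luc = "fully"))
  expect_identical(dependence_classification(5, 5, c(2010, 2020))[["cc"]],
                   "partially")
  expect_identical(dependence_classification(0, 0, c(2020, 2030))[["luc"]],
                   "not")
  # differing driver lags are classified per driver
  expect_identical(dependence_classification(30, 5, c(2010, 2020)),
                   c(cc = "fully", luc = "partially"))
  # a window starting exactly at the baseline is not locked in
  expect_identical(dependence_classification(30, 0, c(2010, 2020))[["luc"]],
                   "not")
})

test_that("predictions reduce to the intercept at training means", {
  sim <- small_sim()
  meta <- sim$populations$meta
  rates <- driver_rates(sim$trends, meta, sim$environment, 0, 0)
  d <- build_design(sim$trends, rates, meta, "Base")
  ft <- fit_mixed(d, "Base")
  sc <- ft$scaling
  fake_meta <- meta[1, , drop = FALSE]
  fake_meta$body_mass_g <- 10^sc$BM["center"]
  fake_meta$protected_area <- 0
  fake_meta$binomial <- "unseen species"
  fake_meta$location_key <- "unseen location"
  fake_rates <- data.frame(population_id = fake_meta$population_id,
                           CC = sc$CC["center"], LUC = sc$LUC["center"])
  p <- predict(ft, fake_rates, fake_meta, use_ranef = TRUE)
  expect_equal(unname(p), unname(ft$coef["(Intercept)"]), tolerance = 1e-10)
  # dot-product oracle on actual covariates
  p2 <- predict(ft, rates[1:5, ], meta, use_ranef = FALSE)
  z <- function(x, s) (x - s["center"]) / s["scale"]
  i <- match(rates$population_id[1:5], meta$population_id)
  eta <- ft$coef["(Intercept)"] +
    ft$coef["CC"] * z(rates$CC[1:5], sc$CC) +
    ft$coef["LUC"] * z(rates$LUC[1:5], sc$LUC) +
    ft$coef["BM"] * z(log10(meta$body_mass_g[i]), sc$BM) +
    ft$coef["PA"] * meta$protected_area[i] +
    ft$coef["CC:LUC"] * z(rates$CC[1:5], sc$CC) * z(rates$LUC[1:5], sc$LUC)
  expect_equal(unname(p2), unname(eta), tolerance = 1e-10)
})

test_that("fully locked-in decades are scenario-invariant", {
  sim <- small_sim(seed = 31, true_lag_cc = 30, true_lag_luc = 30)
  meta <- sim$populations$meta
  grid <- data.frame(currency = "years", cc_lag = 30, luc_lag = 30)
  sc <- lag_scan(sim$trends, meta, sim$environment, "Base", grid)
  proj <- project_index(sc, sim$trends, meta, sim$environment)
  first <- proj[proj$decade_start == 2010, ]
  expect_identical(unique(first$cc_dependence), "fully")
  expect_equal(diff(range(first$index)), 0, tolerance = 1e-12)
  # later decades draw on post-divergence environment and must diverge
  last <- proj[proj$decade_start == 2040, ]
  expect_identical(unique(last$cc_dependence), "not")
  expect_gt(diff(range(last$index)), 0)
  expect_true(all(proj$index > 0))
})

test_that("decade windows reuse the lag-offset rate machinery", {
  sim <- small_sim()
  meta <- sim$populations$meta
  r <- driver_rates(sim$trends, meta, sim$environment, 30, 30,
                    scenario = "ssp1_rcp26", span = c(2010, 2020))
  # lag 30 over 2010-2020 reads the historical 1980-1990 window
  loc <- meta$location_key[match(r$population_id[1], meta$population_id)]
  e <- sim$environment
  e <- e[e$location_key == loc & e$scenario == "historical", ]
  e <- e[order(e$year), ]
  win <- e$year >= 1980 & e$year <= 1990
  expect_equal(r$CC[1], climate_rate(e$temperature_C[win]), tolerance = 1e-12)
  # before divergence the scenarios give identical rates
  r2 <- driver_rates(sim$trends, meta, sim$environment, 30, 30,
                     scenario = "ssp5_rcp85", span = c(2010, 2020))
  expect_equal(r$CC, r2$CC, tolerance = 1e-15)
  expect_equal(r$LUC, r2$LUC, tolerance = 1e-15)
})
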