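test_that("the design table is centred, scaled and complete", {
  sim <- small_sim()
  tr <- sim$trends
  meta <- sim$populations$meta
  rates <- driver_rates(tr, meta, sim$environment, 0, 0)
  d <- build_design(tr, rates, meta, "MU")
  for (v in c("CC", "LUC", "BM")) {
    expect_lt(abs(mean(d[[v]])), 1e-10)
    expect_equal(sd(d[[v]]), 1, tolerance = 1e-10)
  }
  expect_true(all(d$PA %in% 0:1))
  sc <- attr(d, "scaling")
  expect_named(sc, c("CC", "LUC", "BM"))
  # Null structure still carries response and grouping keys
  d0 <- build_design(tr, rates, meta, "Null")
  expect_true(all(c("lambda", "species", "location") %in% names(d0)))
  # a single population cannot be scaled
  expect_error(build_design(tr[1, , drop = FALSE], rates, meta, "Base"),
               "fewer than two")
})

test_that("AICc follows the small-sample formula", {
  expect_equal(aicc(-100, 5, 50), 200 + 10 + 2 * 5 * 6 / (50 - 5 - 1))
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  expect_error(aicc(0, 9, 10), "n must exceed")
})

test_that("noiseless data identify the generating coefficients", {
  cfg <- sim_config(n_species = 40, pops_per_species = c(2, 2),
                    sigma_species = 0, sigma_location = 0, sigma_resid = 0,
                    missingness = 0, zero_rate = 0, seed = 3)
  sim <- simulate_lpd(cfg)
  tr <- population_trends(sim$populations)
  rates <- driver_rates(tr, sim$populations$meta, sim$environment,
                        cfg$true_lag_cc, cfg$true_lag_luc)
  d <- build_design(tr, rates, sim$populations$meta, "MU")
  ft <- fit_mixed(d, "MU")
  b <- attr(sim$truth, "beta")
  gen <- setNames(b[c("intercept", "cc", "luc", "bm", "pa", "man", "use",
                      "cc_luc")],
                  c("(Intercept)", "CC", "LUC", "BM", "PA", "Man", "Use",
                    "CC:LUC"))
  expect_lt(max(abs(ft$coef[names(gen)] - gen)), 1e-6)
  expect_identical(ft$k, length(ft$coef) + 3L)
  expect_equal(ft$AICc, aicc(ft$logLik, ft$k, ft$n), tolerance = 1e-10)
})

test_that("the null model intercept is near the sample mean trend", {
  sim <- small_sim()
  rates <- driver_rates(sim$trends, sim$populations$meta, sim$environment, 0, 0)
  d <- build_design(sim$trends, rates, sim$populations$meta, "Null")
  ft <- fit_mixed(d, "Null")
  expect_equal(unname(ft$coef["(Intercept)"]), mean(d$lambda), tolerance = 0.01)
  # nested-model inequality at ML: richer structures fit no worse
  fb <- fit_mixed(build_design(sim$trends, rates, sim$populations$meta, "Base"),
                  "Base")
  expect_gte(fb$logLik, ft$logLik)
})

test_that("Akaike weights match their closed forms and resist overflow", {
  expect_equal(akaike_weights(c(10, 10, 10, 10)), rep(0.25, 4))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  w2 <- akaike_weights(c(0, 1000))
  expect_equal(w2[1], 1, tolerance = 1e-12)
  expect_false(any(is.nan(w2)))
  w3 <- akaike_weights(c(5, NA, 7))
  expect_true(is.na(w3[2]))
  expect_equal(sum(w3, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_error(akaike_weights(c(NA_real_, NA_real_)), "finite")
})

test_that("scan bookkeeping: weights, deltas, retention, averaging", {
  sim <- small_sim()
  meta <- sim$populations$meta
  grid <- lag_grid("bird", "years", year_lags = 0:3)
  sc <- lag_scan(sim$trends, meta, sim$environment, "Base", grid)
  tab <- sc$table
  expect_equal(sum(tab$weight, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_identical(min(tab$delta_aicc, na.rm = TRUE), 0)
  expect_true(all(tab$retained == (tab$delta_aicc < 6), na.rm = TRUE))
  # model averaging equals an independently recomputed weighted sum
  w <- retained_weights(sc)
  idx <- which(w > 0)
  oracle <- Reduce(`+`, Map(function(i, wi) wi * sc$fits[[i]]$coef,
                            idx, w[idx] / sum(w[idx])))
  avg <- coef(sc)
  expect_equal(as.numeric(avg), as.numeric(oracle), tolerance = 1e-12)
  # a grid of one combination carries the full weight
  sc1 <- lag_scan(sim$trends, meta, sim$environment, "Base",
                  grid[1, , drop = FALSE])
  expect_equal(sc1$table$weight, 1)
  expect_equal(as.numeric(coef(sc1)), as.numeric(sc1$fits[[1]]$coef))
})

test_that("lag support sums retained weights by lag value", {
  # hand-built scan table: 4 combinations, uniform weights, 2 cc-lag values
  fake <- structure(list(table = data.frame(
    currency = "years", cc_lag = c(0, 0, 5, 5), luc_lag = c(0, 1, 0, 1),
    weight = rep(0.25, 4), retained = TRUE)), class = "lag_scan")
  prof <- lag_support(fake, "cc")
  expect_equal(prof$support, c(0.5, 0.5))
  expect_equal(prof$lag, c(0, 5))
  one <- structure(list(table = data.frame(
    currency = "years", cc_lag = 3, luc_lag = 2, weight = 1, retained = TRUE)),
    class = "lag_scan")
  expect_equal(lag_support(one, "luc")$support, 1)
})

test_that("ecological subsets follow the tertile, diet and latitude rules", {
  sim <- small_sim()
  meta <- sim$populations$meta
  lat <- make_subsets(meta, "latitude")
  m0 <- meta
  m0$latitude <- c(0, 30, -40, rep(10, nrow(meta) - 3))
  lat <- make_subsets(m0, "latitude")
  expect_true(m0$population_id[1] %in% lat$tropical)
  expect_true(all(m0$population_id[2:3] %in% lat$temperate))
  # diet 70% animal is a carnivore (0.7 >= 2/3); 50/50 is excluded
  m1 <- meta
  m1$diet_animal <- 0.7; m1$diet_plant <- 0.3
  expect_setequal(make_subsets(m1, "trophic")$carnivore, m1$population_id)
  m1$diet_animal <- 0.5; m1$diet_plant <- 0.5
  tro <- make_subsets(m1, "trophic")
  expect_identical(length(tro$carnivore), 0L)
  expect_setequal(attr(tro, "dropped"), m1$population_id)
  # nine species with distinct masses split 3/3/3 and partition exhaustively
  m2 <- meta[!duplicated(meta$binomial), ][1:9, ]
  m2$body_mass_g <- 10^(1:9)
  bm <- make_subsets(m2, "body_mass")
  expect_identical(lengths(bm), c(small = 3L, medium = 3L, large = 3L))
  expect_setequal(unlist(bm), m2$population_id)
  full <- make_subsets(meta, "body_mass")
  expect_setequal(unlist(full), meta$population_id)
  expect_identical(anyDuplicated(unlist(full)), 0L)
})

test_that("case-deletion influence flags a planted extreme population", {
  sim <- small_sim(seed = 21, n_species = 20, missingness = 0)
  tr <- sim$trends
  meta <- sim$populations$meta
  rates <- driver_rates(tr, meta, sim$environment, 0, 0)
  d <- build_design(tr, rates, meta, "Base")
  # plant one population with an extreme response at extreme leverage
  d2 <- d
  d2$lambda[1] <- 1.5
  d2$CC[1] <- max(d2$CC) + 4
  infl <- influence_screen(d2, "Base")
  expect_identical(which.max(infl$cooks_d), 1L)
  expect_true(infl$flagged[1])
  # balanced duplicated data: no single case is influential because its
  # near-twin remains after deletion (tiny jitter keeps the ML fit away from
  # the zero-residual boundary)
  dd <- d[1:20, , drop = FALSE]
  d3 <- rbind(dd, dd)
  d3$population_id <- paste0(d3$population_id, "_", rep(1:2, each = nrow(dd)))
  set.seed(1)
  d3$lambda <- d3$lambda + rnorm(nrow(d3), 0, 1e-4)
  infl3 <- influence_screen(d3, "Base")
  expect_lt(max(infl3$cooks_d, na.rm = TRUE), 0.5)
})
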