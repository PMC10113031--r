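# Shared synthetic fixtures, generated in code and cached for the session.

.sim_cache <- new.env(parent = emptyenv())

# A small, clean dataset (no zeros) for scan/projection tests.
small_sim <- function(seed = 11, ...) {
  opts <- utils::modifyList(list(n_species = 40, pops_per_species = c(2, 2),
                                 zero_rate = 0, seed = seed), list(...))
  key <- paste0(names(opts), unlist(lapply(opts, paste, collapse = "_")),
                collapse = "|")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  cfg <- do.call(sim_config, opts)
  sim <- simulate_lpd(cfg)
  sim$trends <- suppressWarnings(quality_filter(population_trends(sim$populations)))
  .sim_cache[[key]] <- sim
  sim
}

# Strong-effect generating betas for parameter-recovery experiments: driver
# effects doubled relative to the realistic defaults and confined to the span
# of the Base structure (man = use = 0) so the generating model is the model
# being fitted.
recovery_beta <- c(intercept = -0.005, cc = -0.04, luc = -0.04,
                   cc_luc = -0.02, bm = -0.005, pa = 0.015,
                   man = 0, use = 0)

recovery_beta_named <- c("(Intercept)" = -0.005, CC = -0.04, LUC = -0.04,
                         BM = -0.005, PA = 0.015, "CC:LUC" = -0.02)

# One parameter-recovery replicate: n = 300 populations, Base structure,
# reduced year-lag grid 0-10.
recovery_replicate <- function(seed) {
  cfg <- sim_config(n_species = 150, pops_per_species = c(2, 2),
                    beta = recovery_beta, zero_rate = 0, seed = seed)
  sim <- simulate_lpd(cfg)
  tr <- suppressWarnings(quality_filter(population_trends(sim$populations)))
  sc <- lag_scan(tr, sim$populations$meta, sim$environment,
                 structure = "Base",
                 grid = lag_grid("bird", "years", year_lags = 0:10))
  list(scan = sc, truth = sim$truth)
}
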