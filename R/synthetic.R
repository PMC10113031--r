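#' Configuration for the synthetic Living-Planet-style generator
#'
#' Collects and validates the parameters of the synthetic data generator:
#' population counts, monitoring and environmental spans, the ground-truth
#' lag pair and effect sizes, variance components, and the observation
#' process (missingness and recorded zeros). Defaults describe a moderately
#' noisy bird dataset with strong, recoverable lag structure.
#'
#' @param n_species number of species.
#' @param pops_per_species inclusive range `c(min, max)` of populations per
#'   species.
#' @param year_span inclusive range of observation years (default 1950-2014).
#' @param env_span inclusive range of environmental years (default 1901-2100).
#' @param true_lag_cc,true_lag_luc generating lags in whole years.
#' @param beta named coefficients on the lambda-bar scale per year, for terms
#'   `intercept`, `cc`, `luc`, `cc_luc`, `bm`, `pa`, `man`, `use` (continuous
#'   terms apply to z-scored covariates). Effect sizes default to magnitudes
#'   comparable to reported field estimates (use about -7%/yr, protection up
#'   to +6%/yr, management about +4%/yr).
#' @param sigma_species,sigma_location standard deviations of the species and
#'   location random intercepts.
#' @param sigma_resid standard deviation of the annual log10 observation
#'   noise (multiplicative log-normal on abundance).
#' @param missingness probability an interior annual observation is absent.
#' @param zero_rate probability an observation is recorded as zero (only in
#'   series whose mean is at least 1, so the 1% replacement rule is
#'   well-behaved).
#' @param taxon_class `"bird"` or `"mammal"`.
#' @param n_locations number of distinct locations (default: about 60% of the
#'   expected number of populations, so locations are shared).
#' @param env_temp_noise standard deviation of interannual temperature noise
#'   (degrees C); set to 0 for exactly linear temperature trends.
#' @param env_lu_noise standard deviation of the annual land-use fraction
#'   noise; set to 0 for exactly smooth ramps.
#' @param divergence_year first year of the scenario trajectories.
#' @param scenario_multipliers named trend multipliers applied to the three
#'   post-divergence scenario variants.
#' @param seed integer seed; every generator call is deterministic given the
#'   config.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 100,
                       pops_per_species = c(1, 3),
                       year_span = c(1950, 2014),
                       env_span = c(1901, 2100),
                       true_lag_cc = 6,
                       true_lag_luc = 2,
                       beta = c(intercept = -0.005, cc = -0.02, luc = -0.015,
                                cc_luc = -0.01, bm = -0.005, pa = 0.015,
                                man = 0.017, use = -0.03),
                       sigma_species = 0.01,
                       sigma_location = 0.008,
                       sigma_resid = 0.02,
                       missingness = 0.15,
                       zero_rate = 0.02,
                       taxon_class = c("bird", "mammal"),
                       n_locations = NULL,
                       env_temp_noise = 0.35,
                       env_lu_noise = 0.008,
                       divergence_year = 2015,
                       scenario_multipliers = c(ssp1_rcp26 = 0.5,
                                                ssp3_rcp70 = 1.5,
                                                ssp5_rcp85 = 2.0),
                       seed = 1L) {
  taxon_class <- match.arg(taxon_class)
  allowed <- c("intercept", "cc", "luc", "cc_luc", "bm", "pa", "man", "use")
  extra <- setdiff(names(beta), allowed)
  if (length(extra))
    stop("beta refers to covariates absent from the model structure: ",
         paste(extra, collapse = ", "))
  full <- setNames(numeric(length(allowed)), allowed)
  full[names(beta)] <- beta
  if (diff(year_span) < 0 || diff(env_span) < 0)
    stop("year spans must be non-decreasing ranges")
  if (true_lag_cc < 0 || true_lag_luc < 0) stop("true lags must be non-negative")
  if (year_span[1L] - max(true_lag_cc, true_lag_luc) < env_span[1L])
    stop("environmental span does not cover the lagged windows: need env ",
         "coverage from ", year_span[1L] - max(true_lag_cc, true_lag_luc))
  if (year_span[2L] > env_span[2L])
    stop("environmental span ends before the observation span")
  if (any(c(sigma_species, sigma_location, sigma_resid) < 0))
    stop("standard deviations must be non-negative")
  if (missingness < 0 || missingness > 1 || zero_rate < 0 || zero_rate > 1)
    stop("missingness and zero_rate must be probabilities in [0, 1]")
  if (env_temp_noise < 0 || env_lu_noise < 0)
    stop("environmental noise standard deviations must be non-negative")
  if (length(pops_per_species) != 2L || any(pops_per_species < 1))
    stop("pops_per_species must be a positive range c(min, max)")
  n_pop_expected <- n_species * mean(pops_per_species)
  if (is.null(n_locations))
    n_locations <- max(2L, round(0.6 * n_pop_expected))
  structure(list(
    n_species = as.integer(n_species),
    pops_per_species = as.integer(pops_per_species),
    year_span = as.integer(year_span), env_span = as.integer(env_span),
    true_lag_cc = as.integer(true_lag_cc),
    true_lag_luc = as.integer(true_lag_luc),
    beta = full, sigma_species = sigma_species,
    sigma_location = sigma_location, sigma_resid = sigma_resid,
    missingness = missingness, zero_rate = zero_rate,
    taxon_class = taxon_class, n_locations = as.integer(n_locations),
    env_temp_noise = env_temp_noise, env_lu_noise = env_lu_noise,
    divergence_year = as.integer(divergence_year),
    scenario_multipliers = scenario_multipliers,
    seed = as.integer(seed)), class = "sim_config")
}

#' Generate synthetic environmental series
#'
#' Per location, an annual mean-temperature series (location-specific linear
#' trend plus independent noise) and an annual anthropogenic land-cover
#' fraction (smooth logistic ramp plus small noise, clipped to [0, 1]) over
#' the configured span. After the divergence year the three named scenario
#' variants continue the series with their trend multipliers applied, sharing
#' the historical record exactly.
#'
#' @param config a `sim_config`.
#' @param n_locations number of locations (default from the config).
#' @return long-format environment data frame (`location_key`, `year`,
#'   `temperature_C`, `anthro_fraction`, `scenario`) with per-location
#'   latitude/longitude in the `"locations"` attribute.
#' @export
simulate_environment <- function(config, n_locations = config$n_locations) {
  stopifnot(inherits(config, "sim_config"))
  if (n_locations < 1L) stop("need at least one location")
  if (diff(config$env_span) < 1L) stop("non-positive environmental span")
  set.seed(config$seed)
  y0 <- config$env_span[1L]; y1 <- config$env_span[2L]
  div <- config$divergence_year
  hist_years <- seq.int(y0, min(div - 1L, y1))
  scen_years <- if (div <= y1) seq.int(div, y1) else integer(0)
  mult <- config$scenario_multipliers
  locs <- data.frame(
    location_key = sprintf("loc_%04d", seq_len(n_locations)),
    latitude = runif(n_locations, -55, 70),
    longitude = runif(n_locations, -180, 180),
    stringsAsFactors = FALSE)
  # per-location generating parameters
  t_base <- rnorm(n_locations, 12, 6)
  t_trend <- rnorm(n_locations, 0.015, 0.012)
  lu_max <- runif(n_locations, 0.25, 0.9)
  lu_rate <- runif(n_locations, 0.04, 0.12)
  lu_mid <- runif(n_locations, 1930, 2000)
  t_noise_sd <- config$env_temp_noise
  lu_noise_sd <- config$env_lu_noise
  logistic <- function(y, i) lu_max[i] / (1 + exp(-lu_rate[i] * (y - lu_mid[i])))
  out <- vector("list", n_locations)
  for (i in seq_len(n_locations)) {
    temp_h <- t_base[i] + t_trend[i] * (hist_years - y0) +
      rnorm(length(hist_years), 0, t_noise_sd)
    frac_h <- pmin(1, pmax(0, logistic(hist_years, i) +
                             rnorm(length(hist_years), 0, lu_noise_sd)))
    blocks <- list(data.frame(location_key = locs$location_key[i],
                              year = hist_years, temperature_C = temp_h,
                              anthro_fraction = frac_h,
                              scenario = "historical",
                              stringsAsFactors = FALSE))
    if (length(scen_years)) {
      t_at_div <- t_base[i] + t_trend[i] * (div - y0)
      f_at_div <- logistic(div, i)
      for (s in names(mult)) {
        temp_s <- t_at_div + mult[[s]] * t_trend[i] * (scen_years - div) +
          rnorm(length(scen_years), 0, t_noise_sd)
        frac_s <- pmin(1, pmax(0, f_at_div +
                                 mult[[s]] * (logistic(scen_years, i) - f_at_div) +
                                 rnorm(length(scen_years), 0, lu_noise_sd)))
        blocks[[length(blocks) + 1L]] <-
          data.frame(location_key = locs$location_key[i], year = scen_years,
                     temperature_C = temp_s, anthro_fraction = frac_s,
                     scenario = s, stringsAsFactors = FALSE)
      }
    }
    out[[i]] <- do.call(rbind, blocks)
  }
  env <- do.call(rbind, out)
  rownames(env) <- NULL
  attr(env, "locations") <- locs
  env
}

#' Generate synthetic populations with known ground truth
#'
#' Builds species traits (log-normal body mass; generation length positively
#' correlated with body mass; bimodal diet fractions), assigns populations to
#' environment locations, draws species and location random intercepts, and
#' sets each population's expected trend from the generating model
#' \deqn{\bar\lambda = \beta_0 + \beta_{CC} z(CC) + \beta_{LUC} z(LUC) +
#'   \beta_{int} z(CC) z(LUC) + \beta_{BM} z(\log_{10} BM) + \beta_{PA} PA +
#'   \beta_{Man} Man + \beta_{Use} Use + u_{species} + u_{location},}
#' where CC and LUC are the rates over each population's monitoring window
#' offset by the generating lags and z() is the z-score across populations.
#' Abundance follows `N_1 * 10^(lambda * (t - 1))` with multiplicative
#' log-normal observation noise, then interior years are thinned at the
#' missingness rate and zeros injected at the zero rate (only in series whose
#' non-zero mean is at least 1).
#'
#' @param config a `sim_config`.
#' @param env environment table from [simulate_environment()] (its coverage
#'   must include every lagged window).
#' @return list with `populations` (an `lpd_data` object) and `truth` (a data
#'   frame of per-population true trends, covariate z-scores and random
#'   intercepts, with the generating betas and lags as attributes).
#' @export
simulate_populations <- function(config, env) {
  stopifnot(inherits(config, "sim_config"))
  env <- validate_environment(env)
  locs <- attr(env, "locations")
  if (is.null(locs))
    locs <- data.frame(location_key = unique(env$location_key),
                       latitude = NA_real_, longitude = NA_real_)
  set.seed(config$seed + 1L)
  realms <- c("Afrotropical", "Australasia", "Indomalayan", "Nearctic",
              "Neotropical", "Palearctic")
  loc_realm <- sample(realms, nrow(locs), replace = TRUE)
  u_loc <- rnorm(nrow(locs), 0, config$sigma_location)
  names(u_loc) <- locs$location_key
  # species traits
  ns <- config$n_species
  bm_mu <- if (config$taxon_class == "bird") 2.2 else 2.8
  log_bm <- rnorm(ns, bm_mu, 0.9)
  log_gl <- 0.05 + 0.3 * (log_bm - 2) + rnorm(ns, 0, 0.12)
  diet_animal <- rbeta(ns, 0.6, 0.6)
  u_sp <- rnorm(ns, 0, config$sigma_species)
  sp_names <- sprintf("Genus species%03d", seq_len(ns))
  pp <- seq.int(config$pops_per_species[1L], config$pops_per_species[2L])
  npop_per_sp <- pp[sample.int(length(pp), ns, replace = TRUE)]
  n_pop <- sum(npop_per_sp)
  sp_idx <- rep.int(seq_len(ns), npop_per_sp)
  loc_idx <- sample(nrow(locs), n_pop, replace = TRUE)
  ys <- config$year_span
  start <- sample(seq.int(ys[1L], ys[2L] - 14L), n_pop, replace = TRUE)
  len <- sample(15:30, n_pop, replace = TRUE)
  end <- pmin(start + len - 1L, ys[2L])
  meta <- data.frame(
    population_id = sprintf("pop_%05d", seq_len(n_pop)),
    binomial = sp_names[sp_idx],
    class = config$taxon_class,
    latitude = locs$latitude[loc_idx],
    longitude = locs$longitude[loc_idx],
    location_key = locs$location_key[loc_idx],
    realm = loc_realm[loc_idx],
    protected_area = rbinom(n_pop, 1, 0.5),
    managed = rbinom(n_pop, 1, 0.3),
    utilised = rbinom(n_pop, 1, 0.35),
    body_mass_g = 10^log_bm[sp_idx],
    generation_length_y = 10^log_gl[sp_idx],
    diet_animal = diet_animal[sp_idx],
    diet_plant = 1 - diet_animal[sp_idx],
    stringsAsFactors = FALSE)
  # true lagged rates over each population's full monitoring window
  cache <- lapply(unique(meta$location_key), function(l) env_series(env, l))
  names(cache) <- unique(meta$location_key)
  CC <- LUC <- numeric(n_pop)
  for (i in seq_len(n_pop)) {
    s <- cache[[meta$location_key[i]]]
    wcc <- lag_window(c(start[i], end[i]), config$true_lag_cc,
                      env_start = s$years[1L])
    wluc <- lag_window(c(start[i], end[i]), config$true_lag_luc,
                       env_start = s$years[1L])
    CC[i] <- climate_rate(window_values(s, s$temperature, wcc))
    LUC[i] <- landuse_rate(window_values(s, s$fraction, wluc))
  }
  z <- function(x) (x - mean(x)) / sd(x)
  z_cc <- z(CC); z_luc <- z(LUC); z_bm <- z(log_bm[sp_idx])
  b <- config$beta
  lambda_true <- b["intercept"] + b["cc"] * z_cc + b["luc"] * z_luc +
    b["cc_luc"] * z_cc * z_luc + b["bm"] * z_bm +
    b["pa"] * meta$protected_area + b["man"] * meta$managed +
    b["use"] * meta$utilised + u_sp[sp_idx] + u_loc[meta$location_key]
  lambda_true <- as.numeric(lambda_true)
  # abundance series with observation noise, thinning and recorded zeros
  obs <- vector("list", n_pop)
  for (i in seq_len(n_pop)) {
    yrs <- seq.int(start[i], end[i])
    # abundance is a proxy unit, so the scale is free: start each series high
    # enough that its expected path stays well above 1 and the zero/+1
    # adjustments (which compress log-slopes when triggered) stay exceptional
    log_n1 <- runif(1, 1.5, 3.5) + max(0, -lambda_true[i] * (length(yrs) - 1L))
    log_n <- log_n1 + lambda_true[i] * (yrs - yrs[1L]) +
      rnorm(length(yrs), 0, config$sigma_resid)
    vals <- 10^log_n
    keep <- rep(TRUE, length(yrs))
    if (length(yrs) > 2L && config$missingness > 0) {
      interior <- seq.int(2L, length(yrs) - 1L)
      keep[interior] <- runif(length(interior)) >= config$missingness
    }
    yrs <- yrs[keep]; vals <- vals[keep]
    if (config$zero_rate > 0 && mean(vals) >= 1) {
      zz <- runif(length(vals)) < config$zero_rate
      if (sum(!zz) >= 1L) vals[zz] <- 0
    }
    obs[[i]] <- data.frame(population_id = meta$population_id[i], year = yrs,
                           abundance = vals, stringsAsFactors = FALSE)
  }
  pops <- as_lpd_data(meta, do.call(rbind, obs))
  truth <- data.frame(population_id = meta$population_id,
                      binomial = meta$binomial,
                      location_key = meta$location_key,
                      lambda_true = lambda_true,
                      CC_true = CC, LUC_true = LUC,
                      z_cc = z_cc, z_luc = z_luc, z_bm = z_bm,
                      protected_area = meta$protected_area,
                      managed = meta$managed, utilised = meta$utilised,
                      u_species = u_sp[sp_idx],
                      u_location = as.numeric(u_loc[meta$location_key]),
                      stringsAsFactors = FALSE)
  attr(truth, "beta") <- b
  attr(truth, "true_lag_cc") <- config$true_lag_cc
  attr(truth, "true_lag_luc") <- config$true_lag_luc
  list(populations = pops, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_environment()] and
#' [simulate_populations()] from one configuration.
#'
#' @param config a `sim_config`.
#' @return list with `populations`, `environment` and `truth`.
#' @export
simulate_lpd <- function(config = sim_config()) {
  env <- simulate_environment(config)
  pops <- simulate_populations(config, env)
  list(populations = pops$populations, environment = env, truth = pops$truth)
}

#' Recompute expected trends from stored ground truth
#'
#' Applies the generating model formula to the covariates and random
#' intercepts stored in a truth table; by construction this reproduces the
#' stored `lambda_true` exactly, which the test suite uses as a consistency
#' invariant.
#'
#' @param truth a truth data frame from [simulate_populations()].
#' @return numeric vector of expected trends.
#' @export
truth_lambda <- function(truth) {
  b <- attr(truth, "beta")
  as.numeric(b["intercept"] + b["cc"] * truth$z_cc + b["luc"] * truth$z_luc +
               b["cc_luc"] * truth$z_cc * truth$z_luc + b["bm"] * truth$z_bm +
               b["pa"] * truth$protected_area + b["man"] * truth$managed +
               b["use"] * truth$utilised + truth$u_species + truth$u_location)
}
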