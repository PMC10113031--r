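#' Rate of climate change over a window
#'
#' The slope of an ordinary least-squares regression of mean annual
#' temperature on year, in degrees C per year.
#'
#' @param temperature numeric vector of mean annual temperatures for
#'   consecutive years.
#' @param years optional year labels (defaults to consecutive integers); any
#'   gap is an error because the window must be contiguous.
#' @return OLS slope (degrees C / yr).
#' @export
climate_rate <- function(temperature, years = seq_along(temperature)) {
  if (length(temperature) < 2L) stop("window must contain at least two years")
  if (anyNA(temperature)) stop("missing temperature values within the window")
  if (any(diff(years) != 1L)) stop("missing years within the window")
  x <- years - mean(years)
  sum(x * (temperature - mean(temperature))) / sum(x * x)
}

#' Rate of land-use change over a window
#'
#' The mean of consecutive annual differences of the anthropogenic land-cover
#' fraction (cropland + pasture + rangeland), which telescopes to
#' (last - first) / (n - 1). Units: proportion per year.
#'
#' @param fraction numeric vector of annual anthropogenic fractions in [0, 1]
#'   for consecutive years.
#' @return mean annual change (proportion / yr).
#' @export
landuse_rate <- function(fraction) {
  if (length(fraction) < 2L) stop("window must contain at least two years")
  if (anyNA(fraction)) stop("missing land-use values within the window")
  if (any(fraction < 0 | fraction > 1))
    stop("anthropogenic fractions must lie in [0, 1]")
  mean(diff(fraction))
}

#' Lag-offset window for environmental rates
#'
#' Shifts a population's monitoring span back in time by the lag, keeping the
#' window the same length: the environmental series a population responds to
#' under an L-year lag is the one observed L years before monitoring.
#'
#' @param span integer vector `c(start, end)` of the monitoring window.
#' @param lag_years non-negative integer lag.
#' @param env_start earliest year of environmental coverage; the offset window
#'   may not extend before it.
#' @return integer vector `c(start - lag, end - lag)`.
#' @export
lag_window <- function(span, lag_years, env_start = -Inf) {
  stopifnot(length(span) == 2L, span[2L] >= span[1L])
  if (lag_years < 0) stop("lag must be non-negative")
  win <- c(span[1L] - lag_years, span[2L] - lag_years)
  if (win[1L] < env_start)
    stop(sprintf("lagged window starts %d, before environmental coverage (%d)",
                 win[1L], as.integer(env_start)))
  win
}

#' Convert a generation-based lag multiplier to whole years
#'
#' Generation-based lags are expressed as a multiple of a species' generation
#' length and converted to whole years (round half up) for modelling. A lag of
#' two generations is 50 years for a species with a 25-year generation length
#' and 2 years for one with a 1-year generation length.
#'
#' @param multiplier positive lag in generations.
#' @param generation_length positive generation length in years.
#' @return non-negative integer number of years.
#' @export
generations_to_years <- function(multiplier, generation_length) {
  if (any(multiplier <= 0) || any(generation_length <= 0))
    stop("multiplier and generation length must be positive")
  as.integer(floor(multiplier * generation_length + 0.5))
}

#' Maximum feasible year-based lag
#'
#' Determined by the temporal limits of the data: with abundance monitoring
#' starting in 1950 and environmental coverage starting in 1901 the longest
#' lag for which every offset window exists is 49 years.
#'
#' @param abundance_start first year of abundance monitoring (default 1950).
#' @param env_start first year of environmental coverage (default 1901).
#' @return integer maximum lag in years.
#' @export
max_year_lag <- function(abundance_start = 1950, env_start = 1901) {
  lag <- as.integer(abundance_start) - as.integer(env_start)
  if (lag < 0) stop("environmental coverage starts after abundance monitoring")
  lag
}

#' Generation-multiplier grid for a vertebrate class
#'
#' Birds use multipliers 0.3 to 3.1 generations and mammals 0.3 to 2.3, both
#' in steps of 0.1; the upper limits are set by the temporal extent of the
#' environmental data.
#'
#' @param taxon_class `"bird"` or `"mammal"`.
#' @return numeric vector of generation multipliers (29 for birds, 21 for
#'   mammals).
#' @export
generation_grid <- function(taxon_class = c("bird", "mammal")) {
  taxon_class <- match.arg(taxon_class)
  upper <- if (taxon_class == "bird") 31L else 23L
  seq.int(3L, upper) / 10
}

#' Enumerate the full grid of lag combinations
#'
#' All combinations of climate-change and land-use-change lags, in both
#' currencies: year-based lags 0--49 crossed with themselves (50^2 = 2500)
#' plus generation-based multipliers crossed on the class grid (29^2 = 841
#' for birds, 21^2 = 441 for mammals), giving 3341 combinations for birds and
#' 2941 for mammals.
#'
#' @param taxon_class `"bird"` or `"mammal"`.
#' @param currency `"both"` (default), `"years"` or `"generations"`.
#' @param year_lags integer vector of year-based lags (default `0:49`); pass a
#'   shorter vector for reduced demonstration grids.
#' @return data frame with columns `currency`, `cc_lag`, `luc_lag`; one row
#'   per lag combination.
#' @export
lag_grid <- function(taxon_class = c("bird", "mammal"),
                     currency = c("both", "years", "generations"),
                     year_lags = 0:49) {
  taxon_class <- match.arg(taxon_class)
  currency <- match.arg(currency)
  out <- list()
  if (currency %in% c("both", "years")) {
    if (any(year_lags < 0) || any(year_lags != as.integer(year_lags)))
      stop("year lags must be non-negative integers")
    g <- expand.grid(cc_lag = as.integer(year_lags),
                     luc_lag = as.integer(year_lags))
    out$years <- data.frame(currency = "years", g, stringsAsFactors = FALSE)
  }
  if (currency %in% c("both", "generations")) {
    m <- generation_grid(taxon_class)
    g <- expand.grid(cc_lag = m, luc_lag = m)
    out$generations <- data.frame(currency = "generations", g,
                                  stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Validate a long-format environment table and index it by location.
# Columns: location_key, year, temperature_C, anthro_fraction, scenario
# ("historical" for the shared pre-divergence record).
validate_environment <- function(env) {
  need <- c("location_key", "year", "temperature_C", "anthro_fraction", "scenario")
  miss <- setdiff(need, names(env))
  if (length(miss))
    stop("environment table missing columns: ", paste(miss, collapse = ", "))
  if (any(env$anthro_fraction < 0 | env$anthro_fraction > 1, na.rm = TRUE))
    stop("anthropogenic fractions outside [0, 1]")
  env
}

# Assemble the annual trajectory for one location: the historical record plus
# (optionally) one scenario's post-divergence continuation. Returns a list
# with years, temperature and fraction vectors on a contiguous grid.
env_series <- function(env, location, scenario = NULL) {
  e <- env[env$location_key == location, , drop = FALSE]
  if (nrow(e) == 0L) stop("no environmental data for location ", location)
  keep <- e$scenario == "historical"
  if (!is.null(scenario)) keep <- keep | e$scenario == scenario
  e <- e[keep, , drop = FALSE]
  e <- e[order(e$year), , drop = FALSE]
  if (any(duplicated(e$year)))
    stop("overlapping historical/scenario years for location ", location)
  if (any(diff(e$year) != 1L))
    stop("environmental years not contiguous for location ", location)
  list(years = e$year, temperature = e$temperature_C,
       fraction = e$anthro_fraction)
}

# Extract a contiguous window [w1, w2] from an env_series component.
window_values <- function(series, values, window) {
  idx <- match(seq.int(window[1L], window[2L]), series$years)
  if (anyNA(idx))
    stop(sprintf("environmental coverage (from %d) does not reach window %d-%d",
                 series$years[1L], window[1L], window[2L]))
  values[idx]
}

#' Lag-adjusted driver rates for a set of populations
#'
#' For every population, computes the rate of climate change (OLS temperature
#' slope) and rate of land-use change (mean annual change in anthropogenic
#' fraction) over its monitoring span offset back in time by the given lags.
#' With `currency = "generations"` the lag multipliers are converted to whole
#' years per species using its generation length before windowing.
#'
#' @param trends a `population_trends` data frame (needs `population_id`,
#'   `start_year`, `end_year`).
#' @param meta population metadata with `population_id`, `location_key` and,
#'   for generation-based lags, `generation_length_y`.
#' @param env long-format environment table (see [read_environment()]).
#' @param cc_lag,luc_lag lag for each driver, in years or generations.
#' @param currency `"years"` or `"generations"`.
#' @param scenario optional scenario label whose post-divergence values extend
#'   the historical record (used for projections).
#' @param span optional `c(start, end)` overriding each population's
#'   monitoring span (used for decade windows in projections).
#' @return data frame: `population_id`, `cc_lag_years`, `luc_lag_years`,
#'   `CC`, `LUC`.
#' @export
driver_rates <- function(trends, meta, env, cc_lag, luc_lag,
                         currency = c("years", "generations"),
                         scenario = NULL, span = NULL) {
  currency <- match.arg(currency)
  env <- validate_environment(env)
  ids <- trends$population_id
  m <- meta[match(ids, meta$population_id), , drop = FALSE]
  if (anyNA(m$location_key)) stop("populations without location metadata")
  if (currency == "generations") {
    gl <- m$generation_length_y
    if (anyNA(gl)) stop("generation length required for generation-based lags")
    cc_years <- generations_to_years(cc_lag, gl)
    luc_years <- generations_to_years(luc_lag, gl)
  } else {
    cc_years <- rep.int(as.integer(cc_lag), length(ids))
    luc_years <- rep.int(as.integer(luc_lag), length(ids))
  }
  # cache per-location trajectories
  locs <- unique(m$location_key)
  cache <- lapply(locs, function(l) env_series(env, l, scenario))
  names(cache) <- locs
  CC <- LUC <- numeric(length(ids))
  for (i in seq_along(ids)) {
    s <- cache[[as.character(m$location_key[i])]]
    sp <- if (is.null(span)) c(trends$start_year[i], trends$end_year[i]) else span
    wcc <- lag_window(sp, cc_years[i], env_start = s$years[1L])
    wluc <- lag_window(sp, luc_years[i], env_start = s$years[1L])
    CC[i] <- climate_rate(window_values(s, s$temperature, wcc))
    LUC[i] <- landuse_rate(window_values(s, s$fraction, wluc))
  }
  data.frame(population_id = ids, cc_lag_years = cc_years,
             luc_lag_years = luc_years, CC = CC, LUC = LUC,
             stringsAsFactors = FALSE)
}
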