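#' Predict population trends from a fitted lag model
#'
#' Evaluates the fixed-effect linear predictor of an `ecolag_fit` for new
#' driver rates, scaling the continuous covariates with the constants stored
#' from model fitting (the coefficients live on the scaled scale). Random
#' intercepts are added at their estimated values for species and locations
#' seen during fitting and set to zero otherwise.
#'
#' @param object an `ecolag_fit`.
#' @param rates data frame with `population_id`, `CC`, `LUC` on the raw scale.
#' @param meta population metadata (body mass, flags, realm, grouping keys).
#' @param use_ranef add stored random intercepts (default `TRUE`).
#' @param ... unused.
#' @return named numeric vector of predicted lambda-bar values per population.
#' @export
predict.ecolag_fit <- function(object, rates, meta, use_ranef = TRUE, ...) {
  m <- meta[match(rates$population_id, meta$population_id), , drop = FALSE]
  sc <- object$scaling
  d <- data.frame(
    CC = (rates$CC - sc$CC["center"]) / sc$CC["scale"],
    LUC = (rates$LUC - sc$LUC["center"]) / sc$LUC["scale"],
    BM = (log10(m$body_mass_g) - sc$BM["center"]) / sc$BM["scale"],
    PA = as.numeric(m$protected_area),
    Man = as.numeric(m$managed),
    Use = as.numeric(m$utilised),
    Realm = factor(m$realm, levels = object$realm_levels),
    stringsAsFactors = FALSE)
  rhs <- model_structures()[[object$structure]]
  X <- stats::model.matrix(as.formula(paste("~", rhs)), d)
  if (!identical(colnames(X), names(object$coef)))
    stop("prediction design does not match fitted coefficients")
  eta <- as.numeric(X %*% object$coef)
  if (use_ranef) {
    us <- object$ranef_species[as.character(m$binomial)]
    ul <- object$ranef_location[as.character(m$location_key)]
    us[is.na(us)] <- 0
    ul[is.na(ul)] <- 0
    eta <- eta + us + ul
  }
  setNames(eta, rates$population_id)
}

#' Hierarchical average of population trends
#'
#' Averages predicted trends up the taxonomic/geographic hierarchy without
#' weighting: populations to species (within realm), species to realm, realms
#' to the class-level value. This keeps data-rich species and realms from
#' dominating the aggregate.
#'
#' @param lambda numeric vector of population-level trends.
#' @param species,realm grouping vectors aligned with `lambda`.
#' @return list with `class` (scalar), `realm` and `species` data frames.
#' @export
hierarchical_average <- function(lambda, species, realm) {
  ok <- is.finite(lambda)
  if (!all(ok)) {
    lambda <- lambda[ok]; species <- species[ok]; realm <- realm[ok]
  }
  if (length(lambda) == 0L) stop("no finite trends to average")
  sp <- aggregate(lambda, by = list(species = species, realm = realm), FUN = mean)
  names(sp)[3L] <- "lambda"
  rl <- aggregate(sp$lambda, by = list(realm = sp$realm), FUN = mean)
  names(rl)[2L] <- "lambda"
  list(class = mean(rl$lambda), realm = rl, species = sp)
}

#' Akaike-weighted average of per-model trends
#'
#' @param lambda numeric vector, one class-level trend per retained model.
#' @param weights renormalized Akaike weights of the retained models; must
#'   align with `lambda` and sum to 1.
#' @return scalar weighted mean.
#' @export
model_average_trend <- function(lambda, weights) {
  if (length(lambda) != length(weights))
    stop("one weight per model trend is required")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1 (renormalize over the retained set)")
  sum(weights * lambda)
}

#' Decadal abundance index path
#'
#' Converts decadal trend values into an index of relative abundance anchored
#' at 1 in the baseline year: each decade multiplies the index by
#' `10^(10 * lambda)` for that decade.
#'
#' @param lambda numeric vector of decadal trends (log10 units per year), in
#'   chronological order.
#' @param start baseline year (default 2010), where the index is 1.
#' @param step decade length in years (default 10).
#' @return data frame `year`, `index` including the baseline row.
#' @export
index_path <- function(lambda, start = 2010, step = 10) {
  if (any(!is.finite(lambda))) stop("non-finite decadal trend")
  idx <- cumprod(10^(step * lambda))
  data.frame(year = seq(start, by = step, length.out = length(lambda) + 1L),
             index = c(1, idx))
}

classify_window <- function(win_start, win_end, baseline) {
  if (win_end <= baseline) "fully"
  else if (win_start >= baseline) "not"
  else "partially"
}

#' Dependence of a projected decade on pre-baseline environment
#'
#' A projected decade is "locked in" to the extent its lagged environmental
#' window predates the projection baseline: `fully` if the window ends at or
#' before the baseline, `not` if it starts at or after it, `partially` if it
#' straddles it. When the climate and land-use lags differ the classification
#' is made per driver.
#'
#' @param cc_lag_years,luc_lag_years lags in whole years.
#' @param decade `c(start, end)` of the projected decade.
#' @param baseline baseline year (default 2010).
#' @return named character vector `c(cc = ..., luc = ...)`.
#' @export
dependence_classification <- function(cc_lag_years, luc_lag_years, decade,
                                      baseline = 2010) {
  stopifnot(length(decade) == 2L, decade[2L] > decade[1L])
  c(cc = classify_window(decade[1L] - cc_lag_years, decade[2L] - cc_lag_years,
                         baseline),
    luc = classify_window(decade[1L] - luc_lag_years, decade[2L] - luc_lag_years,
                          baseline))
}

# Combine per-model dependence tags: fully/not only when unanimous.
combine_dependence <- function(tags) {
  u <- unique(tags)
  if (length(u) == 1L) u else "partially"
}

#' Project decadal abundance indices under environmental scenarios
#'
#' For every retained model in a lag scan, every scenario and every decade
#' from the baseline, recomputes the lag-offset driver rates on the decade
#' window, predicts per-population trends (at recorded protection,
#' management and use status, with stored random intercepts), averages them
#' hierarchically (population, species, realm, class), model-averages across
#' the retained set by renormalized Akaike weight, and accumulates the
#' abundance index from 1 at the baseline.
#'
#' @param scan a `lag_scan` object.
#' @param trends the `population_trends` used in fitting.
#' @param meta population metadata.
#' @param env long-format environment table containing the scenario
#'   trajectories.
#' @param scenarios scenario labels to project (default: every non-historical
#'   label in `env`).
#' @param decades decade start years (default `seq(2010, 2040, 10)`); each
#'   decade window is `[start, start + 10]`.
#' @param baseline baseline year where the index is anchored at 1.
#' @return object of class `ecolag_projection`: a data frame with columns
#'   `scenario`, `decade_start`, `decade_end`, `lambda`, `index`,
#'   `cc_dependence`, `luc_dependence`.
#' @export
project_index <- function(scan, trends, meta, env, scenarios = NULL,
                          decades = seq(2010, 2040, 10), baseline = 2010) {
  stopifnot(inherits(scan, "lag_scan"))
  env <- validate_environment(env)
  if (is.null(scenarios))
    scenarios <- setdiff(unique(env$scenario), "historical")
  if (length(scenarios) == 0L) stop("no scenario trajectories in environment")
  w <- retained_weights(scan)
  idx <- which(w > 0)
  wr <- w[idx] / sum(w[idx])
  tab <- scan$table
  rows <- list()
  for (x in scenarios) {
    lam_d <- numeric(length(decades))
    dep_cc <- dep_luc <- character(length(decades))
    for (di in seq_along(decades)) {
      ds <- decades[di]
      decade <- c(ds, ds + 10)
      lam_m <- numeric(length(idx))
      tags_cc <- tags_luc <- character(length(idx))
      for (mi in seq_along(idx)) {
        i <- idx[mi]
        rates <- driver_rates(trends, meta, env,
                              cc_lag = tab$cc_lag[i], luc_lag = tab$luc_lag[i],
                              currency = tab$currency[i], scenario = x,
                              span = decade)
        pred <- predict(scan$fits[[i]], rates, meta, use_ranef = TRUE)
        m <- meta[match(rates$population_id, meta$population_id), , drop = FALSE]
        lam_m[mi] <- hierarchical_average(pred, m$binomial, m$realm)$class
        # dependence per driver: unanimous over populations, else partial
        tags_cc[mi] <- combine_dependence(vapply(rates$cc_lag_years, function(L)
          classify_window(decade[1L] - L, decade[2L] - L, baseline), ""))
        tags_luc[mi] <- combine_dependence(vapply(rates$luc_lag_years, function(L)
          classify_window(decade[1L] - L, decade[2L] - L, baseline), ""))
      }
      lam_d[di] <- model_average_trend(lam_m, wr)
      dep_cc[di] <- combine_dependence(tags_cc)
      dep_luc[di] <- combine_dependence(tags_luc)
    }
    path <- index_path(lam_d, start = decades[1L])
    rows[[x]] <- data.frame(scenario = x, decade_start = decades,
                            decade_end = decades + 10, lambda = lam_d,
                            index = path$index[-1L],
                            cc_dependence = dep_cc, luc_dependence = dep_luc,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  class(out) <- c("ecolag_projection", "data.frame")
  out
}

#' @export
print.ecolag_projection <- function(x, ...) {
  cat("Projected abundance index (baseline", attr(x, "baseline"),
      "= 1) by scenario and decade\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.ecolag_projection <- function(x, ...) {
  scen <- unique(x$scenario)
  yr <- sort(unique(c(x$decade_start, x$decade_end)))
  rng <- range(c(1, x$index))
  graphics::plot(NULL, xlim = range(yr), ylim = rng, xlab = "year",
                 ylab = "abundance index (2010 = 1)", ...)
  graphics::abline(h = 1, lty = 3)
  for (i in seq_along(scen)) {
    s <- x[x$scenario == scen[i], ]
    graphics::lines(c(s$decade_start[1L], s$decade_end),
                    c(1, s$index), col = i, lwd = 2)
  }
  graphics::legend("topleft", legend = scen, col = seq_along(scen), lwd = 2,
                   bty = "n")
  invisible(x)
}
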