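#' Eligibility filter for abundance time series
#'
#' A population enters the analysis only if its monitoring window spans at
#' least five calendar years (end - start + 1 >= 5) and it has at least three
#' observed time points.
#'
#' @param years integer vector of observation years (strictly increasing).
#' @return `TRUE` if the series is eligible, `FALSE` otherwise.
#' @examples
#' filter_eligible(c(2000, 2004))        # span 5 but only 2 points
#' filter_eligible(c(2000, 2002, 2004))  # eligible
#' @export
filter_eligible <- function(years) {
  years <- as.integer(years)
  if (length(years) == 0L) return(FALSE)
  if (is.unsorted(years, strictly = TRUE))
    stop("observation years must be strictly increasing")
  span <- years[length(years)] - years[1L] + 1L
  span >= 5L && length(years) >= 3L
}

#' Pre-process raw abundance values
#'
#' Applies the two standard adjustments before log10 modelling: zeros are
#' replaced by 1% of the mean of the non-zero entries of the same series, and
#' series containing recorded (non-zero) values below one get 1 added to
#' every value. The sub-unit check looks at the recorded values, not at the
#' zero replacements — a replacement value below one does not itself trigger
#' the shift.
#'
#' @param values numeric vector of non-negative abundance values.
#' @return strictly positive numeric vector of the same length.
#' @examples
#' preprocess_abundance(c(0, 10, 30))   # 0 -> 0.01 * mean(10, 30) = 0.2
#' preprocess_abundance(c(0.5, 2, 3))   # +1 shift because 0.5 < 1
#' @export
preprocess_abundance <- function(values) {
  if (any(!is.finite(values)) || any(values < 0))
    stop("abundance values must be finite and non-negative")
  nz <- values[values > 0]
  if (length(nz) == 0L)
    stop("all-zero series: zero replacement is undefined")
  shift <- any(nz < 1)
  values[values == 0] <- 0.01 * mean(nz)
  if (shift) values <- values + 1
  values
}

#' Interpolate a population's annual log10 abundance series
#'
#' Series with fewer than six observed points are linearly interpolated on the
#' log10 scale between observations; series with six or more points are
#' smoothed with a thin-plate GAM of log10 abundance on year whose basis
#' dimension is half the number of data points (rounded up), following the
#' Living Planet Index convention. The adjusted R-squared of the trend model
#' (OLS for the linear branch, the GAM itself otherwise) is recorded for
#' downstream quality filtering.
#'
#' @param years integer observation years (strictly increasing).
#' @param values strictly positive abundance values (already pre-processed).
#' @return a list with components `years` (full annual grid), `log10_values`,
#'   `adj_r2` and `method` ("linear" or "gam").
#' @export
interpolate_log10 <- function(years, values) {
  years <- as.integer(years)
  if (is.unsorted(years, strictly = TRUE))
    stop("observation years must be strictly increasing")
  if (length(years) != length(values))
    stop("years and values differ in length")
  if (any(values <= 0)) stop("values must be strictly positive; preprocess first")
  span <- seq.int(years[1L], years[length(years)])
  if (length(span) < 2L) stop("monitoring span of a single year cannot be interpolated")
  lv <- log10(values)
  n <- length(years)
  if (n < 6L) {
    out <- approx(years, lv, xout = span, method = "linear")$y
    fit <- lm(lv ~ years)
    adj <- suppressWarnings(summary(fit)$adj.r.squared)
    method <- "linear"
  } else {
    k <- ceiling(n / 2)
    dat <- data.frame(y = lv, year = years)
    fit <- mgcv::gam(y ~ s(year, k = k), data = dat, method = "GCV.Cp")
    out <- as.numeric(predict(fit, newdata = data.frame(year = span)))
    adj <- summary(fit)$r.sq
    method <- "gam"
  }
  list(years = span, log10_values = out, adj_r2 = adj, method = method)
}

#' Mean annual log10 rate of change (lambda-bar)
#'
#' The population trend statistic: the mean of consecutive annual log10
#' ratios of the interpolated series,
#' \deqn{\bar\lambda = \sum_{t=2}^{T} \log_{10}(N_t/N_{t-1}) / (T - 1),}
#' which by telescoping equals
#' \eqn{(\log_{10} N_T - \log_{10} N_1)/(T-1)}.
#'
#' @param log10_values numeric vector of annual log10 abundance values
#'   (length >= 2).
#' @return the trend in log10 units per year.
#' @export
lambda_bar <- function(log10_values) {
  if (length(log10_values) < 2L) stop("need at least two annual values")
  if (any(!is.finite(log10_values))) stop("non-finite interpolated values")
  mean(diff(log10_values))
}

#' Compute population trends for a collection of abundance series
#'
#' Runs the eligibility filter, zero/+1 pre-processing, log10 interpolation
#' and the lambda-bar statistic for every population in an `lpd_data` object.
#' Populations failing the eligibility rule are dropped and counted.
#'
#' @param pops an `lpd_data` object (see [as_lpd_data()]).
#' @return a data frame of class `population_trends` with one row per retained
#'   population: `population_id`, `lambda`, `n_years` (interpolated length),
#'   `adj_r2`, `method`, `start_year`, `end_year`. The interpolated series are
#'   attached as the `"series"` attribute; exclusion counts as `"exclusions"`.
#' @export
population_trends <- function(pops) {
  stopifnot(inherits(pops, "lpd_data"))
  ids <- pops$meta$population_id
  rows <- vector("list", length(ids))
  series <- vector("list", length(ids))
  excluded <- character(0)
  for (i in seq_along(ids)) {
    ob <- pops$obs[pops$obs$population_id == ids[i], , drop = FALSE]
    ob <- ob[order(ob$year), , drop = FALSE]
    if (!filter_eligible(ob$year)) {
      excluded <- c(excluded, ids[i])
      next
    }
    vals <- preprocess_abundance(ob$abundance)
    interp <- interpolate_log10(ob$year, vals)
    rows[[i]] <- data.frame(
      population_id = ids[i],
      lambda = lambda_bar(interp$log10_values),
      n_years = length(interp$years),
      adj_r2 = interp$adj_r2,
      method = interp$method,
      start_year = interp$years[1L],
      end_year = interp$years[length(interp$years)],
      stringsAsFactors = FALSE
    )
    series[[i]] <- interp
  }
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  names(series) <- ids
  attr(out, "series") <- series[keep]
  attr(out, "exclusions") <- list(ineligible = excluded)
  class(out) <- c("population_trends", "data.frame")
  out
}

#' Quality filter on trend-model fit
#'
#' Retains only populations whose trend model has adjusted R-squared greater
#' than zero, a deliberately simple threshold that removes poorly fitted and
#' potentially unreliable series.
#'
#' @param trends a `population_trends` data frame.
#' @return the filtered data frame; the number removed is recorded in the
#'   `"exclusions"` attribute under `low_r2`.
#' @export
quality_filter <- function(trends) {
  stopifnot(is.data.frame(trends), "adj_r2" %in% names(trends))
  keep <- trends$adj_r2 > 0
  out <- trends[keep, , drop = FALSE]
  excl <- attr(trends, "exclusions")
  excl$low_r2 <- trends$population_id[!keep]
  attr(out, "exclusions") <- excl
  ser <- attr(trends, "series")
  if (!is.null(ser)) attr(out, "series") <- ser[keep]
  class(out) <- class(trends)
  out
}

#' IUCN Red List decline thresholds on the lambda-bar scale
#'
#' Converts an IUCN criterion A2 population decline (e.g. 50% over 10 years,
#' Endangered) into the equivalent constant annual log10 rate of change:
#' `log10(1 - decline_fraction) / horizon`.
#'
#' @param decline_fraction proportion declined over the horizon, in (0, 1).
#' @param horizon assessment horizon in years (default 10, the A2 window).
#' @return lambda-bar equivalent (log10 units per year, negative).
#' @examples
#' iucn_threshold_lambda(0.5)   # Endangered: about -0.0301
#' iucn_threshold_lambda(0.8)   # Critically Endangered: about -0.0699
#' @export
iucn_threshold_lambda <- function(decline_fraction, horizon = 10) {
  if (any(decline_fraction <= 0) || any(decline_fraction >= 1))
    stop("decline_fraction must be strictly between 0 and 1")
  if (any(horizon <= 0)) stop("horizon must be positive")
  log10(1 - decline_fraction) / horizon
}
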