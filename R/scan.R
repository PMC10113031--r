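#' Scan a grid of lag combinations with mixed-effects models
#'
#' The core fitting function. For every lag combination in the grid it
#' offsets each population's monitoring window, recomputes the climate and
#' land-use rates, rebuilds the centred/scaled design, and fits the chosen
#' mixed-model structure by maximum likelihood. Fits are ranked by AICc;
#' Akaike weights are computed over the scan; the plausible set
#' (delta AICc < `delta_retain`) is flagged for model averaging.
#'
#' @param trends `population_trends` data frame (after [quality_filter()]).
#' @param meta population metadata table.
#' @param env long-format environment table.
#' @param structure model structure id (see [model_structures()]).
#' @param grid data frame of lag combinations (see [lag_grid()]). Defaults to
#'   the full grid for the class found in `meta`.
#' @param weights_by `"combined"` (default) computes delta AICc and weights
#'   over the whole scan; `"currency"` computes them separately within the
#'   year-based and generation-based subsets.
#' @param delta_retain retention threshold on delta AICc (default 6).
#' @return object of class `lag_scan` with components `table` (one row per
#'   lag combination: lags, logLik, k, n, AICc, delta_aicc, weight, retained),
#'   `fits` (per-combination `ecolag_fit` objects), `structure`, `grid`.
#' @seealso [coef.lag_scan()], [lag_support()], [modal_lags()],
#'   [project_index()]
#' @export
lag_scan <- function(trends, meta, env, structure = "Base", grid = NULL,
                     weights_by = c("combined", "currency"),
                     delta_retain = 6) {
  weights_by <- match.arg(weights_by)
  if (is.null(grid)) {
    cls <- unique(meta$class[meta$population_id %in% trends$population_id])
    if (length(cls) != 1L)
      stop("metadata must contain a single taxonomic class, found: ",
           paste(cls, collapse = ", "))
    grid <- lag_grid(cls)
  }
  n_comb <- nrow(grid)
  fits <- vector("list", n_comb)
  rec <- data.frame(currency = grid$currency, cc_lag = grid$cc_lag,
                    luc_lag = grid$luc_lag, logLik = NA_real_,
                    k = NA_integer_, n = NA_integer_, AICc = NA_real_)
  failures <- character(0)
  for (i in seq_len(n_comb)) {
    res <- tryCatch({
      rates <- driver_rates(trends, meta, env,
                            cc_lag = grid$cc_lag[i], luc_lag = grid$luc_lag[i],
                            currency = grid$currency[i])
      design <- build_design(trends, rates, meta, structure)
      fit_mixed(design, structure)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s cc=%g luc=%g: %s", grid$currency[i],
                                      grid$cc_lag[i], grid$luc_lag[i],
                                      conditionMessage(res)))
      next
    }
    fits[[i]] <- res
    rec$logLik[i] <- res$logLik
    rec$k[i] <- res$k
    rec$n[i] <- res$n
    rec$AICc[i] <- res$AICc
  }
  if (length(failures))
    warning(length(failures), " lag combination(s) failed to fit and were ",
            "excluded from weights:\n  ", paste(failures, collapse = "\n  "))
  if (all(is.na(rec$AICc))) stop("no lag combination could be fitted")
  if (weights_by == "combined") {
    rec$delta_aicc <- rec$AICc - min(rec$AICc, na.rm = TRUE)
    rec$weight <- akaike_weights(rec$AICc)
  } else {
    rec$delta_aicc <- NA_real_
    rec$weight <- NA_real_
    for (cur in unique(rec$currency)) {
      idx <- rec$currency == cur
      rec$delta_aicc[idx] <- rec$AICc[idx] - min(rec$AICc[idx], na.rm = TRUE)
      rec$weight[idx] <- akaike_weights(rec$AICc[idx])
    }
  }
  rec$retained <- !is.na(rec$delta_aicc) & rec$delta_aicc < delta_retain
  structure(list(table = rec, fits = fits, structure = structure,
                 grid = grid, weights_by = weights_by,
                 delta_retain = delta_retain, failures = failures),
            class = "lag_scan")
}

#' Renormalized weights over the retained model set
#'
#' @param scan a `lag_scan` object.
#' @return numeric vector over all scan rows: renormalized Akaike weights for
#'   retained models, 0 elsewhere.
#' @export
retained_weights <- function(scan) {
  stopifnot(inherits(scan, "lag_scan"))
  w <- ifelse(scan$table$retained, scan$table$weight, 0)
  if (sum(w, na.rm = TRUE) == 0) stop("retained model set is empty")
  w[is.na(w)] <- 0
  w / sum(w)
}

#' Model-averaged coefficients
#'
#' Averages the fixed-effect coefficients of the retained (delta AICc < 6)
#' models, weighting by their Akaike weights renormalized over the retained
#' set. All members of a scan share one fixed-effect structure, so
#' coefficients align term by term.
#'
#' @param object a `lag_scan` object.
#' @param ... unused.
#' @return named numeric vector of averaged coefficients, with the
#'   weighted-average standard errors in the `"se"` attribute.
#' @export
coef.lag_scan <- function(object, ...) {
  w <- retained_weights(object)
  idx <- which(w > 0)
  strs <- unique(vapply(object$fits[idx], `[[`, "", "structure"))
  if (length(strs) != 1L)
    stop("retained set mixes model structures; cannot average term by term")
  terms <- names(object$fits[[idx[1L]]]$coef)
  avg <- se <- setNames(numeric(length(terms)), terms)
  for (i in idx) {
    f <- object$fits[[i]]
    if (!identical(names(f$coef), terms))
      stop("coefficient terms differ between retained models")
    avg <- avg + w[i] * f$coef
    se <- se + w[i] * f$se
  }
  attr(avg, "se") <- se
  avg
}

#' Summed Akaike-weight support per lag value
#'
#' For one driver, sums the scan's Akaike weights of all retained models
#' sharing each lag value -- the lag-support profile used to read off the
#' best-supported lag. Sums over all lag values of a driver are at most 1.
#'
#' @param scan a `lag_scan` object.
#' @param driver `"cc"` or `"luc"`.
#' @param retained_only sum only over the retained set (default `TRUE`).
#' @return data frame `currency`, `lag`, `support`, sorted by currency then
#'   lag.
#' @export
lag_support <- function(scan, driver = c("cc", "luc"), retained_only = TRUE) {
  stopifnot(inherits(scan, "lag_scan"))
  driver <- match.arg(driver)
  tab <- scan$table
  if (retained_only) tab <- tab[tab$retained %in% TRUE, , drop = FALSE]
  tab <- tab[is.finite(tab$weight), , drop = FALSE]
  lagcol <- paste0(driver, "_lag")
  agg <- aggregate(tab$weight,
                   by = list(currency = tab$currency, lag = tab[[lagcol]]),
                   FUN = sum)
  names(agg)[3L] <- "support"
  agg[order(agg$currency, agg$lag), , drop = FALSE]
}

#' Best-supported lag per driver
#'
#' The lag value with the largest summed Akaike weight, for each driver.
#'
#' @param scan a `lag_scan` object.
#' @return named numeric vector `c(cc = ..., luc = ...)` (with the currency
#'   of each mode in the `"currency"` attribute).
#' @export
modal_lags <- function(scan) {
  out <- c(cc = NA_real_, luc = NA_real_)
  cur <- c(cc = NA_character_, luc = NA_character_)
  for (d in c("cc", "luc")) {
    prof <- lag_support(scan, d)
    top <- prof[which.max(prof$support), ]
    out[d] <- top$lag
    cur[d] <- top$currency
  }
  attr(out, "currency") <- cur
  out
}

#' @export
print.lag_scan <- function(x, ...) {
  tab <- x$table
  cat("Lag scan:", nrow(tab), "lag combinations, structure", x$structure, "\n")
  cat(sprintf("  populations fitted: %d; retained (delta AICc < %g): %d\n",
              max(tab$n, na.rm = TRUE), x$delta_retain, sum(tab$retained)))
  best <- tab[which.min(tab$AICc), ]
  cat(sprintf("  best: %s currency, cc lag %g, luc lag %g (AICc %.2f, weight %.3f)\n",
              best$currency, best$cc_lag, best$luc_lag, best$AICc, best$weight))
  invisible(x)
}

#' @export
summary.lag_scan <- function(object, ...) {
  ml <- modal_lags(object)
  avg <- coef(object)
  out <- list(structure = object$structure,
              n_combinations = nrow(object$table),
              n_retained = sum(object$table$retained),
              modal_lags = ml,
              coefficients = cbind(Estimate = as.numeric(avg),
                                   `Std. Error` = attr(avg, "se")))
  rownames(out$coefficients) <- names(avg)
  class(out) <- "summary.lag_scan"
  out
}

#' @export
print.summary.lag_scan <- function(x, ...) {
  cat("Lag scan summary (structure", x$structure, ")\n")
  cat(sprintf("  %d lag combinations, %d retained (delta AICc < 6)\n",
              x$n_combinations, x$n_retained))
  cat(sprintf("  best-supported lags: CC = %g, LUC = %g (%s)\n",
              x$modal_lags["cc"], x$modal_lags["luc"],
              attr(x$modal_lags, "currency")["cc"]))
  cat("  model-averaged coefficients:\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Plot lag-support profiles
#'
#' Summed Akaike weights against lag value for both drivers, on a square-root
#' scale to make low-support lags visible.
#'
#' @param x a `lag_scan` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lag_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (d in c("cc", "luc")) {
    prof <- lag_support(x, d)
    graphics::plot(prof$lag, sqrt(prof$support), type = "h",
                   xlab = paste(toupper(d), "lag"),
                   ylab = "sqrt(summed Akaike weight)", ...)
  }
  invisible(x)
}
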