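#' Fixed-effect model structures
#'
#' The five candidate structures linking population trends to drivers. All
#' share crossed random intercepts for species identity and population
#' location; the non-null structures all include the CC:LUC interaction.
#'
#' \describe{
#'   \item{Base}{CC*LUC + BM + PA}
#'   \item{MU}{CC*LUC + BM + PA + Man + Use}
#'   \item{R}{CC*LUC + BM + PA + Realm}
#'   \item{MUR}{CC*LUC + BM + PA + Man + Use + Realm}
#'   \item{Null}{intercept only}
#' }
#'
#' @return named list of right-hand-side fixed-effect formulas (as character).
#' @export
model_structures <- function() {
  list(Base = "CC * LUC + BM + PA",
       MU   = "CC * LUC + BM + PA + Man + Use",
       R    = "CC * LUC + BM + PA + Realm",
       MUR  = "CC * LUC + BM + PA + Man + Use + Realm",
       Null = "1")
}

structure_formula <- function(structure) {
  ms <- model_structures()
  if (!structure %in% names(ms))
    stop("unknown model structure: ", structure,
         " (use one of ", paste(names(ms), collapse = ", "), ")")
  as.formula(paste("lambda ~", ms[[structure]],
                   "+ (1 | species) + (1 | location)"))
}

# Covariates each structure needs from the design table.
structure_terms <- function(structure) {
  switch(structure,
         Base = c("CC", "LUC", "BM", "PA"),
         MU   = c("CC", "LUC", "BM", "PA", "Man", "Use"),
         R    = c("CC", "LUC", "BM", "PA", "Realm"),
         MUR  = c("CC", "LUC", "BM", "PA", "Man", "Use", "Realm"),
         Null = character(0),
         stop("unknown model structure: ", structure))
}

#' Build the model-ready design table
#'
#' Joins trends, lagged driver rates and traits into one table; centres and
#' scales the continuous covariates (CC, LUC, log10 body mass) to mean 0 and
#' standard deviation 1 within the fitted dataset; codes the protection,
#' management and use flags as 0/1; attaches species and location grouping
#' keys. Populations with a missing required trait are dropped and recorded.
#'
#' @param trends `population_trends` data frame (response `lambda`).
#' @param rates output of [driver_rates()] for one lag combination.
#' @param meta population metadata (traits, flags, grouping keys).
#' @param structure model structure id (see [model_structures()]).
#' @return data frame with attributes `"scaling"` (centres and sds used) and
#'   `"dropped"` (ids excluded for missing traits).
#' @export
build_design <- function(trends, rates, meta, structure = "Base") {
  terms <- structure_terms(structure)
  m <- meta[match(trends$population_id, meta$population_id), , drop = FALSE]
  r <- rates[match(trends$population_id, rates$population_id), , drop = FALSE]
  d <- data.frame(population_id = trends$population_id,
                  lambda = trends$lambda,
                  CC = r$CC, LUC = r$LUC,
                  BM = log10(m$body_mass_g),
                  PA = as.numeric(m$protected_area),
                  Man = as.numeric(m$managed),
                  Use = as.numeric(m$utilised),
                  Realm = m$realm,
                  species = m$binomial,
                  location = as.character(m$location_key),
                  stringsAsFactors = FALSE)
  need <- c("lambda", "species", "location", terms)
  ok <- complete.cases(d[need])
  dropped <- d$population_id[!ok]
  d <- d[ok, , drop = FALSE]
  if (nrow(d) < 2L)
    stop("fewer than two populations after trait filtering; scaling undefined")
  scaling <- list()
  for (v in c("CC", "LUC", "BM")) {
    mu <- mean(d[[v]]); sdev <- sd(d[[v]])
    if (!is.finite(sdev) || sdev == 0)
      stop("cannot scale constant covariate ", v)
    d[[v]] <- (d[[v]] - mu) / sdev
    scaling[[v]] <- c(center = mu, scale = sdev)
  }
  d$Realm <- factor(d$Realm)
  d$species <- factor(d$species)
  d$location <- factor(d$location)
  attr(d, "scaling") <- scaling
  attr(d, "dropped") <- dropped
  d
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (fixed effects + 2 random-intercept
#'   variances + residual variance).
#' @param n number of observations (populations).
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one mixed-effects model
#'
#' Maximum-likelihood fit (not REML, so likelihoods are comparable across
#' fixed-effect structures) of lambda-bar on the structure's fixed effects
#' with crossed random intercepts for species and location. The parameter
#' count for AICc is the number of fixed effects plus the two random-intercept
#' variances plus the residual variance.
#'
#' @param design output of [build_design()].
#' @param structure model structure id.
#' @return object of class `ecolag_fit`: coefficients, standard errors,
#'   covariance of the fixed effects, random intercepts, log-likelihood, `k`,
#'   `n`, `AICc`, and the scaling constants carried from the design.
#' @export
fit_mixed <- function(design, structure = "Base") {
  if (nlevels(droplevels(design$species)) < 2L ||
      nlevels(droplevels(design$location)) < 2L)
    stop("need at least two species and two locations to fit random intercepts")
  form <- structure_formula(structure)
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore")
  fit <- suppressMessages(
    lme4::lmer(form, data = design, REML = FALSE, control = ctrl))
  if (any(is.na(lme4::fixef(fit, add.dropped = TRUE))))
    stop("rank-deficient design: structure '", structure,
         "' cannot be fitted on this subset")
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  k <- length(beta) + 3L  # + 2 random-intercept variances + residual variance
  n <- nrow(design)
  ll <- as.numeric(logLik(fit))
  re <- lme4::ranef(fit)
  structure(list(
    structure = structure,
    coef = beta,
    se = sqrt(diag(V)),
    vcov = V,
    logLik = ll, k = k, n = n,
    AICc = aicc(ll, k, n),
    ranef_species = setNames(re$species[[1L]], rownames(re$species)),
    ranef_location = setNames(re$location[[1L]], rownames(re$location)),
    realm_levels = levels(design$Realm),
    scaling = attr(design, "scaling"),
    formula = form
  ), class = "ecolag_fit")
}

#' @export
print.ecolag_fit <- function(x, ...) {
  cat("Linear mixed model (ML), structure", x$structure, "\n")
  cat(sprintf("n = %d populations, k = %d, logLik = %.3f, AICc = %.3f\n",
              x$n, x$k, x$logLik, x$AICc))
  print(round(cbind(Estimate = x$coef, `Std. Error` = x$se), 5))
  invisible(x)
}

#' Akaike weights
#'
#' Normalized relative likelihoods of a model set:
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`. Computed on differences from the best
#' model so arbitrarily large Delta values do not overflow.
#'
#' @param aicc_values numeric vector of AICc values; `NA` entries (failed
#'   fits) receive weight `NA` and are excluded from the normalization.
#' @return numeric weights summing to 1 over the finite entries.
#' @export
akaike_weights <- function(aicc_values) {
  ok <- is.finite(aicc_values)
  if (!any(ok)) stop("no finite AICc values")
  delta <- aicc_values[ok] - min(aicc_values[ok])
  rel <- exp(-delta / 2)
  w <- rep(NA_real_, length(aicc_values))
  w[ok] <- rel / sum(rel)
  w
}
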