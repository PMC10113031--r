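#' Ecological subsets of populations
#'
#' Partitions populations for subset-specific lag scans along one of three
#' trait dimensions:
#' \describe{
#'   \item{body_mass}{three equal parts (small / medium / large) at the
#'     tertiles of species-level log10 body mass within the class; boundary
#'     ties go to the lower bin.}
#'   \item{trophic}{carnivores have diets of at least 2/3 animal matter,
#'     herbivores at least 2/3 plant matter; mixed diets are excluded.}
#'   \item{latitude}{temperate populations lie above 23.5 degrees N or below
#'     -23.5 degrees S; tropical populations lie between.}
#'   \item{all}{single subset containing every population.}
#' }
#' Populations missing the required trait are excluded from that dimension
#' and listed in the `"dropped"` attribute.
#'
#' @param meta population metadata table.
#' @param dimension one of `"body_mass"`, `"trophic"`, `"latitude"`, `"all"`.
#' @return named list of population-id vectors, one element per level.
#' @export
make_subsets <- function(meta,
                         dimension = c("body_mass", "trophic", "latitude", "all")) {
  dimension <- match.arg(dimension)
  ids <- meta$population_id
  if (dimension == "all") {
    out <- list(all = ids)
    attr(out, "dropped") <- character(0)
    return(out)
  }
  if (dimension == "body_mass") {
    ok <- is.finite(meta$body_mass_g) & meta$body_mass_g > 0
    m <- meta[ok, , drop = FALSE]
    # tertile breaks on species-level masses, one value per species
    sp_mass <- tapply(log10(m$body_mass_g), m$binomial, mean)
    breaks <- quantile(sp_mass, probs = c(1 / 3, 2 / 3), type = 7)
    level_of <- function(x) {
      ifelse(x <= breaks[1L], "small",
             ifelse(x <= breaks[2L], "medium", "large"))
    }
    lev <- level_of(sp_mass[m$binomial])
    out <- split(m$population_id, factor(lev, levels = c("small", "medium", "large")))
  } else if (dimension == "trophic") {
    ok <- is.finite(meta$diet_animal) & is.finite(meta$diet_plant)
    m <- meta[ok, , drop = FALSE]
    lev <- ifelse(m$diet_animal >= 2 / 3, "carnivore",
                  ifelse(m$diet_plant >= 2 / 3, "herbivore", NA))
    keep <- !is.na(lev)
    out <- split(m$population_id[keep],
                 factor(lev[keep], levels = c("carnivore", "herbivore")))
    ok[ok] <- keep  # mixed diets count as excluded from this dimension
  } else {  # latitude
    ok <- is.finite(meta$latitude)
    m <- meta[ok, , drop = FALSE]
    lev <- ifelse(m$latitude > 23.5 | m$latitude < -23.5, "temperate", "tropical")
    out <- split(m$population_id, factor(lev, levels = c("temperate", "tropical")))
  }
  attr(out, "dropped") <- setdiff(ids, unlist(out, use.names = FALSE))
  out
}

#' Influence screen by population-level case deletion
#'
#' A Cook's-distance style diagnostic for the mixed model: each population is
#' deleted in turn, the model refitted, and the influence score computed as
#' the squared displacement of the fixed-effect vector scaled by its
#' covariance, `D_i = (b - b_(i))' V^-1 (b - b_(i)) / p`, where `V` is the
#' fixed-effect covariance of the full fit and `p` the number of fixed
#' effects. Populations with `D_i` above the threshold are flagged for
#' exclusion (and the model should be refitted without them).
#'
#' @param design output of [build_design()].
#' @param structure model structure id.
#' @param threshold flagging threshold on the influence score (default 0.5).
#' @return data frame `population_id`, `cooks_d`, `flagged`. If a deletion
#'   would leave fewer than two species or locations, screening is skipped
#'   with a warning and an empty frame returned.
#' @export
influence_screen <- function(design, structure = "Base", threshold = 0.5) {
  full <- fit_mixed(design, structure)
  Vinv <- solve(full$vcov)
  p <- length(full$coef)
  n <- nrow(design)
  d <- numeric(n)
  for (i in seq_len(n)) {
    sub <- design[-i, , drop = FALSE]
    if (nlevels(droplevels(sub$species)) < 2L ||
        nlevels(droplevels(sub$location)) < 2L) {
      warning("case deletion would leave fewer than two grouping levels; ",
              "influence screening skipped")
      return(data.frame(population_id = character(0), cooks_d = numeric(0),
                        flagged = logical(0)))
    }
    attr(sub, "scaling") <- attr(design, "scaling")
    fi <- tryCatch(fit_mixed(sub, structure), error = function(e) NULL)
    if (is.null(fi)) { d[i] <- NA_real_; next }
    db <- full$coef - fi$coef
    d[i] <- as.numeric(db %*% Vinv %*% db) / p
  }
  data.frame(population_id = design$population_id, cooks_d = d,
             flagged = !is.na(d) & d > threshold,
             stringsAsFactors = FALSE)
}
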