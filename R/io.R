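lpd_meta_cols <- c("population_id", "binomial", "class", "latitude",
                   "longitude", "location_key", "realm", "protected_area",
                   "managed", "utilised", "body_mass_g",
                   "generation_length_y", "diet_animal", "diet_plant")

#' Construct an `lpd_data` object
#'
#' The package's container for abundance records: a metadata table (one row
#' per population, with taxonomy, coordinates, protection/management/use
#' flags and traits) plus a long observations table (`population_id`, `year`,
#' `abundance`).
#'
#' @param meta metadata data frame.
#' @param obs observations data frame.
#' @return object of class `lpd_data`.
#' @export
as_lpd_data <- function(meta, obs) {
  miss <- setdiff(lpd_meta_cols, names(meta))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$population_id))
    stop("duplicate population ids: ",
         paste(unique(meta$population_id[duplicated(meta$population_id)]),
               collapse = ", "))
  stopifnot(all(c("population_id", "year", "abundance") %in% names(obs)))
  if (any(!is.finite(obs$abundance)) || any(obs$abundance < 0))
    stop("abundance values must be finite and non-negative")
  orphan <- setdiff(obs$population_id, meta$population_id)
  if (length(orphan))
    stop("observations for unknown populations: ",
         paste(head(orphan, 5), collapse = ", "))
  empty <- setdiff(meta$population_id, obs$population_id)
  if (length(empty))
    stop("populations without any observation: ",
         paste(head(empty, 5), collapse = ", "))
  structure(list(meta = meta, obs = obs), class = "lpd_data")
}

#' @export
print.lpd_data <- function(x, ...) {
  cat("LPD-style abundance data:", nrow(x$meta), "populations,",
      length(unique(x$meta$binomial)), "species,",
      nrow(x$obs), "observations\n")
  cat("  classes:", paste(unique(x$meta$class), collapse = ", "),
      "; years:", min(x$obs$year), "-", max(x$obs$year), "\n")
  invisible(x)
}

#' Write populations to an LPD-style wide CSV
#'
#' One row per population: the metadata columns followed by one column per
#' year of the observed range; unobserved years are blank.
#'
#' @param pops an `lpd_data` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_populations <- function(pops, path) {
  stopifnot(inherits(pops, "lpd_data"))
  years <- seq.int(min(pops$obs$year), max(pops$obs$year))
  wide <- matrix(NA_real_, nrow = nrow(pops$meta), ncol = length(years),
                 dimnames = list(NULL, as.character(years)))
  row_of <- match(pops$obs$population_id, pops$meta$population_id)
  col_of <- match(pops$obs$year, years)
  wide[cbind(row_of, col_of)] <- pops$obs$abundance
  out <- cbind(pops$meta[lpd_meta_cols], as.data.frame(wide, check.names = FALSE))
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read populations from an LPD-style wide CSV
#'
#' Expects the metadata columns of [write_populations()] plus annual columns
#' labelled by four-digit year; blank cells are unobserved years. Problems
#' (duplicate ids, negative or non-numeric abundance, rows with no
#' observation) are reported with the offending rows.
#'
#' @param path CSV file.
#' @return an `lpd_data` object.
#' @export
read_populations <- function(path) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(lpd_meta_cols, names(raw))
  if (length(miss))
    stop("populations file missing columns: ", paste(miss, collapse = ", "))
  year_cols <- names(raw)[grepl("^[0-9]{4}$", names(raw))]
  if (length(year_cols) == 0L) stop("no year columns found")
  other <- setdiff(names(raw), c(lpd_meta_cols, year_cols))
  if (length(other))
    stop("unparseable columns (not metadata, not a 4-digit year): ",
         paste(other, collapse = ", "))
  meta <- raw[lpd_meta_cols]
  if (anyDuplicated(meta$population_id))
    stop("duplicate population ids: ",
         paste(unique(meta$population_id[duplicated(meta$population_id)]),
               collapse = ", "))
  errs <- character(0)
  obs <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    vals <- suppressWarnings(as.numeric(raw[i, year_cols]))
    bad_num <- !is.na(raw[i, year_cols]) & raw[i, year_cols] != "" & is.na(vals)
    if (any(bad_num)) {
      errs <- c(errs, sprintf("%s: non-numeric abundance in %s",
                              meta$population_id[i],
                              paste(year_cols[bad_num], collapse = ", ")))
      next
    }
    seen <- !is.na(vals)
    if (!any(seen)) {
      errs <- c(errs, sprintf("%s: no observed years", meta$population_id[i]))
      next
    }
    if (any(vals[seen] < 0)) {
      errs <- c(errs, sprintf("%s: negative abundance", meta$population_id[i]))
      next
    }
    obs[[i]] <- data.frame(population_id = meta$population_id[i],
                           year = as.integer(year_cols[seen]),
                           abundance = vals[seen], stringsAsFactors = FALSE)
  }
  if (length(errs))
    stop("invalid population rows:\n  ", paste(errs, collapse = "\n  "))
  as_lpd_data(meta, do.call(rbind, obs))
}

#' Write / read the long-format environment CSV
#'
#' Columns `location_key`, `year`, `temperature_C`, `anthro_fraction`,
#' `scenario` (the value `"historical"` marks the shared pre-divergence
#' record).
#'
#' @param env environment data frame.
#' @param path CSV file.
#' @return `path` (write) or the validated data frame (read).
#' @export
write_environment <- function(env, path) {
  env <- validate_environment(env)
  write.csv(env[c("location_key", "year", "temperature_C", "anthro_fraction",
                  "scenario")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  validate_environment(read.csv(path, stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Ties the stages together: trend extraction (eligibility filter,
#' pre-processing, interpolation, lambda-bar), the adjusted-R2 quality
#' filter, the influence screen (Base structure at lag zero), the lag-grid
#' scan per requested structure, model averaging and lag-support profiles,
#' and (when scenario trajectories are present) the decadal index projection.
#' All result tables plus a machine-readable manifest (seed, stage counts)
#' are written to the output directory.
#'
#' @param populations an `lpd_data` object or path to a wide CSV.
#' @param env environment data frame or path to a long CSV.
#' @param out_dir output directory (created if needed).
#' @param structures model structures to scan (default `"Base"`).
#' @param grid lag grid (default: reduced year grid 0-10 for desk-scale runs).
#' @param project run the scenario projection (default `TRUE` when the
#'   environment contains scenario rows).
#' @param influence run the case-deletion influence screen (default `TRUE`;
#'   quadratic in the number of populations).
#' @param seed integer seed recorded in the manifest.
#' @return list with `trends`, `scans`, `averaged`, `support`, `projection`,
#'   `manifest`, invisibly; tables are also written as CSV/JSON files.
#' @export
run_pipeline <- function(populations, env, out_dir, structures = "Base",
                         grid = lag_grid("bird", "years", year_lags = 0:10),
                         project = NULL, influence = TRUE, seed = 1L) {
  if (is.character(populations)) populations <- read_populations(populations)
  if (is.character(env)) env <- read_environment(env)
  env <- validate_environment(env)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = as.integer(seed),
                   n_populations_input = nrow(populations$meta))
  trends <- population_trends(populations)
  manifest$n_eligible <- nrow(trends)
  trends <- quality_filter(trends)
  manifest$n_quality <- nrow(trends)
  manifest$excluded <- lapply(attr(trends, "exclusions"), as.character)
  meta <- populations$meta
  if (influence) {
    r0 <- driver_rates(trends, meta, env, cc_lag = 0, luc_lag = 0)
    d0 <- build_design(trends, r0, meta, "Base")
    infl <- influence_screen(d0, "Base")
    flagged <- infl$population_id[infl$flagged]
    manifest$excluded$influence <- as.character(flagged)
    if (length(flagged)) {
      keep <- !trends$population_id %in% flagged
      ser <- attr(trends, "series")
      trends <- trends[keep, , drop = FALSE]
      attr(trends, "series") <- ser[keep]
    }
    write.csv(infl, file.path(out_dir, "influence.csv"), row.names = FALSE)
  }
  manifest$n_final <- nrow(trends)
  write.csv(as.data.frame(trends), file.path(out_dir, "trends.csv"),
            row.names = FALSE)
  scans <- list(); averaged <- list(); support <- list()
  for (st in structures) {
    sc <- lag_scan(trends, meta, env, structure = st, grid = grid)
    scans[[st]] <- sc
    avg <- coef(sc)
    averaged[[st]] <- data.frame(structure = st, term = names(avg),
                                 estimate = as.numeric(avg),
                                 se = as.numeric(attr(avg, "se")),
                                 stringsAsFactors = FALSE)
    sup <- rbind(cbind(driver = "cc", lag_support(sc, "cc")),
                 cbind(driver = "luc", lag_support(sc, "luc")))
    support[[st]] <- cbind(structure = st, sup)
    write.csv(sc$table, file.path(out_dir, paste0("scan_", st, ".csv")),
              row.names = FALSE)
  }
  write.csv(do.call(rbind, averaged),
            file.path(out_dir, "averaged_coefficients.csv"), row.names = FALSE)
  write.csv(do.call(rbind, support), file.path(out_dir, "lag_support.csv"),
            row.names = FALSE)
  manifest$n_lag_combinations <- nrow(grid)
  proj <- NULL
  scen <- setdiff(unique(env$scenario), "historical")
  if (is.null(project)) project <- length(scen) > 0
  if (project && length(scen)) {
    proj <- project_index(scans[[1L]], trends, meta, env)
    write.csv(as.data.frame(proj), file.path(out_dir, "projection.csv"),
              row.names = FALSE)
    manifest$scenarios <- scen
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(trends = trends, scans = scans, averaged = averaged,
                 support = support, projection = proj, manifest = manifest))
}
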