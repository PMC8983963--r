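TRIAL_COLUMNS <- c("trial_id", "analyte", "chamber_volume_ml",
                   "flow_ml_min", "mass_g", "midpoint_hr", "duration_min",
                   "conc_mg_m3")

#' Write chamber trials to CSV
#'
#' One row per sample with columns `trial_id, analyte, chamber_volume_ml,
#' flow_ml_min, mass_g, midpoint_hr, duration_min, conc_mg_m3`. Ground
#' truth of synthetic trials, when present, is written to a sidecar JSON
#' file `<path>.truth.json`.
#'
#' @param trials A [chamber_trial()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chamber_trials <- function(trials, path) {
  if (inherits(trials, "chamber_trial")) trials <- list(trials)
  rows <- lapply(trials, function(tr) {
    data.frame(trial_id = tr$trial_id, analyte = tr$analyte,
               chamber_volume_ml = tr$chamber_volume,
               flow_ml_min = tr$flow_rate, mass_g = tr$sample_mass,
               midpoint_hr = tr$samples$midpoint_hr,
               duration_min = tr$samples$duration_min,
               conc_mg_m3 = tr$samples$conc_mg_m3)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  truths <- Filter(Negate(is.null), lapply(trials, function(tr) tr$truth))
  if (length(truths)) {
    names(truths) <- vapply(Filter(function(tr) !is.null(tr$truth), trials),
                            function(tr) tr$trial_id, character(1))
    jsonlite::write_json(truths, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read chamber trials from CSV
#'
#' Parses and validates a trials CSV (schema of
#' [write_chamber_trials()]); rows of each trial are sorted by midpoint
#' time. Schema or value problems are reported with the offending
#' column/row.
#'
#' @param path CSV path.
#' @return A named list of [chamber_trial()] objects.
#' @export
read_chamber_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols))
    stop("parse-error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num_cols <- setdiff(TRIAL_COLUMNS, c("trial_id", "analyte"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & df[[cc]] != "")
    if (length(bad))
      stop("parse-error: non-numeric value in column '", cc, "', row ",
           bad[1], call. = FALSE)
    df[[cc]] <- v
  }
  out <- lapply(split(df, df$trial_id), function(d) {
    d <- d[order(d$midpoint_hr), ]
    if (any(diff(d$midpoint_hr) <= 0))
      stop("parse-error: duplicate midpoint times in trial '",
           d$trial_id[1], "'", call. = FALSE)
    chamber_trial(trial_id = d$trial_id[1], analyte = d$analyte[1],
                  chamber_volume = d$chamber_volume_ml[1],
                  flow_rate = d$flow_ml_min[1], sample_mass = d$mass_g[1],
                  midpoint_hr = d$midpoint_hr,
                  conc_mg_m3 = d$conc_mg_m3,
                  duration_min = d$duration_min)
  })
  out[unique(df$trial_id)]
}

#' Write emission fits to JSON
#'
#' @param fits List of `emission_fit` objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_emission_fits <- function(fits, path) {
  if (inherits(fits, "emission_fit")) fits <- list(fits)
  jsonlite::write_json(lapply(fits, unclass), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write an exposure profile to CSV
#'
#' Columns `time_min, conc_ppb, running_twa_ppb`.
#'
#' @param profile An [simulate_schedule()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exposure_profile <- function(profile, path) {
  stopifnot(inherits(profile, "exposure_profile"))
  write.csv(data.frame(time_min = profile$time_min,
                       conc_ppb = profile$conc_ppb,
                       running_twa_ppb = profile$running_twa_ppb),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline/scenario configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON, returned as a nested list.
#'
#' @param path Config path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
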