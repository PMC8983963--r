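#' Chamber design used by the synthetic-data generator
#'
#' Defaults reproduce the laboratory setup: a 114 mL chamber at 39.4 mL/min
#' holding 5.2 g of coffee, sampled at midpoints of 2, 4, 6, 8, 10, 15, 35
#' and 60 minutes (the first five samples last 30 s, the last three 1 min).
#'
#' @param chamber_volume mL.
#' @param flow_rate mL/min.
#' @param sample_mass g.
#' @param midpoint_min Sample midpoints in minutes, strictly increasing.
#' @param duration_min Per-sample durations in minutes.
#' @return A list of class `chamber_design`.
#' @export
chamber_design <- function(chamber_volume = 114, flow_rate = 39.4,
                           sample_mass = 5.2,
                           midpoint_min = c(2, 4, 6, 8, 10, 15, 35, 60),
                           duration_min = c(rep(0.5, 5), rep(1, 3))) {
  stopifnot(chamber_volume > 0, flow_rate > 0, sample_mass > 0,
            length(midpoint_min) >= 1, all(midpoint_min > 0),
            all(diff(midpoint_min) > 0),
            length(duration_min) == length(midpoint_min))
  structure(list(chamber_volume = chamber_volume, flow_rate = flow_rate,
                 sample_mass = sample_mass,
                 midpoint_hr = midpoint_min / 60,
                 duration_min = duration_min),
            class = "chamber_design")
}

#' Ground-truth emission parameters for synthetic chamber trials
#'
#' @param ef0,ef_ss True initial and steady-state SERs, mg/kg/hr (>= 0).
#' @param k True source decay constant, 1/hr (> 0).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 = noiseless). The noise has unit median, so the
#'   noiseless curve is the median response.
#' @param seed Integer RNG seed.
#' @return A list of class `true_emission_params`.
#' @export
true_emission_params <- function(ef0, ef_ss, k, noise_cv = 0, seed = 1L) {
  stopifnot(ef0 >= 0, ef_ss >= 0, k > 0, noise_cv >= 0)
  structure(list(ef0 = ef0, ef_ss = ef_ss, k = k,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "true_emission_params")
}

#' Generate a synthetic chamber trial with known ground truth
#'
#' Evaluates the decaying-source concentration model at the design's
#' midpoint times and multiplies each value by independent lognormal noise
#' with unit median and the requested CV. The same seed reproduces the same
#' trial bit-for-bit. The truth parameters are retained on the returned
#' trial for recovery tests.
#'
#' @param design A [chamber_design()].
#' @param truth A [true_emission_params()].
#' @param trial_id,analyte Metadata for the generated trial.
#' @return A [chamber_trial()] with `$truth` populated.
#' @export
gen_chamber_series <- function(design, truth, trial_id = "synthetic",
                               analyte = "diacetyl") {
  stopifnot(inherits(design, "chamber_design"),
            inherits(truth, "true_emission_params"))
  N <- air_exchange_rate(design$flow_rate, design$chamber_volume)
  L <- loading_factor(design$sample_mass, design$chamber_volume)
  conc <- model_concentration(truth$ef0, truth$ef_ss, truth$k, N, L,
                              design$midpoint_hr)
  if (any(!is.finite(conc)))
    stop("invalid parameters: non-finite model concentration", call. = FALSE)
  if (truth$noise_cv > 0) {
    sdlog <- sqrt(log(1 + truth$noise_cv^2))
    noise <- with_seed(truth$seed,
                       rlnorm(length(conc), meanlog = 0, sdlog = sdlog))
    conc <- conc * noise
  }
  chamber_trial(trial_id = trial_id, analyte = analyte,
                chamber_volume = design$chamber_volume,
                flow_rate = design$flow_rate,
                sample_mass = design$sample_mass,
                midpoint_hr = design$midpoint_hr,
                conc_mg_m3 = conc,
                duration_min = design$duration_min,
                truth = unclass(truth))
}

#' Sample lognormal particle diameters with stated GM and GSD
#'
#' Draws n diameters from a lognormal distribution with geometric mean `gm`
#' and geometric standard deviation `gsd` (log-mean `log(gm)`, log-SD
#' `log(gsd)`). `gsd = 1` returns the degenerate sample of identical values.
#'
#' @param gm Geometric mean diameter (cm), > 0.
#' @param gsd Geometric standard deviation, >= 1.
#' @param n Sample size, >= 1.
#' @param seed Integer RNG seed.
#' @return Numeric vector of n positive diameters (cm).
#' @examples
#' gen_particle_sample(gm = 0.036, gsd = 2.0, n = 5, seed = 1)
#' @export
gen_particle_sample <- function(gm, gsd, n, seed) {
  if (gsd < 1) stop("invalid parameters: gsd must be >= 1", call. = FALSE)
  stopifnot(gm > 0, n >= 1)
  with_seed(seed, rlnorm(n, meanlog = log(gm), sdlog = log(gsd)))
}

#' Generate a storage-age SER series with a linear trend
#'
#' SER(day) = intercept + slope*day + Gaussian noise, for testing the
#' storage-trend regression against known ground truth.
#'
#' @param intercept SER at day 0, mg/kg/hr.
#' @param slope Change in SER per storage day.
#' @param days Nonempty vector of storage ages (days).
#' @param noise_sd SD of additive Gaussian noise, >= 0.
#' @param seed Integer RNG seed.
#' @return A data.frame with columns `day` and `ser`.
#' @export
gen_storage_series <- function(intercept, slope, days, noise_sd = 0,
                               seed = 1L) {
  stopifnot(length(days) >= 1, noise_sd >= 0)
  ser <- intercept + slope * days
  if (noise_sd > 0)
    ser <- ser + with_seed(seed, rnorm(length(days), 0, noise_sd))
  data.frame(day = days, ser = ser)
}
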