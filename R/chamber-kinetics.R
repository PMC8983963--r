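#' Construct and validate a chamber emission trial
#'
#' A `chamber_trial` holds the geometry and flow of one small-chamber
#' emission test together with its timed concentration samples. The
#' concentration model has three free parameters, so at least four samples
#' are required for fitting.
#'
#' @param trial_id Character identifier.
#' @param analyte `"diacetyl"` or `"2,3-pentanedione"`.
#' @param chamber_volume Chamber volume in mL.
#' @param flow_rate Air flow through the chamber in mL/min.
#' @param sample_mass Coffee mass in the chamber in g.
#' @param midpoint_hr Sample midpoint times in hours, strictly increasing.
#' @param conc_mg_m3 Measured concentrations in mg/m3, all non-negative.
#' @param duration_min Per-sample durations in minutes (metadata).
#' @param truth Optional list of ground-truth generator parameters, retained
#'   for recovery tests on synthetic trials.
#' @return An object of class `chamber_trial`.
#' @export
chamber_trial <- function(trial_id, analyte, chamber_volume, flow_rate,
                          sample_mass, midpoint_hr, conc_mg_m3,
                          duration_min = rep(NA_real_, length(midpoint_hr)),
                          truth = NULL) {
  stopifnot(chamber_volume > 0, flow_rate > 0, sample_mass > 0)
  if (length(midpoint_hr) != length(conc_mg_m3))
    stop("midpoint_hr and conc_mg_m3 must have equal length", call. = FALSE)
  if (any(!is.finite(midpoint_hr)) || any(midpoint_hr <= 0))
    stop("midpoint times must be finite and positive", call. = FALSE)
  if (any(diff(midpoint_hr) <= 0))
    stop("midpoint times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(conc_mg_m3)) || any(conc_mg_m3 < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  structure(
    list(trial_id = as.character(trial_id), analyte = analyte,
         chamber_volume = chamber_volume, flow_rate = flow_rate,
         sample_mass = sample_mass,
         samples = data.frame(midpoint_hr = midpoint_hr,
                              conc_mg_m3 = conc_mg_m3,
                              duration_min = duration_min),
         truth = truth),
    class = "chamber_trial")
}

#' @export
print.chamber_trial <- function(x, ...) {
  cat(sprintf("Chamber trial '%s' (%s): V=%g mL, Q=%g mL/min, m=%g g, %d samples\n",
              x$trial_id, x$analyte, x$chamber_volume, x$flow_rate,
              x$sample_mass, nrow(x$samples)))
  invisible(x)
}

#' Air-exchange rate of the chamber
#'
#' N (air changes per hour) is the volumetric flow divided by the chamber
#' volume: `N = 60 * flow / volume` for mL/min and mL inputs.
#'
#' @param flow_rate Flow in mL/min.
#' @param chamber_volume Volume in mL.
#' @return N in 1/hr.
#' @examples
#' air_exchange_rate(39.4, 114)  # ~20.7 / hr
#' @export
air_exchange_rate <- function(flow_rate, chamber_volume) {
  if (any(chamber_volume <= 0) || any(flow_rate <= 0))
    stop("flow_rate and chamber_volume must be positive", call. = FALSE)
  60 * flow_rate / chamber_volume
}

#' Loading factor of the chamber
#'
#' Mass of material per unit chamber volume, in kg/m3. For a 5.2 g sample in
#' a 114 mL chamber this is about 45.6 kg/m3.
#'
#' @param sample_mass Mass in g.
#' @param chamber_volume Volume in mL.
#' @return L in kg/m3.
#' @examples
#' loading_factor(5.2, 114)
#' @export
loading_factor <- function(sample_mass, chamber_volume) {
  if (any(chamber_volume <= 0) || any(sample_mass <= 0))
    stop("sample_mass and chamber_volume must be positive", call. = FALSE)
  (sample_mass / 1000) / (chamber_volume / 1e6)
}

#' First-order decaying-source chamber concentration model
#'
#' Concentration at time t in a well-mixed chamber with a source that decays
#' from an initial specific emission rate `ef0` at rate `k` towards a
#' steady-state rate `ef_ss`:
#'
#'   C(t) = L*ef0*(exp(-k t) - exp(-N t)) / (N - k)
#'          + L*ef_ss*(1 - exp(-N t)) / N
#'
#' The second term is the chamber response to a constant source of strength
#' `ef_ss`, whose long-time value is the steady-state concentration
#' `L*ef_ss/N`; `ef_ss` is therefore reported in the same SER units as
#' `ef0`. C(0) = 0 always.
#'
#' @param ef0 Initial SER, mg/kg/hr.
#' @param ef_ss Steady-state SER, mg/kg/hr.
#' @param k Source decay constant, 1/hr; must differ from `N`.
#' @param N Chamber air-exchange rate, 1/hr.
#' @param L Loading factor, kg/m3.
#' @param t Time(s) in hours, >= 0.
#' @return Concentration(s) in mg/m3.
#' @examples
#' model_concentration(2, 0, 1, 20.74, 45.6, 0.15)
#' @export
model_concentration <- function(ef0, ef_ss, k, N, L, t) {
  stopifnot(k > 0, N > 0, L > 0, all(t >= 0))
  if (isTRUE(all.equal(k, N, tolerance = 1e-12)))
    stop("degenerate parameters: k equals the air-exchange rate N",
         call. = FALSE)
  L * ef0 * (exp(-k * t) - exp(-N * t)) / (N - k) +
    L * ef_ss * (1 - exp(-N * t)) / N
}

#' Peak of the modelled concentration curve
#'
#' Finds the maximum of [model_concentration()] on `(0, t_end]` by a grid
#' scan (1e-4 hr resolution) followed by golden-section polish. When
#' `ef_ss = 0` the result matches the closed form
#' `t_max = log(N/k)/(N - k)`. A curve that is still rising at `t_end`
#' (pure asymptotic buildup, `ef0 = 0`) returns the window edge with
#' `boundary = TRUE`.
#'
#' @inheritParams model_concentration
#' @param t_end Right edge of the search window, hr.
#' @return List with `c_max` (mg/m3), `t_max` (hr) and `boundary` flag.
#' @export
peak_concentration <- function(ef0, ef_ss, k, N, L, t_end) {
  stopifnot(is.finite(t_end), t_end > 0)
  f <- function(t) model_concentration(ef0, ef_ss, k, N, L, t)
  grid <- seq(1e-4, t_end, by = 1e-4)
  vals <- f(grid)
  i <- which.max(vals)
  if (i == length(grid)) {
    return(list(c_max = vals[i], t_max = t_end, boundary = TRUE))
  }
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(f, interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
  list(c_max = opt$objective, t_max = opt$maximum, boundary = FALSE)
}

#' Maximum specific emission rate from the peak concentration
#'
#' `ef_max = c_max * Q / m`, algebraically identical to `c_max * N / L`.
#'
#' @param c_max Peak concentration, mg/m3.
#' @param flow_rate Chamber flow in m3/hr.
#' @param sample_mass Coffee mass in kg.
#' @return EF_max in mg/kg/hr.
#' @export
ef_max <- function(c_max, flow_rate, sample_mass) {
  if (any(sample_mass <= 0) || any(flow_rate <= 0))
    stop("flow_rate and sample_mass must be positive", call. = FALSE)
  stopifnot(all(c_max >= 0))
  c_max * flow_rate / sample_mass
}

#' Buildup-corrected maximum emission factor
#'
#' At the concentration peak the chamber has not fully equilibrated; the
#' transient mass balance gives the source strength as
#' `ef_buildup = ef_max / (1 - exp(-N * t_max))`, which is always at least
#' `ef_max` and converges to it as `N*t_max` grows.
#'
#' @param ef_max EF_max in mg/kg/hr.
#' @param N Air-exchange rate, 1/hr.
#' @param t_max Time of the concentration peak, hr; must be positive.
#' @return EF_buildup in mg/kg/hr.
#' @export
ef_buildup <- function(ef_max, N, t_max) {
  if (any(t_max <= 0) || any(N <= 0))
    stop("N and t_max must be positive", call. = FALSE)
  ef_max / (1 - exp(-N * t_max))
}

#' Fit the decaying-source model to a chamber trial
#'
#' Least-squares fit of (ef0, ef_ss, k) to the trial's concentration
#' samples, with the air-exchange rate N and loading factor L fixed from the
#' measured trial geometry (never fitted). The optimiser is run from every
#' point of a start grid and the converged solution with the lowest sum of
#' squared errors is kept (ties broken towards the smallest k). All three
#' parameters are constrained non-negative (k strictly positive); a start
#' value of k landing exactly on N is perturbed by 1e-6 relative.
#'
#' @param trial A [chamber_trial()].
#' @param grid_ef0,grid_ef_ss Start values for ef0 and ef_ss (mg/kg/hr).
#' @param grid_k Start values for k (1/hr).
#' @return An object of class `emission_fit`: the fitted parameters, the
#'   fixed `N` and `L`, the derived `c_max`, `t_max`, `ef_max`,
#'   `ef_buildup`, the objective value `sse` and a `converged` flag. A trial
#'   whose concentrations are all zero returns the exact zero fit.
#' @export
fit_emission_curve <- function(trial,
                               grid_ef0 = seq(0.1, 5, by = 1),
                               grid_ef_ss = seq(0.1, 5, by = 1),
                               grid_k = seq(0.1, 4, by = 1)) {
  stopifnot(inherits(trial, "chamber_trial"))
  s <- trial$samples
  if (nrow(s) < 4)
    stop("insufficient data: at least 4 samples are required", call. = FALSE)
  N <- air_exchange_rate(trial$flow_rate, trial$chamber_volume)
  L <- loading_factor(trial$sample_mass, trial$chamber_volume)
  t_end <- max(s$midpoint_hr)

  if (all(s$conc_mg_m3 == 0)) {
    fit <- list(trial_id = trial$trial_id, analyte = trial$analyte,
                ef0 = 0, ef_ss = 0, k = grid_k[1], N = N, L = L,
                c_max = 0, t_max = t_end, ef_max = 0, ef_buildup = 0,
                boundary_maximum = TRUE, sse = 0, converged = TRUE)
    class(fit) <- "emission_fit"
    return(fit)
  }

  best <- NULL
  for (k0 in grid_k) {
    if (abs(k0 - N) < 1e-12 * max(1, N)) k0 <- k0 * (1 + 1e-6)
    for (e0 in grid_ef0) for (ess in grid_ef_ss) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          conc_mg_m3 ~ model_concentration(ef0, ef_ss, k, N, L, midpoint_hr),
          data = s,
          start = list(ef0 = e0, ef_ss = ess, k = k0),
          lower = c(0, 0, 1e-9),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(residuals(fit)^2)
      kk <- coef(fit)[["k"]]
      if (is.null(best) || sse < best$sse - 1e-12 ||
          (abs(sse - best$sse) <= 1e-12 && kk < best$k)) {
        cf <- coef(fit)
        best <- list(ef0 = cf[["ef0"]], ef_ss = cf[["ef_ss"]], k = kk,
                     sse = sse)
      }
    }
  }

  if (is.null(best)) {
    fit <- list(trial_id = trial$trial_id, analyte = trial$analyte,
                N = N, L = L, sse = NA_real_, converged = FALSE)
    class(fit) <- "emission_fit"
    return(fit)
  }

  pk <- peak_concentration(best$ef0, best$ef_ss, best$k, N, L, t_end)
  Q_m3_hr <- trial$flow_rate * 60 / 1e6
  m_kg <- trial$sample_mass / 1000
  efm <- ef_max(pk$c_max, Q_m3_hr, m_kg)
  fit <- list(trial_id = trial$trial_id, analyte = trial$analyte,
              ef0 = best$ef0, ef_ss = best$ef_ss, k = best$k, N = N, L = L,
              c_max = pk$c_max, t_max = pk$t_max, ef_max = efm,
              ef_buildup = ef_buildup(efm, N, pk$t_max),
              boundary_maximum = pk$boundary,
              sse = best$sse, converged = TRUE)
  class(fit) <- "emission_fit"
  fit
}

#' @export
print.emission_fit <- function(x, ...) {
  cat(sprintf("Emission fit for trial '%s' (%s)\n", x$trial_id, x$analyte))
  if (!isTRUE(x$converged)) {
    cat("  fit did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  EF0 = %.4g, EF_ss = %.4g mg/kg/hr, k = %.4g /hr (SSE %.4g)\n",
              x$ef0, x$ef_ss, x$k, x$sse))
  cat(sprintf("  N = %.4g /hr, L = %.4g kg/m3\n", x$N, x$L))
  cat(sprintf("  Cmax = %.4g mg/m3 at t = %.4g hr%s; EF_max = %.4g, EF_buildup = %.4g mg/kg/hr\n",
              x$c_max, x$t_max,
              if (isTRUE(x$boundary_maximum)) " (window edge)" else "",
              x$ef_max, x$ef_buildup))
  invisible(x)
}
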