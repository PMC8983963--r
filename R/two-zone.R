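#' Construct a two-zone near-field/far-field system
#'
#' The standard two-zone topology: a small near field of volume `nf_volume`
#' containing the source exchanges air with the surrounding far field at the
#' inter-zone flow `beta`; the far field receives clean supply air and is
#' exhausted at `supply_air`. Both zones are instantaneously well mixed, the
#' only removal is exhaust, and supply air is contaminant-free.
#'
#' @param room_volume Total room volume V, m3.
#' @param nf_volume Near-field volume V_N, m3 (0 < V_N < V).
#' @param supply_air Supply/exhaust flow Q, m3/min.
#' @param beta Inter-zone air flow, m3/min.
#' @param generation Source generation rate G in the near field, mg/min.
#' @param analyte Analyte name for unit conversions (see
#'   [analyte_constants()]).
#' @return A list of class `two_zone_system`.
#' @export
two_zone_system <- function(room_volume, nf_volume, supply_air, beta,
                            generation, analyte = "diacetyl") {
  stopifnot(room_volume > nf_volume, nf_volume > 0, supply_air > 0,
            beta > 0, generation >= 0)
  structure(list(room_volume = room_volume, nf_volume = nf_volume,
                 ff_volume = room_volume - nf_volume,
                 supply_air = supply_air, beta = beta,
                 generation = generation, analyte = analyte),
            class = "two_zone_system")
}

#' @export
print.two_zone_system <- function(x, ...) {
  cat(sprintf("Two-zone system (%s): V=%g m3 (NF %g m3), Q=%g m3/min, beta=%g m3/min, G=%g mg/min\n",
              x$analyte, x$room_volume, x$nf_volume, x$supply_air, x$beta,
              x$generation))
  invisible(x)
}

#' Inter-zone air flow from boundary air speed
#'
#' `beta = s/2 * A_FS`: half the random air speed at the near-field boundary
#' times the free-slip surface area (air crosses the boundary inward half
#' the time).
#'
#' @param s Random air speed at the boundary, m/min.
#' @param free_slip_area Free-slip boundary area A_FS, m2.
#' @return beta in m3/min.
#' @examples
#' interzone_flow(6.0, near_field_geometry()$free_slip_area)  # ~10.6
#' @export
interzone_flow <- function(s, free_slip_area) {
  stopifnot(all(s > 0), free_slip_area > 0)
  0.5 * s * free_slip_area
}

#' Steady-state zone concentrations
#'
#' As t grows the zone balances reduce to `C_F = G/Q` and
#' `C_N = G/Q + G/beta`, independent of the zone volumes.
#'
#' @param system A [two_zone_system()].
#' @return List with `c_nf` and `c_ff` in mg/m3.
#' @export
steady_state <- function(system) {
  stopifnot(inherits(system, "two_zone_system"))
  cf <- system$generation / system$supply_air
  list(c_nf = cf + system$generation / system$beta, c_ff = cf)
}

# Internal: coefficient matrix, steady state, and eigen pieces of the
# coupled zone balances
#   V_N dC_N/dt = G + beta (C_F - C_N)
#   V_F dC_F/dt = beta (C_N - C_F) - Q C_F
two_zone_eigen <- function(system) {
  vn <- system$nf_volume; vf <- system$ff_volume
  b <- system$beta; q <- system$supply_air
  A <- matrix(c(-b / vn, b / vn,
                b / vf, -(b + q) / vf),
              nrow = 2, byrow = TRUE)
  ss <- steady_state(system)
  ev <- eigen(A)
  list(A = A, ss = c(ss$c_nf, ss$c_ff),
       values = ev$values, vectors = ev$vectors)
}

#' Transient solution of the two-zone balances
#'
#' Exact analytic solution of the coupled linear balances (see
#' [two_zone_system()]) from arbitrary initial zone concentrations,
#' evaluated at the requested times via the two-eigenvalue form
#' `x(t) = x_ss + V exp(L t) V^-1 (x0 - x_ss)`. A (measure-zero) repeated
#' eigenvalue falls back to the limiting form
#' `exp(At) = exp(lt) (I + (A - lI) t)` and flags the result.
#'
#' @param system A [two_zone_system()].
#' @param initial Numeric length-2 vector `c(c_nf, c_ff)` in mg/m3
#'   (default both zero).
#' @param t Time(s) in minutes, >= 0.
#' @return data.frame with columns `time_min`, `c_nf`, `c_ff` (mg/m3);
#'   attribute `repeated_eigenvalue` is TRUE when the fallback was used.
#' @export
transient_solution <- function(system, initial = c(0, 0), t) {
  stopifnot(inherits(system, "two_zone_system"),
            length(initial) == 2, all(initial >= 0), all(t >= 0))
  eg <- two_zone_eigen(system)
  d0 <- initial - eg$ss
  lam <- eg$values
  repeated <- abs(lam[1] - lam[2]) <= 1e-9 * max(abs(lam), 1e-12)
  if (!repeated) {
    w <- solve(eg$vectors) %*% d0
    # columns of E are exp(lambda_i t_j) * w_i; 2 x length(t)
    E <- exp(outer(lam, t)) * as.numeric(w)
    out <- t(eg$vectors %*% E + eg$ss)
  } else {
    l <- mean(lam)
    B <- eg$A - diag(l, 2)
    base <- matrix(d0, nrow = 2, ncol = length(t)) + (B %*% d0) %*% rbind(t)
    out <- t(eg$ss + base * rep(exp(l * t), each = 2))
  }
  out[out < 0 & out > -1e-12] <- 0
  res <- data.frame(time_min = t, c_nf = out[, 1], c_ff = out[, 2])
  attr(res, "repeated_eigenvalue") <- repeated
  res
}

#' Convert a mass concentration to parts per billion
#'
#' Uses the ideal-gas molar volume of 24.45 L/mol (25 degC, 1 atm):
#' `ppb = C_mg_m3 * 1000 * 24.45 / molar_mass`.
#'
#' @param conc Concentration(s) in mg/m3.
#' @param molar_mass Molar mass in g/mol.
#' @return Concentration(s) in ppb (v/v).
#' @examples
#' mass_to_ppb(1, analyte_constants("diacetyl")$molar_mass)  # ~284 ppb
#' @export
mass_to_ppb <- function(conc, molar_mass) {
  stopifnot(molar_mass > 0)
  conc * 1000 * MOLAR_VOLUME_L / molar_mass
}

#' Generation rate from a specific emission rate and source mass
#'
#' `G = SER * mass / 60`: a SER in mg per kg of coffee per hour applied to
#' `coffee_mass` kilograms, converted to mg/min.
#'
#' @param ser Specific emission rate, mg/kg/hr.
#' @param coffee_mass Source mass, kg.
#' @return G in mg/min.
#' @examples
#' generation_rate(3.60, 10)  # 0.6 mg/min
#' @export
generation_rate <- function(ser, coffee_mass) {
  stopifnot(all(ser >= 0), all(coffee_mass >= 0))
  ser * coffee_mass / 60
}

#' Mass emitted by a constant source over a task
#'
#' @param G Generation rate, mg/min.
#' @param duration Task duration, min.
#' @return Emitted mass in mg.
#' @export
emitted_mass <- function(G, duration) {
  stopifnot(all(G >= 0), all(duration >= 0))
  G * duration
}

#' Time-weighted average concentration over segments
#'
#' `sum(c_i d_i) / sum(d_i)` over (concentration, duration) segments.
#'
#' @param conc Segment concentrations, ppb.
#' @param duration Segment durations, min; total must be positive.
#' @return TWA in ppb.
#' @examples
#' twa(c(123.5, 0.2), c(1, 14))  # 8.4 ppb
#' @export
twa <- function(conc, duration) {
  if (length(conc) == 0 || length(duration) == 0)
    stop("twa requires at least one segment", call. = FALSE)
  stopifnot(length(conc) == length(duration), all(duration >= 0))
  tot <- sum(duration)
  if (tot <= 0) stop("total duration must be positive", call. = FALSE)
  sum(conc * duration) / tot
}
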