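# Shared fixtures and independent numerical oracles.

# The laboratory chamber setup: 114 mL, 39.4 mL/min, 5.2 g, midpoints
# 2..60 min.
lab_design <- function() chamber_design()

# Fixed-step RK4 integration of the two-zone balances (independent of the
# analytic eigenvalue path in the package).
rk4_two_zone <- function(system, initial, t_end, dt) {
  requireNamespace("deSolve", quietly = TRUE)
  deriv <- function(t, y, p) {
    list(c((p$G + p$beta * (y[2] - y[1])) / p$vn,
           (p$beta * (y[1] - y[2]) - p$Q * y[2]) / p$vf))
  }
  p <- list(G = system$generation, beta = system$beta,
            Q = system$supply_air, vn = system$nf_volume,
            vf = system$ff_volume)
  times <- seq(0, t_end, by = dt)
  out <- deSolve::rk4(initial, times, deriv, p)
  data.frame(time_min = out[, 1], c_nf = out[, 2], c_ff = out[, 3])
}

# Random but physically plausible two-zone systems for property sweeps.
random_two_zone <- function() {
  two_zone_system(room_volume = runif(1, 2000, 32000),
                  nf_volume = runif(1, 0.6, 2),
                  supply_air = runif(1, 50, 300),
                  beta = runif(1, 1.77, 42.4),
                  generation = runif(1, 0.03, 12))
}
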