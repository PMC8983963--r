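test_that("air-exchange rate and loading factor match the chamber geometry", {
  expect_equal(air_exchange_rate(39.4, 114), 20.7, tolerance = 0.005)
  expect_equal(air_exchange_rate(114, 114), 60)
  expect_equal(air_exchange_rate(10, 1000), 0.6)
  expect_error(air_exchange_rate(39.4, 0), "positive")

  expect_equal(loading_factor(5.2, 114), 45.6, tolerance = 0.005)
  expect_equal(loading_factor(0.114, 114), 1.0)
  expect_equal(loading_factor(1.0, 500), 2.0)
  expect_error(loading_factor(1, 0), "positive")
})

test_that("concentration model: zero source, zero time, steady state and degeneracy", {
  expect_equal(model_concentration(0, 0, 1, 20.74, 45.6, c(0, 0.1, 1)),
               rep(0, 3))
  # C(0) = 0 for arbitrary parameter sets
  set.seed(42)
  for (i in 1:20) {
    expect_equal(model_concentration(runif(1, 0, 5), runif(1, 0, 5),
                                     runif(1, 0.1, 4), runif(1, 5, 60),
                                     runif(1, 10, 90), 0), 0)
  }
  # asymptote term tends to the steady-state concentration L*ef_ss/N
  expect_equal(model_concentration(0, 1, 1, 20.74, 45.6, 10),
               45.6 / 20.74, tolerance = 1e-6)
  expect_error(model_concentration(1, 0, 20.74, 20.74, 45.6, 0.1),
               "degenerate")
})

test_that("model concentration agrees with direct substitution", {
  # frozen from direct evaluation of the closed form:
  # 45.6*2*(exp(-0.1538) - exp(-20.74*0.1538))/(20.74 - 1) = 3.7712
  expect_equal(model_concentration(2, 0, 1, 20.74, 45.6, 0.1538),
               3.771189, tolerance = 1e-5)
})

test_that("peak location matches the closed form when ef_ss = 0", {
  N <- air_exchange_rate(39.4, 114)
  L <- loading_factor(5.2, 114)
  for (k in c(0.3, 1, 2.5, 4)) {
    pk <- peak_concentration(2, 0, k, N, L, t_end = 1)
    expect_false(pk$boundary)
    expect_equal(pk$t_max, log(N / k) / (N - k), tolerance = 1e-6)
  }
})

test_that("a pure asymptotic buildup flags a boundary maximum at the window edge", {
  pk <- peak_concentration(0, 1, 1, 20.74, 45.6, t_end = 1)
  expect_true(pk$boundary)
  expect_equal(pk$t_max, 1)
})

test_that("peak search matches a brute-force grid oracle with a nonzero asymptote", {
  N <- 20.74; L <- 45.6
  pk <- peak_concentration(2, 0.5, 1, N, L, t_end = 1)
  grid <- seq(1e-4, 1, by = 1e-4)
  vals <- model_concentration(2, 0.5, 1, N, L, grid)
  expect_equal(pk$t_max, grid[which.max(vals)], tolerance = 2e-4)
  expect_gte(pk$c_max, max(vals) - 1e-12)
})

test_that("EF_max obeys both algebraic forms of the flow identity", {
  # c_max * Q/m must equal c_max * N/L to machine precision
  Q <- 39.4 * 60 / 1e6; m <- 0.0052
  N <- air_exchange_rate(39.4, 114); L <- loading_factor(5.2, 114)
  for (cm in c(0.5, 1, 3.78)) {
    e <- ef_max(cm, Q, m)
    expect_equal(e, cm * N / L, tolerance = 1e-12)
    expect_equal(e * m / Q, cm, tolerance = 1e-12)
  }
  expect_equal(ef_max(3.78, Q, m), 1.72, tolerance = 0.005)
  expect_equal(ef_max(0, Q, m), 0)
  expect_equal(ef_max(1, 1, 1), 1)
  expect_error(ef_max(1, 1, 0), "positive")
})

test_that("buildup correction increases EF_max and vanishes for an equilibrated chamber", {
  # frozen: 1.716 / (1 - exp(-20.74*0.1538)) = 1.789699
  expect_equal(ef_buildup(1.716, 20.74, 0.1538), 1.7897, tolerance = 1e-4)
  expect_equal(ef_buildup(1, 50, 1), 1, tolerance = 1e-12)
  expect_equal(ef_buildup(0, 20.74, 0.1538), 0)
  expect_error(ef_buildup(1, 20.74, 0), "positive")
  set.seed(7)
  for (i in 1:20) {
    e <- runif(1, 0.1, 5); N <- runif(1, 5, 60); tm <- runif(1, 0.02, 1)
    expect_gte(ef_buildup(e, N, tm), e)
  }
})

test_that("noiseless round trip recovers generator truth to 0.1%", {
  d <- lab_design()
  truth <- true_emission_params(2, 0.5, 1, noise_cv = 0)
  fit <- fit_emission_curve(gen_chamber_series(d, truth))
  expect_true(fit$converged)
  expect_equal(fit$ef0, 2, tolerance = 1e-3)
  expect_equal(fit$ef_ss, 0.5, tolerance = 1e-3)
  expect_equal(fit$k, 1, tolerance = 1e-3)
  # derived quantities are consistent with the fitted parameters
  pk <- peak_concentration(fit$ef0, fit$ef_ss, fit$k, fit$N, fit$L,
                           max(d$midpoint_hr))
  expect_equal(fit$c_max, pk$c_max)
  expect_equal(fit$ef_buildup, ef_buildup(fit$ef_max, fit$N, fit$t_max))
})

test_that("an all-zero trial fits to the exact zero source", {
  d <- lab_design()
  tr <- gen_chamber_series(d, true_emission_params(0, 0, 1))
  fit <- fit_emission_curve(tr)
  expect_true(fit$converged)
  expect_identical(fit$ef0, 0)
  expect_identical(fit$ef_ss, 0)
  expect_identical(fit$ef_max, 0)
})

test_that("fitting fewer than four samples is refused", {
  tr <- chamber_trial("t", "diacetyl", 114, 39.4, 5.2,
                      midpoint_hr = c(0.05, 0.1, 0.2),
                      conc_mg_m3 = c(1, 2, 1.5))
  expect_error(fit_emission_curve(tr), "insufficient")
})

test_that("trial validation rejects malformed inputs", {
  expect_error(chamber_trial("t", "diacetyl", 114, 39.4, 5.2,
                             midpoint_hr = c(0.1, 0.1),
                             conc_mg_m3 = c(1, 2)), "increasing")
  expect_error(chamber_trial("t", "diacetyl", 114, 39.4, 5.2,
                             midpoint_hr = c(0.1, 0.2),
                             conc_mg_m3 = c(-1, 2)), "non-negative")
})
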