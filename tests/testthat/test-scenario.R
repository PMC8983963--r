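scenario_system <- function(beta = 10.6) {
  two_zone_system(7787, near_field_geometry()$nf_volume, 73.2, beta, 0,
                  "diacetyl")
}

test_that("scenario presets build valid 480-min schedules", {
  for (sc in c("scenario_A", "scenario_B")) {
    sch <- build_schedule(sc)
    expect_s3_class(sch, "schedule")
    expect_equal(sum(sch$duration), 480)
    expect_equal(sum(sch$label == "grinding"), 4)
    expect_equal(sum(sch$label == "packaging"), 12)
    expect_equal(sum(sch$duration[sch$location == "off_exposure"]), 60)
  }
  expect_equal(build_schedule("scenario_B")$duration[
    build_schedule("scenario_B")$label == "grinding"], rep(1, 4))
})

test_that("invalid schedules are rejected with the residual reported", {
  expect_error(build_schedule(list()), "schedule-invalid")
  expect_error(
    build_schedule(list(task_segment("idle", "far_field", 100))),
    "residual 380")
})

test_that("an all-off-exposure schedule yields a zero profile", {
  sch <- build_schedule(list(task_segment("off", "off_exposure", 480)))
  prof <- simulate_schedule(sch, scenario_system())
  expect_equal(max(prof$conc_ppb), 0)
  expect_equal(full_shift_twa(prof), 0)
  exc <- exceedance(prof, rel = 5, stel = 25)
  expect_false(exc$exceeds_rel)
  expect_false(exc$exceeds_stel)
})

test_that("scenario A emits the reference per-task masses", {
  prof <- simulate_schedule(build_schedule("scenario_A"),
                            scenario_system())
  tk <- prof$tasks
  expect_equal(unique(tk$emitted_mg[tk$label == "grinding"]), 9)
  expect_equal(unique(tk$emitted_mg[tk$label == "packaging"]), 0.53,
               tolerance = 0.01)
  # emitted-mass additivity over the near-field segments
  nf <- tk$location == "near_field"
  expect_equal(sum(tk$emitted_mg),
               sum(tk$G_mg_min[nf] * tk$duration[nf]))
})

test_that("scenario B per-task packaging mass matches hand arithmetic", {
  prof <- simulate_schedule(build_schedule("scenario_B"),
                            scenario_system())
  tk <- prof$tasks
  # 0.21 mg/kg/hr * 181.8 kg / 60 * 15 min = 9.54 mg
  expect_equal(unique(tk$emitted_mg[tk$label == "packaging"]), 9.6,
               tolerance = 0.01)
})

test_that("a single task dilutes into the shift by its duration share", {
  sch <- build_schedule(list(
    task_segment("grinding", "near_field", 15, coffee_mass = 10, ser = 3.6),
    task_segment("off", "off_exposure", 465)))
  prof <- simulate_schedule(sch, scenario_system(), dt = 0.05)
  task_twa <- prof$tasks$twa_ppb[1]
  expect_equal(full_shift_twa(prof), task_twa * 15 / 480,
               tolerance = 1e-6)
})

test_that("full-shift TWA of a constant profile equals the constant", {
  sch <- build_schedule(list(task_segment("fixed", "far_field", 480,
                                          fixed_conc = 5)))
  prof <- simulate_schedule(sch, scenario_system())
  expect_equal(full_shift_twa(prof), 5, tolerance = 1e-9)
})

test_that("running TWA at shift end equals the full-shift TWA", {
  prof <- simulate_schedule(build_schedule("scenario_A"),
                            scenario_system())
  expect_equal(prof$running_twa_ppb[length(prof$running_twa_ppb)],
               full_shift_twa(prof), tolerance = 1e-9)
  expect_true(all(prof$conc_ppb >= 0))
})

test_that("STEL comparison reports the reference excursion ratio", {
  sch <- build_schedule(list(
    task_segment("grinding", "near_field", 1, fixed_conc = 123.5),
    task_segment("off", "off_exposure", 479)))
  prof <- simulate_schedule(sch, scenario_system())
  exc <- exceedance(prof, rel = 5, stel = 25)
  expect_equal(exc$max_task_stel_ratio, 4.9, tolerance = 0.01)

  flat <- build_schedule(list(task_segment("t", "far_field", 480,
                                           fixed_conc = 25)))
  exc2 <- exceedance(simulate_schedule(flat, scenario_system()),
                     rel = 5, stel = 25)
  expect_equal(exc2$max_task_stel_ratio, 1)
})

test_that("content fraction stays under the 5% sanity bound for every preset task", {
  expect_equal(content_fraction(9, 10, 19), 4.7, tolerance = 0.01)
  expect_equal(content_fraction(0, 10, 19), 0)
  expect_equal(content_fraction(9.6, 181.8, 19), 0.28, tolerance = 0.01)
  for (sc in c("scenario_A", "scenario_B")) {
    sch <- build_schedule(sc)
    prof <- simulate_schedule(sch, scenario_system())
    nf <- prof$tasks[prof$tasks$location == "near_field", ]
    mass <- sch$coffee_mass[sch$location == "near_field"]
    expect_true(all(content_fraction(nf$emitted_mg, mass, 19) <= 5))
  }
})

test_that("the exposure engine is linear in the generation rate", {
  sch1 <- build_schedule("scenario_A")
  sch2 <- sch1
  sch2$ser <- sch2$ser * 2
  p1 <- simulate_schedule(sch1, scenario_system())
  p2 <- simulate_schedule(sch2, scenario_system())
  expect_equal(full_shift_twa(p2), 2 * full_shift_twa(p1),
               tolerance = 1e-9)
  expect_equal(p2$tasks$twa_ppb, 2 * p1$tasks$twa_ppb, tolerance = 1e-9)
})

test_that("adding off-exposure time never increases the full-shift TWA", {
  base <- list(
    task_segment("grinding", "near_field", 15, coffee_mass = 10, ser = 3.6),
    task_segment("idle", "far_field", 225))
  p_base <- simulate_schedule(build_schedule(base, shift_length = 240),
                              scenario_system())
  extended <- c(base, list(task_segment("off", "off_exposure", 240)))
  p_ext <- simulate_schedule(build_schedule(extended, shift_length = 480),
                             scenario_system())
  expect_lte(full_shift_twa(p_ext), full_shift_twa(p_base))
})
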