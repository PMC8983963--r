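#' Construct one task segment of a work schedule
#'
#' @param label Segment label (e.g. "packaging", "grinding", "break").
#' @param location `"near_field"`, `"far_field"` or `"off_exposure"`.
#' @param duration Segment duration in minutes, > 0.
#' @param coffee_mass,ser Source description for near-field segments: mass
#'   of coffee (kg) and its specific emission rate (mg/kg/hr).
#' @param fixed_conc Optional fixed worker concentration in ppb that
#'   overrides the modelled concentration for this segment.
#' @return A one-row data.frame.
#' @export
task_segment <- function(label, location, duration,
                         coffee_mass = NA_real_, ser = NA_real_,
                         fixed_conc = NA_real_) {
  location <- match.arg(location,
                        c("near_field", "far_field", "off_exposure"))
  stopifnot(duration > 0)
  if (location == "near_field" && is.na(fixed_conc) &&
      (is.na(coffee_mass) || is.na(ser)))
    stop("near-field segments must carry a source (coffee_mass and ser) ",
         "or a fixed concentration", call. = FALSE)
  data.frame(label = label, location = location, duration = duration,
             coffee_mass = coffee_mass, ser = ser, fixed_conc = fixed_conc)
}

# Default sources for the built-in scenarios: dark-roast SERs (mg/kg/hr)
# for whole-bean packaging and fine-ground grinding.
SCENARIO_SER <- c(whole_bean = 0.21, fine_ground = 3.60)

scenario_cycle <- function(mass_kg, grind_min, ser_pack, ser_grind) {
  gap <- task_segment("gap", "far_field", 5)
  pack <- task_segment("packaging", "near_field", 15,
                       coffee_mass = mass_kg, ser = ser_pack)
  rbind(pack, gap, pack, gap, pack, gap,
        task_segment("grinding", "near_field", grind_min,
                     coffee_mass = mass_kg, ser = ser_grind),
        gap,
        task_segment("cleaning_labeling", "far_field", 15))
}

#' Build a validated work-shift schedule
#'
#' Either from a preset name or from a list of [task_segment()] rows. The
#' presets describe an 8-h (480 min) shift in which a production worker
#' runs four cycles of three 15-min whole-bean packaging tasks and one
#' grinding task, separated by 5-min far-field gaps, with 15 min of
#' far-field cleaning/labeling per cycle, two 15-min breaks and a 30-min
#' lunch (no exposure), and far-field idle time padding the shift to
#' 480 min:
#' * `"scenario_A"`: 10 kg of dark roast per task, 15-min grinding
#'   (small facility).
#' * `"scenario_B"`: 181.8 kg per task, 1-min grinding (medium facility
#'   with a large grinder).
#'
#' @param spec Preset name or a data.frame/list of segments.
#' @param shift_length Required total duration in minutes.
#' @return A data.frame of class `schedule` whose durations sum to
#'   `shift_length`.
#' @export
build_schedule <- function(spec, shift_length = 480) {
  if (is.character(spec) && length(spec) == 1 &&
      spec %in% c("scenario_A", "scenario_B")) {
    mass <- if (spec == "scenario_A") 10 else 181.8
    grind_min <- if (spec == "scenario_A") 15 else 1
    cyc <- scenario_cycle(mass, grind_min,
                          SCENARIO_SER[["whole_bean"]],
                          SCENARIO_SER[["fine_ground"]])
    idle10 <- task_segment("idle", "far_field", 10)
    segs <- rbind(cyc, idle10,
                  task_segment("break", "off_exposure", 15),
                  cyc, idle10,
                  task_segment("lunch", "off_exposure", 30),
                  cyc, idle10,
                  task_segment("break", "off_exposure", 15),
                  cyc)
    pad <- shift_length - sum(segs$duration)
    if (pad > 0)
      segs <- rbind(segs, task_segment("idle", "far_field", pad))
  } else {
    if (is.null(spec) || (is.list(spec) && length(spec) == 0))
      stop("schedule-invalid: empty scenario specification", call. = FALSE)
    segs <- if (is.data.frame(spec)) spec else do.call(rbind, spec)
  }
  needed <- c("label", "location", "duration", "coffee_mass", "ser",
              "fixed_conc")
  missing_cols <- setdiff(needed, names(segs))
  if (length(missing_cols))
    stop("schedule-invalid: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  total <- sum(segs$duration)
  if (abs(total - shift_length) > 1e-9)
    stop(sprintf(
      "schedule-invalid: durations sum to %g min, not %g (residual %g)",
      total, shift_length, shift_length - total), call. = FALSE)
  structure(segs, class = c("schedule", "data.frame"),
            shift_length = shift_length)
}

#' Simulate a worker's exposure over a schedule
#'
#' Runs the two-zone model across the shift. The far field evolves
#' continuously; sources are active only during their own segments. During a
#' near-field task both zones start at the prevailing far-field
#' concentration (the worker walks up to a ventilated room) and the worker
#' breathes the near-field concentration; during far-field segments the
#' worker breathes the evolving far-field concentration; off-exposure
#' segments contribute zero. Segments with `fixed_conc` use that value for
#' the worker while the room evolves source-free.
#'
#' @param schedule A [build_schedule()] result.
#' @param system A [two_zone_system()] template supplying room geometry,
#'   supply air, inter-zone flow and analyte (its `generation` is ignored;
#'   each segment's source sets G).
#' @param dt Evaluation time step in minutes.
#' @return An object of class `exposure_profile`: `time_min`,
#'   `conc_ppb` (worker), `running_twa_ppb` at each time; `tasks`, a
#'   per-segment table with TWA and emitted mass; and the shift length.
#' @export
simulate_schedule <- function(schedule, system, dt = 0.25) {
  stopifnot(inherits(schedule, "schedule"),
            inherits(system, "two_zone_system"), dt > 0)
  mm <- analyte_constants(system$analyte)$molar_mass
  state <- c(0, 0)  # (c_nf, c_ff) mg/m3
  t0 <- 0
  times <- numeric(0); conc <- numeric(0)
  tasks <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    seg <- schedule[i, ]
    G <- if (seg$location == "near_field" && !is.na(seg$ser)) {
      generation_rate(seg$ser, seg$coffee_mass)
    } else 0
    if (seg$location == "near_field" && G == 0 && is.na(seg$fixed_conc))
      stop("missing-ser: near-field segment '", seg$label,
           "' has no resolvable source", call. = FALSE)
    sys_i <- two_zone_system(system$room_volume, system$nf_volume,
                             system$supply_air, system$beta, G,
                             system$analyte)
    x0 <- if (seg$location == "near_field") c(state[2], state[2]) else state
    n <- max(2L, as.integer(ceiling(seg$duration / dt)) + 1L)
    tt <- seq(0, seg$duration, length.out = n)
    sol <- transient_solution(sys_i, x0, tt)
    worker_mg <- switch(seg$location,
                        near_field = sol$c_nf,
                        far_field = sol$c_ff,
                        off_exposure = rep(0, n))
    worker_ppb <- mass_to_ppb(worker_mg, mm)
    if (!is.na(seg$fixed_conc)) worker_ppb <- rep(seg$fixed_conc, n)
    seg_twa <- twa((head(worker_ppb, -1) + tail(worker_ppb, -1)) / 2,
                   diff(tt))
    tasks[[i]] <- data.frame(segment = i, label = seg$label,
                             location = seg$location,
                             start_min = t0, duration = seg$duration,
                             G_mg_min = G,
                             twa_ppb = seg_twa,
                             emitted_mg = emitted_mass(G, seg$duration))
    # keep the segment's own start point: worker concentration can jump at
    # segment boundaries, and the duplicated time makes the trapezoid
    # integral exact across the jump
    times <- c(times, t0 + tt)
    conc <- c(conc, worker_ppb)
    state <- c(sol$c_nf[n], sol$c_ff[n])
    t0 <- t0 + seg$duration
  }
  # cumulative trapezoid integral -> running TWA
  cum <- c(0, cumsum(diff(times) * (head(conc, -1) + tail(conc, -1)) / 2))
  running <- ifelse(times > 0, cum / times, 0)
  structure(list(time_min = times, conc_ppb = conc,
                 running_twa_ppb = running,
                 tasks = do.call(rbind, tasks),
                 shift_length = attr(schedule, "shift_length"),
                 analyte = system$analyte),
            class = "exposure_profile")
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat(sprintf("Exposure profile (%s), %g-min shift, %d segments\n",
              x$analyte, x$shift_length, nrow(x$tasks)))
  cat(sprintf("  full-shift TWA: %.3g ppb; max instantaneous: %.3g ppb\n",
              full_shift_twa(x), max(x$conc_ppb)))
  invisible(x)
}

#' Full-shift time-weighted average of an exposure profile
#'
#' TWA over the whole shift, zero-exposure periods included.
#'
#' @param profile An [simulate_schedule()] result.
#' @return TWA in ppb.
#' @export
full_shift_twa <- function(profile) {
  stopifnot(inherits(profile, "exposure_profile"))
  tt <- profile$time_min; cc <- profile$conc_ppb
  sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2) / profile$shift_length
}

#' REL/STEL exceedance report for an exposure profile
#'
#' Compares the full-shift TWA against the recommended exposure limit (REL)
#' and short-term behaviour against the 15-min short-term exposure limit
#' (STEL): the maximum rolling 15-min TWA (1-min step) and the largest
#' per-task TWA as a ratio to the STEL.
#'
#' @param profile An exposure profile.
#' @param rel,stel Limits in ppb, > 0.
#' @return List with `full_shift_twa_ppb`, `exceeds_rel`,
#'   `max_rolling_15min_ppb`, `max_task_twa_ppb`, `max_task_stel_ratio`,
#'   `exceeds_stel`.
#' @export
exceedance <- function(profile, rel, stel) {
  stopifnot(inherits(profile, "exposure_profile"), rel > 0, stel > 0)
  fst <- full_shift_twa(profile)
  grid <- seq(0, profile$shift_length, by = 1)
  cgrid <- approx(profile$time_min, profile$conc_ppb, xout = grid,
                  rule = 2, ties = "ordered")$y
  cum <- c(0, cumsum((head(cgrid, -1) + tail(cgrid, -1)) / 2))
  win <- 15L
  n <- length(grid)
  roll <- (cum[(win + 1L):n] - cum[1:(n - win)]) / win
  max_roll <- max(roll)
  max_task <- max(profile$tasks$twa_ppb)
  list(full_shift_twa_ppb = fst,
       exceeds_rel = fst > rel,
       max_rolling_15min_ppb = max_roll,
       max_task_twa_ppb = max_task,
       max_task_stel_ratio = max_task / stel,
       exceeds_stel = max_roll > stel)
}

#' Emitted mass as a fraction of the chemical content of the coffee
#'
#' Model-sanity check: the mass emitted during a task should be a small
#' fraction of the total analyte content of the coffee handled
#' (`content` micrograms per gram, i.e. mg per kg).
#'
#' @param emitted_total Emitted mass, mg.
#' @param coffee_mass Coffee handled, kg.
#' @param content Analyte content of the coffee, ug/g.
#' @return Fraction in percent.
#' @examples
#' content_fraction(9, 10, 19)  # ~4.7%
#' @export
content_fraction <- function(emitted_total, coffee_mass, content) {
  stopifnot(all(coffee_mass > 0), all(content > 0), all(emitted_total >= 0))
  100 * emitted_total / (content * coffee_mass)
}
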