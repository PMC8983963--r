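#' Distribution specifications for Monte Carlo inputs
#'
#' @param lo,hi Uniform bounds, `lo < hi`.
#' @param mean,sd Normal parameters, `sd >= 0`.
#' @param truncate_positive Resample normal draws until positive (physical
#'   parameters cannot be negative); the number of rejected draws is
#'   reported by [sample_inputs()].
#' @param value Fixed (degenerate) value.
#' @return A distribution spec list.
#' @name mc_distributions
NULL

#' @rdname mc_distributions
#' @export
dist_uniform <- function(lo, hi) {
  stopifnot(lo < hi)
  list(kind = "uniform", lo = lo, hi = hi)
}

#' @rdname mc_distributions
#' @export
dist_normal <- function(mean, sd, truncate_positive = TRUE) {
  stopifnot(sd >= 0)
  list(kind = "normal", mean = mean, sd = sd,
       truncate_positive = truncate_positive)
}

#' @rdname mc_distributions
#' @export
dist_fixed <- function(value) list(kind = "fixed", value = value)

#' Monte Carlo specification
#'
#' @param n_iterations Number of draws, >= 1 (default 10000).
#' @param seed Mandatory integer seed.
#' @param distributions Named list of distribution specs (see
#'   [mc_distributions]). Recognised names in [run_mc()]: `Q` (supply air,
#'   m3/min), `beta` (inter-zone flow, m3/min), and `G_<label>` (generation
#'   rate in mg/min for every schedule segment with that label).
#' @return A list of class `mc_spec`.
#' @export
mc_spec <- function(n_iterations = 10000, seed, distributions) {
  stopifnot(n_iterations >= 1, !missing(seed),
            is.list(distributions), length(names(distributions)) > 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 distributions = distributions),
            class = "mc_spec")
}

#' Sample the Monte Carlo input distributions
#'
#' Draws `n_iterations` values from each named distribution. Identical
#' seeds give identical draws. Truncated-normal rejections are counted per
#' parameter in the `truncations` attribute.
#'
#' @param spec An [mc_spec()].
#' @return data.frame with one column per parameter and
#'   `spec$n_iterations` rows.
#' @export
sample_inputs <- function(spec) {
  stopifnot(inherits(spec, "mc_spec"))
  n <- spec$n_iterations
  trunc_counts <- setNames(integer(length(spec$distributions)),
                           names(spec$distributions))
  draws <- with_seed(spec$seed, {
    out <- lapply(names(spec$distributions), function(nm) {
      d <- spec$distributions[[nm]]
      switch(d$kind,
        uniform = runif(n, d$lo, d$hi),
        normal = {
          x <- rnorm(n, d$mean, d$sd)
          if (isTRUE(d$truncate_positive)) {
            bad <- which(x <= 0)
            while (length(bad)) {
              trunc_counts[nm] <<- trunc_counts[nm] + length(bad)
              x[bad] <- rnorm(length(bad), d$mean, d$sd)
              bad <- bad[x[bad] <= 0]
            }
          }
          x
        },
        fixed = rep(d$value, n),
        stop("config-error: unknown distribution kind '", d$kind, "'",
             call. = FALSE))
    })
    names(out) <- names(spec$distributions)
    as.data.frame(out, check.names = FALSE)
  })
  attr(draws, "truncations") <- trunc_counts
  draws
}

apply_draw <- function(schedule, system, draw) {
  for (nm in names(draw)) {
    val <- draw[[nm]]
    if (nm == "Q") {
      system$supply_air <- val
    } else if (nm == "beta") {
      system$beta <- val
    } else if (startsWith(nm, "G_")) {
      lab <- substring(nm, 3)
      hit <- schedule$label == lab
      if (!any(hit))
        stop("config-error: no schedule segment labelled '", lab, "'",
             call. = FALSE)
      # encode the drawn G (mg/min) as a unit-mass source
      schedule$coffee_mass[hit] <- 1
      schedule$ser[hit] <- val * 60
    } else {
      stop("config-error: unknown parameter '", nm, "'", call. = FALSE)
    }
  }
  list(schedule = schedule, system = system)
}

#' Monte Carlo exposure summary over a schedule
#'
#' Runs [simulate_schedule()] once per input draw and reduces the results
#' to medians and 95th percentiles (linear interpolation between order
#' statistics) per task label and for the full-shift TWA, plus exceedance
#' probabilities against the REL and STEL. Draws whose simulation fails are
#' skipped and counted; more than 1% failures aborts the run. A batch
#' standard error of the full-shift median (10 batches) quantifies Monte
#' Carlo noise.
#'
#' @param schedule A [build_schedule()] result.
#' @param system A [two_zone_system()] template.
#' @param spec An [mc_spec()].
#' @param rel,stel Exposure limits in ppb for exceedance probabilities
#'   (defaults from the system's analyte).
#' @param dt Simulation time step, min.
#' @return List of class `exposure_summary`.
#' @export
run_mc <- function(schedule, system, spec, rel = NULL, stel = NULL,
                   dt = 1) {
  stopifnot(inherits(schedule, "schedule"),
            inherits(system, "two_zone_system"), inherits(spec, "mc_spec"))
  consts <- analyte_constants(system$analyte)
  if (is.null(rel)) rel <- consts$rel_ppb
  if (is.null(stel)) stel <- consts$stel_ppb
  draws <- sample_inputs(spec)
  n <- nrow(draws)
  labels <- unique(schedule$label[schedule$location == "near_field"])
  task_mat <- matrix(NA_real_, nrow = n, ncol = length(labels),
                     dimnames = list(NULL, labels))
  fst <- rep(NA_real_, n)
  over_rel <- rep(NA, n); over_stel <- rep(NA, n)
  failures <- 0L
  for (i in seq_len(n)) {
    res <- tryCatch({
      mod <- apply_draw(schedule, system, draws[i, , drop = FALSE])
      prof <- simulate_schedule(mod$schedule, mod$system, dt = dt)
      prof
    }, error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    for (lab in labels) {
      task_mat[i, lab] <-
        mean(res$tasks$twa_ppb[res$tasks$label == lab])
    }
    fst[i] <- full_shift_twa(res)
    if (!is.na(rel)) over_rel[i] <- fst[i] > rel
    if (!is.na(stel))
      over_stel[i] <- max(res$tasks$twa_ppb) > stel
  }
  if (failures > 0.01 * n)
    stop(sprintf("aborted: %d of %d Monte Carlo draws failed", failures, n),
         call. = FALSE)
  ok <- !is.na(fst)
  q <- function(x) quantile(x, c(0.5, 0.95), names = FALSE, na.rm = TRUE)
  per_task <- do.call(rbind, lapply(labels, function(lab) {
    qq <- q(task_mat[ok, lab])
    data.frame(label = lab, median_ppb = qq[1], p95_ppb = qq[2])
  }))
  fq <- q(fst[ok])
  nb <- 10L
  batch <- split(fst[ok], rep_len(seq_len(nb), sum(ok)))
  batch_medians <- vapply(batch, median, numeric(1))
  structure(list(
    per_task = per_task,
    full_shift_median_ppb = fq[1],
    full_shift_p95_ppb = fq[2],
    full_shift_median_se = sd(batch_medians) / sqrt(nb),
    p_exceed_rel = if (!is.na(rel)) mean(over_rel[ok]) else NA_real_,
    p_exceed_stel = if (!is.na(stel)) mean(over_stel[ok]) else NA_real_,
    n_iterations = n, n_failures = failures,
    truncations = attr(draws, "truncations"),
    seed = spec$seed), class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat(sprintf("Monte Carlo exposure summary (%d draws, seed %d, %d failed)\n",
              x$n_iterations, x$seed, x$n_failures))
  for (i in seq_len(nrow(x$per_task)))
    cat(sprintf("  %s: median %.3g ppb (95th %.3g)\n",
                x$per_task$label[i], x$per_task$median_ppb[i],
                x$per_task$p95_ppb[i]))
  cat(sprintf("  full shift: median %.3g ppb (95th %.3g; batch SE %.2g)\n",
              x$full_shift_median_ppb, x$full_shift_p95_ppb,
              x$full_shift_median_se))
  if (!is.na(x$p_exceed_rel))
    cat(sprintf("  P(full-shift TWA > REL) = %.3f; P(task TWA > STEL) = %.3f\n",
                x$p_exceed_rel, x$p_exceed_stel))
  invisible(x)
}

#' Sensitivity of the near-field concentration to inter-zone flow
#'
#' Evaluates the steady-state near-field concentration (in ppb) over a grid
#' of inter-zone flows with all other inputs at their central values, and
#' fits concentration against 1/beta by least squares. The reduced-form
#' steady state `C_N = G/Q + G/beta` makes the fit exact: slope equal to
#' the generation rate and intercept equal to generation over supply air
#' (both in ppb units).
#'
#' @param system A [two_zone_system()] with the central G and Q.
#' @param beta_grid Inter-zone flows, m3/min, all > 0.
#' @return List with `table` (beta, inv_beta, conc_ppb), `slope`,
#'   `intercept` (NA for a single grid point), and `fold_changes` between
#'   consecutive grid points.
#' @export
sensitivity_beta <- function(system, beta_grid) {
  stopifnot(inherits(system, "two_zone_system"), all(beta_grid > 0))
  mm <- analyte_constants(system$analyte)$molar_mass
  conc <- vapply(beta_grid, function(b) {
    s <- system; s$beta <- b
    mass_to_ppb(steady_state(s)$c_nf, mm)
  }, numeric(1))
  tab <- data.frame(beta = beta_grid, inv_beta = 1 / beta_grid,
                    conc_ppb = conc)
  slope <- intercept <- NA_real_
  if (length(beta_grid) > 1) {
    fit <- lm(conc_ppb ~ inv_beta, data = tab)
    slope <- unname(coef(fit)[["inv_beta"]])
    intercept <- unname(coef(fit)[["(Intercept)"]])
  }
  folds <- if (length(beta_grid) > 1) {
    data.frame(beta_from = head(beta_grid, -1),
               beta_to = tail(beta_grid, -1),
               fold = head(conc, -1) / tail(conc, -1))
  } else NULL
  list(table = tab, slope = slope, intercept = intercept,
       fold_changes = folds)
}
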