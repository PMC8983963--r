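#' Summary statistics of replicate specific emission rates
#'
#' Reports the sample mean, sample SD (n-1 denominator), coefficient of
#' variation in percent (100*sd/mean), minimum, maximum and n, the columns
#' of the replicate SER summary table.
#'
#' @param values Nonempty numeric vector of SERs (>= 0), mg/kg/hr.
#' @return A one-row data.frame with columns `mean`, `sd`, `cv_percent`,
#'   `min`, `max`, `n`. For n = 1 the SD and CV are NA.
#' @examples
#' summarize_sers(c(2.22, 2.43, 2.85))
#' @export
summarize_sers <- function(values) {
  stopifnot(length(values) >= 1, all(is.finite(values)), all(values >= 0))
  n <- length(values)
  m <- mean(values)
  s <- if (n > 1) sd(values) else NA_real_
  cv <- if (n > 1) {
    if (m == 0 && s > 0)
      stop("cv undefined: zero mean with nonzero spread", call. = FALSE)
    if (m == 0) 0 else 100 * s / m
  } else NA_real_
  data.frame(mean = m, sd = s, cv_percent = cv,
             min = min(values), max = max(values), n = n)
}

#' Least-squares trend of SER against storage age
#'
#' Ordinary least squares of SER on storage day, with a 95% confidence
#' interval for the slope from the t distribution on n-2 degrees of
#' freedom.
#'
#' @param records data.frame with columns `day` and `ser` (>= 3 rows
#'   spanning >= 2 distinct days).
#' @return List with `slope`, `intercept`, `slope_ci` (length-2 vector),
#'   `slope_se` and the underlying `lm` fit.
#' @export
storage_trend <- function(records) {
  stopifnot(is.data.frame(records), all(c("day", "ser") %in% names(records)))
  if (nrow(records) < 3)
    stop("at least 3 records are required", call. = FALSE)
  if (length(unique(records$day)) < 2)
    stop("no design spread: all storage days identical", call. = FALSE)
  fit <- lm(ser ~ day, data = records)
  cf <- coef(fit)
  # a perfect fit makes summary.lm warn about unreliable SEs; the zero SE
  # (and zero-width CI) is the correct answer here
  ci <- suppressWarnings(confint(fit, "day", level = 0.95))
  se <- suppressWarnings(summary(fit))$coefficients["day", "Std. Error"]
  list(slope = unname(cf[["day"]]), intercept = unname(cf[["(Intercept)"]]),
       slope_ci = as.numeric(ci), slope_se = se, fit = fit)
}

#' Geometric summary of a particle-diameter sample
#'
#' Geometric mean `exp(mean(log(d)))` and geometric standard deviation
#' `exp(sd(log(d)))` (n-1 denominator), the standard summary for lognormal
#' particle-size distributions, plus the sample extremes.
#'
#' @param diameters Numeric vector of diameters, all > 0; n >= 2 for the GSD.
#' @return List with `gm`, `gsd`, `min`, `max`, `n`.
#' @examples
#' geometric_summary(c(1, 4))  # gm 2
#' @export
geometric_summary <- function(diameters) {
  if (any(!is.finite(diameters)) || any(diameters <= 0))
    stop("all diameters must be positive", call. = FALSE)
  n <- length(diameters)
  lg <- log(diameters)
  list(gm = exp(mean(lg)),
       gsd = if (n >= 2) exp(sd(lg)) else NA_real_,
       min = min(diameters), max = max(diameters), n = n)
}

#' Feret (caliper) diameter of a 2-D outline
#'
#' For a fixed direction, the width of the point set projected onto that
#' direction (distance between the two parallel tangent lines perpendicular
#' to it). For `direction = "max"` the maximum caliper width over all
#' directions, which equals the maximum pairwise distance between convex
#' hull vertices.
#'
#' @param outline Two-column matrix (or data.frame) of x,y points, >= 2 rows.
#' @param direction Angle in degrees, or `"max"`.
#' @return Length in the units of the coordinates.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' feret_diameter(sq, "max")      # sqrt(2)
#' feret_diameter(sq, 0)          # 1
#' @export
feret_diameter <- function(outline, direction = "max") {
  pts <- as.matrix(outline)
  if (nrow(pts) < 2 || ncol(pts) != 2)
    stop("outline must contain at least 2 points with x,y columns",
         call. = FALSE)
  storage.mode(pts) <- "double"
  if (identical(direction, "max")) {
    hp <- if (nrow(pts) > 3) {
      pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
    } else pts
    return(max(stats::dist(hp)))
  }
  theta <- direction * pi / 180
  proj <- pts[, 1] * cos(theta) + pts[, 2] * sin(theta)
  max(proj) - min(proj)
}
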