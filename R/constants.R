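#' Physical and regulatory constants for the supported analytes
#'
#' Molar masses come from the molecular formulas (diacetyl C4H6O2,
#' 2,3-pentanedione C5H8O2). The NIOSH recommended exposure limit (REL,
#' full-shift TWA) and short-term exposure limit (STEL, 15 min) for diacetyl
#' are 5.0 and 25 ppb; no limits are carried for 2,3-pentanedione.
#'
#' @param analyte `"diacetyl"` or `"2,3-pentanedione"`.
#' @return A list with elements `analyte`, `molar_mass` (g/mol), `rel_ppb`
#'   and `stel_ppb` (NA when not defined).
#' @examples
#' analyte_constants("diacetyl")$molar_mass
#' @export
analyte_constants <- function(analyte = c("diacetyl", "2,3-pentanedione")) {
  analyte <- match.arg(analyte)
  switch(analyte,
    "diacetyl" = list(analyte = "diacetyl", molar_mass = 86.09,
                      rel_ppb = 5.0, stel_ppb = 25),
    "2,3-pentanedione" = list(analyte = "2,3-pentanedione",
                              molar_mass = 100.12,
                              rel_ppb = NA_real_, stel_ppb = NA_real_))
}

# Molar volume of an ideal gas at 25 degC, 1 atm (L/mol); the convention used
# for all mg/m3 <-> ppb conversions in this package.
MOLAR_VOLUME_L <- 24.45

#' Default near-field geometry
#'
#' A hemispherical near field around the worker/source. The free-slip
#' boundary area of a hemisphere of radius r is `2*pi*r^2` and its volume is
#' `2/3*pi*r^3`. The default radius of 0.75 m gives a free-slip area of
#' about 3.53 m2, which reproduces the inter-zone flows implied by the
#' reference air speeds (beta = s/2 * A_FS: 1.0 -> 1.77, 3.0 -> 5.3,
#' 6.0 -> 10.6, 24 -> 42.4 m3/min).
#'
#' @param radius Hemisphere radius in m.
#' @return A list of class `near_field_geometry` with elements `shape`,
#'   `radius` (m), `free_slip_area` (m2) and `nf_volume` (m3).
#' @examples
#' near_field_geometry()$free_slip_area  # ~3.53 m2
#' @export
near_field_geometry <- function(radius = 0.75) {
  stopifnot(is.numeric(radius), length(radius) == 1, radius > 0)
  structure(
    list(shape = "hemisphere", radius = radius,
         free_slip_area = 2 * pi * radius^2,
         nf_volume = 2 / 3 * pi * radius^3),
    class = "near_field_geometry")
}

#' @export
print.near_field_geometry <- function(x, ...) {
  cat(sprintf("Hemispherical near field: radius %.3g m, A_FS %.3f m2, V_N %.4f m3\n",
              x$radius, x$free_slip_area, x$nf_volume))
  invisible(x)
}

# Internal: run an expression with a local, restored RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
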