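# Anatomical leaf hydraulic conductance.
#
# Vessels are treated as ideal capillaries: the volumetric conductivity of
# one vessel is pi r^4 / (8 eta l) (Hagen-Poiseuille). The published form
# of the single-vessel equation omits the conduit length; a conductivity
# requires one, so the petiole length l (default 0.02 m, configurable)
# enters here explicitly. Absolute magnitudes therefore depend on that
# choice; relative comparisons across treatments do not. Leaf-level
# conductance is the vessel sum scaled by the counted-to-total ratio and
# leaf area, converted from volumetric SI units to mmol m-2 s-1 MPa-1 via
# the molar volume of water (1.8e-5 m3 mol-1), 1e3 mmol/mol and 1e6
# Pa/MPa.

# mmol m-2 s-1 MPa-1 per (m3 s-1 Pa-1 m-2)
.KMAX_UNIT <- 1e3 * 1e6 / 1.8e-5

#' Dynamic viscosity of water
#'
#' Vogel correlation eta = 2.414e-5 * 10^(247.8 / (T - 140)) Pa s with T
#' in kelvin; accurate to well under 1% over 0-60 deg C (1.002e-3 at
#' 20 deg C, 0.891e-3 at 25 deg C).
#'
#' @param temp_c Temperature in degrees Celsius.
#' @return Viscosity in Pa s.
#' @export
water_viscosity <- function(temp_c = 25) {
  2.414e-5 * 10^(247.8 / (temp_c + 273.15 - 140))
}

#' Equivalent circular radius of a vessel cross-section
#'
#' Vessels are irregular; their lumen area is converted to the radius of
#' the circle with the same area.
#'
#' @param area Cross-section area (any squared length unit).
#' @return Radius in the matching length unit, vectorized.
#' @export
equivalent_radius <- function(area) {
  if (any(area <= 0)) stop("vessel area must be positive")
  sqrt(area / pi)
}

#' Volumetric conductivity of a single vessel
#'
#' pi r^4 / (8 eta l): volumetric flow per unit pressure drop along a
#' capillary of radius r and length l.
#'
#' @param radius Vessel radius, m.
#' @param viscosity Water viscosity, Pa s.
#' @param petiole_length Conduit length, m.
#' @return Conductivity in m3 s-1 Pa-1, vectorized over `radius`.
#' @export
single_vessel_conductivity <- function(radius, viscosity = water_viscosity(25),
                                       petiole_length = 0.02) {
  if (viscosity <= 0) stop("viscosity must be positive")
  if (petiole_length <= 0) stop("petiole_length must be positive")
  if (any(radius < 0)) stop("radius must be >= 0")
  pi * radius^4 / (8 * viscosity * petiole_length)
}

#' Petiole vessel anatomy record
#'
#' @param vessel_areas Cross-section areas of the sized vessels, um^2.
#' @param n_total Total vessel count in the petiole (>= number sized).
#' @param leaf_area Supported leaf area, m^2.
#' @param petiole_length Petiole length, m.
#' @param water_temperature Water temperature, deg C.
#' @return A validated list of class `vessel_anatomy`.
#' @export
vessel_anatomy <- function(vessel_areas, n_total, leaf_area = 0.003,
                           petiole_length = 0.02, water_temperature = 25) {
  if (length(vessel_areas) == 0L) stop("no vessels supplied")
  if (any(vessel_areas <= 0)) stop("vessel areas must be positive")
  n_counted <- length(vessel_areas)
  if (n_counted > n_total) stop("counted vessels exceed total count")
  if (leaf_area <= 0 || petiole_length <= 0)
    stop("leaf_area and petiole_length must be positive")
  structure(list(vessel_areas = as.numeric(vessel_areas),
                 n_counted = n_counted, n_total = as.integer(n_total),
                 leaf_area = leaf_area, petiole_length = petiole_length,
                 water_temperature = water_temperature),
            class = "vessel_anatomy")
}

#' Maximum leaf hydraulic conductance from vessel anatomy
#'
#' Sums single-vessel conductivities over the sized subset, scales by
#' N/n to estimate the whole-petiole sum, divides by leaf area and
#' converts to mmol m-2 s-1 MPa-1. Warns when fewer than two-thirds of
#' the vessels were sized (the protocol's sampling rule).
#'
#' @param anatomy A [vessel_anatomy()] record (areas in um^2).
#' @return Kmax in mmol m-2 s-1 MPa-1, with attribute `Ki` holding the
#'   per-vessel volumetric conductivities (m3 s-1 Pa-1).
#' @examples
#' an <- vessel_anatomy(rep(pi * 6^2, 50), n_total = 50)
#' leaf_kmax(an)
#' @export
leaf_kmax <- function(anatomy) {
  stopifnot(inherits(anatomy, "vessel_anatomy"))
  if (anatomy$n_counted < ceiling(2 * anatomy$n_total / 3))
    warning("fewer than two-thirds of vessels sized; Kmax estimate is noisy")
  r_m <- equivalent_radius(anatomy$vessel_areas) * 1e-6
  ki <- single_vessel_conductivity(r_m, water_viscosity(anatomy$water_temperature),
                                   anatomy$petiole_length)
  k_si <- (anatomy$n_total / (anatomy$n_counted * anatomy$leaf_area)) * sum(ki)
  out <- k_si * .KMAX_UNIT
  attr(out, "Ki") <- ki
  out
}

#' Relative water content
#'
#' (fresh - dry) / (saturated - dry). Values outside [dry, saturated] by
#' at most 1% of the water pool (balance noise) are clipped with a
#' warning; larger excursions are an error.
#'
#' @param fresh,saturated,dry Leaf weights, g.
#' @return Relative water content as a fraction, vectorized over `fresh`.
#' @export
relative_water_content <- function(fresh, saturated, dry) {
  if (saturated <= dry) stop("saturated weight must exceed dry weight")
  pool <- saturated - dry
  r <- (fresh - dry) / pool
  tol <- 0.01
  if (any(r < -tol | r > 1 + tol))
    stop("fresh weight outside the dry..saturated range by more than 1%")
  if (any(r < 0 | r > 1)) {
    warning("fresh weight slightly outside the dry..saturated range; clipped")
    r <- pmin(pmax(r, 0), 1)
  }
  r
}
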