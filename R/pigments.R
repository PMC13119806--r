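# Spectrophotometric pigment quantification.
#
# The experiment's pigment protocol reports absorbances of an 80% acetone
# extract at 445/645/663 nm (chlorophylls, carotenoids) and of an acidified
# methanol extract at 530/657 nm (anthocyanins). The exact coefficient set
# used by any given lab varies with solvent and instrument, so coefficients
# are configuration with documented defaults: Arnon-style chlorophyll
# equations for 80% acetone and a carotenoid equation adapted to 445 nm.
# Anthocyanins default to relative (delta-absorbance) units because molar
# extinction conventions differ between labs; a molar mode is available
# via `ant_scale`.

#' Default pigment coefficient set
#'
#' All concentration coefficients are mg L-1 per absorbance unit.
#' `chl_total`, `chl_a`, `chl_b` are linear forms over A645/A663;
#' `car` encodes (scale * A445 - k_chla * Chla - k_chlb * Chlb) / denom;
#' `ant_subtraction` is the A657 pheophytin correction coefficient and
#' `ant_scale` converts the corrected delta-absorbance to content units
#' (1 = relative delta-A units).
#'
#' @return A named list of class `pigment_coefficients`.
#' @export
default_pigment_coefficients <- function() {
  structure(list(
    chl_total = c(A645 = 20.2, A663 = 8.02),
    chl_a = c(A663 = 12.7, A645 = -2.69),
    chl_b = c(A645 = 22.9, A663 = -4.68),
    car = list(scale = 1000, k_chla = 3.27, k_chlb = 104, denom = 229),
    ant_subtraction = 0.25,
    ant_scale = 1
  ), class = "pigment_coefficients")
}

#' Absorbance record for one replicate's pigment extracts
#'
#' @param A445,A645,A663 Chlorophyll/carotenoid extract absorbances.
#' @param A530,A657 Anthocyanin extract absorbances.
#' @param mass,volume,dilution Chl/Car extraction: fresh mass (g), extract
#'   volume (L), dilution factor.
#' @param ant_mass,ant_volume,ant_dilution Anthocyanin extraction
#'   (protocol: 1 g, 0.01 L, five-fold dilution).
#' @return A validated list of class `absorbance_set`.
#' @export
absorbance_set <- function(A445 = 0, A645 = 0, A663 = 0, A530 = 0, A657 = 0,
                           mass = 0.2, volume = 0.005, dilution = 1,
                           ant_mass = 1, ant_volume = 0.01, ant_dilution = 5) {
  vals <- c(A445, A645, A663, A530, A657)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("absorbances must be finite and >= 0")
  if (mass <= 0 || volume <= 0 || dilution <= 0 ||
      ant_mass <= 0 || ant_volume <= 0 || ant_dilution <= 0)
    stop("extraction mass, volume and dilution must be positive")
  structure(list(A445 = A445, A645 = A645, A663 = A663, A530 = A530,
                 A657 = A657, mass = mass, volume = volume,
                 dilution = dilution, ant_mass = ant_mass,
                 ant_volume = ant_volume, ant_dilution = ant_dilution),
            class = "absorbance_set")
}

# concentration (mg L-1) -> content per g fresh weight
.per_fw <- function(conc, volume, dilution, mass) conc * volume * dilution / mass

#' Total chlorophyll content per fresh weight
#'
#' Cuvette concentration from the configured linear form over A645 and
#' A663 (default 20.2 * A645 + 8.02 * A663 mg L-1), scaled by extract
#' volume and dilution and divided by extracted fresh mass.
#'
#' @param abs An [absorbance_set()].
#' @param coeffs Coefficient set (default [default_pigment_coefficients()]).
#' @return Chlorophyll content, mg g-1 FW.
#' @examples
#' a <- absorbance_set(A645 = 0.2, A663 = 0.5)
#' chlorophyll_content(a)  # 0.201 mg g-1
#' @export
chlorophyll_content <- function(abs, coeffs = default_pigment_coefficients()) {
  ct <- coeffs$chl_total
  conc <- ct[["A645"]] * abs$A645 + ct[["A663"]] * abs$A663
  .per_fw(conc, abs$volume, abs$dilution, abs$mass)
}

#' Carotenoid content per fresh weight
#'
#' Chlorophyll a and b concentrations are computed from the configured
#' two-band forms, then removed from the 445 nm signal:
#' (scale * A445 - k_chla * Chla - k_chlb * Chlb) / denom, in mg L-1,
#' scaled to content per g fresh weight.
#'
#' @inheritParams chlorophyll_content
#' @return Carotenoid content, mg g-1 FW (floored at 0).
#' @export
carotenoid_content <- function(abs, coeffs = default_pigment_coefficients()) {
  ca <- coeffs$chl_a; cb <- coeffs$chl_b; cr <- coeffs$car
  chla <- ca[["A663"]] * abs$A663 + ca[["A645"]] * abs$A645
  chlb <- cb[["A645"]] * abs$A645 + cb[["A663"]] * abs$A663
  conc <- (cr$scale * abs$A445 - cr$k_chla * chla - cr$k_chlb * chlb) / cr$denom
  .per_fw(max(conc, 0), abs$volume, abs$dilution, abs$mass)
}

#' Anthocyanin content per fresh weight
#'
#' The pheophytin-corrected absorbance dA = A530 - c * A657 (floored at
#' zero; flooring is flagged via the `"floored"` attribute) is scaled by
#' `ant_scale` and the anthocyanin extraction's volume, dilution and mass.
#' With the default `ant_scale = 1` the result is in relative
#' delta-absorbance units per g FW.
#'
#' @inheritParams chlorophyll_content
#' @return Anthocyanin content per g FW, with attribute `floored`.
#' @examples
#' a <- absorbance_set(A530 = 0.30, A657 = 0.08)
#' anthocyanin_content(a)  # 0.014 units g-1
#' @export
anthocyanin_content <- function(abs, coeffs = default_pigment_coefficients()) {
  dA <- abs$A530 - coeffs$ant_subtraction * abs$A657
  floored <- dA < 0
  dA <- max(dA, 0)
  out <- coeffs$ant_scale *
    .per_fw(dA, abs$ant_volume, abs$ant_dilution, abs$ant_mass)
  attr(out, "floored") <- floored
  out
}

#' Pigment ratios
#'
#' @param chl,car,ant Pigment contents (same fresh-weight basis).
#' @return Data frame with `AntChl`, `CarChl`, `AntCar`; ratios with a
#'   non-positive denominator are `NA` (undefined), not an error.
#' @export
pigment_ratios <- function(chl, car, ant) {
  safe <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  data.frame(AntChl = safe(ant, chl), CarChl = safe(car, chl),
             AntCar = safe(ant, car))
}

#' Full pigment profile from one absorbance set
#'
#' @inheritParams chlorophyll_content
#' @return One-row data frame: `Chl`, `Car`, `Ant` and the three ratios.
#' @export
pigment_profile <- function(abs, coeffs = default_pigment_coefficients()) {
  chl <- chlorophyll_content(abs, coeffs)
  car <- carotenoid_content(abs, coeffs)
  ant <- as.numeric(anthocyanin_content(abs, coeffs))
  cbind(data.frame(Chl = chl, Car = car, Ant = ant),
        pigment_ratios(chl, car, ant))
}
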