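#' Oxygen solubility in fresh water
#'
#' Equilibrium (100% air saturation) dissolved-oxygen concentration of fresh
#' water at one atmosphere, from the Benson-Krause temperature polynomial used
#' by standard water-quality references (salinity 0, constant barometric
#' pressure).
#'
#' @param temp_c Water temperature in degrees Celsius, between 0 and 40.
#'
#' @return Solubility in mg O2 per litre.
#' @export
#' @examples
#' o2_solubility(21.5)
o2_solubility <- function(temp_c) {
  check_temp_range(temp_c)
  tk <- temp_c + 273.15
  exp(-139.34411 +
        1.575701e5 / tk -
        6.642308e7 / tk^2 +
        1.2438e10 / tk^3 -
        8.621949e11 / tk^4)
}

#' Convert between oxygen saturation and concentration
#'
#' `sat_to_concentration()` maps percent air saturation to mg O2 per litre at
#' the given water temperature; `concentration_to_sat()` is its inverse. The
#' two are mutually consistent to better than 1e-9.
#'
#' @param sat_pct Percent air saturation (100 = equilibrium with air).
#' @param o2_mg_per_l Dissolved oxygen concentration, mg O2 per litre.
#' @param temp_c Water temperature in degrees Celsius, between 0 and 40.
#'
#' @return A numeric vector (concentration in mg per litre, or percent
#'   saturation).
#' @export
#' @examples
#' sat_to_concentration(80, 21.5)
#' concentration_to_sat(sat_to_concentration(80, 21.5), 21.5)
sat_to_concentration <- function(sat_pct, temp_c) {
  sat_pct / 100 * o2_solubility(temp_c)
}

#' @rdname sat_to_concentration
#' @export
concentration_to_sat <- function(o2_mg_per_l, temp_c) {
  o2_mg_per_l / o2_solubility(temp_c) * 100
}

check_temp_range <- function(temp_c) {
  if (any(!is.finite(temp_c)) || any(temp_c < 0) || any(temp_c > 40)) {
    abort("`temp_c` must be finite and within 0-40 degrees C.")
  }
  invisible(temp_c)
}
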