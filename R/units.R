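# Unit conventions used throughout the package:
#   concentrations  ng/L (water, porewater, air), ng/g (sediment sorbed)
#   masses          ng
#   time            d
#   velocities      cm/d, areas cm^2, particle radii cm
# Every velocity*area product (cm^3/d) is converted to L/d here, and every
# Kd (L/kg) to L/g, so that each ODE term is ng/d. All conversions live in
# this file so the whole system can be audited in one place.

#' Convert a volume in cubic centimetres to litres
#' @param cm3 volume, cm^3
#' @return volume, L
#' @keywords internal
cm3_to_l <- function(cm3) cm3 / 1000

#' Volumetric exchange rate from a mass-transfer velocity and an area
#'
#' @param v_cm_d mass-transfer velocity, cm/d
#' @param a_cm2 interfacial area, cm^2
#' @return exchange rate, L/d (multiply by a concentration in ng/L for ng/d)
#' @keywords internal
exchange_l_per_d <- function(v_cm_d, a_cm2) cm3_to_l(v_cm_d * a_cm2)

#' Convert a sediment-water distribution coefficient from L/kg to L/g
#' @param kd_l_kg distribution coefficient, L/kg
#' @return distribution coefficient, L/g
#' @keywords internal
kd_l_per_g <- function(kd_l_kg) kd_l_kg / 1000

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_num <- function(x, name, lower = -Inf, upper = Inf,
                      allow_zero_lower = TRUE) {
  stop_if(!is.numeric(x) || anyNA(x), sprintf("'%s' must be numeric and non-missing", name))
  lo_ok <- if (allow_zero_lower) all(x >= lower) else all(x > lower)
  stop_if(!lo_ok || !all(x <= upper),
          sprintf("'%s' out of range [%s, %s]", name, lower, upper))
  invisible(x)
}
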