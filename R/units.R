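#' Unit conversions between laboratory and SI units
#'
#' Pressures are logged in mBar, temperatures set in degrees Celsius and
#' volumes pipetted in ml; the model works in Pa, K and m3. These helpers
#' are exact (1 mBar = 100 Pa, 0 degC = 273.15 K, 1 ml = 1e-6 m3).
#'
#' @param p_mbar,p_pa Pressure in mBar / Pa.
#' @param t_celsius,t_kelvin Temperature in degrees Celsius / K.
#' @param v_ml,v_m3 Volume in ml / m3.
#' @return Numeric vector in the target unit.
#' @name units
#' @examples
#' mbar_to_pa(600)          # 60000 Pa
#' celsius_to_kelvin(65)    # 338.15 K
NULL

#' @rdname units
#' @export
mbar_to_pa <- function(p_mbar) p_mbar * 100

#' @rdname units
#' @export
pa_to_mbar <- function(p_pa) p_pa / 100

#' @rdname units
#' @export
celsius_to_kelvin <- function(t_celsius) t_celsius + 273.15

#' @rdname units
#' @export
kelvin_to_celsius <- function(t_kelvin) t_kelvin - 273.15

#' @rdname units
#' @export
ml_to_m3 <- function(v_ml) v_ml * 1e-6

#' @rdname units
#' @export
m3_to_ml <- function(v_m3) v_m3 * 1e6
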