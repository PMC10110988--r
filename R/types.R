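## Domain types. Lightweight validated S3 lists, in the style of the
## constructor-plus-validator pattern used across scientific R packages.

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Reactor geometry
#'
#' @param total_volume Total reactor volume, m3.
#' @param liquid_volume Water-phase volume, m3 (must be < total).
#' @param gas_liquid_contact_area Gas-water interfacial area, m2.
#' @return An object of class `reactor_geometry` with the derived
#'   `gas_volume` field.
#' @export
#' @examples
#' # the 132.5 ml bottle reactor with 47 ml of medium
#' reactor_geometry(ml_to_m3(132.5), ml_to_m3(47), 1963.4e-6)
reactor_geometry <- function(total_volume, liquid_volume,
                             gas_liquid_contact_area) {
  stop_if(!is.numeric(total_volume) || total_volume <= 0,
          "total_volume must be > 0")
  stop_if(liquid_volume <= 0 || liquid_volume >= total_volume,
          "liquid_volume must satisfy 0 < liquid_volume < total_volume")
  stop_if(gas_liquid_contact_area <= 0, "contact area must be > 0")
  structure(
    list(total_volume = total_volume,
         liquid_volume = liquid_volume,
         gas_volume = total_volume - liquid_volume,
         gas_liquid_contact_area = gas_liquid_contact_area),
    class = "reactor_geometry")
}

#' Lag-phase parameters
#'
#' The lag phase is modelled as a piecewise linear ramp: no growth before
#' `t_L`, full exponential growth after `t_E`, linear in between. The
#' degenerate case `t_L == t_E` is a step.
#'
#' @param t_L End of the no-growth lag, s.
#' @param t_E Onset of full exponential growth, s (>= `t_L`).
#' @return An object of class `lag_phase`.
#' @export
lag_phase <- function(t_L = 0, t_E = 0) {
  stop_if(t_L < 0 || t_E < t_L, "need 0 <= t_L <= t_E")
  structure(list(t_L = t_L, t_E = t_E), class = "lag_phase")
}

#' Growth kinetics of one archaeal strain
#'
#' @param mu_max Maximum specific growth rate, 1/s.
#' @param K_H2,K_CO2 Half-saturation constants of the dissolved substrates,
#'   mol/m3.
#' @param decay_b Decay/maintenance coefficient, 1/s.
#' @param yield_Y_H2 Yield coefficient: cells produced per mole of H2
#'   consumed, cells/mol. Applied with the stoichiometric vector to all
#'   components.
#' @param lag A [lag_phase()].
#' @return An object of class `species_kinetics`.
#' @export
#' @examples
#' species_kinetics(1.7e-4, 0.02, 0.011, 3e-7, 4.1e12, lag_phase(10800, 21600))
species_kinetics <- function(mu_max, K_H2 = 0.02, K_CO2 = 0.011,
                             decay_b = 0, yield_Y_H2, lag = lag_phase()) {
  for (v in c(mu_max, K_H2, K_CO2, decay_b))
    stop_if(!is.numeric(v) || v < 0, "rates and constants must be >= 0")
  stop_if(yield_Y_H2 <= 0, "yield_Y_H2 must be > 0")
  stop_if(!inherits(lag, "lag_phase"), "lag must be a lag_phase()")
  structure(
    list(mu_max = mu_max, K_H2 = K_H2, K_CO2 = K_CO2, decay_b = decay_b,
         yield_Y_H2 = yield_Y_H2, lag = lag),
    class = "species_kinetics")
}

#' Henry solubility entry for one component
#'
#' Henry's law solubility `H = C_liq / p_partial` at a reference
#' temperature, with the van't Hoff constant (-Delta_sol H / R, in K) for
#' temperature correction via [henry_at_temperature()].
#'
#' @param component One of `"H2"`, `"CO2"`, `"CH4"`, `"N2"`.
#' @param H_ref Solubility at `T_ref`, mol/(m3 Pa).
#' @param T_ref Reference temperature, K.
#' @param vant_hoff_C Temperature-dependence constant, K. 0 disables the
#'   correction.
#' @return An object of class `henry_entry`.
#' @export
henry_entry <- function(component, H_ref, T_ref, vant_hoff_C = 0) {
  component <- match.arg(component, COMPONENTS)
  stop_if(H_ref <= 0, "H_ref must be > 0")
  stop_if(T_ref <= 0, "T_ref must be > 0")
  structure(
    list(component = component, H_ref = H_ref, T_ref = T_ref,
         vant_hoff_C = vant_hoff_C),
    class = "henry_entry")
}

#' Gas-water mass-transfer parameters
#'
#' Two-film transfer flux `J = k_gw * (C_eq - C_liq) / C_ref` (mol/s,
#' positive into the liquid). The driving force is normalized by the
#' reference concentration `C_ref = 1 mol/m3` so that `k_gw` carries units
#' of mol/s, matching the magnitudes this coefficient is reported in.
#'
#' @param k_gw Mass-transfer coefficient, mol/s (same for all components).
#' @param C_ref Normalizing concentration, mol/m3 (fixed default 1).
#' @return An object of class `mass_transfer`.
#' @export
mass_transfer <- function(k_gw, C_ref = 1) {
  stop_if(k_gw < 0, "k_gw must be >= 0")
  stop_if(C_ref <= 0, "C_ref must be > 0")
  structure(list(k_gw = k_gw, C_ref = C_ref), class = "mass_transfer")
}

#' Reactor state vector
#'
#' Builds the named ODE state vector: moles of each component in the gas
#' phase (`Ng_*`), in the liquid phase (`Nl_*`), and the total cell number
#' `X`. Component order is H2, CO2, CH4, N2.
#'
#' @param N_gas Named (or length-4) numeric vector of gas-phase moles.
#'   Missing components default to 0.
#' @param N_liq Same for the liquid phase.
#' @param X Total cells in the water phase.
#' @return Named numeric vector of length 9.
#' @export
reactor_state <- function(N_gas = c(H2 = 0, CO2 = 0, CH4 = 0, N2 = 0),
                          N_liq = c(H2 = 0, CO2 = 0, CH4 = 0, N2 = 0),
                          X = 0) {
  fill <- function(v) {
    out <- setNames(numeric(4), COMPONENTS)
    if (is.null(names(v))) {
      out[seq_along(v)] <- v
    } else {
      stop_if(!all(names(v) %in% COMPONENTS), "unknown component name")
      out[names(v)] <- v
    }
    out
  }
  Ng <- fill(N_gas); Nl <- fill(N_liq)
  stop_if(any(Ng < 0) || any(Nl < 0) || X < 0,
          "moles and cell number must be >= 0")
  c(setNames(Ng, paste0("Ng_", COMPONENTS)),
    setNames(Nl, paste0("Nl_", COMPONENTS)),
    X = X)
}

## Split a state vector back into its parts.
state_parts <- function(state) {
  list(N_gas = setNames(state[paste0("Ng_", COMPONENTS)], COMPONENTS),
       N_liq = setNames(state[paste0("Nl_", COMPONENTS)], COMPONENTS),
       X = unname(state[["X"]]))
}

#' @export
print.reactor_geometry <- function(x, ...) {
  cat(sprintf(
    "<reactor_geometry> total %.4g ml, liquid %.4g ml, gas %.4g ml, area %.4g mm2\n",
    m3_to_ml(x$total_volume), m3_to_ml(x$liquid_volume),
    m3_to_ml(x$gas_volume), x$gas_liquid_contact_area * 1e6))
  invisible(x)
}

#' @export
print.species_kinetics <- function(x, ...) {
  cat(sprintf(
    "<species_kinetics> mu_max %.3g 1/s, K_H2 %.3g, K_CO2 %.3g mol/m3, b %.3g 1/s, Y_H2 %.3g cells/mol, lag [%.5g, %.5g] s\n",
    x$mu_max, x$K_H2, x$K_CO2, x$decay_b, x$yield_Y_H2,
    x$lag$t_L, x$lag$t_E))
  invisible(x)
}
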