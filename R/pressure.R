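#' Partial pressure of a component
#'
#' Mole-fraction weighting of the total pressure:
#' `p_n = N_n / N_total * P_total`. Partial pressures over all components
#' sum to the total pressure.
#'
#' @param N_comp Moles of the component in the gas phase.
#' @param N_total_gas Total gas-phase moles (> 0).
#' @param P_total Total pressure, Pa.
#' @return Partial pressure, Pa.
#' @export
partial_pressure <- function(N_comp, N_total_gas, P_total) {
  stop_if(any(N_total_gas <= 0), "total gas moles must be > 0")
  stop_if(any(N_comp < 0) || any(N_comp > N_total_gas),
          "need 0 <= N_comp <= N_total_gas")
  N_comp / N_total_gas * P_total
}

#' Total gas-phase pressure (ideal gas closure)
#'
#' `P = N R T / V_gas` with R = 8.314 J/(mol K). This is the model's link
#' from simulated gas-phase moles to the recorded pressure trace.
#'
#' @param N_total_gas Total gas-phase moles.
#' @param T Temperature, K (> 0).
#' @param V_gas Gas headspace volume, m3 (> 0).
#' @return Pressure, Pa.
#' @export
#' @examples
#' total_pressure(3.0815e-3, 338.15, 8.55e-5)  # ~ 1 atm
total_pressure <- function(N_total_gas, T, V_gas) {
  stop_if(any(T <= 0), "temperature must be > 0")
  stop_if(any(V_gas <= 0), "gas volume must be > 0")
  N_total_gas * R_GAS * T / V_gas
}

#' Two-film gas-water transfer flux
#'
#' `J = k_gw * (C_eq - C_liq) / C_ref`, positive from gas into liquid. The
#' flux vanishes at Henry equilibrium and its sign always drives the
#' dissolved concentration toward the equilibrium value; the gas phase
#' receives `-J` so moles are conserved across the interface.
#'
#' @param C_liq Current dissolved concentration, mol/m3.
#' @param C_eq Equilibrium concentration from
#'   [equilibrium_liquid_concentration()], mol/m3.
#' @param mt A [mass_transfer()].
#' @return Flux, mol/s (positive = dissolution, negative = degassing).
#' @export
transfer_flux <- function(C_liq, C_eq, mt) {
  stopifnot(inherits(mt, "mass_transfer"))
  mt$k_gw * (C_eq - C_liq) / mt$C_ref
}
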