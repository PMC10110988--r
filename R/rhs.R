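## Right-hand side of the coupled ODE system.
##
## State (length 9): Ng_H2, Ng_CO2, Ng_CH4, Ng_N2, Nl_H2, Nl_CO2, Nl_CH4,
## Nl_N2, X. Two implementations exist: this readable R version (reference,
## exported) and a C translation under src/ that deSolve calls during
## integration; the test suite asserts their pointwise agreement.

## Pack the model parameters into the flat numeric vector the C derivative
## function expects. lag_origin shifts the lag clock (refill cycles restart
## it); t_L/t_E are relative to lag_origin.
pack_parms <- function(geometry, temperature, kinetics, mt, henry,
                       n2_transfer = FALSE, lag_origin = 0) {
  c(V_gas = geometry$gas_volume,
    V_liq = geometry$liquid_volume,
    Temp = temperature,
    k_gw = mt$k_gw,
    C_ref = mt$C_ref,
    mu_max = kinetics$mu_max,
    K_H2 = kinetics$K_H2,
    K_CO2 = kinetics$K_CO2,
    decay_b = kinetics$decay_b,
    Y_H2 = kinetics$yield_Y_H2,
    t_L = kinetics$lag$t_L,
    t_E = kinetics$lag$t_E,
    H_H2 = henry[["H2"]],
    H_CO2 = henry[["CO2"]],
    H_CH4 = henry[["CH4"]],
    H_N2 = henry[["N2"]],
    n2_transfer = as.numeric(n2_transfer),
    lag_origin = lag_origin)
}

#' Time derivatives of the coupled reactor model
#'
#' Reference R implementation of the full right-hand side: two-film
#' transfer moves each component between gas and liquid toward its Henry
#' equilibrium with the current partial pressure, methanation consumes
#' dissolved H2 and CO2 and produces CH4 in 4:1:1 stoichiometry scaled by
#' the yield coefficient, and the cell number follows lag-gated
#' growth-minus-decay. Inert N2 reacts never and transfers only if enabled.
#'
#' @param t Time, s.
#' @param state Named state vector from [reactor_state()] or
#'   [initialize_state()].
#' @param parms Parameter vector from the internal packer; built by
#'   [integrate_scenario()] from a scenario. Advanced use only.
#' @return List (deSolve convention) whose first element is the derivative
#'   vector in the state order.
#' @export
reactor_rhs <- function(t, state, parms) {
  p <- as.list(parms)
  Ng <- state[1:4]; Nl <- state[5:8]; X <- state[[9]]

  ## partial pressure p_n = Ng_n/Ng_tot * P_tot = Ng_n * R T / V_gas
  RTV <- R_GAS * p$Temp / p$V_gas
  H <- c(p$H_H2, p$H_CO2, p$H_CH4, p$H_N2)
  C_liq <- Nl / p$V_liq
  C_eq <- H * (Ng * RTV)
  J <- p$k_gw * (C_eq - C_liq) / p$C_ref
  if (p$n2_transfer < 0.5) J[4] <- 0

  tau <- t - p$lag_origin
  lag <- lag_phase(p$t_L, p$t_E)
  lam <- lag_factor(tau, lag)
  C_H2 <- max(C_liq[[1]], 0); C_CO2 <- max(C_liq[[2]], 0)
  mu <- p$mu_max * (C_H2 / (p$K_H2 + C_H2)) * (C_CO2 / (p$K_CO2 + C_CO2))

  growth_mol <- lam * mu * X / p$Y_H2          # mol H2-equivalents per s
  dNg <- -J
  dNl <- J + unname(ZETA) * growth_mol
  dX <- lam * X * (mu - p$decay_b)
  list(c(dNg, dNl, dX))
}
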