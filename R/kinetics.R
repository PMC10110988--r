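#' Lag-phase factor
#'
#' Piecewise-linear growth-activation factor: 0 before `t_L`, ramping
#' linearly to 1 at `t_E`, 1 afterwards. When `t_L == t_E` the ramp
#' degenerates to a step (0 strictly before `t_L`, 1 from `t_L` on).
#'
#' @param t Time since first substrate contact, s (vectorized).
#' @param lag A [lag_phase()].
#' @return Dimensionless factor in \[0, 1\].
#' @export
#' @examples
#' lag_factor(c(1e4, 703500, 2e6), lag_phase(57000, 1.35e6))
lag_factor <- function(t, lag) {
  stopifnot(inherits(lag, "lag_phase"))
  if (lag$t_E > lag$t_L) {
    pmin(pmax((t - lag$t_L) / (lag$t_E - lag$t_L), 0), 1)
  } else {
    as.numeric(t >= lag$t_L)
  }
}

#' Double-Monod specific growth rate
#'
#' `mu = mu_max * C_H2/(K_H2 + C_H2) * C_CO2/(K_CO2 + C_CO2)`, with both
#' dissolved substrates limiting. Negative concentrations (transient
#' integrator undershoot) are clamped to 0 inside the Monod factors.
#'
#' @param C_H2,C_CO2 Dissolved substrate concentrations, mol/m3.
#' @param kin A [species_kinetics()].
#' @return Growth rate in 1/s, bounded in \[0, mu_max\].
#' @export
specific_growth_rate <- function(C_H2, C_CO2, kin) {
  C_H2 <- pmax(C_H2, 0)
  C_CO2 <- pmax(C_CO2, 0)
  kin$mu_max * (C_H2 / (kin$K_H2 + C_H2)) * (C_CO2 / (kin$K_CO2 + C_CO2))
}

#' Biomass rate
#'
#' `dX/dt = lambda(t) * X * (mu - b)`: growth minus decay/maintenance, both
#' gated by the lag factor so the cell number stays constant during the lag
#' phase and declines once the substrates are depleted.
#'
#' @param X Total cells.
#' @param t Time, s.
#' @param C_H2,C_CO2 Dissolved substrate concentrations, mol/m3.
#' @param kin A [species_kinetics()].
#' @return Cell rate, cells/s.
#' @export
biomass_rate <- function(X, t, C_H2, C_CO2, kin) {
  lam <- lag_factor(t, kin$lag)
  mu <- specific_growth_rate(C_H2, C_CO2, kin)
  lam * X * (mu - kin$decay_b)
}

#' Component reaction rates in the liquid phase
#'
#' Methanation turnover expressed per component through the stoichiometric
#' vector and the hydrogen yield coefficient:
#' `rate_n = zeta_n * lambda * mu * X / Y_H2` (mol/s). Hydrogen is consumed
#' four times faster than CO2; CH4 appears at the CO2 rate.
#'
#' @param mu Specific growth rate, 1/s.
#' @param X Total cells.
#' @param lag_lambda Lag factor in \[0, 1\].
#' @param kin A [species_kinetics()].
#' @return Named vector of mol/s over (H2, CO2, CH4, N2).
#' @export
reaction_rates <- function(mu, X, lag_lambda, kin) {
  stop_if(kin$yield_Y_H2 <= 0, "yield_Y_H2 must be > 0")
  ZETA * (lag_lambda * mu * X / kin$yield_Y_H2)
}
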