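# Shared fixtures. Small, fast variants of the bottle-reactor setup for
# property tests; the full presets come from table1_scenarios().

bottle_geometry <- function() {
  reactor_geometry(total_volume = ml_to_m3(132.5),
                   liquid_volume = ml_to_m3(47),
                   gas_liquid_contact_area = 1963.4e-6)
}

# a fast-growing short scenario for property checks (~2e4 s)
quick_scenario <- function(X0 = 5e7, k_gw = 8e-2, duration = 2e4,
                           lag = lag_phase(0, 0), events = list()) {
  scenario(
    geometry = bottle_geometry(),
    temperature = celsius_to_kelvin(65),
    initial_pressure = mbar_to_pa(600),
    kinetics = species_kinetics(mu_max = 5e-4, K_H2 = 0.02, K_CO2 = 0.011,
                                decay_b = 3e-7, yield_Y_H2 = 4.1e12,
                                lag = lag),
    mass_transfer = mass_transfer(k_gw),
    henry_table = reference_henry_table(65),
    initial_cell_density = X0,
    events = events,
    duration = duration)
}

# random nonnegative state for rhs property checks
random_state <- function() {
  reactor_state(N_gas = runif(4, 0, 2e-3) * c(1, 1, 1, 0.1),
                N_liq = runif(4, 0, 5e-4) * c(1, 1, 1, 0),
                X = runif(1, 0, 1e10))
}

# closed-form Henry equilibrium for a transfer-only (abiotic) reactor:
# per component, conservation M = Ng + Nl with Cl = H * p and
# p = Ng R T / V_gas gives Cl = H R T M / (V_gas + H R T V_liq).
abiotic_equilibrium <- function(M, H, T, V_gas, V_liq) {
  HRT <- H * 8.314 * T
  C_l <- HRT * M / (V_gas + HRT * V_liq)
  N_l <- C_l * V_liq
  list(N_gas = M - N_l, N_liq = N_l, C_liq = C_l)
}

total_moles <- function(traj, comp) {
  traj[[paste0("Ng_", comp)]] + traj[[paste0("Nl_", comp)]]
}
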