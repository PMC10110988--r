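# Trajectory-level behavior: conservation laws, events, convergence.

test_that("biotic trajectories conserve carbon and obey 4:1:1 coupling", {
  scn <- quick_scenario()
  traj <- integrate_scenario(scn, output_times = seq(0, 2e4, 500))
  carbon <- total_moles(traj, "CO2") + total_moles(traj, "CH4")
  expect_equal(carbon, rep(carbon[1], length(carbon)),
               tolerance = 1e-6)
  dH2 <- total_moles(traj, "H2") - total_moles(traj, "H2")[1]
  dCO2 <- total_moles(traj, "CO2") - total_moles(traj, "CO2")[1]
  dCH4 <- total_moles(traj, "CH4") - total_moles(traj, "CH4")[1]
  sub <- abs(dH2) > 1e-8   # skip the pre-growth points (0/0)
  expect_equal(dH2[sub] / dCO2[sub], rep(4, sum(sub)), tolerance = 1e-6)
  expect_equal(dCH4[sub], -dCO2[sub], tolerance = 1e-6)
})

test_that("series-1.1 pressure falls sigmoidally until H2 runs out", {
  scn <- table1_scenarios()$series_1_1
  traj <- integrate_scenario(scn)
  d <- as.data.frame(traj)
  n <- nrow(d)
  # lag plateau: essentially no drop in the first two hours
  expect_gt(d$pressure_mbar[d$time_s == 7200], 599)
  # overall decline of several hundred mBar to a low plateau
  expect_lt(d$pressure_mbar[n], 250)
  expect_lt(abs(d$pressure_mbar[n] - d$pressure_mbar[n - 20]), 1)
  # hydrogen is the limiting substrate: < 1% of it remains, CO2 does not
  h2_left <- total_moles(d, "H2")[n] / total_moles(d, "H2")[1]
  co2_left <- total_moles(d, "CO2")[n] / total_moles(d, "CO2")[1]
  expect_lt(h2_left, 0.01)
  expect_gt(co2_left, 0.2)
  # cells grew by about Y * consumed H2
  dX <- d$cells_total[n] - d$cells_total[1]
  dH2 <- total_moles(d, "H2")[1] - total_moles(d, "H2")[n]
  expect_equal(dX / (scn$kinetics$yield_Y_H2 * dH2), 1, tolerance = 0.05)
})

test_that("refill adds exactly the ideal-gas mole deficit", {
  g <- bottle_geometry()
  state <- initialize_state(20000, c(H2 = 0.8, CO2 = 0.2), g, 338.15,
                            reference_henry_table(65), 1e7)
  out <- apply_refill(state, 1e5, c(H2 = 0.8, CO2 = 0.2), g, 338.15)
  dN <- sum(out[1:4]) - sum(state[1:4])
  expect_equal(dN, 2.4330e-3, tolerance = 1e-4)   # dP V / (R T)
  expect_equal(unname(out[1] - state[1]), dN * 0.8)
  expect_equal(total_pressure(sum(out[1:4]), 338.15, g$gas_volume), 1e5,
               tolerance = 1e-9)
  expect_equal(out[5:9], state[5:9])   # liquid and cells untouched
  # idempotent at the current pressure, error below it
  expect_equal(apply_refill(out, 1e5, c(H2 = 1), g, 338.15), out)
  expect_error(apply_refill(out, 5e4, c(H2 = 1), g, 338.15), "venting")
})

test_that("liquid sampling modes behave as documented", {
  g <- bottle_geometry()
  state <- initialize_state(60000, c(H2 = 0.8, CO2 = 0.2), g, 338.15,
                            reference_henry_table(65), 1e7)
  expect_equal(apply_liquid_sampling(state, 0, g, "proportional"), state)
  out <- apply_liquid_sampling(state, g$liquid_volume / 100, g,
                               "proportional")
  expect_equal(unname(out[5:9]), unname(state[5:9] * 0.99))
  expect_equal(out[1:4], state[1:4])
  # negligible mode ignores the volume entirely
  expect_equal(apply_liquid_sampling(state, ml_to_m3(5), g), state)
  expect_error(apply_liquid_sampling(state, g$liquid_volume, g),
               "volume")
})

test_that("refill events produce a sawtooth with restarted lag clocks", {
  ev <- lapply(c(6e3, 12e3), function(tt) {
    refill_event(tt, target_pressure = mbar_to_pa(600))
  })
  scn <- quick_scenario(X0 = 5e8, duration = 1.8e4, events = ev)
  traj <- integrate_scenario(scn, output_times = seq(0, 1.8e4, 200))
  d <- as.data.frame(traj)
  # pressure jumps upward right after each event time
  for (tt in c(6e3, 12e3)) {
    pre <- d$pressure_mbar[d$time_s == tt]
    post <- d$pressure_mbar[d$time_s == tt + 200]
    expect_gt(post, pre + 50)
  }
  # three local pressure maxima at/above ~600 less consumption
  expect_equal(max(d$pressure_mbar), 600, tolerance = 1e-6)
})

test_that("between-event pressure is nonincreasing once growth is active", {
  scn <- quick_scenario(X0 = 5e7, lag = lag_phase(0, 0))
  traj <- integrate_scenario(scn, output_times = seq(0, 2e4, 250))
  # nonincreasing up to the integrator's plateau wiggle (~1e-5 Pa)
  expect_true(all(diff(traj$pressure_Pa) <= 1e-3))
})

test_that("halving integrator tolerances barely moves the final state", {
  scn <- quick_scenario()
  t_out <- c(0, 2e4)
  a <- integrate_scenario(scn, output_times = t_out, rtol = 1e-8,
                          atol = 1e-12)
  b <- integrate_scenario(scn, output_times = t_out, rtol = 5e-9,
                          atol = 5e-13)
  fa <- as.data.frame(a)[2, ]; fb <- as.data.frame(b)[2, ]
  # pressure and cells relative; moles relative to the total gas charge
  # (depleted components sit at the atol floor, where a relative
  # comparison against ~0 is meaningless)
  expect_equal(fa$pressure_Pa, fb$pressure_Pa, tolerance = 1e-6)
  expect_equal(fa$cells_total, fb$cells_total, tolerance = 1e-6)
  mole_cols <- grep("^N[gl]_", names(fa), value = TRUE)
  N_scale <- sum(as.data.frame(a)[1, grep("^Ng_", names(fa))])
  expect_lt(max(abs(fa[mole_cols] - fb[mole_cols])), 1e-6 * N_scale)
})

test_that("integration failures carry a diagnostic condition class", {
  # an absurdly stiff, unresolvable setup: force maxsteps exhaustion by
  # requesting a huge transfer coefficient with loose step budget
  scn <- quick_scenario(k_gw = 1e12, duration = 1e6)
  expect_error(
    suppressWarnings(integrate_scenario(scn,
                                        output_times = c(0, 1e6),
                                        rtol = 1e-13, atol = 1e-18)),
    class = "mb_integration_error")
})
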