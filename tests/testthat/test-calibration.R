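# Initialization, lag heuristics, objective and the fitting machinery.
# Deep recovery checks live in test-acceptance.R; here the fast paths.

test_that("initial state follows ideal gas + Henry equilibrium", {
  g <- bottle_geometry()
  st <- initialize_state(60000, c(H2 = 0.8, CO2 = 0.2), g,
                         celsius_to_kelvin(65),
                         reference_henry_table(65), 1e7)
  # P V / (R T) split 80/20
  expect_equal(sum(st[1:4]), 1.8247e-3, tolerance = 1e-4)
  expect_equal(unname(st["Ng_H2"]), 1.4598e-3, tolerance = 1e-4)
  expect_equal(unname(st["Ng_CO2"]), 3.6494e-4, tolerance = 1e-4)
  # dissolved H2: 8.58e-6 * 48000 Pa * 47 ml
  expect_equal(unname(st["Nl_H2"]), 1.9356e-5, tolerance = 1e-4)
  # inoculum over 47 ml
  expect_equal(unname(st["X"]), 4.7e8)
  expect_equal(unname(st["Ng_N2"]), 0)
  # missing Henry entry for a present component errors
  expect_error(
    initialize_state(60000, c(H2 = 0.8, CO2 = 0.2), g, 338.15,
                     reference_henry_table(65)[1], 1e7),
    "Henry")
})

test_that("lag heuristic finds the drop onset and the half-drop time", {
  # flat at 600 mBar until 57000 s, then linear decline
  tt <- seq(0, 2e5, 600)
  P <- ifelse(tt <= 57000, 60000, 60000 - 0.3 * (tt - 57000))
  P <- pmax(P, 20000)
  obs <- observation_series(tt, P, pressure_sigma = 10)
  lag <- estimate_lag_times(obs)
  expect_equal(lag$t_L, 57000)
  # half drop: baseline 60000 to final 20000 -> 40000 Pa crossed at
  # 57000 + 20000/0.3
  expect_equal(lag$t_E, tt[which(P <= 40000)[1]])
  expect_gte(lag$t_E, lag$t_L)

  # strictly constant series: no growth detected
  flat <- observation_series(tt, rep(60000, length(tt)),
                             pressure_sigma = 10)
  expect_error(estimate_lag_times(flat), class = "mb_no_growth")
  # too few points
  short <- observation_series(1:5, rep(6e4, 5), pressure_sigma = 10)
  expect_error(estimate_lag_times(short), "10 pressure points")
})

test_that("objective is zero on self-generated data and discriminates", {
  scn <- quick_scenario()
  gen <- generate_observations(scn, sampling_interval = 500,
                               noise = noise_model(0, 0, seed = 1))
  obs <- gen$observations
  expect_equal(calibration_objective(scn, obs), 0)
  # +50% growth rate must be visible
  expect_gt(calibration_objective(
    scn, obs, params = c(mu_max = scn$kinetics$mu_max * 1.5)), 1)
  # broken parameters fall back to the penalty, not an error
  w <- capture_warnings(
    val <- calibration_objective(
      scn, obs, params = c(k_gw = 1e30), rtol = 1e-12))
  expect_true(any(grepl("integration failed", w)))
  expect_gte(val, 1e6)
})

test_that("empty free set returns the base case unchanged", {
  scn <- quick_scenario()
  gen <- generate_observations(scn, sampling_interval = 1000,
                               noise = noise_model(0, 0, seed = 2))
  spec <- calibration_spec(free = character(0))
  fit <- fit_scenario(scn, gen$observations, spec)
  expect_equal(fit$fitted, spec$start)
  expect_equal(fit$objective_value,
               calibration_objective(scn, gen$observations))
})

test_that("fitting is deterministic given the spec seed", {
  scn <- quick_scenario()
  gen <- generate_observations(scn, sampling_interval = 1000,
                               noise = noise_model(200, 0.2, seed = 3))
  spec <- calibration_spec(free = c("mu_max", "yield_Y_H2"),
                           start = c(mu_max = 3e-4, yield_Y_H2 = 3e12,
                                     k_gw = 8e-2,
                                     initial_cell_density = 5e7,
                                     decay_b = 3e-7),
                           multistart_count = 3, seed = 7)
  f1 <- fit_scenario(scn, gen$observations, spec)
  f2 <- fit_scenario(scn, gen$observations, spec)
  expect_identical(f1$fitted, f2$fitted)
  expect_identical(f1$starts, f2$starts)
  # and the global RNG stream is left untouched
  set.seed(1); before <- runif(1)
  fit_scenario(scn, gen$observations, spec)
  set.seed(1); expect_identical(runif(1), before)
})

test_that("calibration spec validates bounds and free names", {
  expect_error(calibration_spec(free = "not_a_param"), "free parameters")
  expect_error(calibration_spec(lower = c(mu_max = 1),
                                upper = c(mu_max = 0.1)), "lower")
  s <- calibration_spec(species = 2)
  expect_equal(unname(s$start["mu_max"]), 3e-5)
  expect_equal(unname(s$lower["mu_max"]), 3e-7)
  expect_equal(unname(s$upper["mu_max"]), 3e-3)
})
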