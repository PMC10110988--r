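# Synthetic observation generator: presets, determinism, noise structure.

test_that("scenario presets carry the experiment conditions", {
  sc <- table1_scenarios()
  expect_named(sc, c("series_1_1", "series_2_1", "series_3"))
  expect_equal(sc$series_1_1$initial_pressure, 60000)
  expect_equal(sc$series_1_1$temperature, 338.15)
  expect_equal(sc$series_1_1$kinetics$mu_max, 1.7e-4)
  expect_equal(sc$series_1_1$kinetics$yield_Y_H2, 4.1e12)
  expect_equal(sc$series_1_1$mass_transfer$k_gw, 8e-2)
  expect_equal(sc$series_1_1$initial_cell_density, 1.43e7)
  expect_equal(sc$series_2_1$initial_pressure, 55000)
  expect_equal(sc$series_2_1$temperature, 310.15)
  expect_equal(sc$series_2_1$kinetics$mu_max, 1e-5)
  expect_equal(sc$series_2_1$mass_transfer$k_gw, 9e-3)
  # the refill preset has five cycles -> four refill events back to P0
  expect_length(sc$series_3$events, 4)
  expect_true(all(vapply(sc$series_3$events,
                         function(e) e$kind == "refill", logical(1))))
  expect_equal(sc$series_3$initial_pressure, 72000)
  expect_equal(sc$series_3$kinetics$mu_max, 1.33e-5)
  expect_equal(sc$series_3$events[[1]]$new_kinetics$mu_max, 7e-5)
  expect_equal(sc$series_3$mass_transfer$k_gw, 5e-2)
})

test_that("noise-free generation equals the simulator output", {
  scn <- quick_scenario()
  gen <- generate_observations(scn, sampling_interval = 1000,
                               noise = noise_model(0, 0, seed = 5))
  traj <- integrate_scenario(scn, output_times = gen$observations$times,
                             rtol = 1e-11, atol = 1e-14)
  expect_equal(gen$observations$pressures, traj$pressure_Pa)
  # default cell sampling: start, middle, end
  expect_equal(gen$observations$cell_times,
               c(0, scn$duration / 2, scn$duration))
  expect_length(gen$observations$cell_densities, 3)
})

test_that("generation is reproducible and truth records regenerate", {
  scn <- quick_scenario()
  g1 <- generate_observations(scn, noise = noise_model(seed = 9))
  g2 <- generate_observations(scn, noise = noise_model(seed = 9))
  expect_identical(g1$observations, g2$observations)
  g3 <- regenerate_from_truth(g1$truth)
  expect_identical(g1$observations, g3$observations)
  # a different seed gives different noise
  g4 <- generate_observations(scn, noise = noise_model(seed = 10))
  expect_false(identical(g1$observations$pressures,
                         g4$observations$pressures))
})

test_that("pressure noise is unbiased additive Gaussian", {
  scn <- quick_scenario()
  gen0 <- generate_observations(scn, sampling_interval = 200,
                                noise = noise_model(0, 0, seed = 1))
  genN <- generate_observations(scn, sampling_interval = 200,
                                noise = noise_model(500, 0, seed = 1))
  res <- genN$observations$pressures - gen0$observations$pressures
  n <- length(res)
  expect_lt(abs(mean(res)), 3 * 500 / sqrt(n))
  expect_equal(sd(res), 500, tolerance = 0.15)
})

test_that("benchmark suite covers the design grid with truths", {
  suite <- generate_benchmark_suite(seed = 1)
  expect_length(suite$datasets, 9)
  expect_equal(nrow(suite$manifest), 9)
  expect_setequal(
    grep("^species", names(suite$datasets), value = TRUE),
    c(t(outer(c("species1", "species2"),
              c("_clean_cells", "_clean_nocells", "_noisy_cells",
                "_noisy_nocells"), paste0))))
  # nocells datasets really have no cell observations
  expect_null(suite$datasets$species1_clean_nocells$observations$cell_times)
  expect_length(suite$datasets$species1_clean_cells$observations$cell_times,
                3)
  # refill dataset exists and spans two cycles
  expect_length(suite$datasets$refill_two_cycle$truth$scenario$events, 1)
  # manifest truths match the generating scenarios
  m <- suite$manifest
  expect_equal(m$mu_max[m$dataset == "species1_clean_cells"], 1.7e-4)
  expect_equal(m$k_gw[m$dataset == "species2_noisy_cells"], 9e-3)
})
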