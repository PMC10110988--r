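#' Observation noise model
#'
#' Additive Gaussian noise on the logged pressures (the scatter scale of
#' an absolute pressure sensor, default 5 mBar = 500 Pa) and multiplicative
#' log-normal noise on microscopy cell counts (default 0.3 decades).
#' Sigmas of 0 give noise-free observations.
#'
#' @param pressure_sigma Pressure noise standard deviation, Pa.
#' @param cell_sigma_log10 Cell-count noise standard deviation, log10
#'   units.
#' @param seed RNG seed; the generator is fully reproducible from it.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(pressure_sigma = 500, cell_sigma_log10 = 0.3,
                        seed = 1) {
  stop_if(pressure_sigma < 0 || cell_sigma_log10 < 0,
          "sigmas must be >= 0")
  structure(list(pressure_sigma = pressure_sigma,
                 cell_sigma_log10 = cell_sigma_log10, seed = seed),
            class = "noise_model")
}

## The bottle reactor used by all experiments: 132.5 ml total, 40 ml
## medium + 7 ml inoculum = 47 ml liquid, 1963.4 mm2 gas-water interface.
default_geometry <- function() {
  reactor_geometry(total_volume = ml_to_m3(132.5),
                   liquid_volume = ml_to_m3(47),
                   gas_liquid_contact_area = 1963.4e-6)
}

## Matched per-strain parameter sets used as synthetic-data truths.
matched_kinetics <- function(species, lag) {
  if (species == 1) {
    species_kinetics(mu_max = 1.7e-4, K_H2 = 0.02, K_CO2 = 0.011,
                     decay_b = 3e-7, yield_Y_H2 = 4.1e12, lag = lag)
  } else {
    species_kinetics(mu_max = 1e-5, K_H2 = 0.02, K_CO2 = 0.011,
                     decay_b = 3e-7, yield_Y_H2 = 1e11, lag = lag)
  }
}

#' Refill-experiment scenario preset
#'
#' The five-cycle refill experiment (species 1, 720 mBar, 65 degrees C):
#' after each growth period the reactor is re-pressurized to the initial
#' pressure with fresh 80/20 feed, and each cycle carries its own matched
#' kinetics. The first cycle has a strong lag (t_L 57000 s, t_E 1.35e6 s)
#' and a lower yield; the refilled cycles grow faster with little or no
#' lag. The mass-transfer coefficient is shared (5e-2 mol/s) since the
#' contact area never changes. Cycle boundary times are configurable - the
#' defaults give each refilled cycle 3e5 s, enough to reach its plateau.
#'
#' @param n_cycles Number of growth cycles to include (1-5).
#' @param cycle_durations Duration of each cycle, s (length `n_cycles`).
#' @return A [scenario()] with `n_cycles - 1` refill events.
#' @export
series3_scenario <- function(n_cycles = 5,
                             cycle_durations = c(2e6,
                                                 rep(3e5, n_cycles - 1))) {
  stop_if(n_cycles < 1 || n_cycles > 5, "n_cycles must be 1..5")
  stop_if(length(cycle_durations) != n_cycles,
          "need one duration per cycle")
  P0 <- mbar_to_pa(720)
  cyc <- list(
    list(mu = 1.33e-5, Y = 2.5e11, lag = lag_phase(57000, 1.35e6)),
    list(mu = 7e-5, Y = 2.6e12, lag = lag_phase(60, 2400)),
    list(mu = 1e-4, Y = 2.6e12, lag = lag_phase(0, 0)),
    list(mu = 1.1e-4, Y = 2.6e12, lag = lag_phase(16800, 33000)),
    list(mu = 8e-5, Y = 2.5e11, lag = lag_phase(30000, 60000)))
  kin <- function(i) species_kinetics(cyc[[i]]$mu, 0.02, 0.011, 3e-7,
                                      cyc[[i]]$Y, cyc[[i]]$lag)
  t_ref <- cumsum(cycle_durations)
  events <- lapply(seq_len(n_cycles - 1), function(i) {
    refill_event(t_ref[i], target_pressure = P0,
                 new_kinetics = kin(i + 1))
  })
  scenario(
    geometry = default_geometry(),
    temperature = celsius_to_kelvin(65),
    initial_pressure = P0,
    kinetics = kin(1),
    mass_transfer = mass_transfer(5e-2),
    henry_table = reference_henry_table(65),
    initial_cell_density = 5e6,
    events = events,
    duration = sum(cycle_durations))
}

#' Scenario presets for the modelled experiments
#'
#' Named presets reproducing the modelled experimental series with their
#' matched parameter sets as synthetic-data truths:
#' \describe{
#'   \item{series_1_1}{Species 1 (thermophilic strain), 600 mBar, 65 degC;
#'     mu_max 1.7e-4 1/s, Y 4.1e12 cells/mol, k_gw 8e-2 mol/s, inoculum
#'     1.43e7 cells/ml; 1.5e5 s.}
#'   \item{series_2_1}{Species 2 (mesophilic strain), 550 mBar, 37 degC;
#'     mu_max 1e-5 1/s, Y 1e11 cells/mol, k_gw 9e-3 mol/s, inoculum 1e7
#'     cells/ml; 2e6 s.}
#'   \item{series_3}{Five-cycle refill experiment, see
#'     [series3_scenario()].}
#' }
#' Lag times for series 1.1 / 2.1 are package assumptions on the hours
#' scale of the observed pre-drop plateaus (see the vignette); all other
#' numbers are the matched experimental values.
#'
#' @return Named list of [scenario()] objects.
#' @export
#' @examples
#' names(table1_scenarios())
table1_scenarios <- function() {
  list(
    series_1_1 = scenario(
      geometry = default_geometry(),
      temperature = celsius_to_kelvin(65),
      initial_pressure = mbar_to_pa(600),
      kinetics = matched_kinetics(1, lag_phase(10800, 21600)),
      mass_transfer = mass_transfer(8e-2),
      henry_table = reference_henry_table(65),
      initial_cell_density = 1.43e7,
      duration = 1.5e5),
    series_2_1 = scenario(
      geometry = default_geometry(),
      temperature = celsius_to_kelvin(37),
      initial_pressure = mbar_to_pa(550),
      kinetics = matched_kinetics(2, lag_phase(57600, 115200)),
      mass_transfer = mass_transfer(9e-3),
      henry_table = reference_henry_table(37),
      initial_cell_density = 1e7,
      duration = 2e6),
    series_3 = series3_scenario())
}

#' Generate synthetic observations from a scenario
#'
#' Simulates the scenario, samples the pressure on a regular grid with
#' additive Gaussian sensor noise, and samples the cell density at the
#' given times with multiplicative log-normal counting noise. Fully
#' reproducible from the noise model's seed; the returned truth record
#' regenerates the dataset bit-exactly.
#'
#' @param scn A [scenario()].
#' @param sampling_interval Pressure sampling interval, s (default 600).
#' @param noise A [noise_model()].
#' @param cell_sample_times Times of cell-count probes, s; default start,
#'   middle and end of the run (`NA` disables cell counts).
#' @param rtol,atol Integrator tolerances. The defaults match the
#'   calibration side's (tight, so noise-free datasets are resolved below
#'   the sensitivity of the least-identifiable parameter).
#' @return List with elements `observations` (an [observation_series()])
#'   and `truth` (a `truth_record` holding the scenario, noise model and
#'   generator version).
#' @export
#' @examples
#' scn <- table1_scenarios()$series_1_1
#' gen <- generate_observations(scn, noise = noise_model(seed = 7))
#' gen$observations
generate_observations <- function(scn, sampling_interval = 600,
                                  noise = noise_model(),
                                  cell_sample_times = NULL,
                                  rtol = 1e-11, atol = 1e-14) {
  stopifnot(inherits(scn, "mb_scenario"), inherits(noise, "noise_model"))
  stop_if(sampling_interval <= 0, "sampling_interval must be > 0")
  times <- unique(c(seq(0, scn$duration, by = sampling_interval),
                    scn$duration))
  if (is.null(cell_sample_times))
    cell_sample_times <- c(0, scn$duration / 2, scn$duration)
  has_cells <- !anyNA(cell_sample_times) && length(cell_sample_times) > 0
  grid <- sort(unique(c(times, if (has_cells) cell_sample_times)))
  traj <- integrate_scenario(scn, output_times = grid, rtol = rtol,
                             atol = atol)

  P <- trajectory_at(traj, times, "pressure_Pa")
  rho <- if (has_cells)
    trajectory_at(traj, cell_sample_times, "cells_per_ml")

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(noise$seed)
  P_obs <- P + rnorm(length(P), 0, noise$pressure_sigma)
  rho_obs <- if (has_cells)
    rho * 10^rnorm(length(rho), 0, noise$cell_sigma_log10)

  obs <- observation_series(
    times, P_obs,
    pressure_sigma = max(noise$pressure_sigma, 1),
    cell_times = if (has_cells) cell_sample_times,
    cell_densities = rho_obs,
    cell_sigma_log10 = max(noise$cell_sigma_log10, 0.01))
  truth <- structure(
    list(scenario = scn, noise = noise,
         sampling_interval = sampling_interval,
         cell_sample_times = if (has_cells) cell_sample_times,
         true_parameters = c(
           mu_max = scn$kinetics$mu_max,
           yield_Y_H2 = scn$kinetics$yield_Y_H2,
           decay_b = scn$kinetics$decay_b,
           k_gw = scn$mass_transfer$k_gw,
           initial_cell_density = scn$initial_cell_density),
         generator_version = "1"),
    class = "truth_record")
  list(observations = obs, truth = truth)
}

#' Fixed benchmark suite for recovery testing
#'
#' A deterministic collection covering both strains, noise on/off and
#' cell counts present/absent (8 datasets), plus one two-cycle refill
#' dataset, each bundled with its truth record. The manifest lists the
#' true parameter values and seeds, so recovery harnesses can check any
#' fit against its generating truth.
#'
#' @param seed Base RNG seed; dataset `i` uses `seed + i`.
#' @return List with `datasets` (named list of
#'   [generate_observations()] outputs) and `manifest` (data frame of
#'   truth values).
#' @export
generate_benchmark_suite <- function(seed = 1) {
  presets <- table1_scenarios()
  datasets <- list()
  i <- 0
  for (sp in c(1, 2)) {
    scn <- if (sp == 1) presets$series_1_1 else presets$series_2_1
    for (noisy in c(FALSE, TRUE)) {
      for (cells in c(TRUE, FALSE)) {
        i <- i + 1
        nm <- noise_model(
          pressure_sigma = if (noisy) 500 else 0,
          cell_sigma_log10 = if (noisy) 0.3 else 0,
          seed = seed + i)
        datasets[[sprintf("species%d_%s_%s", sp,
                          if (noisy) "noisy" else "clean",
                          if (cells) "cells" else "nocells")]] <-
          generate_observations(
            scn, noise = nm,
            cell_sample_times = if (cells) NULL else NA)
      }
    }
  }
  i <- i + 1
  datasets$refill_two_cycle <- generate_observations(
    series3_scenario(n_cycles = 2, cycle_durations = c(8e5, 3e5)),
    noise = noise_model(0, 0, seed = seed + i),
    cell_sample_times = NA)

  manifest <- do.call(rbind, lapply(names(datasets), function(nm) {
    tr <- datasets[[nm]]$truth
    data.frame(dataset = nm, t(tr$true_parameters),
               pressure_sigma = tr$noise$pressure_sigma,
               cell_sigma_log10 = tr$noise$cell_sigma_log10,
               seed = tr$noise$seed,
               n_pressure = length(datasets[[nm]]$observations$times),
               n_cells = length(datasets[[nm]]$observations$cell_times))
  }))
  list(datasets = datasets, manifest = manifest)
}

#' Regenerate a dataset from its truth record
#'
#' @param truth A `truth_record` from [generate_observations()].
#' @return The regenerated [generate_observations()] output;
#'   bit-identical to the original.
#' @export
regenerate_from_truth <- function(truth) {
  stopifnot(inherits(truth, "truth_record"))
  generate_observations(truth$scenario, truth$sampling_interval,
                        truth$noise,
                        cell_sample_times = if (is.null(
                          truth$cell_sample_times)) NA
                        else truth$cell_sample_times)
}
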