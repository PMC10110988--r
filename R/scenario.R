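#' Refill event
#'
#' Repressurization of the sealed reactor with fresh feed gas: moles are
#' added to the gas phase until the target pressure is reached (additive
#' top-up, no venting), the liquid phase and cells are untouched, and the
#' lag clock restarts at the event time. Unless `new_lag` (or the lag
#' carried by `new_kinetics`) says otherwise, the new cycle has no lag
#' phase, reflecting how adapted cultures respond to a refill.
#'
#' @param time Event time, s (strictly inside the scenario duration).
#' @param target_pressure Target total pressure after the refill, Pa; must
#'   be at or above the pressure at the event time.
#' @param new_lag Optional [lag_phase()] for the new cycle, measured from
#'   the refill time. Default: no lag.
#' @param new_kinetics Optional [species_kinetics()] replacing the current
#'   kinetics from this cycle on (per-cycle parameter schedules).
#' @return An object of class `mb_event`.
#' @export
refill_event <- function(time, target_pressure, new_lag = NULL,
                         new_kinetics = NULL) {
  stop_if(time < 0, "event time must be >= 0")
  stop_if(target_pressure <= 0, "refill target pressure must be > 0")
  structure(
    list(kind = "refill", time = time, target_pressure = target_pressure,
         new_lag = new_lag, new_kinetics = new_kinetics),
    class = "mb_event")
}

#' Liquid sampling event
#'
#' Withdrawal of a liquid probe for cell counting. In the default
#' `"negligible"` mode the withdrawn volume (a few tens of microliters on a
#' microchip) leaves the state untouched; in `"proportional"` mode cells
#' and dissolved moles are reduced by the withdrawn volume fraction.
#'
#' @param time Event time, s.
#' @param volume Withdrawn volume, m3 (< liquid volume).
#' @param mode `"negligible"` (default) or `"proportional"`.
#' @return An object of class `mb_event`.
#' @export
liquid_sample_event <- function(time, volume, mode = c("negligible",
                                                       "proportional")) {
  stop_if(time < 0, "event time must be >= 0")
  stop_if(volume < 0, "sample volume must be >= 0")
  structure(
    list(kind = "liquid_sample", time = time, volume = volume,
         mode = match.arg(mode)),
    class = "mb_event")
}

#' Batch-reactor scenario
#'
#' Bundles everything that defines one simulation: geometry, temperature,
#' initial pressure and feed composition, strain kinetics, mass-transfer
#' parameters, Henry solubilities, inoculum density, the event schedule and
#' the duration.
#'
#' @param geometry A [reactor_geometry()].
#' @param temperature Operating temperature, K.
#' @param initial_pressure Initial total pressure, Pa.
#' @param feed_fractions Named mole fractions of the feed gas over
#'   `c("H2","CO2","CH4","N2")`; must be >= 0 and sum to 1. Default 80/20
#'   H2/CO2.
#' @param kinetics A [species_kinetics()].
#' @param mass_transfer A [mass_transfer()].
#' @param henry_table List of [henry_entry()] covering every reactive
#'   component present in the feed.
#' @param initial_cell_density Inoculum density, cells/ml.
#' @param events List of [refill_event()] / [liquid_sample_event()],
#'   sorted by time within `(0, duration)`.
#' @param duration Simulated time span, s.
#' @param initial_n2 Residual inert nitrogen in the gas phase, mol
#'   (default 0).
#' @param n2_transfer Should N2 also exchange with the liquid? Default
#'   `FALSE` (inert headspace gas).
#' @param output_dt Default output grid spacing, s (mimics a slow pressure
#'   logger).
#' @return An object of class `mb_scenario`.
#' @export
scenario <- function(geometry, temperature, initial_pressure,
                     feed_fractions = c(H2 = 0.8, CO2 = 0.2),
                     kinetics, mass_transfer, henry_table,
                     initial_cell_density, events = list(), duration,
                     initial_n2 = 0, n2_transfer = FALSE, output_dt = 600) {
  stop_if(!inherits(geometry, "reactor_geometry"), "bad geometry")
  stop_if(temperature <= 0, "temperature must be > 0 K")
  stop_if(initial_pressure <= 0, "initial pressure must be > 0")
  ff <- setNames(numeric(4), COMPONENTS)
  stop_if(is.null(names(feed_fractions)) ||
            !all(names(feed_fractions) %in% COMPONENTS),
          "feed_fractions must be named over H2/CO2/CH4/N2")
  ff[names(feed_fractions)] <- feed_fractions
  stop_if(any(ff < 0) || abs(sum(ff) - 1) > 1e-9,
          "feed fractions must be >= 0 and sum to 1")
  stop_if(!inherits(kinetics, "species_kinetics"), "bad kinetics")
  stop_if(!inherits(mass_transfer, "mass_transfer"), "bad mass_transfer")
  stop_if(initial_cell_density < 0, "cell density must be >= 0")
  stop_if(duration <= 0, "duration must be > 0")
  ev_t <- vapply(events, function(e) e$time, numeric(1))
  stop_if(length(ev_t) > 0 &&
            (is.unsorted(ev_t, strictly = TRUE) || any(ev_t <= 0) ||
               any(ev_t >= duration)),
          "events must be strictly increasing within (0, duration)")
  structure(
    list(geometry = geometry, temperature = temperature,
         initial_pressure = initial_pressure, feed_fractions = ff,
         kinetics = kinetics, mass_transfer = mass_transfer,
         henry_table = henry_table,
         initial_cell_density = initial_cell_density, events = events,
         duration = duration, initial_n2 = initial_n2,
         n2_transfer = n2_transfer, output_dt = output_dt),
    class = "mb_scenario")
}

#' @export
print.mb_scenario <- function(x, ...) {
  cat(sprintf(
    paste0("<mb_scenario> P0 %.4g mBar, T %.4g degC, %s feed, ",
           "X0 %.3g cells/ml, k_gw %.3g mol/s, %d event(s), %.3g s\n"),
    pa_to_mbar(x$initial_pressure), kelvin_to_celsius(x$temperature),
    paste(sprintf("%g%% %s", 100 * x$feed_fractions[x$feed_fractions > 0],
                  names(x$feed_fractions)[x$feed_fractions > 0]),
          collapse = "/"),
    x$initial_cell_density, x$mass_transfer$k_gw, length(x$events),
    x$duration))
  invisible(x)
}

## Replace free calibration parameters inside a scenario. Understood names:
## mu_max, yield_Y_H2, decay_b, K_H2, K_CO2, k_gw, initial_cell_density,
## t_L, t_E.
apply_params <- function(scn, params) {
  stopifnot(inherits(scn, "mb_scenario"))
  if (length(params) == 0) return(scn)
  stop_if(is.null(names(params)), "params must be named")
  kin <- scn$kinetics
  lag <- kin$lag
  for (nm in names(params)) {
    val <- params[[nm]]
    switch(nm,
      mu_max = , yield_Y_H2 = , decay_b = , K_H2 = , K_CO2 = {
        kin[[nm]] <- val
      },
      t_L = {
        lag <- lag_phase(val, max(val, lag$t_E))
      },
      t_E = {
        lag <- lag_phase(min(lag$t_L, val), val)
      },
      k_gw = {
        scn$mass_transfer <- mass_transfer(val, scn$mass_transfer$C_ref)
      },
      initial_cell_density = {
        scn$initial_cell_density <- val
      },
      stop("unknown parameter name: ", nm, call. = FALSE))
  }
  kin$lag <- lag
  scn$kinetics <- species_kinetics(kin$mu_max, kin$K_H2, kin$K_CO2,
                                   kin$decay_b, kin$yield_Y_H2, kin$lag)
  scn
}
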