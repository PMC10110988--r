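## Simulation engine: stiff integration of the coupled ODE system with
## refill / sampling events handled by stop-and-restart at the (known)
## event times.

## One continuous integration leg. atol is per-state: tight on moles,
## looser on the cell count whose magnitude is ~1e8-1e10.
run_leg <- function(state, times, parms, rtol, atol, use_compiled) {
  atol_vec <- c(rep(atol, 8), max(atol, 1e-3))
  out <- if (use_compiled) {
    deSolve::ode(y = state, times = times, func = "reactor_derivs",
                 parms = parms, dllname = "methanobatch",
                 initfunc = "reactor_init", method = "lsoda",
                 rtol = rtol, atol = atol_vec, maxsteps = 100000)
  } else {
    deSolve::ode(y = state, times = times, func = reactor_rhs,
                 parms = parms, method = "lsoda",
                 rtol = rtol, atol = atol_vec, maxsteps = 100000)
  }
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    last_t <- out[nrow(out), 1]
    stop(structure(
      class = c("mb_integration_error", "error", "condition"),
      list(message = sprintf(
             "ODE integration failed (istate %d) at t = %g s", istate,
             last_t),
           call = NULL, last_time = last_t)))
  }
  out
}

#' Apply a refill to a reactor state
#'
#' Adds `dN = (P_target - P_current) V_gas / (R T)` moles of
#' feed-composition gas to the gas phase; liquid phase and cells are
#' unchanged. Venting is not modelled, so targets below the current
#' pressure are an error.
#'
#' @param state State vector (see [reactor_state()]).
#' @param target_pressure Target total pressure, Pa.
#' @param feed_fractions Named feed mole fractions.
#' @param geometry A [reactor_geometry()].
#' @param T Temperature, K.
#' @return The post-refill state vector.
#' @export
apply_refill <- function(state, target_pressure, feed_fractions, geometry,
                         T) {
  Ng <- state[1:4]
  P_cur <- total_pressure(sum(Ng), T, geometry$gas_volume)
  stop_if(target_pressure < P_cur * (1 - 1e-12),
          "refill target below current pressure (venting not modelled)")
  dN <- (target_pressure - P_cur) * geometry$gas_volume / (R_GAS * T)
  ff <- setNames(numeric(4), COMPONENTS)
  ff[names(feed_fractions)] <- feed_fractions
  state[1:4] <- Ng + dN * ff
  state
}

#' Apply a liquid sampling to a reactor state
#'
#' In `"negligible"` mode (the default, matching microliter-scale probes)
#' the state is returned unchanged. In `"proportional"` mode the cells and
#' dissolved moles are reduced by the withdrawn volume fraction; the
#' liquid volume itself is held constant.
#'
#' @param state State vector.
#' @param volume Withdrawn volume, m3 (must be < liquid volume).
#' @param geometry A [reactor_geometry()].
#' @param mode `"negligible"` or `"proportional"`.
#' @return The post-sampling state vector.
#' @export
apply_liquid_sampling <- function(state, volume, geometry,
                                  mode = c("negligible", "proportional")) {
  mode <- match.arg(mode)
  stop_if(volume < 0 || volume >= geometry$liquid_volume,
          "sample volume must satisfy 0 <= volume < liquid_volume")
  if (mode == "negligible") return(state)
  frac <- 1 - volume / geometry$liquid_volume
  state[5:8] <- state[5:8] * frac
  state[9] <- state[9] * frac
  state
}

#' Integrate a scenario through time
#'
#' Solves the coupled stiff ODE system (lsoda) over the scenario duration,
#' applying refill and sampling events as state discontinuities at their
#' scheduled times (stop-and-restart; between events the solution is
#' continuous). Rows at an event time report the pre-event state, so a
#' refill shows as a jump to the next output point.
#'
#' @param scn A [scenario()].
#' @param output_times Output grid, s, within `[0, duration]`. Default:
#'   every `output_dt` seconds from 0 to duration.
#' @param init_state Optional initial state vector; default
#'   [initialize_state()] from the scenario (gas at feed composition and
#'   initial pressure, liquid at Henry equilibrium).
#' @param rtol,atol Integrator tolerances (defaults 1e-8 relative, 1e-12
#'   mol absolute).
#' @param use_compiled Use the compiled derivative function (default);
#'   `FALSE` integrates with the R reference implementation.
#' @return A `reactor_trajectory`: data frame with time, total pressure
#'   (Pa and mBar), per-component moles in both phases, total cells and
#'   cell density.
#' @export
#' @examples
#' scn <- table1_scenarios()$series_1_1
#' traj <- integrate_scenario(scn, output_times = seq(0, 3600, 600))
#' head(as.data.frame(traj))
integrate_scenario <- function(scn, output_times = NULL, init_state = NULL,
                               rtol = 1e-8, atol = 1e-12,
                               use_compiled = TRUE) {
  stopifnot(inherits(scn, "mb_scenario"))
  if (is.null(output_times)) {
    output_times <- unique(c(seq(0, scn$duration, by = scn$output_dt),
                             scn$duration))
  }
  stop_if(any(output_times < 0) || any(output_times > scn$duration),
          "output_times must lie within [0, duration]")
  output_times <- sort(unique(output_times))

  geom <- scn$geometry
  henry <- henry_vector(scn$henry_table, scn$temperature)
  state <- if (is.null(init_state)) initialize_state_scn(scn) else init_state
  kin <- scn$kinetics
  lag_origin <- 0

  bounds <- c(0, vapply(scn$events, function(e) e$time, numeric(1)),
              scn$duration)
  rows <- vector("list", length(bounds) - 1)
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    lt <- sort(unique(c(t0, output_times[output_times > t0 &
                                           output_times <= t1], t1)))
    parms <- pack_parms(geom, scn$temperature, kin, scn$mass_transfer,
                        henry, scn$n2_transfer, lag_origin)
    out <- run_leg(state, lt, parms, rtol, atol, use_compiled)
    keep <- lt %in% output_times
    if (i > 1) keep[1] <- FALSE   # t0 row already emitted by previous leg
    rows[[i]] <- out[keep, , drop = FALSE]
    state <- out[nrow(out), -1]

    if (i <= length(scn$events)) {
      ev <- scn$events[[i]]
      if (ev$kind == "refill") {
        state <- apply_refill(state, ev$target_pressure,
                              scn$feed_fractions, geom, scn$temperature)
        if (!is.null(ev$new_kinetics)) kin <- ev$new_kinetics
        kin$lag <- if (!is.null(ev$new_lag)) ev$new_lag
                   else if (!is.null(ev$new_kinetics)) ev$new_kinetics$lag
                   else lag_phase(0, 0)
        lag_origin <- ev$time
      } else if (ev$kind == "liquid_sample") {
        state <- apply_liquid_sampling(state, ev$volume, geom, ev$mode)
      }
    }
  }
  m <- do.call(rbind, rows)
  build_trajectory(m, scn)
}

build_trajectory <- function(m, scn) {
  geom <- scn$geometry
  Ng_tot <- rowSums(m[, 1 + 1:4, drop = FALSE])
  P <- total_pressure(Ng_tot, scn$temperature, geom$gas_volume)
  df <- data.frame(
    time_s = m[, 1],
    pressure_Pa = P,
    pressure_mbar = pa_to_mbar(P),
    m[, -1, drop = FALSE],
    cells_per_ml = m[, "X"] / m3_to_ml(geom$liquid_volume),
    check.names = FALSE)
  names(df)[names(df) == "X"] <- "cells_total"
  structure(df, class = c("reactor_trajectory", "data.frame"),
            scenario = scn)
}

#' @export
print.reactor_trajectory <- function(x, ...) {
  cat(sprintf(
    "<reactor_trajectory> %d points over %.4g s; pressure %.4g -> %.4g mBar; peak %.3g cells/ml\n",
    nrow(x), max(x$time_s), x$pressure_mbar[1],
    x$pressure_mbar[nrow(x)], max(x$cells_per_ml)))
  invisible(x)
}

## Trajectory values at requested times (exact grid match or linear
## interpolation between output points).
trajectory_at <- function(traj, times, column) {
  approx(traj$time_s, traj[[column]], xout = times, rule = 2)$y
}
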