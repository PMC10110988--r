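#' Observation series
#'
#' Timestamped pressure measurements, optionally with sparse cell-density
#' counts, plus their noise scales - the calibration target.
#'
#' @param times Measurement times, s, strictly increasing.
#' @param pressures Total pressures, Pa.
#' @param pressure_sigma Pressure noise scale, Pa (> 0).
#' @param cell_times,cell_densities Optional sparse cell counts (times in
#'   s within the pressure time range, densities in cells/ml).
#' @param cell_sigma_log10 Noise scale of log10 cell densities
#'   (multiplicative counting error).
#' @return An object of class `observation_series`.
#' @export
observation_series <- function(times, pressures, pressure_sigma = 500,
                               cell_times = NULL, cell_densities = NULL,
                               cell_sigma_log10 = 0.3) {
  stop_if(length(times) != length(pressures),
          "times and pressures must have equal length")
  stop_if(is.unsorted(times, strictly = TRUE),
          "times must be strictly increasing")
  stop_if(pressure_sigma <= 0, "pressure_sigma must be > 0")
  has_cells <- !is.null(cell_times)
  if (has_cells) {
    stop_if(length(cell_times) != length(cell_densities),
            "cell_times and cell_densities must have equal length")
    stop_if(any(cell_times < min(times)) || any(cell_times > max(times)),
            "cell observations must lie within the pressure time range")
    stop_if(any(cell_densities <= 0), "cell densities must be > 0")
    stop_if(cell_sigma_log10 <= 0, "cell_sigma_log10 must be > 0")
  }
  structure(
    list(times = as.numeric(times), pressures = as.numeric(pressures),
         pressure_sigma = pressure_sigma,
         cell_times = if (has_cells) as.numeric(cell_times),
         cell_densities = if (has_cells) as.numeric(cell_densities),
         cell_sigma_log10 = cell_sigma_log10),
    class = "observation_series")
}

#' @export
print.observation_series <- function(x, ...) {
  cat(sprintf(
    "<observation_series> %d pressure points over %.4g s (sigma %.3g Pa)%s\n",
    length(x$times), max(x$times) - min(x$times), x$pressure_sigma,
    if (!is.null(x$cell_times))
      sprintf(", %d cell counts", length(x$cell_times)) else ""))
  invisible(x)
}

#' Initialize the reactor state from a scenario's starting conditions
#'
#' Gas-phase moles from the ideal gas law at the initial pressure and feed
#' composition; dissolved moles at Henry equilibrium with the initial
#' partial pressures; cells from the inoculum density.
#'
#' @param P0 Initial total pressure, Pa.
#' @param feed_fractions Named feed mole fractions.
#' @param geometry A [reactor_geometry()].
#' @param T Temperature, K.
#' @param henry_table List of [henry_entry()]; every reactive component
#'   present in the feed must have an entry.
#' @param cell_density Inoculum density, cells/ml.
#' @param initial_n2 Residual inert N2, mol (added on top of any N2 feed
#'   fraction; not equilibrated with the liquid).
#' @return Named state vector (see [reactor_state()]).
#' @export
#' @examples
#' g <- reactor_geometry(ml_to_m3(132.5), ml_to_m3(47), 1963.4e-6)
#' initialize_state(60000, c(H2 = 0.8, CO2 = 0.2), g,
#'                  celsius_to_kelvin(65), reference_henry_table(65), 1e7)
initialize_state <- function(P0, feed_fractions, geometry, T, henry_table,
                             cell_density, initial_n2 = 0) {
  stop_if(P0 <= 0, "initial pressure must be > 0")
  ff <- setNames(numeric(4), COMPONENTS)
  ff[names(feed_fractions)] <- feed_fractions
  henry <- henry_vector(henry_table, T)
  missing <- REACTIVE[ff[REACTIVE] > 0 & henry[REACTIVE] <= 0]
  stop_if(length(missing) > 0,
          "missing Henry entry for component(s): ",
          paste(missing, collapse = ", "))
  N_tot <- P0 * geometry$gas_volume / (R_GAS * T)
  Ng <- ff * N_tot
  Ng["N2"] <- Ng["N2"] + initial_n2
  C_eq <- equilibrium_liquid_concentration(pmax(henry, .Machine$double.xmin),
                                           ff * P0)
  C_eq[henry <= 0] <- 0
  Nl <- C_eq * geometry$liquid_volume
  Nl["N2"] <- 0
  reactor_state(N_gas = Ng, N_liq = Nl,
                X = cell_density * m3_to_ml(geometry$liquid_volume))
}

## Scenario-facing wrapper used by the engine.
initialize_state_scn <- function(scn) {
  initialize_state(scn$initial_pressure, scn$feed_fractions, scn$geometry,
                   scn$temperature, scn$henry_table,
                   scn$initial_cell_density, scn$initial_n2)
}

#' Estimate lag-phase times from a pressure trace
#'
#' Heuristic used before fitting: the end of the lag phase `t_L` is where
#' the first clear pressure drop is measured (the last point still
#' consistent with the pre-drop baseline, taken as the running median,
#' before the trace falls `drop_threshold_sigma` noise scales below it),
#' and `t_E` is the first time the trace reaches half of the total
#' pressure drop.
#'
#' @param obs An [observation_series()] with at least 10 pressure points.
#' @param drop_threshold_sigma Detection threshold in units of
#'   `pressure_sigma` (default 3).
#' @return A [lag_phase()].
#' @export
estimate_lag_times <- function(obs, drop_threshold_sigma = 3) {
  stopifnot(inherits(obs, "observation_series"))
  P <- obs$pressures; tt <- obs$times
  stop_if(length(P) < 10, "need at least 10 pressure points")
  thr <- drop_threshold_sigma * obs$pressure_sigma
  idx <- NA_integer_
  baseline <- P[1]
  for (i in 3:length(P)) {
    baseline <- median(P[1:(i - 1)])
    if (P[i] < baseline - thr) { idx <- i; break }
  }
  P_final <- median(tail(P, 5))
  if (is.na(idx) || baseline - P_final <= thr) {
    stop(structure(
      class = c("mb_no_growth", "error", "condition"),
      list(message = "no pressure drop detected (no growth?)",
           call = NULL)))
  }
  t_L <- tt[idx - 1]
  half <- (baseline + P_final) / 2
  t_E <- tt[which(P <= half)[1]]
  lag_phase(t_L, max(t_E, t_L))
}

#' Weighted least-squares calibration objective
#'
#' Simulates the scenario on the observation grid and returns
#' `sum(((P_sim - P_obs)/sigma_P)^2) +
#'  w * sum(((log10 rho_sim - log10 rho_obs)/sigma_log)^2)`,
#' with cell densities compared on the log10 scale (counting error is
#' multiplicative). Integrator failures yield a large penalty with a
#' warning rather than an error, so optimizers can route around bad
#' parameter regions.
#'
#' The default integrator tolerances here (and in [fit_scenario()]) are
#' tighter than [integrate_scenario()]'s: the pressure trace's sensitivity
#' to the mass-transfer coefficient sits at the 1e-4 Pa scale in the
#' near-equilibrium regime, so the forward model must be resolved well
#' below that for the least-identifiable direction of the objective to be
#' meaningful.
#'
#' @param scn A [scenario()] (after applying any candidate parameters).
#' @param obs An [observation_series()].
#' @param params Optional named parameter vector applied to the scenario
#'   first (see [fit_scenario()] for understood names).
#' @param cell_weight Relative weight `w` of the cell-count term.
#' @param rtol,atol Integrator tolerances.
#' @return Scalar objective >= 0.
#' @export
calibration_objective <- function(scn, obs, params = NULL,
                                  cell_weight = 1, rtol = 1e-11,
                                  atol = 1e-14) {
  r <- calibration_residuals(scn, obs, params, cell_weight, rtol, atol)
  sum(r^2)
}

## Residual vector behind the objective: pressure residuals in sigma
## units, then sqrt(cell_weight)-scaled log10 cell residuals. Constant
## length for a given obs, so Levenberg-Marquardt can use it directly;
## integration failures return a flat penalty vector.
calibration_residuals <- function(scn, obs, params = NULL,
                                  cell_weight = 1, rtol = 1e-11,
                                  atol = 1e-14) {
  if (!is.null(params)) scn <- apply_params(scn, params)
  times <- sort(unique(c(obs$times, obs$cell_times)))
  times <- times[times <= scn$duration]
  n_res <- length(obs$times) + length(obs$cell_times)
  traj <- tryCatch(
    integrate_scenario(scn, output_times = times, rtol = rtol,
                       atol = atol),
    mb_integration_error = function(e) {
      warning("integration failed during objective evaluation: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  if (is.null(traj)) return(rep(1e6, n_res))
  P_sim <- trajectory_at(traj, obs$times, "pressure_Pa")
  r <- (P_sim - obs$pressures) / obs$pressure_sigma
  if (!is.null(obs$cell_times)) {
    rho_sim <- pmax(trajectory_at(traj, obs$cell_times, "cells_per_ml"),
                    .Machine$double.xmin)
    r <- c(r, sqrt(cell_weight) *
             (log10(rho_sim) - log10(obs$cell_densities)) /
             obs$cell_sigma_log10)
  }
  r
}

#' Base-case starting parameters for calibration
#'
#' Literature-derived starting values for the matching workflow: maximum
#' growth rate 1.11e-4 1/s (thermophilic strain, species 1) or 3e-5 1/s
#' (mesophilic strain, species 2), decay 9e-8 1/s, hydrogen yield 5e12
#' cells/mol and inoculum 1e7 cells/ml. The mass-transfer coefficient has
#' no literature base case; the package starts it at 1e-2 mol/s, the
#' geometric middle of the decade range this coefficient takes in bottle
#' reactors.
#'
#' @param species 1 or 2.
#' @return Named numeric vector of starting values.
#' @export
base_case_start <- function(species = 1) {
  c(mu_max = if (species == 1) 1.11e-4 else 3e-5,
    decay_b = 9e-8,
    yield_Y_H2 = 5e12,
    initial_cell_density = 1e7,
    k_gw = 1e-2)
}

#' Calibration specification
#'
#' Which parameters are free, their bounds and starting values, the
#' pressure/cell weighting, and the multistart settings used for the
#' uniqueness diagnostic.
#'
#' @param free Character vector of free parameter names, a subset of
#'   `mu_max`, `yield_Y_H2`, `k_gw`, `decay_b`, `initial_cell_density`.
#' @param start Named vector of starting values covering `free`; default
#'   [base_case_start()].
#' @param species Species preset for the default start (1 or 2).
#' @param bounds_decades Half-width of the default box around `start`, in
#'   decades (default 2: each bound is start / 100 .. start * 100).
#' @param lower,upper Optional explicit named bounds overriding the
#'   default box.
#' @param cell_weight Weight of the cell-count objective term.
#' @param multistart_count Number of optimization starts (the first is
#'   `start`, the rest random within the bounds).
#' @param seed RNG seed for the random starts.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(free = c("mu_max", "yield_Y_H2", "k_gw"),
                             start = NULL, species = 1,
                             bounds_decades = 2, lower = NULL,
                             upper = NULL, cell_weight = 1,
                             multistart_count = 8, seed = 1) {
  allowed <- c("mu_max", "yield_Y_H2", "k_gw", "decay_b",
               "initial_cell_density")
  stop_if(!all(free %in% allowed),
          "free parameters must be among: ",
          paste(allowed, collapse = ", "))
  if (is.null(start)) start <- base_case_start(species)
  stop_if(!all(free %in% names(start)),
          "start must provide a value for every free parameter")
  stop_if(any(start[free] <= 0), "start values must be > 0")
  lo <- start[free] * 10^(-bounds_decades)
  hi <- start[free] * 10^(bounds_decades)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  stop_if(any(lo <= 0) || any(lo >= hi), "need 0 < lower < upper")
  stop_if(any(start[free] < lo) || any(start[free] > hi),
          "start must lie within the bounds")
  stop_if(multistart_count < 1, "multistart_count must be >= 1")
  structure(
    list(free = free, start = start, lower = lo, upper = hi,
         cell_weight = cell_weight, multistart_count = multistart_count,
         seed = seed),
    class = "calibration_spec")
}

## One bounded local search in log10 space. Two stages:
##  1. Nelder-Mead on the summed squares - robust to the base-case start
##     being an order of magnitude off, and to the lag plateau making
##     early residuals flat;
##  2. Levenberg-Marquardt on the residual vector with a ladder of
##     finite-difference steps. The default (machine-epsilon) step
##     resolves the stiff mu/Y directions; the mass-transfer coefficient
##     direction is many orders of magnitude shallower (the liquid is
##     near Henry equilibrium), so its Jacobian column only rises above
##     the integrator noise floor at larger steps (epsfcn 1e-6), after
##     which a finer pass polishes.
local_search <- function(resid_fn, x0, lo, hi, maxit = 400) {
  clamp <- function(x) pmin(pmax(x, lo), hi)
  ladder <- function(x) {
    value <- NULL
    for (eps in c(.Machine$double.eps, 1e-6, 1e-8)) {
      lm <- minpack.lm::nls.lm(
        par = x, lower = lo, upper = hi, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-18, ptol = 1e-18, gtol = 0, maxiter = 150,
          epsfcn = eps))
      x <- lm$par
      value <- sum(lm$fvec^2)
    }
    list(par = x, value = value, convergence = 0L)
  }
  ## the LM ladder is run both from the Nelder-Mead result and from the
  ## raw start: the simplex occasionally wanders onto the flat
  ## transfer-unlimited plateau (k_gw far above its identifiable range)
  ## from which the damped least-squares steps cannot descend
  cands <- list(ladder(x0))
  if (length(x0) > 1) {
    nm <- optim(x0, function(x) sum(resid_fn(clamp(x))^2),
                method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-12))
    cands <- c(cands, list(ladder(clamp(nm$par))))
  }
  cands[[which.min(vapply(cands, `[[`, numeric(1), "value"))]]
}

#' Fit a scenario to observations
#'
#' Bounded local optimization of the free parameters in log10 space from
#' the base-case start, optionally repeated from random starts within the
#' bounds (multistart). The multistart spread underlies the uniqueness
#' diagnostic: when the best half of the starts disagree on a parameter by
#' more than 5% relative, the solution is flagged non-unique - which is
#' what happens to the yield/inoculum pair whenever cell-count
#' observations are missing.
#'
#' @param scn A [scenario()] carrying the fixed parameters (geometry,
#'   temperature, Henry table, half-saturation constants, lag).
#' @param obs An [observation_series()].
#' @param spec A [calibration_spec()].
#' @param rtol,atol Integrator tolerances used inside the objective.
#' @return An object of class `calibration_result`: fitted values,
#'   objective, per-start table, uniqueness flag and residual series.
#' @export
fit_scenario <- function(scn, obs, spec = calibration_spec(),
                         rtol = 1e-11, atol = 1e-14) {
  stopifnot(inherits(scn, "mb_scenario"),
            inherits(obs, "observation_series"),
            inherits(spec, "calibration_spec"))
  free <- spec$free
  if (length(free) == 0) {
    val <- calibration_objective(scn, obs, cell_weight = spec$cell_weight,
                                 rtol = rtol, atol = atol)
    return(new_calibration_result(scn, obs, spec, fitted = spec$start,
                                  value = val, starts = NULL,
                                  rtol = rtol, atol = atol))
  }
  lo <- log10(spec$lower); hi <- log10(spec$upper)
  x0 <- log10(spec$start[free])
  resid_fn <- function(x) {
    calibration_residuals(scn, obs, params = setNames(10^x, free),
                          cell_weight = spec$cell_weight, rtol = rtol,
                          atol = atol)
  }

  starts <- matrix(x0, nrow = 1)
  if (spec$multistart_count > 1) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(spec$seed)
    rand <- matrix(runif((spec$multistart_count - 1) * length(free),
                         rep(lo, each = spec$multistart_count - 1),
                         rep(hi, each = spec$multistart_count - 1)),
                   ncol = length(free))
    starts <- rbind(starts, rand)
  }

  fits <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fits[[i]] <- tryCatch(
      local_search(resid_fn, starts[i, ], lo, hi),
      error = function(e) list(par = starts[i, ], value = Inf,
                               convergence = 1L))
  }
  vals <- vapply(fits, `[[`, numeric(1), "value")
  stop_if(all(!is.finite(vals)),
          "calibration failed: no start converged")
  best <- which.min(vals)

  start_tab <- data.frame(
    start = seq_len(nrow(starts)),
    objective = vals,
    setNames(as.data.frame(10^t(vapply(fits, `[[`, numeric(length(free)),
                                       "par"))), free))
  fitted <- spec$start
  fitted[free] <- 10^fits[[best]]$par
  new_calibration_result(scn, obs, spec, fitted = fitted,
                         value = vals[best], starts = start_tab,
                         rtol = rtol, atol = atol)
}

new_calibration_result <- function(scn, obs, spec, fitted, value, starts,
                                   rtol, atol) {
  uniq <- NA
  if (!is.null(starts) && nrow(starts) > 1) {
    ok <- starts[is.finite(starts$objective), , drop = FALSE]
    ok <- ok[order(ok$objective), , drop = FALSE]
    half <- ok[seq_len(ceiling(nrow(ok) / 2)), , drop = FALSE]
    spread <- vapply(spec$free, function(p) {
      v <- half[[p]]
      (max(v) - min(v)) / max(abs(v))
    }, numeric(1))
    uniq <- all(spread < 0.05)
    attr(uniq, "spread") <- spread
  }
  scn_fit <- apply_params(scn, fitted[spec$free])
  times <- sort(unique(c(obs$times, obs$cell_times)))
  traj <- integrate_scenario(scn_fit, output_times = times, rtol = rtol,
                             atol = atol)
  res <- data.frame(
    time_s = obs$times,
    pressure_obs_Pa = obs$pressures,
    pressure_sim_Pa = trajectory_at(traj, obs$times, "pressure_Pa"))
  res$residual_Pa <- res$pressure_sim_Pa - res$pressure_obs_Pa
  structure(
    list(fitted = fitted, free = spec$free, objective_value = value,
         starts = starts, uniqueness_flag = uniq, residuals = res,
         scenario = scn_fit),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n  fitted:\n")
  for (p in x$free)
    cat(sprintf("    %-22s %.6g\n", p, x$fitted[[p]]))
  cat(sprintf("  objective: %.6g\n", x$objective_value))
  if (!is.na(x$uniqueness_flag)) {
    cat(sprintf("  unique solution: %s\n",
                if (isTRUE(x$uniqueness_flag)) "yes"
                else "NO (multistart spread > 5%; consider cell counts)"))
  }
  invisible(x)
}

#' Sequential per-cycle calibration of a refill experiment
#'
#' Fits each growth cycle of a refill scenario in order. Cycle 1 fits the
#' full free set (including the mass-transfer coefficient); later cycles
#' inherit the fitted `k_gw` (constant contact area implies a shared
#' coefficient) and each cycle's initial state is the previous cycle's
#' simulated end state after the refill, so only `mu_max` and
#' `yield_Y_H2` (and optionally `decay_b`) remain free.
#'
#' @param scn A [scenario()] whose events define the cycle boundaries;
#'   refill events may carry per-cycle `new_kinetics`/`new_lag` whose lag
#'   values are held fixed during fitting.
#' @param obs An [observation_series()] spanning all cycles.
#' @param spec A [calibration_spec()]; applied to cycle 1 as-is and with
#'   `k_gw` and `initial_cell_density` removed from the free set for later
#'   cycles.
#' @param rtol,atol Integrator tolerances.
#' @return List of per-cycle `calibration_result` objects with the shared
#'   `k_gw` attached as attribute `"k_gw"`.
#' @export
fit_refill <- function(scn, obs, spec = calibration_spec(),
                       rtol = 1e-11, atol = 1e-14) {
  stopifnot(inherits(scn, "mb_scenario"))
  refills <- Filter(function(e) e$kind == "refill", scn$events)
  stop_if(length(refills) == 0, "scenario has no refill events")
  bounds <- c(0, vapply(refills, `[[`, numeric(1), "time"), scn$duration)
  n_cycle <- length(bounds) - 1

  geom <- scn$geometry
  henry <- henry_vector(scn$henry_table, scn$temperature)
  state <- initialize_state_scn(scn)
  kin <- scn$kinetics
  lag_origin <- 0
  results <- vector("list", n_cycle)
  k_shared <- NULL

  for (ci in seq_len(n_cycle)) {
    t0 <- bounds[ci]; t1 <- bounds[ci + 1]
    sel <- if (ci == 1) obs$times >= t0 & obs$times <= t1
           else obs$times > t0 & obs$times <= t1
    stop_if(sum(sel) < 3, "too few observations in cycle ", ci)
    csel <- if (!is.null(obs$cell_times))
      obs$cell_times >= t0 & obs$cell_times <= t1 else logical(0)
    obs_c <- observation_series(
      obs$times[sel], obs$pressures[sel], obs$pressure_sigma,
      cell_times = if (any(csel)) obs$cell_times[csel],
      cell_densities = if (any(csel)) obs$cell_densities[csel],
      cell_sigma_log10 = obs$cell_sigma_log10)

    free_c <- spec$free
    if (ci > 1)
      free_c <- setdiff(free_c, c("k_gw", "initial_cell_density"))
    spec_c <- calibration_spec(
      free = free_c, start = spec$start,
      lower = spec$lower[intersect(names(spec$lower), free_c)],
      upper = spec$upper[intersect(names(spec$upper), free_c)],
      cell_weight = spec$cell_weight,
      multistart_count = spec$multistart_count, seed = spec$seed + ci)

    ## cycle sub-scenario: starts at t0 from the carried state
    scn_c <- scn
    scn_c$kinetics <- kin
    scn_c$events <- list()
    scn_c$duration <- t1
    if (ci > 1 && !is.null(k_shared))
      scn_c$mass_transfer <- mass_transfer(k_shared,
                                           scn$mass_transfer$C_ref)
    res <- fit_cycle(scn_c, obs_c, spec_c, state, t0, lag_origin, kin,
                     rtol, atol)
    results[[ci]] <- res
    if (ci == 1)
      k_shared <- if ("k_gw" %in% free_c) res$fitted[["k_gw"]]
                  else scn$mass_transfer$k_gw

    ## advance the state with the fitted cycle parameters
    kin_fit <- fitted_kinetics(kin, res$fitted, free_c)
    parms <- pack_parms(geom, scn$temperature, kin_fit,
                        mass_transfer(k_shared, scn$mass_transfer$C_ref),
                        henry, scn$n2_transfer, lag_origin)
    leg <- run_leg(state, c(t0, t1), parms, rtol, atol, TRUE)
    state <- leg[nrow(leg), -1]
    if (ci <= length(refills)) {
      ev <- refills[[ci]]
      state <- apply_refill(state, ev$target_pressure, scn$feed_fractions,
                            geom, scn$temperature)
      if (!is.null(ev$new_kinetics)) kin <- ev$new_kinetics
      kin$lag <- if (!is.null(ev$new_lag)) ev$new_lag
                 else if (!is.null(ev$new_kinetics)) ev$new_kinetics$lag
                 else lag_phase(0, 0)
      lag_origin <- ev$time
    }
  }
  attr(results, "k_gw") <- k_shared
  results
}

fitted_kinetics <- function(kin, fitted, free) {
  for (p in intersect(free, c("mu_max", "yield_Y_H2", "decay_b")))
    kin[[p]] <- fitted[[p]]
  species_kinetics(kin$mu_max, kin$K_H2, kin$K_CO2, kin$decay_b,
                   kin$yield_Y_H2, kin$lag)
}

## Fit one cycle leg: like fit_scenario but integrating from a carried
## initial state on [t0, t1] with the cycle's lag clock.
fit_cycle <- function(scn_c, obs_c, spec_c, state0, t0, lag_origin, kin,
                      rtol, atol) {
  free <- spec_c$free
  geom <- scn_c$geometry
  henry <- henry_vector(scn_c$henry_table, scn_c$temperature)
  times <- sort(unique(c(t0, obs_c$times, obs_c$cell_times)))

  eval_cycle <- function(params) {
    kin_p <- kin
    for (p in intersect(names(params), c("mu_max", "yield_Y_H2",
                                         "decay_b")))
      kin_p[[p]] <- params[[p]]
    mt_p <- if ("k_gw" %in% names(params))
      mass_transfer(params[["k_gw"]], scn_c$mass_transfer$C_ref)
    else scn_c$mass_transfer
    st0 <- state0
    if ("initial_cell_density" %in% names(params))
      st0["X"] <- params[["initial_cell_density"]] *
        m3_to_ml(geom$liquid_volume)
    parms <- pack_parms(geom, scn_c$temperature, kin_p, mt_p, henry,
                        scn_c$n2_transfer, lag_origin)
    tryCatch(run_leg(st0, times, parms, rtol, atol, TRUE),
             mb_integration_error = function(e) NULL)
  }
  n_res <- length(obs_c$times) + length(obs_c$cell_times)
  resid_fn <- function(x) {
    out <- eval_cycle(setNames(10^x, free))
    if (is.null(out)) return(rep(1e6, n_res))
    P_sim <- approx(out[, 1], total_pressure(rowSums(out[, 2:5]),
                                             scn_c$temperature,
                                             geom$gas_volume),
                    xout = obs_c$times, rule = 2)$y
    r <- (P_sim - obs_c$pressures) / obs_c$pressure_sigma
    if (!is.null(obs_c$cell_times)) {
      rho <- approx(out[, 1], out[, "X"] / m3_to_ml(geom$liquid_volume),
                    xout = obs_c$cell_times, rule = 2)$y
      r <- c(r, sqrt(spec_c$cell_weight) *
               (log10(pmax(rho, 1)) - log10(obs_c$cell_densities)) /
               obs_c$cell_sigma_log10)
    }
    r
  }

  lo <- log10(spec_c$lower); hi <- log10(spec_c$upper)
  best <- local_search(resid_fn, log10(spec_c$start[free]), lo, hi)
  fitted <- spec_c$start
  fitted[free] <- 10^best$par
  structure(
    list(fitted = fitted, free = free, objective_value = best$value,
         starts = NULL, uniqueness_flag = NA, residuals = NULL,
         scenario = scn_c),
    class = "calibration_result")
}
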