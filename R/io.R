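## File IO. Boundary units follow the laboratory convention (mBar,
## cells/ml, seconds); everything is converted to SI on the way in.
## CSV dialect: comma-separated, header row, "." decimal, UTF-8.

#' Write / read an observation CSV
#'
#' Columns `time_s`, `pressure_mbar` and, when cell counts are present,
#' `cells_per_ml` (non-`NA` only on probe rows; probe times that fall
#' between pressure samples get their own rows with `NA` pressure).
#'
#' @param obs An [observation_series()].
#' @param path File path.
#' @return `write_observation_csv` returns `path` invisibly;
#'   `read_observation_csv` returns an [observation_series()].
#' @name observation_io
#' @export
write_observation_csv <- function(obs, path) {
  stopifnot(inherits(obs, "observation_series"))
  tt <- obs$times
  df <- data.frame(time_s = tt, pressure_mbar = pa_to_mbar(obs$pressures))
  if (!is.null(obs$cell_times)) {
    extra <- setdiff(obs$cell_times, tt)
    if (length(extra) > 0) {
      df <- rbind(df, data.frame(time_s = extra, pressure_mbar = NA))
      df <- df[order(df$time_s), ]
    }
    df$cells_per_ml <- NA_real_
    df$cells_per_ml[match(obs$cell_times, df$time_s)] <- obs$cell_densities
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname observation_io
#' @param pressure_sigma,cell_sigma_log10 Noise scales attached to the
#'   series on reading (the CSV itself carries only measurements).
#' @export
read_observation_csv <- function(path, pressure_sigma = 500,
                                 cell_sigma_log10 = 0.3) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  stop_if(nrow(df) == 0, "empty observation file: ", path)
  stop_if(!all(c("time_s", "pressure_mbar") %in% names(df)),
          "observation CSV needs columns time_s, pressure_mbar")
  has_cells <- "cells_per_ml" %in% names(df) && any(!is.na(df$cells_per_ml))
  pr <- !is.na(df$pressure_mbar)
  observation_series(
    times = df$time_s[pr],
    pressures = mbar_to_pa(df$pressure_mbar[pr]),
    pressure_sigma = pressure_sigma,
    cell_times = if (has_cells) df$time_s[!is.na(df$cells_per_ml)],
    cell_densities = if (has_cells)
      df$cells_per_ml[!is.na(df$cells_per_ml)],
    cell_sigma_log10 = cell_sigma_log10)
}

#' Write a trajectory CSV
#'
#' Columns: `time_s`, `pressure_Pa`, `pressure_mbar`, per-component gas
#' and liquid moles (`Ng_H2` ... `Nl_N2`), `cells_total`, `cells_per_ml`.
#'
#' @param traj A `reactor_trajectory` from [integrate_scenario()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "reactor_trajectory"))
  write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a calibration report
#'
#' Machine-readable JSON with the fitted parameter values, objective,
#' per-start multistart table, uniqueness flag and residual summary.
#'
#' @param result A `calibration_result` from [fit_scenario()].
#' @param path Output JSON path.
#' @param extra Optional named list merged into the report (e.g.
#'   provenance: seed, config hash).
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(result, path, extra = list()) {
  stopifnot(inherits(result, "calibration_result"))
  rep <- c(list(
    fitted = as.list(result$fitted[result$free]),
    fixed = as.list(result$fitted[setdiff(names(result$fitted),
                                          result$free)]),
    objective_value = result$objective_value,
    uniqueness_flag = if (is.na(result$uniqueness_flag)) NULL
                      else isTRUE(result$uniqueness_flag),
    multistart = result$starts,
    residual_rms_Pa = if (!is.null(result$residuals))
      sqrt(mean(result$residuals$residual_Pa^2))),
    extra)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
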