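# Climate analytics: inverse-distance plot-grid interpolation, heat-map
# time series, leave-one-out sensor cross-validation, Pearson sensor
# correlation, and Smith-Period late-blight risk detection.

#' Interpolate one microclimate variable over the plot grid
#'
#' Cells with a sensor get the mean of that device's readings within
#' `window_hours` of `at` (measured cells); every other cell is filled by
#' inverse-distance weighting (power `power`) over all measured cells,
#' using Euclidean distance in grid coordinates. The weights are convex, so
#' interpolation is exact at measured cells, bounded by the measured range,
#' and equivariant under adding a constant to all readings.
#'
#' @param readings a tibble `device_id, variable, timestamp, value` (e.g.
#'   from [store_readings()]).
#' @param plots a tibble mapping devices to grid cells: columns
#'   `device_id`, `row`, `col` (e.g. from [store_plots()]).
#' @param grid_rows,grid_cols grid dimensions.
#' @param variable the sensor variable to interpolate.
#' @param at the frame instant (UTC).
#' @param window_hours half-width of the aggregation window around `at`.
#' @param power IDW exponent (2 = inverse-square).
#' @param experiment_id optional label carried on the result.
#' @return an `fm_climate_grid`: `values` (rows x cols numeric matrix) and
#'   `measured` (same-shape logical mask, `TRUE` = direct sensor reading).
#' @export
interpolate_plot_grid <- function(readings, plots, grid_rows, grid_cols,
                                  variable, at, window_hours = 12, power = 2,
                                  experiment_id = NA_character_) {
  at <- fm_time(at)
  plots <- plots[!is.na(plots$device_id), , drop = FALSE]
  win <- window_hours * 3600
  rd <- readings[readings$variable == variable &
                   abs(as.numeric(difftime(readings$timestamp, at, units = "secs"))) <= win, ,
                 drop = FALSE]
  rd <- rd[rd$device_id %in% plots$device_id, , drop = FALSE]
  if (nrow(rd) == 0) {
    abort(paste0("no ", variable, " readings within ", window_hours,
                 " h of ", fm_iso(at)),
          class = "fm_no_data_error")
  }
  site <- rd |>
    group_by(.data$device_id) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    left_join(plots[, c("device_id", "row", "col")], by = "device_id")

  values <- matrix(NA_real_, grid_rows, grid_cols)
  measured <- matrix(FALSE, grid_rows, grid_cols)
  for (i in seq_len(nrow(site))) {
    values[site$row[i] + 1, site$col[i] + 1] <- site$value[i]
    measured[site$row[i] + 1, site$col[i] + 1] <- TRUE
  }
  for (r in seq_len(grid_rows)) {
    for (cc in seq_len(grid_cols)) {
      if (measured[r, cc]) next
      values[r, cc] <- idw_predict(site$row, site$col, site$value,
                                   r - 1, cc - 1, power)
    }
  }
  structure(
    list(values = values, measured = measured, variable = variable,
         at = at, experiment_id = experiment_id,
         window_hours = window_hours, power = power, empty = FALSE),
    class = "fm_climate_grid"
  )
}

# IDW prediction at (r0, c0) from sensor cells; coincident sensor wins.
idw_predict <- function(rows, cols, vals, r0, c0, power = 2) {
  d <- sqrt((rows - r0)^2 + (cols - c0)^2)
  if (any(d < 1e-12)) return(vals[which.min(d)])
  w <- d^(-power)
  sum(w * vals) / sum(w)
}

#' @export
print.fm_climate_grid <- function(x, ...) {
  cat("<fm_climate_grid>", x$variable, "at", fm_iso(x$at),
      sprintf("(%d x %d, %d measured)", nrow(x$values), ncol(x$values),
              sum(x$measured)), "\n")
  invisible(x)
}

#' @export
tidy.fm_climate_grid <- function(x, ...) {
  gr <- nrow(x$values); gc <- ncol(x$values)
  tibble(
    row = rep(0:(gr - 1), times = gc),
    col = rep(0:(gc - 1), each = gr),
    value = as.vector(x$values),
    measured = as.vector(x$measured),
    variable = x$variable,
    at = x$at
  )
}

#' Interpolated grid straight from a store
#'
#' Convenience wrapper pulling readings, plot layout and grid dimensions
#' for one experiment out of a store before calling
#' [interpolate_plot_grid()].
#'
#' @param store an `fm_store`.
#' @param experiment_id the experiment.
#' @inheritParams interpolate_plot_grid
#' @return an `fm_climate_grid`.
#' @export
climate_grid <- function(store, experiment_id, variable, at,
                         window_hours = 12, power = 2) {
  ex <- DBI::dbGetQuery(store$con,
    "SELECT grid_rows, grid_cols FROM experiments WHERE experiment_id = ?",
    params = list(experiment_id))
  if (nrow(ex) == 0) abort("unknown experiment_id", class = "fm_referential_error")
  plots <- store_plots(store, experiment_id)
  rd <- store_readings(store, variable = variable,
                       from = fm_time(at) - window_hours * 3600,
                       to = fm_time(at) + window_hours * 3600)
  interpolate_plot_grid(rd, plots, ex$grid_rows, ex$grid_cols, variable, at,
                        window_hours = window_hours, power = power,
                        experiment_id = experiment_id)
}

#' Heat-map frame series over a date range
#'
#' One interpolated grid per lattice instant `start, start + interval, ...`
#' up to and including `end` when it falls on the lattice (the field
#' default is a 14-day interval). Frames with no data in the window become
#' explicit empty-frame markers rather than errors.
#'
#' @inheritParams interpolate_plot_grid
#' @param start,end range (inclusive).
#' @param interval_days lattice spacing in days.
#' @return an `fm_climate_series`: a list of `fm_climate_grid` frames in
#'   chronological order.
#' @export
heatmap_series <- function(readings, plots, grid_rows, grid_cols, variable,
                           start, end, interval_days = 14, window_hours = 12,
                           power = 2, experiment_id = NA_character_) {
  start <- fm_time(start); end <- fm_time(end)
  if (start > end) abort("start must not be after end", class = "fm_validation_error")
  instants <- seq(start, end, by = interval_days * 86400)
  frames <- lapply(instants, function(at) {
    tryCatch(
      interpolate_plot_grid(readings, plots, grid_rows, grid_cols, variable,
                            at, window_hours = window_hours, power = power,
                            experiment_id = experiment_id),
      fm_no_data_error = function(e) {
        structure(
          list(values = matrix(NA_real_, grid_rows, grid_cols),
               measured = matrix(FALSE, grid_rows, grid_cols),
               variable = variable, at = fm_time(at),
               experiment_id = experiment_id,
               window_hours = window_hours, power = power, empty = TRUE),
          class = "fm_climate_grid"
        )
      }
    )
  })
  structure(list(frames = frames, variable = variable,
                 interval_days = interval_days),
            class = "fm_climate_series")
}

#' @export
print.fm_climate_series <- function(x, ...) {
  cat("<fm_climate_series>", x$variable, "-", length(x$frames),
      "frame(s) at", x$interval_days, "day interval\n")
  invisible(x)
}

#' @export
length.fm_climate_series <- function(x) length(x$frames)

#' @export
tidy.fm_climate_series <- function(x, ...) {
  bind_rows(lapply(x$frames, tidy))
}

#' Leave-one-out cross-validation of the sensor network
#'
#' Each sensor is removed in turn and its cell is predicted from the
#' remaining sensors with the same inverse-distance scheme used by
#' [interpolate_plot_grid()]; the error table and RMSE quantify how well
#' the network's spatial coverage supports interpolation.
#'
#' @inheritParams interpolate_plot_grid
#' @return an `fm_loo` object: `$table` (per-sensor
#'   observed/predicted/error tibble) and `$rmse`. `tidy()` returns the
#'   table, `glance()` the RMSE summary.
#' @export
loo_validation <- function(readings, plots, variable, at, window_hours = 12,
                           power = 2) {
  at <- fm_time(at)
  plots <- plots[!is.na(plots$device_id), , drop = FALSE]
  win <- window_hours * 3600
  rd <- readings[readings$variable == variable &
                   abs(as.numeric(difftime(readings$timestamp, at, units = "secs"))) <= win, ,
                 drop = FALSE]
  site <- rd |>
    group_by(.data$device_id) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    left_join(plots[, c("device_id", "row", "col")], by = "device_id")
  if (nrow(site) < 2) {
    abort("leave-one-out validation needs at least 2 sensors with data",
          class = "fm_insufficient_sensors_error")
  }
  preds <- vapply(seq_len(nrow(site)), function(i) {
    rest <- site[-i, ]
    idw_predict(rest$row, rest$col, rest$value, site$row[i], site$col[i], power)
  }, numeric(1))
  tab <- tibble(
    device_id = site$device_id, row = site$row, col = site$col,
    observed = site$value, predicted = preds,
    error = preds - site$value
  )
  structure(list(table = tab, rmse = sqrt(mean(tab$error^2)),
                 variable = variable, at = at, n_sensors = nrow(tab)),
            class = "fm_loo")
}

#' @export
print.fm_loo <- function(x, ...) {
  cat("<fm_loo>", x$variable, "at", fm_iso(x$at), "-", x$n_sensors,
      "sensors, RMSE", format(x$rmse, digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.fm_loo <- function(x, ...) x$table

#' @export
glance.fm_loo <- function(x, ...) {
  tibble(rmse = x$rmse, n_sensors = x$n_sensors, variable = x$variable, at = x$at)
}

#' Pearson correlation between two aligned sensor series
#'
#' Used for sensor cross-validation, e.g. whether soil temperature tracks
#' ambient temperature. Computed over pairwise-complete points.
#'
#' @param series_a,series_b aligned numeric vectors.
#' @return the correlation coefficient in [-1, 1].
#' @export
sensor_correlation <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) {
    abort("series must be aligned (equal length)", class = "fm_alignment_error")
  }
  ok <- stats::complete.cases(series_a, series_b)
  if (sum(ok) < 3) {
    abort("need at least 3 aligned complete pairs", class = "fm_alignment_error")
  }
  if (sd(series_a[ok]) == 0 || sd(series_b[ok]) == 0) {
    abort("zero variance in a series", class = "fm_degenerate_series_error")
  }
  cor(series_a[ok], series_b[ok])
}

#' Does a single day qualify under the Smith late-blight rule?
#'
#' A calendar day qualifies iff its minimum temperature over all 24 hourly
#' readings is at least `min_temp` (10 degrees C) and relative humidity is at or
#' above `rh_threshold` (90%) for at least `min_hours` (11) of the 24
#' hours. All thresholds are inclusive. The criterion is order-free within
#' the day.
#'
#' @param temp,rh numeric vectors of 24 hourly values each.
#' @param min_temp,rh_threshold,min_hours rule constants.
#' @return a single logical.
#' @export
smith_day_qualifies <- function(temp, rh, min_temp = 10, rh_threshold = 90,
                                min_hours = 11) {
  if (length(temp) != 24 || length(rh) != 24) {
    abort("a day needs exactly 24 hourly values per series", class = "fm_alignment_error")
  }
  min(temp) >= min_temp && sum(rh >= rh_threshold) >= min_hours
}

#' Detect Smith Periods (late-blight risk windows)
#'
#' A Smith Period is a run of two or more consecutive days each with a
#' minimum temperature of at least 10 degrees C and relative humidity of 90% or
#' above for at least 11 hours. Maximal qualifying runs of at least
#' `min_run_days` consecutive calendar days are returned, non-overlapping
#' and chronological.
#'
#' @param weather a tibble with aligned hourly columns: `timestamp` plus
#'   the temperature and humidity columns named below. Days are calendar
#'   days in `tz` (agronomic convention); partial days (fewer than 24
#'   hours) are excluded with a warning.
#' @param temp_col,rh_col column names of the hourly series.
#' @param tz timezone in which calendar days are cut.
#' @param min_temp,rh_threshold,min_hours per-day rule constants (inclusive).
#' @param min_run_days minimum run length (2 days).
#' @return an `fm_smith_periods` tibble: `start_day, end_day, n_days, rule`.
#' @export
detect_smith_periods <- function(weather, temp_col = "ambient_temp_C",
                                 rh_col = "rel_humidity_pct", tz = "UTC",
                                 min_temp = 10, rh_threshold = 90,
                                 min_hours = 11, min_run_days = 2) {
  stopifnot(all(c("timestamp", temp_col, rh_col) %in% names(weather)))
  if (anyNA(weather[[temp_col]]) != anyNA(weather[[rh_col]])) {
    abort("temperature and humidity series are not aligned", class = "fm_alignment_error")
  }
  df <- tibble(
    day = as.Date(lubridate::with_tz(fm_time(weather$timestamp), tz)),
    temp = weather[[temp_col]], rh = weather[[rh_col]]
  )
  daily <- df |>
    group_by(.data$day) |>
    summarise(n = dplyr::n(), min_temp_day = min(.data$temp),
              wet_hours = sum(.data$rh >= rh_threshold), .groups = "drop") |>
    arrange(.data$day)
  partial <- daily$n != 24
  if (any(partial)) {
    warn(sprintf("excluding %d partial day(s) with != 24 hourly points", sum(partial)))
    daily <- daily[!partial, , drop = FALSE]
  }
  daily$qualifies <- daily$min_temp_day >= min_temp & daily$wet_hours >= min_hours

  periods <- tibble(start_day = as.Date(character(0)),
                    end_day = as.Date(character(0)),
                    n_days = integer(0), rule = character(0))
  if (nrow(daily) > 0) {
    # runs break at non-qualifying days and at calendar gaps
    q <- daily[daily$qualifies, , drop = FALSE]
    if (nrow(q) > 0) {
      grp <- cumsum(c(TRUE, diff(q$day) != 1))
      runs <- q |>
        mutate(grp = grp) |>
        group_by(.data$grp) |>
        summarise(start_day = min(.data$day), end_day = max(.data$day),
                  n_days = dplyr::n(), .groups = "drop") |>
        filter(.data$n_days >= min_run_days) |>
        arrange(.data$start_day)
      if (nrow(runs) > 0) {
        periods <- tibble(start_day = runs$start_day, end_day = runs$end_day,
                          n_days = as.integer(runs$n_days), rule = "smith")
      }
    }
  }
  structure(periods, class = c("fm_smith_periods", class(periods)),
            daily = daily)
}

#' Per-day qualification table behind a Smith-Period result
#' @param x an `fm_smith_periods` result.
#' @return the daily tibble with min temperature, wet hours and
#'   qualification flags.
#' @export
smith_daily_table <- function(x) attr(x, "daily")
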