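# Static plot rendering: heat-map frames with the measured/interpolated
# outline convention, device time-series panels, and Smith-Period ribbons.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_rect
#'   scale_fill_gradientn scale_color_manual facet_wrap labs theme_minimal
#'   scale_y_reverse ggsave
NULL

#' Heat-map of one interpolated climate grid
#'
#' One tile per plot cell; measured cells (direct sensor reading) are
#' outlined in red, interpolated cells in green. Row 0 (the north edge) is
#' drawn at the top.
#'
#' @param object an `fm_climate_grid`.
#' @param limits fixed fill-scale limits `c(lo, hi)`; supply the same
#'   limits across frames of a series for comparability.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fm_climate_grid <- function(object, limits = NULL, ...) {
  df <- tidy(object)
  df$outline <- ifelse(df$measured, "measured", "interpolated")
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_tile(aes(color = .data$outline), linewidth = 1.1, width = 0.92, height = 0.92) +
    scale_color_manual(values = c(measured = "red", interpolated = "green3"),
                       name = NULL) +
    scale_fill_gradientn(colours = c("#2c7bb6", "#ffffbf", "#d7191c"),
                         limits = limits, name = object$variable) +
    scale_y_reverse(breaks = unique(df$row)) +
    labs(title = paste0(object$variable, " @ ", fm_iso(object$at)),
         x = "column", y = "row") +
    theme_minimal()
}

#' @export
autoplot.fm_climate_series <- function(object, limits = NULL, ...) {
  df <- tidy(object)
  df$frame <- fm_iso(df$at)
  df$outline <- ifelse(df$measured, "measured", "interpolated")
  limits <- limits %||% range(df$value, na.rm = TRUE)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_tile(aes(color = .data$outline), linewidth = 0.8, width = 0.92, height = 0.92) +
    scale_color_manual(values = c(measured = "red", interpolated = "green3"),
                       name = NULL) +
    scale_fill_gradientn(colours = c("#2c7bb6", "#ffffbf", "#d7191c"),
                         limits = limits, name = object$variable) +
    scale_y_reverse() +
    facet_wrap(~frame) +
    labs(x = "column", y = "row") +
    theme_minimal()
}

#' Render a heat-map series to PNG files
#'
#' Writes one PNG per frame with a color scale fixed across the whole
#' series, measured cells outlined in red and interpolated cells in green.
#' Rendering is deterministic: identical grids yield pixel-identical
#' images.
#'
#' @param series an `fm_climate_series` (or a single `fm_climate_grid`).
#' @param out_dir output directory (created if needed).
#' @param palette_range fixed fill limits `c(lo, hi)`; default is the range
#'   over all frames.
#' @param width,height,dpi device geometry.
#' @return character vector of the written PNG paths, one per frame.
#' @export
render_heatmap <- function(series, out_dir, palette_range = NULL,
                           width = 6, height = 4.5, dpi = 96) {
  if (inherits(series, "fm_climate_grid")) {
    series <- structure(list(frames = list(series), variable = series$variable,
                             interval_days = NA), class = "fm_climate_series")
  }
  if (length(series$frames) == 0) abort("empty frame series", class = "fm_validation_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vals <- unlist(lapply(series$frames, function(g) g$values))
  palette_range <- palette_range %||%
    (if (all(is.na(vals))) c(0, 1) else range(vals, na.rm = TRUE))
  paths <- character(0)
  for (i in seq_along(series$frames)) {
    g <- series$frames[[i]]
    p <- autoplot(g, limits = palette_range)
    path <- file.path(out_dir, sprintf("frame_%03d_%s.png", i, fm_compact_ts(g$at)))
    ggsave(path, p, width = width, height = height, dpi = dpi,
           device = grDevices::png)
    paths <- c(paths, path)
  }
  paths
}

#' Line-chart panel of a device's sensor series
#'
#' Mirrors the individual device view: one panel per variable over the
#' requested range, with gaps left open (no interpolation).
#'
#' @param series a tibble from [device_series()].
#' @return a ggplot object.
#' @export
plot_device_series <- function(series) {
  ggplot(series, aes(x = .data$timestamp, y = .data$value)) +
    geom_line(na.rm = FALSE, color = "#2c7bb6") +
    facet_wrap(~variable, scales = "free_y", ncol = 2) +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' @export
autoplot.fm_smith_periods <- function(object, ...) {
  daily <- smith_daily_table(object)
  p <- ggplot(daily, aes(x = .data$day, y = .data$min_temp_day)) +
    geom_line(color = "#d7191c") +
    labs(x = NULL, y = "daily minimum temperature (deg C)",
         title = "Smith-Period risk windows") +
    theme_minimal()
  if (nrow(object) > 0) {
    p <- p + geom_rect(
      data = as_tibble(object),
      aes(xmin = .data$start_day - 0.5, xmax = .data$end_day + 0.5),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "orange",
      inherit.aes = FALSE
    )
  }
  p
}
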