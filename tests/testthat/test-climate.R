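test_that("a uniform sensor field interpolates to a constant grid", {
  w <- sensors_at(c(7, 7, 7), list(c(0, 0), c(1, 2), c(2, 1)))
  g <- interpolate_plot_grid(w$readings, w$plots, 3, 3, "ambient_temp_C",
                             "2017-05-01 12:00:00")
  expect_equal(g$values, matrix(7, 3, 3), tolerance = 1e-12)
  expect_equal(sum(g$measured), 3)
  expect_true(all(g$measured[cbind(c(1, 2, 3), c(1, 3, 2))]))
})

test_that("interpolation is exact at sensor cells and at the equidistant midpoint", {
  w <- sensors_at(c(10, 20), list(c(0, 0), c(0, 2)))
  g <- interpolate_plot_grid(w$readings, w$plots, 1, 3, "ambient_temp_C",
                             "2017-05-01 12:00:00")
  expect_identical(g$values[1, 1], 10)
  expect_identical(g$values[1, 3], 20)
  expect_equal(g$values[1, 2], 15.0)     # equal weights at equal distance
})

test_that("a sensor cell equals its own windowed mean exactly", {
  rd <- tibble::tibble(
    device_id = "s1", variable = "ambient_temp_C",
    timestamp = UTC("2017-05-01 12:00:00") + c(-3600, 0, 3600),
    value = c(9, 10, 14)
  )
  plots <- tibble::tibble(device_id = "s1", row = 0, col = 0)
  g <- interpolate_plot_grid(rd, plots, 1, 2, "ambient_temp_C",
                             "2017-05-01 12:00:00", window_hours = 2)
  expect_identical(g$values[1, 1], mean(c(9, 10, 14)))
})

test_that("interpolated values are bounded and translation-equivariant", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    cells <- sample(0:24, n)   # distinct cells on a 5x5 grid
    w <- sensors_at(runif(n, 5, 25),
                    lapply(cells, function(k) c(k %/% 5, k %% 5)))
    g <- interpolate_plot_grid(w$readings, w$plots, 5, 5, "ambient_temp_C",
                               "2017-05-01 12:00:00")
    expect_true(all(g$values >= min(w$readings$value) - 1e-9))
    expect_true(all(g$values <= max(w$readings$value) + 1e-9))

    shifted <- w
    shifted$readings$value <- shifted$readings$value + 3.25
    g2 <- interpolate_plot_grid(shifted$readings, shifted$plots, 5, 5,
                                "ambient_temp_C", "2017-05-01 12:00:00")
    expect_equal(g2$values, g$values + 3.25, tolerance = 1e-9)
  }
})

test_that("no readings in the window raises a no-data error", {
  w <- sensors_at(10, list(c(0, 0)))
  expect_error(
    interpolate_plot_grid(w$readings, w$plots, 2, 2, "ambient_temp_C",
                          "2019-01-01 00:00:00", window_hours = 1),
    class = "fm_no_data_error"
  )
})

test_that("heat-map series lattices match the requested interval", {
  w <- sensors_at(c(10, 20), list(c(0, 0), c(0, 2)))
  wide <- dplyr::bind_rows(lapply(0:56, function(d) {
    dplyr::mutate(w$readings, timestamp = timestamp + d * 86400)
  }))
  series56 <- heatmap_series(wide, w$plots, 1, 3, "ambient_temp_C",
                             "2017-05-01 12:00:00", "2017-06-26 12:00:00",
                             interval_days = 14)
  expect_length(series56, 5)   # days 0, 14, 28, 42, 56
  expect_equal(vapply(series56$frames, function(g) fm_iso(g$at), character(1)),
               fm_iso(UTC("2017-05-01 12:00:00") + c(0, 14, 28, 42, 56) * 86400))

  short <- heatmap_series(wide, w$plots, 1, 3, "ambient_temp_C",
                          "2017-05-01 12:00:00", "2017-05-03 12:00:00",
                          interval_days = 14)
  expect_length(short, 1)      # span shorter than the interval

  daily <- heatmap_series(wide, w$plots, 1, 3, "ambient_temp_C",
                          "2017-05-01 12:00:00", "2017-05-04 12:00:00",
                          interval_days = 1)
  expect_length(daily, 4)      # 3-day span at interval 1 -> 4 frames
})

test_that("frames with no data become explicit empty markers", {
  w <- sensors_at(c(10, 20), list(c(0, 0), c(0, 2)))
  series <- heatmap_series(w$readings, w$plots, 1, 3, "ambient_temp_C",
                           "2017-05-01 12:00:00", "2017-05-29 12:00:00",
                           interval_days = 14, window_hours = 1)
  expect_length(series, 3)
  expect_false(series$frames[[1]]$empty)
  expect_true(series$frames[[2]]$empty)
  expect_true(all(is.na(series$frames[[2]]$values)))
})

test_that("leave-one-out validation matches hand-computed IDW and handles edge cases", {
  uniform <- sensors_at(c(5, 5, 5), list(c(0, 0), c(0, 2), c(0, 4)))
  v <- loo_validation(uniform$readings, uniform$plots, "ambient_temp_C",
                      "2017-05-01 12:00:00")
  expect_equal(v$rmse, 0)
  expect_true(all(tidy(v)$error == 0))

  one <- sensors_at(10, list(c(0, 0)))
  expect_error(loo_validation(one$readings, one$plots, "ambient_temp_C",
                              "2017-05-01 12:00:00"),
               class = "fm_insufficient_sensors_error")

  # three sensors on a line at 10, 15, 20; hand-computed IDW (power 2)
  line <- sensors_at(c(10, 15, 20), list(c(0, 0), c(0, 1), c(0, 2)))
  v3 <- loo_validation(line$readings, line$plots, "ambient_temp_C",
                       "2017-05-01 12:00:00")
  tab <- tidy(v3)
  # s1 predicted from s2 (d=1) and s3 (d=2): (15/1 + 20/4)/(1 + 1/4)
  expect_equal(tab$predicted[tab$device_id == "s1"], (15 + 20 / 4) / 1.25)
  # s2 equidistant from both neighbours: plain mean
  expect_equal(tab$predicted[tab$device_id == "s2"], 15)
  expect_equal(tab$predicted[tab$device_id == "s3"], (15 + 10 / 4) / 1.25)
  expect_equal(glance(v3)$rmse, sqrt(mean(tab$error^2)))
})

test_that("LOO error shrinks as the spatial field flattens", {
  make_field <- function(slope) {
    cells <- list(c(0, 0), c(0, 4), c(2, 2), c(4, 0), c(4, 4))
    vals <- vapply(cells, function(rc) 15 + slope * (rc[1] + rc[2]), numeric(1))
    sensors_at(vals, cells)
  }
  rmse_at <- function(slope) {
    f <- make_field(slope)
    loo_validation(f$readings, f$plots, "ambient_temp_C", "2017-05-01 12:00:00")$rmse
  }
  expect_lt(rmse_at(0.1), rmse_at(1))
  expect_lt(rmse_at(0.01), rmse_at(0.1))
  expect_equal(rmse_at(0), 0)
})

test_that("Pearson sensor correlation behaves at the boundaries", {
  x <- c(1, 3, 2, 5, 4, 6)
  expect_equal(sensor_correlation(x, x), 1.0)
  expect_equal(sensor_correlation(x, -x), -1.0)
  expect_error(sensor_correlation(x, rep(2, 6)), class = "fm_degenerate_series_error")
  expect_error(sensor_correlation(x, x[1:5]), class = "fm_alignment_error")
})

test_that("simulated soil temperature tracks ambient temperature at the soil lag", {
  m <- weather_model(noise_sd = list(), seed = 1)
  wx <- simulate_weather(m, days = 10)
  n <- nrow(wx)
  lag <- m$soil_lag_h
  r_lagged <- sensor_correlation(wx$ambient_temp_C[1:(n - lag)],
                                 wx$soil_temp_C[(lag + 1):n])
  expect_gt(r_lagged, 0.9)
  # even unaligned the association stays clearly positive
  expect_gt(sensor_correlation(wx$ambient_temp_C, wx$soil_temp_C), 0.5)
})
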