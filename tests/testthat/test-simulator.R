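test_that("a degenerate weather model collapses to its mean", {
  m <- weather_model(diurnal_amplitude_C = 0, seasonal_trend_C_per_day = 0,
                     noise_sd = list())
  wx <- simulate_weather(m, days = 3)
  expect_equal(nrow(wx), 72)
  expect_true(all(wx$ambient_temp_C == 15))
})

test_that("the noise-free sinusoid hits its closed-form daily extrema", {
  m <- weather_model(mean_temp_C = 15, diurnal_amplitude_C = 5,
                     seasonal_trend_C_per_day = 0, noise_sd = list())
  wx <- simulate_weather(m, days = 4)
  daily <- split(wx$ambient_temp_C, rep(1:4, each = 24))
  expect_true(all(vapply(daily, min, numeric(1)) == 10))
  expect_true(all(vapply(daily, max, numeric(1)) == 20))
})

test_that("weather is reproducible by seed and perturbed by a different seed", {
  a <- simulate_weather(weather_model(seed = 3), days = 2)
  b <- simulate_weather(weather_model(seed = 3), days = 2)
  c <- simulate_weather(weather_model(seed = 4), days = 2)
  expect_identical(a, b)
  expect_false(identical(a$ambient_temp_C, c$ambient_temp_C))
})

test_that("per-device streams are independent of other devices", {
  one <- simulate_weather(weather_model(seed = 3), days = 2, stream_id = "devA")
  # simulating another device first must not perturb devA's series
  invisible(simulate_weather(weather_model(seed = 3), days = 2, stream_id = "devB"))
  again <- simulate_weather(weather_model(seed = 3), days = 2, stream_id = "devA")
  expect_identical(one, again)
})

test_that("physical bounds hold for every seed", {
  for (seed in 1:10) {
    wx <- simulate_weather(weather_model(seed = seed), days = 5)
    expect_true(all(wx$rel_humidity_pct >= 0 & wx$rel_humidity_pct <= 100))
    expect_true(all(wx$soil_moisture_pct >= 0 & wx$soil_moisture_pct <= 100))
    expect_true(all(wx$light_lux >= 0))
    expect_true(all(wx$light_lux[lubridate::hour(wx$timestamp) < 5] == 0))
  }
})

test_that("synthetic images are deterministic and respond to their controls", {
  a <- synth_image(96, 72, sharpness = 0.5, exposure = 0.5, seed = 9)
  b <- synth_image(96, 72, sharpness = 0.5, exposure = 0.5, seed = 9)
  expect_identical(a, b)

  blur <- score_image(synth_image(96, 72, sharpness = 0.2, exposure = 0.5, seed = 9))
  sharp <- score_image(synth_image(96, 72, sharpness = 0.8, exposure = 0.5, seed = 9))
  expect_lt(blur$clarity, sharp$clarity)

  dark <- score_image(synth_image(96, 72, sharpness = 0.5, exposure = 0, seed = 9))
  expect_lt(dark$mean_intensity, selection_config()$intensity_low)
  mid <- score_image(synth_image(96, 72, sharpness = 0.5, exposure = 0.5, seed = 9))
  bright <- score_image(synth_image(96, 72, sharpness = 0.5, exposure = 0.9, seed = 9))
  expect_lt(mid$mean_intensity, bright$mean_intensity)
})

test_that("the standard layout registers monitored plots with keyed devices", {
  st <- store_init(":memory:")
  devs <- simulate_field_layout(st, "e1", grid_rows = 4, grid_cols = 8,
                                n_monitored = 16, capture_width = 160,
                                capture_height = 120)
  expect_equal(nrow(devs), 16)
  plots <- store_plots(st, "e1")
  expect_equal(nrow(plots), 32)
  expect_equal(sum(!is.na(plots$device_id)), 16)
  expect_true(all(nchar(devs$shared_key) == 32))
  store_close(st)
})

test_that("a fault-free run delivers exact daily counts", {
  world <- run_simulation(days = 3, n_devices = 2, sync_every_h = 12)
  st <- world$server$store
  reps <- store_images(st, representative_only = TRUE)
  expect_equal(nrow(reps), 2 * 3)                     # one per device per day
  counts <- store_readings(st) |>
    dplyr::count(device_id, variable)
  expect_equal(nrow(counts), 2 * 6)                   # all six variables
  expect_true(all(counts$n == 3 * 24))                # 24 hourly points per day
  expect_true(all(world$transcript$outcome == "delivered"))
  store_close(st)
})

test_that("a reported failure turns the device red from that day on", {
  faults <- fault_schedule(failures = tibble::tibble(
    device_id = "e1-dev01", at = UTC("2017-05-02 00:00:00"), mode = "error"))
  world <- run_simulation(days = 3, n_devices = 2, sync_every_h = 12,
                          faults = faults)
  srv <- world$server
  cls <- classify_device_status(srv, "e1-dev01", "2017-05-04 00:10:00")
  expect_identical(cls$color, "red")
  expect_match(cls$reason, "error")
  healthy <- classify_device_status(srv, "e1-dev02", "2017-05-04 00:10:00")
  expect_identical(healthy$color, "green")
  store_close(srv$store)
})

test_that("identical seeds and fault schedules fully determine the store", {
  a <- run_simulation(days = 2, n_devices = 2, sync_every_h = 12, seed = 13)
  b <- run_simulation(days = 2, n_devices = 2, sync_every_h = 12, seed = 13)
  c <- run_simulation(days = 2, n_devices = 2, sync_every_h = 12, seed = 14)
  expect_identical(fieldmon:::store_checksum(a$server$store),
                   fieldmon:::store_checksum(b$server$store))
  expect_false(identical(fieldmon:::store_checksum(a$server$store),
                         fieldmon:::store_checksum(c$server$store)))
  for (w in list(a, b, c)) store_close(w$server$store)
})
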