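test_that("a fresh store is empty and re-opening is idempotent", {
  path <- withr::local_tempfile(fileext = ".db")
  st <- store_init(path)
  expect_equal(nrow(store_experiments(st)), 0)
  expect_equal(nrow(store_readings(st)), 0)
  store_add_experiment(st, "e1", "t", 0, 0, "2017-05-01", NA, 1, 1)
  store_close(st)

  st2 <- store_init(path)   # re-init on the same path loses nothing
  expect_equal(store_experiments(st2)$experiment_id, "e1")
  store_close(st2)
})

test_that("entity invariants are enforced at registration", {
  st <- make_test_store()
  expect_error(store_add_experiment(st, "bad", "x", 95, 0, "2017-05-01", NA, 2, 2),
               class = "fm_validation_error")
  expect_error(store_add_experiment(st, "bad", "x", 0, 0, "2017-05-02", "2017-05-01", 2, 2),
               class = "fm_validation_error")
  expect_error(store_add_plot(st, "px", "e1", 5, 0), class = "fm_validation_error")
  expect_error(store_add_plot(st, "px", "nope", 0, 0), class = "fm_referential_error")
  # (row, col) unique within an experiment
  expect_error(store_add_plot(st, "px", "e1", 0, 0))
  # at most one device per plot
  expect_error(store_add_plot(st, "px", "e1", 1, 0, device_id = "d1"),
               class = "fm_validation_error")
  expect_error(store_add_device(st, "d9", "", boot_time = "2017-05-01T00:00:00Z"),
               class = "fm_validation_error")
  store_close(st)
})

test_that("record_readings counts inserts and silently skips duplicates", {
  st <- make_test_store()
  rd <- hourly_readings("d1")
  expect_identical(record_readings(st, rd), 24L)
  expect_identical(record_readings(st, rd), 0L)        # full resubmission
  expect_equal(nrow(store_readings(st, "d1")), 24)

  # 24 new readings of which 3 duplicate existing keys -> 21 inserted
  mixed <- dplyr::bind_rows(rd[1:3, ], hourly_readings("d1", start = "2017-05-02 00:00:00", n = 21))
  expected_new <- nrow(dplyr::anti_join(
    mixed[c("device_id", "variable", "timestamp")],
    rd[c("device_id", "variable", "timestamp")],
    by = c("device_id", "variable", "timestamp")))
  expect_equal(expected_new, 21)
  expect_identical(record_readings(st, mixed), 21L)
  store_close(st)
})

test_that("unknown devices and out-of-range percentages are rejected", {
  st <- make_test_store()
  expect_error(record_readings(st, hourly_readings("ghost")),
               class = "fm_referential_error")
  bad <- hourly_readings("d1", variable = "rel_humidity_pct", values = rep(105, 24))
  expect_error(record_readings(st, bad), class = "fm_validation_error")
  expect_error(record_readings(st, dplyr::mutate(hourly_readings("d1"), variable = "wind")),
               class = "fm_validation_error")
  store_close(st)
})

test_that("dedupe key uniqueness survives random interleavings of inserts", {
  st <- make_test_store()
  set.seed(42)
  pool <- tidyr::expand_grid(
    device_id = c("d1", "d2"),
    variable = c("ambient_temp_C", "rel_humidity_pct"),
    hour = 0:23
  ) |>
    dplyr::mutate(timestamp = UTC("2017-05-01 00:00:00") + 3600 * hour,
                  value = 50 + hour) |>
    dplyr::select(-hour)
  seen <- character(0)
  total <- 0L
  for (i in 1:15) {
    batch <- pool[sample(nrow(pool), sample(30, 1), replace = TRUE), ]
    n <- record_readings(st, batch)
    keys <- paste(batch$device_id, batch$variable, fm_iso(batch$timestamp))
    expect_identical(n, length(setdiff(unique(keys), seen)))  # set-based oracle
    seen <- union(seen, keys)
    total <- total + n
  }
  expect_equal(nrow(store_readings(st)), total)
  store_close(st)
})

test_that("status snapshots and device modes are recorded", {
  st <- make_test_store()
  expect_true(record_status(st, "d1", "2017-05-01T10:00:00Z", 20, 30, 8, 32, "operating"))
  expect_false(record_status(st, "d1", "2017-05-01T10:00:00Z", 20, 30, 8, 32, "operating"))
  expect_error(record_status(st, "d1", "2017-05-01T11:00:00Z", 1, 1, 40, 32),
               class = "fm_validation_error")  # free > total
  record_status(st, "d1", "2017-05-01T11:00:00Z", 1, 1, 8, 32, "error")
  expect_equal(store_devices(st)$mode[store_devices(st)$device_id == "d1"], "error")
  store_close(st)
})

test_that("all stored and exported timestamps are UTC ISO-8601", {
  st <- make_test_store()
  # insert with a non-UTC wall clock; storage must normalize to UTC
  paris <- as.POSIXct("2017-05-01 12:00:00", tz = "Europe/Paris")
  record_readings(st, tibble::tibble(device_id = "d1", variable = "ambient_temp_C",
                                     timestamp = paris, value = 1))
  raw <- DBI::dbGetQuery(st$con, "SELECT timestamp_utc FROM readings")$timestamp_utc
  expect_match(raw, "^2017-05-01T10:00:00Z$")
  csv <- export_sensor_csv(st, "d1")
  expect_false(grepl("\\+0[0-9]:00", csv))
  expect_true(grepl("T10:00:00Z", csv))
  store_close(st)
})
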