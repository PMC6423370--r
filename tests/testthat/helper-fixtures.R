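# Shared fixtures: everything is generated in code at test time.

UTC <- function(x) as.POSIXct(x, tz = "UTC")

# A small registered world: 2 x 3 grid, two monitored plots.
make_test_store <- function(path = ":memory:") {
  st <- store_init(path)
  store_add_experiment(st, "e1", "test trial", 52.62, 1.22,
                       "2017-05-01", NA, grid_rows = 2, grid_cols = 3)
  store_add_plot(st, "p1", "e1", 0, 0, genotype = "G01", device_id = "d1")
  store_add_plot(st, "p2", "e1", 0, 2, genotype = "G02", device_id = "d2")
  store_add_plot(st, "p3", "e1", 1, 1, genotype = "G03")
  store_add_device(st, "d1", "key-one", plot_id = "p1",
                   boot_time = "2017-05-01T00:00:00Z",
                   capture_width = 160, capture_height = 120)
  store_add_device(st, "d2", "key-two", plot_id = "p2",
                   boot_time = "2017-05-01T00:00:00Z",
                   capture_width = 160, capture_height = 120)
  st
}

hourly_readings <- function(device_id, variable = "ambient_temp_C",
                            start = "2017-05-01 00:00:00", n = 24,
                            values = NULL) {
  tibble::tibble(
    device_id = device_id, variable = variable,
    timestamp = UTC(start) + 3600 * (seq_len(n) - 1),
    value = values %||% (15 + sin(seq_len(n)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flat_image <- function(value = 0.5, h = 24, w = 32) {
  image_encode(matrix(value, h, w))
}

checkerboard_image <- function(h = 24, w = 32, lo = 0.25, hi = 0.75) {
  m <- matrix(lo, h, w)
  m[(row(m) + col(m)) %% 2 == 0] <- hi
  image_encode(m)
}

sort_by_time <- function(rd) dplyr::arrange(rd, timestamp, variable)

# Point sensors dropped on a grid at one instant (climate fixtures).
sensors_at <- function(values, cells, at = "2017-05-01 12:00:00") {
  list(
    readings = tibble::tibble(
      device_id = paste0("s", seq_along(values)),
      variable = "ambient_temp_C",
      timestamp = UTC(at),
      value = values
    ),
    plots = tibble::tibble(
      device_id = paste0("s", seq_along(values)),
      row = vapply(cells, `[`, numeric(1), 1),
      col = vapply(cells, `[`, numeric(1), 2)
    )
  )
}

# Independent brute-force oracle for representative selection: explicit
# loop over candidates, no dplyr.
oracle_select <- function(images, min_fs, lo, hi) {
  best <- NULL
  for (i in seq_len(nrow(images))) {
    r <- images[i, ]
    if (r$file_size < min_fs) next
    if (r$mean_intensity < lo || r$mean_intensity > hi) next
    if (is.null(best) ||
        r$clarity > best$clarity ||
        (r$clarity == best$clarity && r$capture_time < best$capture_time)) {
      best <- r
    }
  }
  best
}

# Independent brute-force oracle for Smith periods: explicit day scan.
oracle_smith <- function(qualifies, days, min_run = 2) {
  runs <- list()
  i <- 1
  while (i <= length(qualifies)) {
    if (qualifies[i]) {
      j <- i
      while (j + 1 <= length(qualifies) && qualifies[j + 1] &&
             as.integer(days[j + 1] - days[j]) == 1) j <- j + 1
      if (j - i + 1 >= min_run) {
        runs <- c(runs, list(c(start = days[i], end = days[j])))
      }
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

# A registered simulation world + its run, reused by system-level tests.
run_simulation <- function(days, n_devices = 2, grid_rows = 2, grid_cols = 3,
                           sync_every_h = 12, images_per_day = 2, seed = 7,
                           faults = NULL) {
  srv <- server_create(":memory:")
  simulate_field_layout(srv$store, "e1", grid_rows = grid_rows,
                        grid_cols = grid_cols, n_monitored = n_devices,
                        capture_width = 160, capture_height = 120, seed = seed)
  transcript <- simulate_device_run(srv, "e1", days = days,
                                    images_per_day = images_per_day,
                                    sync_every_h = sync_every_h,
                                    model = weather_model(seed = seed),
                                    faults = faults)
  list(server = srv, transcript = transcript)
}
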