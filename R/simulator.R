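# Field simulator: seeded diurnal weather, procedural canopy images,
# device lifecycles and fault injection. Stands in for the physical
# workstations so the full agent -> server -> analytics stack is testable
# with no hardware.

#' Parametric diurnal weather model
#'
#' Hourly microclimate with diurnal sinusoidal structure, a linear seasonal
#' trend, lagged/damped soil temperature, day-night light, and seeded
#' Gaussian noise. Every (device, variable) pair draws from its own
#' pseudo-random stream derived from the master seed, so adding a device
#' never perturbs another device's series.
#'
#' @param mean_temp_C season-mean ambient temperature.
#' @param diurnal_amplitude_C half peak-to-trough ambient swing (peak at
#'   14:00, trough at 02:00).
#' @param seasonal_trend_C_per_day linear warming trend.
#' @param rh_base_pct,rh_diurnal_amplitude_pct relative humidity base and
#'   swing; RH moves in anti-phase with temperature and is clipped to
#'   [0, 100].
#' @param light_max_lux midday clear-sky illuminance; light follows a
#'   half-sine between 06:00 and 18:00 and is 0 at night.
#' @param soil_lag_h hours by which soil temperature lags ambient.
#' @param soil_damping in (0, 1]: how strongly soil temperature follows the
#'   lagged ambient signal versus the running ambient mean.
#' @param soil_moisture_base_pct starting soil moisture; it declines slowly
#'   between simulated rain-free days.
#' @param noise_sd named list of per-variable Gaussian noise SDs (0 = the
#'   closed-form series).
#' @param seed master integer seed.
#' @return a `weather_model` list of parameters.
#' @export
weather_model <- function(mean_temp_C = 15, diurnal_amplitude_C = 5,
                          seasonal_trend_C_per_day = 0.05,
                          rh_base_pct = 75, rh_diurnal_amplitude_pct = 15,
                          light_max_lux = 60000, soil_lag_h = 2,
                          soil_damping = 0.5, soil_moisture_base_pct = 35,
                          noise_sd = list(ambient_temp_C = 0.5,
                                          rel_humidity_pct = 3,
                                          light_lux = 2000,
                                          soil_temp_C = 0.3,
                                          soil_moisture_pct = 1.5,
                                          device_temp_C = 0.7),
                          seed = 1) {
  if (diurnal_amplitude_C < 0 || rh_diurnal_amplitude_pct < 0) {
    abort("amplitudes must be non-negative", class = "fm_validation_error")
  }
  if (soil_damping <= 0 || soil_damping > 1) {
    abort("soil_damping must lie in (0, 1]", class = "fm_validation_error")
  }
  structure(list(mean_temp_C = mean_temp_C,
                 diurnal_amplitude_C = diurnal_amplitude_C,
                 seasonal_trend_C_per_day = seasonal_trend_C_per_day,
                 rh_base_pct = rh_base_pct,
                 rh_diurnal_amplitude_pct = rh_diurnal_amplitude_pct,
                 light_max_lux = light_max_lux, soil_lag_h = soil_lag_h,
                 soil_damping = soil_damping,
                 soil_moisture_base_pct = soil_moisture_base_pct,
                 noise_sd = noise_sd, seed = seed),
            class = "weather_model")
}

stream_noise <- function(model, stream_id, variable, n) {
  sd <- model$noise_sd[[variable]] %||% 0
  if (sd == 0) return(rep(0, n))
  with_stream_seed(fm_stream_seed(model$seed, stream_id, variable),
                   rnorm(n, sd = sd))
}

#' Simulate hourly weather for all sensor variables
#'
#' @param model a [weather_model()].
#' @param days number of simulated days (24 hourly points each).
#' @param start first day (UTC midnight).
#' @param stream_id label selecting the pseudo-random stream (use the
#'   device id so each device gets independent noise).
#' @param temp_offset_C additive site offset (spatial microclimate
#'   variation across the plot grid).
#' @return a wide tibble: `timestamp` plus one column per sensor variable,
#'   `24 * days` rows. Identical inputs (including seed) give identical
#'   series.
#' @export
simulate_weather <- function(model, days, start = as.Date("2017-05-01"),
                             stream_id = "field", temp_offset_C = 0) {
  stopifnot(days >= 1)
  n <- 24 * days
  t0 <- lubridate::as_datetime(start, tz = "UTC")
  ts <- t0 + 3600 * (0:(n - 1))
  hour <- (0:(n - 1)) %% 24
  day <- (0:(n - 1)) %/% 24
  phase <- sin(2 * pi * (hour - 8) / 24)  # max at 14:00, min at 02:00

  temp <- model$mean_temp_C + temp_offset_C +
    model$seasonal_trend_C_per_day * day +
    model$diurnal_amplitude_C * phase +
    stream_noise(model, stream_id, "ambient_temp_C", n)

  rh <- model$rh_base_pct - model$rh_diurnal_amplitude_pct * phase +
    stream_noise(model, stream_id, "rel_humidity_pct", n)
  rh <- pmin(100, pmax(0, rh))

  daylit <- hour >= 6 & hour <= 18
  light <- ifelse(daylit, model$light_max_lux * sin(pi * (hour - 6) / 12), 0)
  light <- ifelse(daylit,
                  pmax(0, light + stream_noise(model, stream_id, "light_lux", n)),
                  0)

  lag <- round(model$soil_lag_h)
  temp_lagged <- c(rep(temp[1], lag), temp)[1:n]
  run_mean <- cumsum(temp) / seq_len(n)
  soil_t <- run_mean + model$soil_damping * (temp_lagged - run_mean) +
    stream_noise(model, stream_id, "soil_temp_C", n)

  soil_m <- model$soil_moisture_base_pct - 0.08 * day +
    stream_noise(model, stream_id, "soil_moisture_pct", n)
  soil_m <- pmin(100, pmax(0, soil_m))

  dev_t <- temp + 8 + stream_noise(model, stream_id, "device_temp_C", n)

  tibble(timestamp = ts, ambient_temp_C = temp, rel_humidity_pct = rh,
         light_lux = light, soil_temp_C = soil_t, soil_moisture_pct = soil_m,
         device_temp_C = dev_t)
}

#' Pivot a wide weather table into sensor readings
#'
#' @param weather a wide tibble from [simulate_weather()].
#' @param device_id device to attribute the readings to.
#' @return a long tibble accepted by [record_readings()].
#' @export
weather_to_readings <- function(weather, device_id) {
  weather |>
    tidyr::pivot_longer(-"timestamp", names_to = "variable", values_to = "value") |>
    mutate(device_id = device_id) |>
    select("device_id", "variable", "timestamp", "value")
}

# Smooth bilinear upsampling of a coarse matrix to (h, w); used for the
# low-frequency canopy structure so its contribution to the Laplacian is
# negligible next to the sharpness-controlled fine detail.
bilinear_upsample <- function(mat, h, w) {
  up1 <- function(n_out, n_in) {
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pos <- pmin(pmax(pos, 1), n_in)
    lo <- floor(pos); hi <- pmin(lo + 1, n_in); f <- pos - lo
    M <- matrix(0, n_out, n_in)
    M[cbind(seq_len(n_out), lo)] <- 1 - f
    M[cbind(seq_len(n_out), hi)] <- M[cbind(seq_len(n_out), hi)] + f
    M
  }
  up1(h, nrow(mat)) %*% mat %*% t(up1(w, ncol(mat)))
}

#' Generate a procedural plant-canopy-like test image
#'
#' A green-tinted texture: smooth low-frequency blobs (canopy structure)
#' plus fine-grained detail whose amplitude grows with `sharpness`, all
#' scaled by `exposure`. For a fixed seed the clarity score is strictly
#' increasing in `sharpness`, mean intensity increases with `exposure`
#' (exposure 0 is a black frame), and the encoded size varies with texture
#' detail. Fully deterministic in `(width, height, sharpness, exposure,
#' seed)`.
#'
#' @param width,height output dimensions in pixels (defaults: the native
#'   capture resolution).
#' @param sharpness in [0, 1]: fine-detail amplitude.
#' @param exposure in [0, 1]: global brightness.
#' @param seed integer stream seed.
#' @return raw PNG bytes.
#' @export
synth_image <- function(width = 2592, height = 1944, sharpness = 0.7,
                        exposure = 0.5, seed = 1) {
  stopifnot(width > 0, height > 0)
  ch <- max(2, round(height / 80)); cw <- max(2, round(width / 80))
  base <- with_stream_seed(fm_stream_seed(seed, "canopy-base"),
                           matrix(runif(ch * cw, 0.35, 0.75), ch, cw))
  base <- bilinear_upsample(base, height, width)
  detail <- with_stream_seed(fm_stream_seed(seed, "canopy-detail"),
                             matrix(rnorm(height * width, sd = 1), height, width))
  g <- exposure * (base + 0.25 * sharpness * detail)
  g[g < 0] <- 0; g[g > 1] <- 1
  img <- array(0, dim = c(height, width, 3))
  img[, , 1] <- 0.55 * g
  img[, , 2] <- g
  img[, , 3] <- 0.40 * g
  image_encode(img)
}

#' Fault schedule for a simulated run
#'
#' @param outages tibble of network-unreachable intervals: columns
#'   `device_id`, `start`, `end` (start < end).
#' @param failures tibble of device failures: columns `device_id`, `at`,
#'   `mode` (`"error"` or `"terminated"`); from `at` on the device reports
#'   that mode.
#' @return a `fault_schedule` list.
#' @export
fault_schedule <- function(outages = NULL, failures = NULL) {
  if (is.null(outages)) {
    outages <- tibble(device_id = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"))
  } else {
    outages <- mutate(outages, start = fm_time(start), end = fm_time(end))
    if (any(outages$start >= outages$end)) {
      abort("outage intervals need start < end", class = "fm_validation_error")
    }
  }
  if (is.null(failures)) {
    failures <- tibble(device_id = character(0),
                       at = as.POSIXct(character(0), tz = "UTC"),
                       mode = character(0))
  } else {
    failures <- mutate(failures, at = fm_time(at))
    stopifnot(all(failures$mode %in% c("error", "terminated")))
  }
  structure(list(outages = outages, failures = failures), class = "fault_schedule")
}

device_unreachable <- function(faults, device_id, at) {
  o <- faults$outages
  any(o$device_id == device_id & o$start <= at & at < o$end)
}

device_mode_at <- function(faults, device_id, at) {
  f <- faults$failures
  f <- f[f$device_id == device_id & f$at <= at, , drop = FALSE]
  if (nrow(f) == 0) return("operating")
  f$mode[which.max(f$at)]
}

#' Simulate a multi-day run of distributed devices against a server
#'
#' Drives the whole stack: each registered device each day captures
#' `images_per_day` procedural images, logs 24 hourly readings per sensor
#' variable with a spatial temperature gradient across the grid, selects
#' and downsizes a daily representative at day close, and syncs signed
#' payloads at the configured cadence. Network outages in the fault
#' schedule route payloads through the store-and-forward queue; failures
#' switch the reported mode. The run is fully determined by
#' `(experiment, model seed, fault schedule)`.
#'
#' @param server an `fm_server` whose store holds the experiment, plots and
#'   registered devices.
#' @param experiment_id the experiment to simulate.
#' @param days number of simulated days.
#' @param start first day (UTC midnight).
#' @param images_per_day candidate captures per device per day.
#' @param model a [weather_model()]; its `seed` drives all randomness.
#' @param faults a [fault_schedule()] (`NULL` = fault-free).
#' @param sync_every_h payload cadence in hours (1 = the hourly field
#'   default; larger values batch more per payload).
#' @param temp_gradient_C_per_cell ambient-temperature offset per grid unit
#'   (row + col), giving the grid a smooth spatial field to interpolate.
#' @param target_width,target_height representative-image resolution;
#'   defaults to 640 x 480 for native-resolution captures, else a quarter
#'   of the capture size.
#' @return a transcript tibble: one row per payload handled with
#'   `device_id`, `sync_time`, `outcome` and `ack_through`.
#' @export
simulate_device_run <- function(server, experiment_id, days,
                                start = as.Date("2017-05-01"),
                                images_per_day = 3, model = weather_model(),
                                faults = NULL, sync_every_h = 1,
                                temp_gradient_C_per_cell = 0.15,
                                target_width = NULL, target_height = NULL) {
  faults <- faults %||% fault_schedule()
  store <- server$store
  plots <- store_plots(store, experiment_id)
  plots <- plots[!is.na(plots$device_id), , drop = FALSE]
  devices <- store_devices(store)
  devices <- devices[devices$device_id %in% plots$device_id, , drop = FALSE]
  if (nrow(devices) == 0) abort("no registered devices on monitored plots",
                                class = "fm_referential_error")
  t0 <- lubridate::as_datetime(start, tz = "UTC")
  sync_hours <- seq(sync_every_h, days * 24, by = sync_every_h)
  transcript <- list()

  for (di in seq_len(nrow(devices))) {
    dev <- devices[di, ]
    key <- device_key(store, dev$device_id)
    cell <- plots[plots$device_id == dev$device_id, ]
    offset <- temp_gradient_C_per_cell * (cell$row + cell$col)

    local <- store_init(":memory:")
    store_add_device(local, dev$device_id, key, boot_time = t0,
                     capture_width = dev$capture_width,
                     capture_height = dev$capture_height)

    wx <- simulate_weather(model, days, start = start,
                           stream_id = dev$device_id, temp_offset_C = offset)
    record_readings(local, weather_to_readings(wx, dev$device_id))

    tw <- target_width %||%
      (if (dev$capture_width == 2592 && dev$capture_height == 1944) 640
       else max(1, round(dev$capture_width / 4)))
    th <- target_height %||%
      (if (dev$capture_width == 2592 && dev$capture_height == 1944) 480
       else max(1, round(dev$capture_height / 4)))

    # capture + score the day's candidates; representative chosen at day close
    day_candidates <- vector("list", days)
    for (d in seq_len(days)) {
      hours <- round(seq(9, 15, length.out = images_per_day))
      imgs <- lapply(seq_len(images_per_day), function(k) {
        pars <- with_stream_seed(
          fm_stream_seed(model$seed, dev$device_id, "capture", d, k),
          c(runif(1, 0.3, 0.9), runif(1, 0.45, 0.75))
        )
        bytes <- synth_image(dev$capture_width, dev$capture_height,
                             sharpness = pars[1], exposure = pars[2],
                             seed = fm_stream_seed(model$seed, dev$device_id, "img", d, k))
        sc <- score_image(bytes)
        ct <- t0 + ((d - 1) * 24 + hours[k]) * 3600 + (k - 1)
        store_add_image(local, dev$device_id, ct, bytes,
                        width = dev$capture_width, height = dev$capture_height,
                        mean_intensity = sc$mean_intensity, clarity = sc$clarity)
        mutate(sc, capture_time = ct, bytes = list(bytes))
      })
      day_candidates[[d]] <- bind_rows(imgs)
    }

    queue <- queue_create()
    cursor <- t0 - 1  # readings are sent strictly after the cursor
    img_cursor <- t0
    closed <- rep(FALSE, days)
    storage_total <- 64

    for (t_h in sync_hours) {
      now <- t0 + t_h * 3600
      # close any fully elapsed day: select + downsize its representative
      for (d in seq_len(days)) {
        if (!closed[d] && (t0 + d * 86400) <= now) {
          chosen <- select_representative(day_candidates[[d]])
          if (nrow(chosen) == 1) {
            small <- downsample_image(chosen$bytes[[1]], tw, th)
            sc <- score_image(small)
            store_add_image(local, dev$device_id, chosen$capture_time + 1, small,
                            width = tw, height = th,
                            mean_intensity = sc$mean_intensity,
                            clarity = sc$clarity, is_representative = TRUE)
          }
          closed[d] <- TRUE
        }
      }
      mode <- device_mode_at(faults, dev$device_id, now)
      vitals <- with_stream_seed(fm_stream_seed(model$seed, dev$device_id, "vitals", t_h),
                                 runif(2, 10, 60))
      record_status(local, dev$device_id, now, cpu_pct = vitals[1],
                    mem_pct = vitals[2],
                    storage_free_gb = max(0, storage_total - 0.02 * t_h),
                    storage_total_gb = storage_total, mode = mode)
      payload <- build_payload(local, dev$device_id, since = cursor,
                               key = key, until = now, image_since = img_cursor)
      json <- payload_serialize(payload)
      reachable <- !device_unreachable(faults, dev$device_id, now)
      rep <- enqueue_and_flush(queue, json, server, reachable, now = now)
      delivered <- rep[rep$outcome == "delivered", , drop = FALSE]
      if (nrow(delivered) > 0) {
        cursor <- max(c(cursor, delivered$ack_through), na.rm = TRUE)
        if (any(!is.na(delivered$image_ack))) {
          img_cursor <- max(c(img_cursor, delivered$image_ack), na.rm = TRUE)
        }
      }
      if (nrow(rep) > 0) {
        transcript <- c(transcript, list(mutate(rep, device_id = dev$device_id,
                                                sync_time = now)))
      }
    }
    store_close(local)
  }
  if (length(transcript) == 0) {
    return(tibble(built_at = as.POSIXct(character(0), tz = "UTC"),
                  outcome = character(0),
                  ack_through = as.POSIXct(character(0), tz = "UTC"),
                  device_id = character(0),
                  sync_time = as.POSIXct(character(0), tz = "UTC")))
  }
  bind_rows(transcript) |>
    select("device_id", "sync_time", "built_at", "outcome", "ack_through")
}

#' Standard simulated field layout
#'
#' Registers the standard fixture into a store: a rectangular grid of
#' genotype plots with a subset monitored by devices (default 16 monitored
#' among 32 plots on a 4 x 8 grid, mirroring a realistic field deployment).
#'
#' @param store an `fm_store`.
#' @param experiment_id identifier for the new experiment.
#' @param grid_rows,grid_cols grid shape.
#' @param n_monitored number of plots fitted with devices (every other
#'   plot, row-major, until the quota is reached).
#' @param start_date trial start.
#' @param seed drives the shared-key generation.
#' @param capture_width,capture_height camera resolution registered for the
#'   devices (native by default; use a smaller 4:3 size to keep large
#'   simulated runs fast).
#' @return a tibble of the registered devices (`device_id`, `plot_id`,
#'   `shared_key`).
#' @export
simulate_field_layout <- function(store, experiment_id = "exp1", grid_rows = 4,
                                  grid_cols = 8, n_monitored = 16,
                                  start_date = as.Date("2017-05-01"), seed = 1,
                                  capture_width = 2592, capture_height = 1944) {
  store_add_experiment(store, experiment_id, name = paste("Simulated trial", experiment_id),
                       latitude = 52.62, longitude = 1.22,
                       start_date = start_date, grid_rows = grid_rows,
                       grid_cols = grid_cols,
                       description = "synthetic plot-grid field trial")
  n_plots <- grid_rows * grid_cols
  monitored_idx <- seq(1, n_plots, by = max(1, floor(n_plots / n_monitored)))[seq_len(min(n_monitored, n_plots))]
  genotypes <- paste0("G", sprintf("%02d", seq_len(n_plots)))
  devs <- list()
  for (i in seq_len(n_plots)) {
    r <- (i - 1) %/% grid_cols
    cc <- (i - 1) %% grid_cols
    plot_id <- sprintf("%s-p%02d", experiment_id, i)
    dev_id <- NA
    if (i %in% monitored_idx) {
      dev_id <- sprintf("%s-dev%02d", experiment_id, which(monitored_idx == i))
    }
    store_add_plot(store, plot_id, experiment_id, r, cc,
                   genotype = genotypes[i], treatment = "control",
                   replicate = 1, drilling_date = start_date - 30,
                   device_id = dev_id)
    if (!is.na(dev_id)) {
      keybytes <- with_stream_seed(fm_stream_seed(seed, "key", dev_id),
                                   sample(0:255, 16, replace = TRUE))
      key <- paste(sprintf("%02x", keybytes), collapse = "")
      store_add_device(store, dev_id, key, plot_id = plot_id,
                       boot_time = lubridate::as_datetime(start_date, tz = "UTC"),
                       capture_width = capture_width,
                       capture_height = capture_height)
      devs <- c(devs, list(tibble(device_id = dev_id, plot_id = plot_id,
                                  shared_key = key)))
    }
  }
  bind_rows(devs)
}
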