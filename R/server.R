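# Collation server: authenticated, idempotent ingestion of sync payloads
# into the central store, device-health classification, and assembly of the
# grid / device views as JSON-able documents.

#' Create a collation server over a central store
#'
#' The server authenticates every payload against the device's registered
#' pre-shared key and ingests all-or-nothing: a malformed or unauthorized
#' payload leaves the store untouched, and replaying any accepted payload
#' changes nothing.
#'
#' @param store the central `fm_store` (or a path handed to
#'   [store_init()]).
#' @param cadence_min expected status/sensor update cadence in minutes
#'   (default 30, the shipped configuration); drives freshness
#'   classification.
#' @param amber_mult,red_mult silence thresholds as multiples of the
#'   cadence: silence beyond `amber_mult` x cadence classifies amber,
#'   beyond `red_mult` x cadence red.
#' @return an `fm_server` handle.
#' @export
server_create <- function(store, cadence_min = 30, amber_mult = 2, red_mult = 6) {
  if (is.character(store)) store <- store_init(store)
  check_store(store)
  s <- new.env(parent = emptyenv())
  s$store <- store
  s$cadence_min <- cadence_min
  s$amber_mult <- amber_mult
  s$red_mult <- red_mult
  s$log <- list()
  class(s) <- "fm_server"
  s
}

#' @export
print.fm_server <- function(x, ...) {
  cat("<fm_server> cadence", x$cadence_min, "min;", length(x$log), "ingest decision(s) logged\n")
  invisible(x)
}

server_log <- function(server, decision) {
  server$log <- c(server$log, list(decision))
  invisible(server)
}

#' Structured log of every ingest decision
#' @param server an `fm_server`.
#' @return a tibble with one row per received payload.
#' @export
server_ingest_log <- function(server) {
  if (length(server$log) == 0) {
    return(tibble(device_id = character(0), accepted = logical(0),
                  reason = character(0), readings_inserted = integer(0)))
  }
  bind_rows(lapply(server$log, as_tibble))
}

#' Authenticate a sync payload
#'
#' Accepts iff the device is registered and the payload signature verifies
#' against the registered pre-shared key over the canonical serialization.
#' Rejections never touch the store.
#'
#' @param server an `fm_server`.
#' @param payload a parsed `sync_payload` (or its JSON string).
#' @return a list `accepted` (logical) and `reason` (`"ok"`,
#'   `"unknown_device"` or `"auth_failure"`).
#' @export
authenticate_payload <- function(server, payload) {
  if (is.character(payload)) {
    payload <- tryCatch(payload_parse(payload),
                        error = function(e) NULL)
    if (is.null(payload)) return(list(accepted = FALSE, reason = "malformed"))
  }
  dev <- payload$device_id
  if (is.null(dev) || !device_exists(server$store, dev)) {
    return(list(accepted = FALSE, reason = "unknown_device"))
  }
  key <- device_key(server$store, dev)
  if (!payload_verify(payload, key)) {
    return(list(accepted = FALSE, reason = "auth_failure"))
  }
  list(accepted = TRUE, reason = "ok")
}

validate_payload_shape <- function(payload) {
  if (is.null(payload$device_id) || is.null(payload$since)) return(FALSE)
  for (r in payload$readings) {
    if (is.null(r$variable) || is.null(r$timestamp) || is.null(r$value)) return(FALSE)
    if (!r$variable %in% SENSOR_VARIABLES) return(FALSE)
  }
  if (!is.null(payload$image)) {
    im <- payload$image
    if (is.null(im$capture_time) || is.null(im$content)) return(FALSE)
  }
  if (!is.null(payload$status)) {
    st <- payload$status
    if (is.null(st$timestamp) || is.null(st$mode)) return(FALSE)
    if (!st$mode %in% DEVICE_MODES) return(FALSE)
  }
  TRUE
}

#' Ingest an authenticated payload
#'
#' All-or-nothing and idempotent: readings pass through the
#' `(device, variable, timestamp)` dedupe, the representative image is
#' stored flagged (no-op if that capture already exists), and the status
#' snapshot is appended. The acknowledgement cursor is the highest ingested
#' reading timestamp (falling back to the image capture time, then the
#' payload's own `since`), which the agent uses to advance its delta
#' cursor.
#'
#' @param server an `fm_server`.
#' @param payload a parsed, authenticated `sync_payload`.
#' @return ingest report: list with `accepted`, `readings_inserted`,
#'   `image_stored`, `status_recorded`, `ack_through` (ISO-8601).
#' @export
ingest_payload <- function(server, payload) {
  store <- server$store
  if (!validate_payload_shape(payload)) {
    return(list(accepted = FALSE, reason = "malformed",
                readings_inserted = 0L, image_stored = FALSE,
                status_recorded = FALSE, ack_through = NA_character_,
                image_ack = NA_character_))
  }
  res <- tryCatch(
    DBI::dbWithTransaction(store$con, {
      inserted <- 0L
      if (length(payload$readings) > 0) {
        rd <- tibble(
          device_id = payload$device_id,
          variable = vapply(payload$readings, `[[`, character(1), "variable"),
          timestamp = fm_time(vapply(payload$readings, `[[`, character(1), "timestamp")),
          value = vapply(payload$readings, `[[`, numeric(1), "value")
        )
        inserted <- record_readings(store, rd)
      }
      image_stored <- FALSE
      if (!is.null(payload$image)) {
        im <- payload$image
        image_stored <- store_add_image(
          store, payload$device_id, im$capture_time,
          openssl::base64_decode(im$content),
          width = im$width %||% NA, height = im$height %||% NA,
          mean_intensity = im$mean_intensity %||% NA,
          clarity = im$clarity %||% NA,
          is_representative = TRUE, format = im$format %||% "png")
      }
      status_recorded <- FALSE
      if (!is.null(payload$status)) {
        st <- payload$status
        record_status(store, payload$device_id, st$timestamp,
                      cpu_pct = st$cpu_pct %||% 0, mem_pct = st$mem_pct %||% 0,
                      storage_free_gb = st$storage_free_gb %||% 0,
                      storage_total_gb = st$storage_total_gb %||% 1,
                      mode = st$mode)
        status_recorded <- TRUE
      }
      ack <- payload$since
      if (length(payload$readings) > 0) {
        ack <- max(vapply(payload$readings, `[[`, character(1), "timestamp"))
      }
      image_ack <- if (is.null(payload$image)) NA_character_ else payload$image$capture_time
      list(accepted = TRUE, reason = "ok", readings_inserted = inserted,
           image_stored = image_stored, status_recorded = status_recorded,
           ack_through = ack, image_ack = image_ack)
    }),
    error = function(e) list(accepted = FALSE, reason = "malformed",
                             readings_inserted = 0L, image_stored = FALSE,
                             status_recorded = FALSE, ack_through = NA_character_,
                             image_ack = NA_character_)
  )
  res
}

#' Receive a payload over the wire (authenticate + ingest)
#'
#' The in-process equivalent of the sync POST endpoint: takes the JSON wire
#' document, authenticates, ingests, logs the decision, and returns the
#' acknowledgement.
#'
#' @param server an `fm_server`.
#' @param payload_json the canonical JSON wire document.
#' @return the ingest report (see [ingest_payload()]), with `reason` set on
#'   rejection.
#' @export
server_receive <- function(server, payload_json) {
  parsed <- tryCatch(payload_parse(payload_json), error = function(e) NULL)
  if (is.null(parsed)) {
    rep <- list(accepted = FALSE, reason = "malformed", readings_inserted = 0L,
                image_stored = FALSE, status_recorded = FALSE,
                ack_through = NA_character_, image_ack = NA_character_)
    server_log(server, list(device_id = NA_character_, accepted = FALSE,
                            reason = "malformed", readings_inserted = 0L))
    return(rep)
  }
  auth <- authenticate_payload(server, parsed)
  if (!auth$accepted) {
    rep <- list(accepted = FALSE, reason = auth$reason, readings_inserted = 0L,
                image_stored = FALSE, status_recorded = FALSE,
                ack_through = NA_character_, image_ack = NA_character_)
    server_log(server, list(device_id = parsed$device_id %||% NA_character_,
                            accepted = FALSE, reason = auth$reason,
                            readings_inserted = 0L))
    return(rep)
  }
  rep <- ingest_payload(server, parsed)
  server_log(server, list(device_id = parsed$device_id, accepted = rep$accepted,
                          reason = rep$reason, readings_inserted = rep$readings_inserted))
  rep
}

#' Classify a device's health as green / amber / red
#'
#' A pure function of the latest status snapshot's mode, the time since the
#' last sync, and the expected cadence: red for error/terminated mode, no
#' contact at all, or silence beyond `red_mult` x cadence; amber for idle
#' mode or silence beyond `amber_mult` x cadence; green otherwise. The
#' classification is monotone in silence — growing silence never improves
#' the color.
#'
#' @param server an `fm_server`.
#' @param device_id the device.
#' @param now classification instant.
#' @return a one-row tibble `device_id, color, reason, as_of`.
#' @export
classify_device_status <- function(server, device_id, now) {
  now <- fm_time(now)
  st <- store_status(server$store, device_id = device_id)
  mk <- function(color, reason) tibble(device_id = device_id, color = color,
                                       reason = reason, as_of = now)
  if (nrow(st) == 0) return(mk("red", "no contact from device"))
  last <- st[nrow(st), ]
  silence_min <- as.numeric(difftime(now, last$timestamp, units = "mins"))
  amber_after <- server$amber_mult * server$cadence_min
  red_after <- server$red_mult * server$cadence_min
  if (last$mode %in% c("error", "terminated")) {
    return(mk("red", paste0("device reported mode '", last$mode, "'")))
  }
  if (silence_min > red_after) {
    return(mk("red", sprintf("silent for %.0f min (> %.0f min)", silence_min, red_after)))
  }
  if (last$mode == "idle") return(mk("amber", "device reported mode 'idle'"))
  if (silence_min > amber_after) {
    return(mk("amber", sprintf("silent for %.0f min (> %.0f min)", silence_min, amber_after)))
  }
  mk("green", "operating within expected cadence")
}

#' Device uptime from boot to the latest captured image
#'
#' @param server an `fm_server` (or a bare `fm_store`).
#' @param device_id the device.
#' @return a `difftime`; zero when no images have been captured yet.
#'   A latest capture before boot raises a clock-skew error rather than
#'   being silently clamped.
#' @export
compute_uptime <- function(server, device_id) {
  store <- if (inherits(server, "fm_server")) server$store else server
  check_store(store)
  dev <- DBI::dbGetQuery(store$con,
    "SELECT boot_time FROM devices WHERE device_id = ?", params = list(device_id))
  if (nrow(dev) == 0) abort("unknown device_id", class = "fm_referential_error")
  imgs <- store_images(store, device_id = device_id)
  if (nrow(imgs) == 0) return(as.difftime(0, units = "secs"))
  latest <- max(imgs$capture_time)
  boot <- fm_time(dev$boot_time)
  if (latest < boot) {
    abort(sprintf("clock skew: latest capture %s precedes boot %s",
                  fm_iso(latest), fm_iso(boot)),
          class = "fm_clock_skew_error")
  }
  difftime(latest, boot, units = "secs")
}

#' Percentage of onboard storage left
#'
#' @param snapshot a data frame with `storage_free_gb` and
#'   `storage_total_gb` columns (e.g. a row of [store_status()]).
#' @return numeric vector in [0, 100], rounded to one decimal.
#' @export
storage_percent <- function(snapshot) {
  if (any(snapshot$storage_total_gb <= 0)) {
    abort("storage_total_gb must be positive", class = "fm_validation_error")
  }
  round(100 * snapshot$storage_free_gb / snapshot$storage_total_gb, 1)
}

#' Assemble the experiment grid view
#'
#' The overview document: experiment geolocation and a plot map with one
#' cell per grid plot carrying genotype/treatment metadata, the monitoring
#' device (if any) with its color-coded health classification, and a
#' reference to its latest daily representative image. Unmonitored plots
#' are marked as such. Assembly is read-only and deterministic: the same
#' store content always yields an identical document.
#'
#' @param server an `fm_server`.
#' @param experiment_id the experiment.
#' @param now classification instant for status colors.
#' @return a list document (serialize with [canonical_json()]); its
#'   `$plots` element is also available as a tibble via
#'   [grid_view_table()].
#' @export
assemble_grid_view <- function(server, experiment_id, now) {
  store <- server$store
  ex <- DBI::dbGetQuery(store$con,
    "SELECT * FROM experiments WHERE experiment_id = ?", params = list(experiment_id))
  if (nrow(ex) == 0) abort("unknown experiment_id", class = "fm_referential_error")
  plots <- store_plots(store, experiment_id)
  cells <- purrr::pmap(plots, function(plot_id, experiment_id, row, col, genotype,
                                       treatment, replicate, drilling_date, device_id, ...) {
    cell <- list(plot_id = plot_id, row = row, col = col, genotype = genotype,
                 treatment = treatment, replicate = replicate,
                 monitored = !is.na(device_id))
    if (!is.na(device_id)) {
      cls <- classify_device_status(server, device_id, now)
      cell$device_id <- device_id
      cell$status_color <- cls$color
      cell$status_reason <- cls$reason
      reps <- store_images(store, device_id = device_id, representative_only = TRUE)
      if (nrow(reps) > 0) {
        cell$latest_image <- fm_iso(max(reps$capture_time))
      }
    }
    cell
  })
  list(
    experiment = list(
      experiment_id = ex$experiment_id, name = ex$name,
      latitude = ex$latitude, longitude = ex$longitude,
      start_date = ex$start_date,
      grid_rows = ex$grid_rows, grid_cols = ex$grid_cols
    ),
    as_of = fm_iso(now),
    plots = cells
  )
}

#' Grid view plot map as a tibble
#' @param view a document from [assemble_grid_view()].
#' @return a tibble with one row per plot cell.
#' @export
grid_view_table <- function(view) {
  bind_rows(lapply(view$plots, function(cell) {
    tibble(
      plot_id = cell$plot_id, row = cell$row, col = cell$col,
      genotype = cell$genotype, treatment = cell$treatment,
      monitored = cell$monitored,
      device_id = cell$device_id %||% NA_character_,
      status_color = cell$status_color %||% NA_character_,
      latest_image = cell$latest_image %||% NA_character_
    )
  }))
}

#' Hourly per-variable series with explicit gaps
#'
#' Expands a device's readings onto the full hourly lattice of the
#' requested range: hours with no stored reading appear as explicit `NA`
#' markers, never fabricated values.
#'
#' @param store an `fm_store`.
#' @param device_id the device.
#' @param from,to inclusive range.
#' @return a tibble `device_id, variable, timestamp, value` with one row
#'   per hour per variable observed for the device.
#' @export
device_series <- function(store, device_id, from, to) {
  rd <- store_readings(store, device_id = device_id, from = from, to = to)
  hours <- seq(lubridate::ceiling_date(fm_time(from), "hour"),
               fm_time(to), by = "hour")
  vars <- unique(rd$variable)
  if (length(vars) == 0) vars <- character(0)
  lattice <- tidyr::expand_grid(device_id = device_id, variable = vars,
                                timestamp = hours)
  left_join(lattice, rd, by = c("device_id", "variable", "timestamp")) |>
    arrange(.data$variable, .data$timestamp)
}

#' Assemble the individual device view
#'
#' Device identity and metadata, current health classification, uptime,
#' latest storage accounting, and per-variable hourly time series over the
#' range, with gaps explicit (`NA`) rather than interpolated.
#'
#' @param server an `fm_server`.
#' @param device_id the device.
#' @param from,to inclusive display range.
#' @param now classification instant (defaults to `to`).
#' @return a list document; `$series` is a tibble from [device_series()].
#' @export
assemble_device_view <- function(server, device_id, from, to, now = to) {
  store <- server$store
  dev <- DBI::dbGetQuery(store$con,
    "SELECT device_id, plot_id, boot_time, capture_width, capture_height, mode
     FROM devices WHERE device_id = ?", params = list(device_id))
  if (nrow(dev) == 0) abort("unknown device_id", class = "fm_referential_error")
  cls <- classify_device_status(server, device_id, now)
  st <- store_status(store, device_id = device_id)
  storage <- if (nrow(st) > 0) storage_percent(st[nrow(st), ]) else NA_real_
  up <- compute_uptime(server, device_id)
  list(
    device = as.list(dev),
    status = list(color = cls$color, reason = cls$reason, as_of = fm_iso(now)),
    uptime_days = as.numeric(up, units = "days"),
    storage_free_pct = storage,
    range = list(from = fm_iso(from), to = fm_iso(to)),
    series = device_series(store, device_id, from, to)
  )
}
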