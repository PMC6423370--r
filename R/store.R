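# Relational store shared by the device agent and the collation server.
# SQLite-backed; every timestamp is a UTC ISO-8601 TEXT column, images are
# BLOBs indexed by (device, capture time).

SENSOR_VARIABLES <- c(
  "ambient_temp_C", "rel_humidity_pct", "light_lux",
  "soil_temp_C", "soil_moisture_pct", "device_temp_C"
)

DEVICE_MODES <- c("operating", "idle", "error", "terminated")

#' Open (and if needed create) a field-monitoring store
#'
#' Creates the full relational schema on first open; re-opening an existing
#' store is idempotent and loses no data. Use `":memory:"` for an ephemeral
#' store.
#'
#' @param path filesystem path of the SQLite database, or `":memory:"`.
#' @return an `fm_store` handle.
#' @export
store_init <- function(path) {
  con <- tryCatch(
    DBI::dbConnect(RSQLite::SQLite(), path),
    error = function(e) abort(
      paste0("cannot open store at '", path, "': ", conditionMessage(e)),
      class = "fm_storage_error"
    )
  )
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  stmts <- c(
    "CREATE TABLE IF NOT EXISTS experiments (
       experiment_id TEXT PRIMARY KEY,
       name TEXT NOT NULL,
       latitude REAL NOT NULL CHECK (latitude BETWEEN -90 AND 90),
       longitude REAL NOT NULL CHECK (longitude BETWEEN -180 AND 180),
       start_date TEXT NOT NULL,
       end_date TEXT,
       grid_rows INTEGER NOT NULL CHECK (grid_rows >= 1),
       grid_cols INTEGER NOT NULL CHECK (grid_cols >= 1),
       description TEXT DEFAULT '')",
    "CREATE TABLE IF NOT EXISTS plots (
       plot_id TEXT PRIMARY KEY,
       experiment_id TEXT NOT NULL REFERENCES experiments(experiment_id),
       row INTEGER NOT NULL CHECK (row >= 0),
       col INTEGER NOT NULL CHECK (col >= 0),
       genotype TEXT DEFAULT '',
       treatment TEXT DEFAULT '',
       replicate INTEGER NOT NULL DEFAULT 1 CHECK (replicate >= 1),
       drilling_date TEXT,
       device_id TEXT,
       UNIQUE (experiment_id, row, col))",
    "CREATE TABLE IF NOT EXISTS devices (
       device_id TEXT PRIMARY KEY,
       shared_key TEXT NOT NULL CHECK (length(shared_key) > 0),
       plot_id TEXT REFERENCES plots(plot_id),
       boot_time TEXT NOT NULL,
       capture_width INTEGER NOT NULL DEFAULT 2592 CHECK (capture_width > 0),
       capture_height INTEGER NOT NULL DEFAULT 1944 CHECK (capture_height > 0),
       mode TEXT NOT NULL DEFAULT 'operating')",
    "CREATE TABLE IF NOT EXISTS readings (
       device_id TEXT NOT NULL REFERENCES devices(device_id),
       variable TEXT NOT NULL,
       timestamp_utc TEXT NOT NULL,
       value REAL NOT NULL,
       PRIMARY KEY (device_id, variable, timestamp_utc))",
    "CREATE TABLE IF NOT EXISTS images (
       device_id TEXT NOT NULL REFERENCES devices(device_id),
       capture_time TEXT NOT NULL,
       width INTEGER NOT NULL,
       height INTEGER NOT NULL,
       file_size INTEGER NOT NULL,
       mean_intensity REAL,
       clarity REAL,
       is_representative INTEGER NOT NULL DEFAULT 0,
       format TEXT NOT NULL DEFAULT 'png',
       content BLOB,
       PRIMARY KEY (device_id, capture_time))",
    "CREATE TABLE IF NOT EXISTS status (
       device_id TEXT NOT NULL REFERENCES devices(device_id),
       timestamp_utc TEXT NOT NULL,
       cpu_pct REAL NOT NULL,
       mem_pct REAL NOT NULL,
       storage_free_gb REAL NOT NULL,
       storage_total_gb REAL NOT NULL CHECK (storage_total_gb > 0),
       mode TEXT NOT NULL,
       PRIMARY KEY (device_id, timestamp_utc),
       CHECK (storage_free_gb <= storage_total_gb))",
    "CREATE INDEX IF NOT EXISTS idx_readings_time ON readings (device_id, timestamp_utc)",
    "CREATE INDEX IF NOT EXISTS idx_images_rep ON images (device_id, is_representative, capture_time)"
  )
  for (s in stmts) DBI::dbExecute(con, s)
  structure(list(con = con, path = path), class = "fm_store")
}

#' @export
print.fm_store <- function(x, ...) {
  counts <- vapply(
    c("experiments", "plots", "devices", "readings", "images", "status"),
    function(tb) DBI::dbGetQuery(x$con, paste0("SELECT COUNT(*) n FROM ", tb))$n,
    numeric(1)
  )
  cat("<fm_store> ", x$path, "\n ", paste(names(counts), counts, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Close a store handle
#' @param store an `fm_store`.
#' @export
store_close <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

run_query <- function(store, sql, params = list()) {
  if (length(params) == 0) DBI::dbGetQuery(store$con, sql)
  else DBI::dbGetQuery(store$con, sql, params = params)
}

check_store <- function(store) {
  if (!inherits(store, "fm_store")) abort("expected an fm_store handle", class = "fm_store_error")
  store
}

#' Register an experiment
#'
#' @param store an `fm_store`.
#' @param experiment_id,name identifiers.
#' @param latitude,longitude decimal degrees of the trial site.
#' @param start_date,end_date calendar dates (`end_date` may be `NA` for an
#'   ongoing trial).
#' @param grid_rows,grid_cols plot-grid dimensions (row 0 is the north edge;
#'   coordinates are 0-based, row-major).
#' @param description free text.
#' @return the store, invisibly.
#' @export
store_add_experiment <- function(store, experiment_id, name, latitude, longitude,
                                 start_date, end_date = NA, grid_rows, grid_cols,
                                 description = "") {
  check_store(store)
  if (abs(latitude) > 90 || abs(longitude) > 180) {
    abort("geolocation outside valid degrees", class = "fm_validation_error")
  }
  if (grid_rows < 1 || grid_cols < 1) abort("grid dimensions must be >= 1", class = "fm_validation_error")
  if (!is.na(end_date) && as.Date(start_date) > as.Date(end_date)) {
    abort("start_date after end_date", class = "fm_validation_error")
  }
  DBI::dbExecute(store$con,
    "INSERT INTO experiments (experiment_id, name, latitude, longitude, start_date,
       end_date, grid_rows, grid_cols, description)
     VALUES (?, ?, ?, ?, ?, ?, ?, ?, ?)",
    params = list(experiment_id, name, latitude, longitude,
                  as.character(as.Date(start_date)),
                  if (is.na(end_date)) NA_character_ else as.character(as.Date(end_date)),
                  as.integer(grid_rows), as.integer(grid_cols), description))
  invisible(store)
}

#' Register a plot within an experiment grid
#'
#' @param store an `fm_store`.
#' @param plot_id,experiment_id identifiers.
#' @param row,col 0-based grid coordinates (must be unique within the
#'   experiment and inside its grid).
#' @param genotype,treatment experimental-design labels.
#' @param replicate positive biological-replicate index.
#' @param drilling_date sowing date.
#' @param device_id optional monitoring device (at most one per plot; `NA`
#'   marks an unmonitored plot).
#' @return the store, invisibly.
#' @export
store_add_plot <- function(store, plot_id, experiment_id, row, col,
                           genotype = "", treatment = "", replicate = 1,
                           drilling_date = NA, device_id = NA) {
  check_store(store)
  exp <- DBI::dbGetQuery(store$con,
    "SELECT grid_rows, grid_cols FROM experiments WHERE experiment_id = ?",
    params = list(experiment_id))
  if (nrow(exp) == 0) abort("unknown experiment_id", class = "fm_referential_error")
  if (row < 0 || row >= exp$grid_rows || col < 0 || col >= exp$grid_cols) {
    abort("plot coordinates outside the experiment grid", class = "fm_validation_error")
  }
  if (!is.na(device_id)) {
    taken <- DBI::dbGetQuery(store$con,
      "SELECT plot_id FROM plots WHERE device_id = ?", params = list(device_id))
    if (nrow(taken) > 0) abort("device already assigned to a plot", class = "fm_validation_error")
  }
  DBI::dbExecute(store$con,
    "INSERT INTO plots (plot_id, experiment_id, row, col, genotype, treatment,
       replicate, drilling_date, device_id) VALUES (?, ?, ?, ?, ?, ?, ?, ?, ?)",
    params = list(plot_id, experiment_id, as.integer(row), as.integer(col),
                  genotype, treatment, as.integer(replicate),
                  if (is.na(drilling_date)) NA_character_ else as.character(as.Date(drilling_date)),
                  if (is.na(device_id)) NA_character_ else device_id))
  invisible(store)
}

#' Register a phenotyping device
#'
#' @param store an `fm_store`.
#' @param device_id identifier.
#' @param shared_key non-empty pre-shared secret authenticating the device's
#'   sync payloads.
#' @param plot_id plot the device monitors (optional).
#' @param boot_time device boot instant (UTC).
#' @param capture_width,capture_height native camera resolution in pixels.
#' @param mode initial operational mode.
#' @return the store, invisibly.
#' @export
store_add_device <- function(store, device_id, shared_key, plot_id = NA,
                             boot_time, capture_width = 2592, capture_height = 1944,
                             mode = "operating") {
  check_store(store)
  if (!nzchar(shared_key)) abort("shared_key must be non-empty", class = "fm_validation_error")
  if (capture_width <= 0 || capture_height <= 0) {
    abort("capture dimensions must be positive", class = "fm_validation_error")
  }
  mode <- match.arg(mode, DEVICE_MODES)
  DBI::dbExecute(store$con,
    "INSERT INTO devices (device_id, shared_key, plot_id, boot_time,
       capture_width, capture_height, mode) VALUES (?, ?, ?, ?, ?, ?, ?)",
    params = list(device_id, shared_key,
                  if (is.na(plot_id)) NA_character_ else plot_id,
                  fm_iso(boot_time), as.integer(capture_width),
                  as.integer(capture_height), mode))
  invisible(store)
}

device_exists <- function(store, device_id) {
  nrow(DBI::dbGetQuery(store$con, "SELECT 1 FROM devices WHERE device_id = ?",
                       params = list(device_id))) > 0
}

#' Record sensor readings, skipping duplicates
#'
#' The dedupe key is `(device_id, variable, timestamp)` at second
#' resolution: re-submitting any reading is a silent no-op, so ingestion is
#' idempotent under payload replay.
#'
#' @param store an `fm_store`.
#' @param readings a data frame with columns `device_id`, `variable`
#'   (one of the sensor variable names), `timestamp` (POSIXct or ISO-8601
#'   string) and `value`.
#' @return the number of newly inserted readings (duplicates excluded).
#' @export
record_readings <- function(store, readings) {
  check_store(store)
  if (nrow(readings) == 0) return(0L)
  stopifnot(all(c("device_id", "variable", "timestamp", "value") %in% names(readings)))
  bad_var <- setdiff(unique(readings$variable), SENSOR_VARIABLES)
  if (length(bad_var) > 0) {
    abort(paste0("unknown sensor variable(s): ", paste(bad_var, collapse = ", ")),
          class = "fm_validation_error")
  }
  for (dev in unique(readings$device_id)) {
    if (!device_exists(store, dev)) {
      abort(paste0("unknown device_id: ", dev), class = "fm_referential_error")
    }
  }
  pct <- readings$variable %in% c("rel_humidity_pct", "soil_moisture_pct")
  if (any(readings$value[pct] < 0 | readings$value[pct] > 100)) {
    abort("percentage variables must lie in [0, 100]", class = "fm_validation_error")
  }
  before <- DBI::dbGetQuery(store$con, "SELECT COUNT(*) n FROM readings")$n
  DBI::dbExecute(store$con,
    "INSERT OR IGNORE INTO readings (device_id, variable, timestamp_utc, value)
     VALUES (?, ?, ?, ?)",
    params = list(readings$device_id, readings$variable,
                  fm_iso(readings$timestamp), as.numeric(readings$value)))
  after <- DBI::dbGetQuery(store$con, "SELECT COUNT(*) n FROM readings")$n
  as.integer(after - before)
}

#' Record a device status snapshot
#'
#' @param store an `fm_store`.
#' @param device_id device reporting.
#' @param timestamp snapshot instant (UTC).
#' @param cpu_pct,mem_pct resource usage percentages.
#' @param storage_free_gb,storage_total_gb onboard storage accounting.
#' @param mode operational mode at the snapshot.
#' @return `TRUE` if appended, `FALSE` if an identical-timestamp snapshot
#'   already existed.
#' @export
record_status <- function(store, device_id, timestamp, cpu_pct, mem_pct,
                          storage_free_gb, storage_total_gb, mode = "operating") {
  check_store(store)
  if (!device_exists(store, device_id)) abort("unknown device_id", class = "fm_referential_error")
  if (storage_free_gb > storage_total_gb) {
    abort("storage_free_gb exceeds storage_total_gb", class = "fm_validation_error")
  }
  mode <- match.arg(mode, DEVICE_MODES)
  n <- DBI::dbExecute(store$con,
    "INSERT OR IGNORE INTO status (device_id, timestamp_utc, cpu_pct, mem_pct,
       storage_free_gb, storage_total_gb, mode) VALUES (?, ?, ?, ?, ?, ?, ?)",
    params = list(device_id, fm_iso(timestamp), cpu_pct, mem_pct,
                  storage_free_gb, storage_total_gb, mode))
  DBI::dbExecute(store$con, "UPDATE devices SET mode = ? WHERE device_id = ?",
                 params = list(mode, device_id))
  n > 0
}

#' Store a captured or representative image
#'
#' Images are keyed by `(device_id, capture_time)`; re-storing the same
#' capture is a no-op (idempotent ingestion).
#'
#' @param store an `fm_store`.
#' @param device_id owning device.
#' @param capture_time capture instant (UTC).
#' @param content raw PNG/JPEG bytes.
#' @param width,height pixel dimensions.
#' @param mean_intensity,clarity quality scores (see [score_image()]).
#' @param is_representative whether this is the device's chosen daily image.
#' @param format `"png"` or `"jpeg"`.
#' @return `TRUE` if newly stored, `FALSE` if it already existed.
#' @export
store_add_image <- function(store, device_id, capture_time, content,
                            width, height, mean_intensity = NA, clarity = NA,
                            is_representative = FALSE, format = "png") {
  check_store(store)
  if (!device_exists(store, device_id)) abort("unknown device_id", class = "fm_referential_error")
  n <- DBI::dbExecute(store$con,
    "INSERT OR IGNORE INTO images (device_id, capture_time, width, height,
       file_size, mean_intensity, clarity, is_representative, format, content)
     VALUES (?, ?, ?, ?, ?, ?, ?, ?, ?, ?)",
    params = list(device_id, fm_iso(capture_time), as.integer(width),
                  as.integer(height), length(content), mean_intensity, clarity,
                  as.integer(is_representative), format, list(content)))
  n > 0
}

#' Query sensor readings as a tibble
#'
#' @param store an `fm_store`.
#' @param device_id optional device filter (vector allowed).
#' @param variable optional variable filter.
#' @param from,to optional inclusive time range.
#' @return a tibble `device_id, variable, timestamp, value` sorted by
#'   timestamp then variable.
#' @export
store_readings <- function(store, device_id = NULL, variable = NULL,
                           from = NULL, to = NULL) {
  check_store(store)
  sql <- "SELECT device_id, variable, timestamp_utc, value FROM readings WHERE 1=1"
  params <- list()
  if (!is.null(device_id)) {
    sql <- paste0(sql, " AND device_id IN (", paste(rep("?", length(device_id)), collapse = ","), ")")
    params <- c(params, as.list(device_id))
  }
  if (!is.null(variable)) {
    sql <- paste0(sql, " AND variable IN (", paste(rep("?", length(variable)), collapse = ","), ")")
    params <- c(params, as.list(variable))
  }
  if (!is.null(from)) { sql <- paste0(sql, " AND timestamp_utc >= ?"); params <- c(params, fm_iso(from)) }
  if (!is.null(to))   { sql <- paste0(sql, " AND timestamp_utc <= ?"); params <- c(params, fm_iso(to)) }
  sql <- paste0(sql, " ORDER BY timestamp_utc, variable, device_id")
  df <- run_query(store, sql, params)
  tibble(
    device_id = df$device_id, variable = df$variable,
    timestamp = fm_time(df$timestamp_utc), value = df$value
  )
}

#' Query image metadata as a tibble
#'
#' @inheritParams store_readings
#' @param representative_only keep only daily representative images.
#' @return a tibble of image metadata (no pixel content), time-sorted.
#' @export
store_images <- function(store, device_id = NULL, from = NULL, to = NULL,
                         representative_only = FALSE) {
  check_store(store)
  sql <- "SELECT device_id, capture_time, width, height, file_size,
            mean_intensity, clarity, is_representative, format
          FROM images WHERE 1=1"
  params <- list()
  if (!is.null(device_id)) { sql <- paste0(sql, " AND device_id = ?"); params <- c(params, device_id) }
  if (!is.null(from)) { sql <- paste0(sql, " AND capture_time >= ?"); params <- c(params, fm_iso(from)) }
  if (!is.null(to))   { sql <- paste0(sql, " AND capture_time <= ?"); params <- c(params, fm_iso(to)) }
  if (representative_only) sql <- paste0(sql, " AND is_representative = 1")
  sql <- paste0(sql, " ORDER BY capture_time, device_id")
  df <- run_query(store, sql, params)
  tibble(
    device_id = df$device_id, capture_time = fm_time(df$capture_time),
    width = df$width, height = df$height, file_size = df$file_size,
    mean_intensity = df$mean_intensity, clarity = df$clarity,
    is_representative = as.logical(df$is_representative), format = df$format
  )
}

#' Fetch one stored image's bytes
#'
#' @param store an `fm_store`.
#' @param device_id,capture_time image key.
#' @return raw vector of encoded image bytes, or `NULL` if absent.
#' @export
store_image_content <- function(store, device_id, capture_time) {
  df <- DBI::dbGetQuery(store$con,
    "SELECT content FROM images WHERE device_id = ? AND capture_time = ?",
    params = list(device_id, fm_iso(capture_time)))
  if (nrow(df) == 0) return(NULL)
  df$content[[1]]
}

#' Query status snapshots as a tibble
#' @inheritParams store_readings
#' @return tibble of snapshots, time-sorted.
#' @export
store_status <- function(store, device_id = NULL, from = NULL, to = NULL) {
  check_store(store)
  sql <- "SELECT * FROM status WHERE 1=1"
  params <- list()
  if (!is.null(device_id)) { sql <- paste0(sql, " AND device_id = ?"); params <- c(params, device_id) }
  if (!is.null(from)) { sql <- paste0(sql, " AND timestamp_utc >= ?"); params <- c(params, fm_iso(from)) }
  if (!is.null(to))   { sql <- paste0(sql, " AND timestamp_utc <= ?"); params <- c(params, fm_iso(to)) }
  sql <- paste0(sql, " ORDER BY timestamp_utc")
  df <- run_query(store, sql, params)
  tibble(
    device_id = df$device_id, timestamp = fm_time(df$timestamp_utc),
    cpu_pct = df$cpu_pct, mem_pct = df$mem_pct,
    storage_free_gb = df$storage_free_gb, storage_total_gb = df$storage_total_gb,
    mode = df$mode
  )
}

#' List experiments / plots / devices
#' @param store an `fm_store`.
#' @return a tibble.
#' @export
store_experiments <- function(store) {
  check_store(store)
  as_tibble(DBI::dbGetQuery(store$con, "SELECT * FROM experiments ORDER BY experiment_id"))
}

#' @rdname store_experiments
#' @param experiment_id optional experiment filter.
#' @export
store_plots <- function(store, experiment_id = NULL) {
  check_store(store)
  if (is.null(experiment_id)) {
    df <- DBI::dbGetQuery(store$con, "SELECT * FROM plots ORDER BY experiment_id, row, col")
  } else {
    df <- DBI::dbGetQuery(store$con,
      "SELECT * FROM plots WHERE experiment_id = ? ORDER BY row, col",
      params = list(experiment_id))
  }
  as_tibble(df)
}

#' @rdname store_experiments
#' @export
store_devices <- function(store) {
  check_store(store)
  df <- DBI::dbGetQuery(store$con,
    "SELECT device_id, plot_id, boot_time, capture_width, capture_height, mode
     FROM devices ORDER BY device_id")
  as_tibble(df)
}

device_key <- function(store, device_id) {
  df <- DBI::dbGetQuery(store$con,
    "SELECT shared_key FROM devices WHERE device_id = ?", params = list(device_id))
  if (nrow(df) == 0) return(NULL)
  df$shared_key[1]
}

# Checksum of all store content; used to prove read-only purity of views.
store_checksum <- function(store) {
  parts <- vapply(
    c("experiments", "plots", "devices", "readings", "status"),
    function(tb) canonical_json(as.list(DBI::dbGetQuery(store$con, paste0("SELECT * FROM ", tb)))),
    character(1)
  )
  imgs <- DBI::dbGetQuery(store$con,
    "SELECT device_id, capture_time, file_size, is_representative FROM images ORDER BY device_id, capture_time")
  as.character(openssl::sha256(charToRaw(paste(c(parts, canonical_json(as.list(imgs))), collapse = "|"))))
}
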