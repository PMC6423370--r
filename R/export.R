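# Standard-format exports. Both are pure functions of store content: two
# stores with identical content yield byte-identical documents (fixed CSV
# dialect; fixed zip compression level and pinned entry mtimes).

#' Export a device's sensor readings as CSV
#'
#' Dialect: comma separator, header
#' `device_id,variable,timestamp_utc,value`, LF line endings, `.` decimal
#' point, UTC ISO-8601 timestamps. Rows are sorted by timestamp then
#' variable, and values are printed with enough digits that parsing the CSV
#' reproduces the stored readings exactly.
#'
#' @param store an `fm_store`.
#' @param device_id device to export.
#' @param from,to optional inclusive time range; an empty range yields a
#'   header-only CSV.
#' @param path optional file to write; when `NULL` the CSV is returned as a
#'   single string.
#' @return the CSV text (invisibly when written to `path`).
#' @export
export_sensor_csv <- function(store, device_id, from = NULL, to = NULL, path = NULL) {
  check_store(store)
  if (!device_exists(store, device_id)) abort("unknown device_id", class = "fm_referential_error")
  rd <- store_readings(store, device_id = device_id, from = from, to = to)
  header <- "device_id,variable,timestamp_utc,value"
  if (nrow(rd) == 0) {
    body <- character(0)
  } else {
    rd <- arrange(rd, .data$timestamp, .data$variable)
    body <- paste(rd$device_id, rd$variable, fm_iso(rd$timestamp),
                  sprintf("%.17g", rd$value), sep = ",")
  }
  txt <- paste0(paste(c(header, body), collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, "wb"); on.exit(close(con))
    writeChar(txt, con, eos = NULL)
    return(invisible(txt))
  }
  txt
}

#' Parse a sensor CSV back into a readings tibble
#'
#' Inverse of [export_sensor_csv()]; useful for round-trip checks and for
#' re-importing downloaded data.
#'
#' @param text CSV text, or a file path.
#' @return a tibble `device_id, variable, timestamp, value`.
#' @export
parse_sensor_csv <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text), collapse = "\n")
  }
  df <- utils::read.csv(text = text, stringsAsFactors = FALSE)
  tibble(
    device_id = as.character(df$device_id), variable = as.character(df$variable),
    timestamp = if (nrow(df)) fm_time(df$timestamp_utc) else fm_time(character(0)),
    value = as.numeric(df$value)
  )
}

#' Export a month of images as a Zip archive
#'
#' Archives every stored image whose capture time falls within the given
#' calendar month (UTC). Entries are named
#' `<device_id>/<YYYYMMDDTHHMMSSZ>.<ext>` and round-trip byte-exact. Entry
#' modification times are pinned and the compression level is fixed, so the
#' archive bytes depend only on store content.
#'
#' @param store an `fm_store`.
#' @param device_id device to export.
#' @param year,month calendar month (UTC).
#' @param path output `.zip` path.
#' @return `path`, invisibly; the archive is empty (but valid) for a month
#'   with no images.
#' @export
export_monthly_archive <- function(store, device_id, year, month, path) {
  check_store(store)
  if (!device_exists(store, device_id)) abort("unknown device_id", class = "fm_referential_error")
  from <- lubridate::make_datetime(year, month, 1, tz = "UTC")
  to <- lubridate::add_with_rollback(from, months(1)) - lubridate::seconds(1)
  meta <- DBI::dbGetQuery(store$con,
    "SELECT capture_time, format FROM images
     WHERE device_id = ? AND capture_time >= ? AND capture_time <= ?
     ORDER BY capture_time",
    params = list(device_id, fm_iso(from), fm_iso(to)))
  staging <- tempfile("fm_zip_")
  dir.create(file.path(staging, device_id), recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE))
  entries <- character(0)
  for (i in seq_len(nrow(meta))) {
    ext <- if (meta$format[i] == "jpeg") "jpg" else meta$format[i]
    entry <- file.path(device_id, paste0(fm_compact_ts(meta$capture_time[i]), ".", ext))
    bytes <- store_image_content(store, device_id, meta$capture_time[i])
    writeBin(bytes, file.path(staging, entry))
    entries <- c(entries, entry)
  }
  # pin mtimes so archive bytes are a pure function of content
  epoch <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  for (e in c(device_id, entries)) Sys.setFileTime(file.path(staging, e), epoch)
  if (length(entries) == 0) {
    # a valid empty zip: just the end-of-central-directory record
    writeBin(as.raw(c(0x50, 0x4b, 0x05, 0x06, rep(0x00, 18))), path)
    return(invisible(path))
  }
  zip::zip(zipfile = file.path(normalizePath(dirname(path)), basename(path)),
           files = device_id, root = staging, compression_level = 6,
           mode = "cherry-pick")
  invisible(path)
}

#' List or extract a monthly archive
#'
#' @param path a `.zip` archive written by [export_monthly_archive()].
#' @param exdir directory to extract into.
#' @return `archive_entries()`: a tibble of entry names and sizes;
#'   `archive_extract()`: the extraction directory, invisibly.
#' @export
archive_entries <- function(path) {
  info <- file.info(path)
  if (info$size <= 22) return(tibble(filename = character(0), uncompressed_size = numeric(0)))
  zl <- zip::zip_list(path)
  files <- !grepl("/$", zl$filename)
  tibble(filename = zl$filename[files],
         uncompressed_size = zl$uncompressed_size[files])
}

#' @rdname archive_entries
#' @export
archive_extract <- function(path, exdir) {
  info <- file.info(path)
  if (info$size > 22) zip::unzip(path, exdir = exdir)
  invisible(exdir)
}
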