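# Time handling: everything stored and emitted in UTC ISO-8601 at second
# resolution; deduplication equality is at second resolution.

#' Format a timestamp as UTC ISO-8601
#'
#' @param t a POSIXct vector (any timezone) or something coercible.
#' @return character vector like `"2017-05-01T06:00:00Z"`.
#' @export
fm_iso <- function(t) {
  t <- fm_time(t)
  format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Parse timestamps to POSIXct UTC
#'
#' Accepts POSIXct, ISO-8601 strings (`"2017-05-01T06:00:00Z"` or with a
#' space separator), or Date (midnight UTC). Sub-second precision is
#' truncated.
#'
#' @param x input vector.
#' @return POSIXct in UTC, floored to whole seconds.
#' @export
fm_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    out <- lubridate::with_tz(x, "UTC")
  } else if (inherits(x, "Date")) {
    out <- lubridate::as_datetime(x, tz = "UTC")
  } else if (is.character(x)) {
    out <- as.POSIXct(gsub("T", " ", sub("Z$", "", x)), tz = "UTC")
    if (anyNA(out) && !anyNA(x)) {
      abort("unparseable timestamp(s); expected UTC ISO-8601", class = "fm_time_error")
    }
  } else {
    abort("cannot interpret as a timestamp", class = "fm_time_error")
  }
  lubridate::floor_date(out, "second")
}

# Compact timestamp used in archive entry names: 20170501T060000Z
fm_compact_ts <- function(t) format(fm_time(t), "%Y%m%dT%H%M%SZ", tz = "UTC")

#' Derive an independent RNG seed for a named stream
#'
#' Each (device, variable) pair draws from its own pseudo-random stream so
#' that adding a device or variable never perturbs any other stream. The
#' stream seed is a deterministic hash of the master seed and the stream
#' labels, kept below 2^31.
#'
#' @param master integer master seed.
#' @param ... character labels identifying the stream.
#' @return a single integer seed.
#' @export
fm_stream_seed <- function(master, ...) {
  labels <- paste(c(format(master), ...), collapse = "\x1f")
  bytes <- utf8ToInt(labels)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483587
  as.integer(h + 1L)
}

# Run code with a local RNG state seeded from `seed`, restoring the global
# state afterwards so library callers are never perturbed.
with_stream_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
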