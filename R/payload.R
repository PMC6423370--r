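# Sync payloads: the single signed JSON document a device POSTs to the
# collation server — latest status, all readings since the cursor, and the
# newest not-yet-acknowledged daily representative image. Signed with
# HMAC-SHA-256 over the canonical serialization.

#' Build a device's sync payload
#'
#' Assembles the delta since the last acknowledged instant from the
#' device's local store: the latest status snapshot, every reading strictly
#' after `since`, and the newest representative image captured after
#' `since`. The payload is signed with the device's pre-shared key.
#'
#' @param store the device-side `fm_store`.
#' @param device_id the device.
#' @param since the last acknowledged instant (readings included are
#'   strictly after it).
#' @param key the pre-shared secret; defaults to the key registered in the
#'   local store.
#' @param until optional upper bound: only data at or before this instant
#'   is included (used by the simulator so a payload built "at" time t
#'   never contains the future).
#' @param image_since separate acknowledgement cursor for representative
#'   images (defaults to `since`): the payload carries the newest
#'   representative captured after it. Kept separate because the readings
#'   cursor can overtake a day's image capture time.
#' @return a `sync_payload` list (see [payload_serialize()]).
#' @export
build_payload <- function(store, device_id, since, key = NULL, until = NULL,
                          image_since = since) {
  check_store(store)
  if (!device_exists(store, device_id)) abort("unknown device_id", class = "fm_referential_error")
  key <- key %||% device_key(store, device_id)
  since <- fm_time(since)

  st <- store_status(store, device_id = device_id, to = until)
  status <- NULL
  if (nrow(st) > 0) {
    last <- st[nrow(st), ]
    status <- list(
      timestamp = fm_iso(last$timestamp), cpu_pct = last$cpu_pct,
      mem_pct = last$mem_pct, storage_free_gb = last$storage_free_gb,
      storage_total_gb = last$storage_total_gb, mode = last$mode
    )
  }

  rd <- store_readings(store, device_id = device_id, to = until)
  rd <- rd[rd$timestamp > since, , drop = FALSE]
  readings <- purrr::pmap(
    list(rd$variable, fm_iso(rd$timestamp), rd$value),
    function(v, t, x) list(variable = v, timestamp = t, value = x)
  )

  reps <- store_images(store, device_id = device_id, to = until,
                       representative_only = TRUE)
  reps <- reps[reps$capture_time > fm_time(image_since), , drop = FALSE]
  image <- NULL
  if (nrow(reps) > 0) {
    newest <- reps[nrow(reps), ]
    bytes <- store_image_content(store, device_id, newest$capture_time)
    image <- list(
      capture_time = fm_iso(newest$capture_time),
      width = newest$width, height = newest$height,
      file_size = newest$file_size, mean_intensity = newest$mean_intensity,
      clarity = newest$clarity, format = newest$format,
      content = openssl::base64_encode(bytes)
    )
  }

  payload <- list(device_id = device_id, since = fm_iso(since),
                  status = status, readings = readings)
  if (!is.null(image)) payload$image <- image
  payload_sign(payload, key)
}

payload_body_json <- function(payload) {
  payload$signature <- NULL
  payload <- payload[!vapply(payload, is.null, logical(1))]
  canonical_json(payload)
}

#' Sign / verify / serialize sync payloads
#'
#' The signature is the HMAC-SHA-256 hex digest of the canonical JSON
#' serialization of every other field, keyed by the device's pre-shared
#' secret. Verification fails if any byte of the body was tampered with or
#' if the key differs.
#'
#' @param payload a `sync_payload` list.
#' @param key the pre-shared secret.
#' @return `payload_sign()`: the payload with a `signature` field;
#'   `payload_verify()`: `TRUE`/`FALSE`; `payload_serialize()`: the
#'   canonical JSON wire document; `payload_parse()`: the list parsed back
#'   from JSON.
#' @export
payload_sign <- function(payload, key) {
  payload$signature <- fm_hmac(payload_body_json(payload), key)
  structure(payload, class = "sync_payload")
}

#' @rdname payload_sign
#' @export
payload_verify <- function(payload, key) {
  if (is.null(payload$signature)) return(FALSE)
  identical(fm_hmac(payload_body_json(payload), key), payload$signature)
}

#' @rdname payload_sign
#' @export
payload_serialize <- function(payload) {
  canonical_json(payload[!vapply(payload, is.null, logical(1))])
}

#' @rdname payload_sign
#' @param json a JSON wire document.
#' @export
payload_parse <- function(json) {
  out <- tryCatch(jsonlite::fromJSON(json, simplifyVector = FALSE),
                  error = function(e) abort("malformed payload document",
                                            class = "fm_malformed_error"))
  structure(out, class = "sync_payload")
}

#' @export
print.sync_payload <- function(x, ...) {
  cat("<sync_payload>", x$device_id, "since", x$since, "-",
      length(x$readings), "readings,",
      if (is.null(x$image)) "no image" else "1 image", "\n")
  invisible(x)
}
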