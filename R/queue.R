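# Store-and-forward buffering: during a network outage outbound payloads
# are held in a FIFO queue (emulating the onboard memory stick, default
# 60-day retention) and drained oldest-first once connectivity returns.

#' Create a store-and-forward queue
#'
#' @param retention_days payloads older than this are dropped, never
#'   delivered (default 60 days of onboard buffering).
#' @param capacity maximum number of buffered payloads; when full the
#'   oldest entries are evicted first.
#' @return an `fm_queue` handle.
#' @export
queue_create <- function(retention_days = 60, capacity = Inf) {
  q <- new.env(parent = emptyenv())
  q$entries <- list()
  q$retention_days <- retention_days
  q$capacity <- capacity
  class(q) <- "fm_queue"
  q
}

#' @export
print.fm_queue <- function(x, ...) {
  cat("<fm_queue>", length(x$entries), "buffered payload(s), retention",
      x$retention_days, "days\n")
  invisible(x)
}

#' Number of buffered payloads
#' @param queue an `fm_queue`.
#' @export
queue_length <- function(queue) length(queue$entries)

queue_push <- function(queue, json, built_at) {
  if (length(queue$entries) >= queue$capacity) {
    warn("store-and-forward queue full; evicting oldest payload")
    queue$entries <- queue$entries[-1]
  }
  queue$entries <- c(queue$entries, list(list(json = json, built_at = fm_time(built_at))))
  invisible(queue)
}

#' Buffer a payload and flush the queue when the server is reachable
#'
#' Implements the store-and-forward contract: while the server is
#' unreachable payloads accumulate in FIFO order; on reconnection the
#' backlog is drained oldest-first, then the current payload is sent.
#' Entries older than the retention horizon are dropped with a warning and
#' never delivered. Delivery reports carry the server's acknowledgement
#' cursor so the agent can advance `since`.
#'
#' @param queue an [queue_create()] handle.
#' @param payload_json the current payload as serialized JSON (`NULL` if
#'   there is nothing new to send this cycle).
#' @param server an `fm_server` (see [server_create()]).
#' @param reachable whether the network is up this cycle.
#' @param now current instant (drives retention).
#' @param built_at when the current payload was assembled (defaults `now`).
#' @return a tibble delivery report: one row per payload handled with
#'   `built_at`, `outcome` (`delivered`, `queued`, `dropped_expired`,
#'   `rejected`) and `ack_through` (UTC, `NA` unless delivered).
#' @export
enqueue_and_flush <- function(queue, payload_json, server, reachable,
                              now, built_at = now) {
  now <- fm_time(now)
  report <- list()
  horizon <- now - queue$retention_days * 86400

  keep <- list()
  for (e in queue$entries) {
    if (e$built_at < horizon) {
      warn(paste0("dropping payload built ", fm_iso(e$built_at),
                  ": older than the ", queue$retention_days, "-day retention horizon"))
      report <- c(report, list(tibble(built_at = e$built_at,
                                      outcome = "dropped_expired",
                                      ack_through = as.POSIXct(NA, tz = "UTC"),
                                      image_ack = as.POSIXct(NA, tz = "UTC"))))
    } else keep <- c(keep, list(e))
  }
  queue$entries <- keep

  deliver <- function(e) {
    res <- server_receive(server, e$json)
    if (isTRUE(res$accepted)) {
      tibble(built_at = e$built_at, outcome = "delivered",
             ack_through = fm_time(res$ack_through),
             image_ack = if (is.na(res$image_ack)) as.POSIXct(NA, tz = "UTC")
                         else fm_time(res$image_ack))
    } else {
      warn(paste0("server rejected buffered payload (", res$reason, "); discarding"))
      tibble(built_at = e$built_at, outcome = "rejected",
             ack_through = as.POSIXct(NA, tz = "UTC"),
             image_ack = as.POSIXct(NA, tz = "UTC"))
    }
  }

  if (!reachable) {
    if (!is.null(payload_json)) {
      queue_push(queue, payload_json, built_at)
      report <- c(report, list(tibble(built_at = fm_time(built_at),
                                      outcome = "queued",
                                      ack_through = as.POSIXct(NA, tz = "UTC"),
                                      image_ack = as.POSIXct(NA, tz = "UTC"))))
    }
  } else {
    while (length(queue$entries) > 0) {
      e <- queue$entries[[1]]
      queue$entries <- queue$entries[-1]
      report <- c(report, list(deliver(e)))
    }
    if (!is.null(payload_json)) {
      report <- c(report, list(deliver(list(json = payload_json,
                                            built_at = fm_time(built_at)))))
    }
  }
  if (length(report) == 0) {
    return(tibble(built_at = as.POSIXct(character(0), tz = "UTC"),
                  outcome = character(0),
                  ack_through = as.POSIXct(character(0), tz = "UTC"),
                  image_ack = as.POSIXct(character(0), tz = "UTC")))
  }
  bind_rows(report)
}
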