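#' Device-agent configuration
#'
#' The shipped defaults mirror the deployed cadences: payloads are built
#' and synchronized hourly, status/sensor updates refresh every 30
#' minutes, and the store-and-forward buffer retains 60 days of data.
#'
#' @param device_id,shared_key device identity and pre-shared secret.
#' @param sync_cadence_h hours between payload builds/syncs.
#' @param status_cadence_min minutes between status/sensor updates.
#' @param retention_days store-and-forward retention horizon.
#' @param target_width,target_height representative-image transmission
#'   resolution in pixels.
#' @return an `agent_config` list.
#' @export
agent_config <- function(device_id = NULL, shared_key = NULL,
                         sync_cadence_h = 1, status_cadence_min = 30,
                         retention_days = 60, target_width = 640,
                         target_height = 480) {
  structure(list(device_id = device_id, shared_key = shared_key,
                 sync_cadence_h = sync_cadence_h,
                 status_cadence_min = status_cadence_min,
                 retention_days = retention_days,
                 target_width = target_width, target_height = target_height),
            class = "agent_config")
}
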