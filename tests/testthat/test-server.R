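server_world <- function() {
  srv <- server_create(":memory:")
  store_add_experiment(srv$store, "e1", "trial", 52.62, 1.22, "2017-05-01", NA, 2, 2)
  store_add_plot(srv$store, "p1", "e1", 0, 0, genotype = "G01", device_id = "d1")
  store_add_plot(srv$store, "p2", "e1", 0, 1, genotype = "G02")
  store_add_plot(srv$store, "p3", "e1", 1, 0, genotype = "G03")
  store_add_plot(srv$store, "p4", "e1", 1, 1, genotype = "G04")
  store_add_device(srv$store, "d1", "key-one", plot_id = "p1",
                   boot_time = "2017-05-01T00:00:00Z",
                   capture_width = 160, capture_height = 120)
  srv
}

signed_payload_json <- function(with_image = TRUE) {
  st <- make_test_store()
  record_readings(st, hourly_readings("d1"))
  record_status(st, "d1", "2017-05-02T00:00:00Z", 20, 30, 8, 32)
  if (with_image) {
    img <- checkerboard_image()
    sc <- score_image(img)
    store_add_image(st, "d1", "2017-05-01T12:00:00Z", img, 32, 24,
                    sc$mean_intensity, sc$clarity, is_representative = TRUE)
  }
  out <- payload_serialize(build_payload(st, "d1", since = UTC("2017-05-01 00:00:00") - 1))
  store_close(st)
  out
}

test_that("authentication accepts valid payloads and rejects tampering and bad keys", {
  srv <- server_world()
  json <- signed_payload_json()
  expect_identical(authenticate_payload(srv, json)$reason, "ok")

  tampered <- sub('"value":15', '"value":16', json)
  expect_identical(authenticate_payload(srv, tampered)$reason, "auth_failure")

  wrong <- server_world()
  DBI::dbExecute(wrong$store$con, "UPDATE devices SET shared_key = 'other'")
  expect_identical(authenticate_payload(wrong, json)$reason, "auth_failure")

  unknown <- payload_parse(json)
  unknown$device_id <- "ghost"
  expect_identical(authenticate_payload(srv, unknown)$reason, "unknown_device")
})

test_that("rejected payloads leave the store untouched", {
  srv <- server_world()
  before <- fieldmon:::store_checksum(srv$store)
  json <- signed_payload_json()
  server_receive(srv, sub('"value":15', '"value":16', json))   # tampered
  server_receive(srv, "not json at all{{")                     # malformed
  expect_identical(fieldmon:::store_checksum(srv$store), before)
  log <- server_ingest_log(srv)
  expect_identical(log$reason, c("auth_failure", "malformed"))
})

test_that("ingestion reports counts and replaying any payload changes nothing", {
  srv <- server_world()
  json <- signed_payload_json()
  r1 <- server_receive(srv, json)
  expect_true(r1$accepted)
  expect_identical(r1$readings_inserted, 24L)
  expect_true(r1$image_stored)
  expect_true(r1$status_recorded)
  expect_identical(r1$ack_through, "2017-05-01T23:00:00Z")

  after_first <- fieldmon:::store_checksum(srv$store)
  r2 <- server_receive(srv, json)      # replay
  expect_true(r2$accepted)
  expect_identical(r2$readings_inserted, 0L)
  expect_false(r2$image_stored)
  expect_identical(fieldmon:::store_checksum(srv$store), after_first)

  # empty-delta payload: status only
  r3 <- server_receive(srv, signed_payload_json(with_image = FALSE))
  expect_true(r3$accepted && r3$status_recorded)
})

test_that("idempotency holds for any replay-augmented payload sequence", {
  base <- list(signed_payload_json(), signed_payload_json(with_image = FALSE))
  run_seq <- function(seqn) {
    srv <- server_world()
    for (j in seqn) server_receive(srv, j)
    fieldmon:::store_checksum(srv$store)
  }
  plain <- run_seq(base)
  set.seed(4)
  for (i in 1:5) {
    augmented <- c(base, sample(base, 4, replace = TRUE))
    expect_identical(run_seq(augmented), plain)
  }
})

test_that("status classification follows mode and silence thresholds", {
  srv <- server_world()    # cadence 30 min -> amber > 60 min, red > 180 min
  t0 <- "2017-05-01T12:00:00Z"
  record_status(srv$store, "d1", t0, 20, 30, 8, 32, "operating")

  expect_identical(classify_device_status(srv, "d1", "2017-05-01T12:10:00Z")$color, "green")
  # silence exactly 3 x cadence = 90 min: between amber_after and red_after
  expect_identical(classify_device_status(srv, "d1", "2017-05-01T13:30:00Z")$color, "amber")
  expect_identical(classify_device_status(srv, "d1", "2017-05-01T18:01:00Z")$color, "red")

  record_status(srv$store, "d1", "2017-05-01T13:00:00Z", 20, 30, 8, 32, "idle")
  expect_identical(classify_device_status(srv, "d1", "2017-05-01T13:05:00Z")$color, "amber")

  record_status(srv$store, "d1", "2017-05-01T14:00:00Z", 20, 30, 8, 32, "error")
  expect_identical(classify_device_status(srv, "d1", "2017-05-01T14:01:00Z")$color, "red")

  srv2 <- server_world()   # no snapshot at all -> red
  expect_identical(classify_device_status(srv2, "d1", t0)$color, "red")
})

test_that("growing silence never improves the status color", {
  srv <- server_world()
  record_status(srv$store, "d1", "2017-05-01T00:00:00Z", 20, 30, 8, 32, "operating")
  rank <- c(green = 1, amber = 2, red = 3)
  colors <- vapply(seq(0, 600, by = 10), function(m) {
    classify_device_status(srv, "d1", UTC("2017-05-01 00:00:00") + m * 60)$color
  }, character(1))
  expect_true(all(diff(rank[colors]) >= 0))
})

test_that("uptime runs from boot to the latest capture and guards clock skew", {
  srv <- server_world()
  expect_equal(as.numeric(compute_uptime(srv, "d1")), 0)   # no images yet
  store_add_image(srv$store, "d1", "2017-05-06T00:00:00Z", flat_image(), 32, 24)
  expect_equal(as.numeric(compute_uptime(srv, "d1"), units = "days"), 5)

  skewed <- server_world()
  store_add_image(skewed$store, "d1", "2017-04-30T23:00:00Z", flat_image(), 32, 24)
  expect_error(compute_uptime(skewed, "d1"), class = "fm_clock_skew_error")
})

test_that("storage percentage is free/total rounded to one decimal", {
  snap <- tibble::tibble(storage_free_gb = c(8, 32, 0, 10),
                         storage_total_gb = c(32, 32, 32, 3))
  expect_identical(storage_percent(snap), c(25.0, 100.0, 0.0, 333.3))
  expect_error(storage_percent(tibble::tibble(storage_free_gb = 0, storage_total_gb = 0)),
               class = "fm_validation_error")
})

test_that("the grid view maps every plot with status and image references", {
  srv <- server_world()
  record_status(srv$store, "d1", "2017-05-02T00:00:00Z", 20, 30, 8, 32, "operating")
  store_add_image(srv$store, "d1", "2017-05-01T12:00:00Z", flat_image(), 32, 24,
                  is_representative = TRUE)
  now <- "2017-05-02T00:10:00Z"
  view <- assemble_grid_view(srv, "e1", now)
  tab <- grid_view_table(view)
  expect_equal(nrow(tab), 4)
  expect_equal(sum(tab$monitored), 1)
  expect_identical(tab$status_color[tab$plot_id == "p1"], "green")
  expect_identical(tab$latest_image[tab$plot_id == "p1"], "2017-05-01T12:00:00Z")
  expect_true(all(is.na(tab$status_color[tab$plot_id != "p1"])))

  # error mode propagates red into the cell
  record_status(srv$store, "d1", "2017-05-02T00:05:00Z", 20, 30, 8, 32, "error")
  tab2 <- grid_view_table(assemble_grid_view(srv, "e1", now))
  expect_identical(tab2$status_color[tab2$plot_id == "p1"], "red")
})

test_that("view assembly is pure: identical documents, store untouched", {
  srv <- server_world()
  record_status(srv$store, "d1", "2017-05-02T00:00:00Z", 20, 30, 8, 32, "operating")
  before <- fieldmon:::store_checksum(srv$store)
  now <- "2017-05-02T00:10:00Z"
  j1 <- canonical_json(assemble_grid_view(srv, "e1", now))
  j2 <- canonical_json(assemble_grid_view(srv, "e1", now))
  expect_identical(j1, j2)
  expect_identical(fieldmon:::store_checksum(srv$store), before)
})

test_that("the device view exposes hourly series with explicit gaps", {
  srv <- server_world()
  rd <- hourly_readings("d1", n = 48)
  rd <- rd[-(25:27), ]  # a 3-hour gap on day 2
  record_readings(srv$store, rd)
  record_status(srv$store, "d1", "2017-05-02T23:00:00Z", 20, 30, 8, 32)
  view <- assemble_device_view(srv, "d1", from = "2017-05-01T00:00:00Z",
                               to = "2017-05-02T23:00:00Z")
  s <- view$series
  expect_equal(nrow(s), 48)                 # full hourly lattice
  expect_equal(sum(is.na(s$value)), 3)      # the gap is explicit, not filled
  expect_equal(view$storage_free_pct, 25.0)

  # a range before any data is an empty but valid document
  early <- assemble_device_view(srv, "d1", from = "2016-01-01T00:00:00Z",
                                to = "2016-01-02T00:00:00Z",
                                now = "2017-05-02T23:10:00Z")
  expect_equal(nrow(early$series), 0)
})
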