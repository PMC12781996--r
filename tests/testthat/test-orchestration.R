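# Broker semantics, schedules, the device scheduler, metadata and uploads.

test_that("topic matching follows MQTT wildcard semantics", {
  expect_true(topic_matches("a/+", "a/b"))
  expect_false(topic_matches("a/+", "a/b/c"))
  expect_true(topic_matches("a/#", "a/b/c"))
  expect_true(topic_matches("a/#", "a"))
  expect_true(topic_matches("+/jobs/#", "pump/jobs/feed/now"))
  expect_false(topic_matches("a/b", "a/c"))
  expect_error(topic_matches("a/#/b", "a/x/b"), "final level")
  expect_error(inproc_broker()$publish("a/+"), "wildcards")
})

test_that("the broker delivers to every matching subscription", {
  br <- inproc_broker()
  got <- list()
  br$subscribe("rig/+/status", function(t, p) got[[length(got) + 1]] <<- t)
  br$subscribe("rig/#", function(t, p) got[[length(got) + 1]] <<- t)
  n <- br$publish("rig/pump/status", "ok")
  expect_equal(n, 2)
  expect_length(got, 2)
  expect_equal(br$publish("other/topic"), 0)
})

test_that("devices refuse undeclared commands", {
  br <- inproc_broker()
  dev <- device_connect(br, "pump", c("feed", "aspirate"))
  br$publish("devices/pump/jobs", job_request("devices/pump/jobs", "feed"))
  br$publish("devices/pump/jobs", job_request("devices/pump/jobs", "selfdestruct"))
  expect_length(dev$inbox, 1)
  expect_length(dev$rejected, 1)
  expect_equal(dev$rejected[[1]]$command, "selfdestruct")
})

test_that("schedule expansion yields 28 six-hourly feeds and 36 hourly records", {
  feeds <- expand_schedule(rig_schedule(periodic = list(
    periodic_entry("pump", "feed", period_h = 6))), horizon_h = 7 * 24)
  expect_equal(nrow(feeds), 28)
  recs <- expand_schedule(rig_schedule(periodic = list(
    periodic_entry("ephys", "record", period_h = 1))), horizon_h = 36)
  expect_equal(nrow(recs), 36)
})

test_that("a feed requested during a recording is deferred until after it", {
  devs <- list(device_spec("ephys", "record", exclusive = TRUE),
               device_spec("pump", "feed"))
  subs <- data.frame(device = c("ephys", "pump"),
                     command = c("record", "feed"),
                     ready_h = c(10, 12), duration_h = c(15, 0.2))
  out <- simulate_devices(devs, subs)
  feed <- out$jobs[out$jobs$command == "feed", ]
  expect_equal(feed$start_h, 25)
  expect_true(feed$deferred)
  expect_equal(feed$status, "done")
  # shadows reflect the pause
  paused <- out$shadows[out$shadows$device == "pump" &
                        out$shadows$state == "paused", ]
  expect_equal(paused$time_h, 10)
})

test_that("a pause issued mid-feed lets the running feed complete atomically", {
  devs <- list(device_spec("ephys", "record", exclusive = TRUE),
               device_spec("pump", "feed"))
  subs <- data.frame(device = c("pump", "ephys", "pump"),
                     command = c("feed", "record", "feed"),
                     ready_h = c(9, 10, 10.5), duration_h = c(2, 5, 0.2))
  out <- simulate_devices(devs, subs)
  j <- out$jobs[order(out$jobs$ready_h), ]
  expect_equal(j$start_h[1], 9)           # first feed runs to completion
  expect_false(j$deferred[1])
  expect_equal(j$start_h[2], 11)          # recording waits for the feed
  expect_equal(j$start_h[3], 16)          # queued feed defers past it
  expect_true(j$deferred[3])
})

test_that("non-conflicting jobs on different devices run in submission order", {
  devs <- list(device_spec("cam", "image"), device_spec("uplink", "upload"))
  subs <- data.frame(device = c("uplink", "cam"),
                     command = c("upload", "image"),
                     ready_h = c(1, 1), duration_h = c(3, 0.5))
  out <- simulate_devices(devs, subs)
  expect_true(all(out$jobs$status == "done"))
  expect_equal(out$jobs$start_h, c(1, 1))  # both start when ready
})

test_that("no job is lost over randomised 200-job schedules", {
  set.seed(60)
  devs <- list(device_spec("ephys", "record", exclusive = TRUE),
               device_spec("pump", "feed"),
               device_spec("cam", "image"),
               device_spec("uplink", "upload"))
  cmds <- c(ephys = "record", pump = "feed", cam = "image", uplink = "upload")
  dv <- sample(names(cmds), 200, replace = TRUE,
               prob = c(0.1, 0.3, 0.3, 0.3))
  subs <- data.frame(device = dv, command = unname(cmds[dv]),
                     ready_h = runif(200, 0, 100),
                     duration_h = runif(200, 0.05, 0.5),
                     fails = runif(200) < 0.05)
  out <- simulate_devices(devs, subs)
  expect_true(all(out$jobs$status %in% c("done", "failed", "rejected")))
  expect_equal(sum(out$jobs$status == "failed"), sum(subs$fails))
  # recording exclusivity: no other device's job overlaps a recording window
  others <- out$jobs[out$jobs$device != "ephys" & out$jobs$status != "rejected", ]
  for (w in seq_len(nrow(out$windows))) {
    overlap <- others$start_h < out$windows$end_h[w] - 1e-9 &
               others$end_h > out$windows$start_h[w] + 1e-9
    started_inside <- others$start_h >= out$windows$start_h[w] - 1e-9 &
                      others$start_h < out$windows$end_h[w] - 1e-9
    expect_false(any(started_inside))
  }
  # per-device serial execution
  for (d in names(cmds)) {
    jd <- out$jobs[out$jobs$device == d & out$jobs$status != "rejected", ]
    jd <- jd[order(jd$start_h), ]
    if (nrow(jd) > 1)
      expect_true(all(jd$start_h[-1] >= jd$end_h[-nrow(jd)] - 1e-9))
  }
})

test_that("shadows are updated on every transition before the next job starts", {
  devs <- list(device_spec("pump", "feed"))
  subs <- data.frame(device = "pump", command = "feed",
                     ready_h = c(1, 2), duration_h = c(0.5, 0.5))
  out <- simulate_devices(devs, subs)
  sh <- out$shadows[out$shadows$device == "pump", ]
  expect_equal(sh$state, c("idle", "busy", "idle", "busy", "idle"))
  expect_true(all(diff(sh$time_h) >= 0))
})

test_that("experiment metadata refuses UUID collisions and appends monotonically", {
  dir <- withr::local_tempdir()
  meta <- init_experiment(dir, uuid = "exp-001", notes = "n",
                          devices = c("pump", "cam"))
  expect_error(init_experiment(dir, uuid = "exp-001"),
               class = "organoidrig_illegal_state")
  expect_length(read_metadata(dir)$data_index$raw, 0)
  set.seed(61)
  keys <- character()
  for (i in 1:20) {
    kind <- sample(c("raw", "analyzed"), 1)
    key <- sprintf("exp-001/%s/file%02d", kind, i)
    add_data_record(dir, key, checksum = sprintf("%032x", i), kind = kind)
    keys <- c(keys, key)
    idx <- read_metadata(dir)$data_index
    stored <- c(vapply(idx$raw, `[[`, "", "key"),
                vapply(idx$analyzed, `[[`, "", "key"))
    expect_setequal(stored, keys)   # append-only: nothing lost
  }
})

test_that("uploads verify checksums, retry on corruption, and bound retries", {
  dir <- withr::local_tempdir()
  src <- file.path(dir, "data.bin")
  writeLines(c("payload", "lines"), src)

  store <- local_blob_store(file.path(dir, "store"))
  rec <- upload_record(src, "exp/raw/data.bin")
  rec <- upload_queue_step(rec, store)
  expect_equal(rec$status, "uploaded")
  expect_equal(rec$retries, 0)

  flaky <- corrupting_store(local_blob_store(file.path(dir, "store2")), times = 1)
  rec2 <- process_upload(upload_record(src, "k"), flaky)
  expect_equal(rec2$status, "uploaded")
  expect_equal(rec2$retries, 1)

  broken <- corrupting_store(local_blob_store(file.path(dir, "store3")),
                             times = Inf)
  rec3 <- process_upload(upload_record(src, "k", max_retries = 5), broken)
  expect_equal(rec3$status, "failed")
  expect_equal(rec3$retries, 5)
  expect_true(rec3$alert)
})
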