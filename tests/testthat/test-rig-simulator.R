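# Rig fluid physics, fault injection, renderer determinism and the closed
# loop end to end.

test_that("pump jobs move the volumes the chamber allows", {
  st <- rig_state(chamber_ul = 559)
  r <- apply_job(st, pump_job("aspirate", 143))
  expect_equal(r$state$chamber_ul, 416)
  expect_equal(r$state$reservoir_ul, 143)
  expect_equal(r$moved_ul, 143)

  # at the 170 uL floor the line draws air
  low <- rig_state(chamber_ul = 170)
  r2 <- apply_job(low, pump_job("aspirate", 100))
  expect_equal(r2$state$chamber_ul, 170)
  expect_equal(r2$state$reservoir_ul, 0)
  expect_equal(r2$moved_ul, 0)

  # a 70% retained fraction moves 30% of the command
  blocked <- fault_model(clog_prob = 1, retained_shape1 = 7e7,
                         retained_shape2 = 3e7, spontaneous_clear_prob = 0)
  set.seed(50)
  r3 <- apply_job(rig_state(chamber_ul = 559), pump_job("aspirate", 143), blocked)
  expect_equal(r3$moved_ul, 143 * 0.3, tolerance = 1e-3)
})

test_that("a cycle is one aspirate followed by one equal dispense", {
  st <- rig_state(chamber_ul = 559)
  r <- apply_job(st, pump_job("cycle", 143))
  expect_equal(r$state$chamber_ul, 559)      # net zero in the chamber
  expect_equal(r$state$reservoir_ul, 143)
  expect_equal(r$state$cum_dispensed_ul, 143)
})

test_that("overflow is latched and further jobs are refused", {
  st <- rig_state(chamber_ul = 1400)
  r <- apply_job(st, pump_job("dispense", 200))
  expect_true(r$state$overflow)
  expect_error(apply_job(r$state, pump_job("aspirate", 10)),
               class = "organoidrig_illegal_state")
})

test_that("volume is conserved to 1e-9 uL over arbitrary job sequences", {
  set.seed(51)
  for (rep in 1:5) {
    st <- rig_state()
    base <- st$chamber_ul + st$reservoir_ul
    faults <- fault_model(clog_prob = 0.4)
    for (i in 1:150) {
      kind <- sample(c("aspirate", "dispense", "pull", "cycle"), 1)
      vol <- if (kind == "pull") NULL else runif(1, 5, 120)
      r <- tryCatch(apply_job(st, pump_job(kind, vol), faults),
                    organoidrig_illegal_state = function(e) NULL)
      if (is.null(r)) break
      st <- r$state
    }
    expect_equal(st$chamber_ul + st$reservoir_ul - st$cum_dispensed_ul, base,
                 tolerance = 1e-9)
  }
})

test_that("the renderer is deterministic for a fixed seed", {
  cfg <- render_config()
  set.seed(52); a <- render_reservoir(4000, cfg)
  set.seed(52); b <- render_reservoir(4000, cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  expect_error(render_reservoir(-5, cfg), class = "organoidrig_invalid_input")
  expect_error(render_reservoir(13000, cfg), class = "organoidrig_invalid_input")
})

test_that("render and estimate round-trip within 2% across the tube range", {
  model <- sim_calibration_model()
  set.seed(53)
  vols <- seq(300, 12000, length.out = 20)
  for (v in vols) {
    # ideal render settings: sharp, noise-free, nominal lighting
    r <- render_reservoir(v, clean_render_config())
    est <- estimate_image_volume(r$image, model)
    expect_identical(est$status, "ok")
    expect_lt(abs(est$volume_ul - v) / v, 0.02)
  }
})

test_that("a fault-free 7-day run needs no feedback and books 4004 uL", {
  ex <- run_experiment(seed = 1)
  expect_equal(nrow(ex$feeds), 28)
  expect_true(all(ex$feeds$status == "within_tolerance"))
  expect_equal(ex$alerts, 0)
  expect_equal(ex$ledger$expected_ul, 4004)
  expect_equal(sum(ex$events$origin == "feedback"), 0)
  expect_equal(sum(ex$events$kind == "cycle"), 28)
  # expected and estimated traces coincide within estimator noise
  expect_lt(max(abs(ex$trace$estimate_ul - ex$trace$expected_ul)), 143)
  hist <- job_histogram(ex)
  expect_equal(sum(hist[, "cycle"]), 28)
  expect_equal(unname(rowSums(hist)), rep(4, 7))  # four feeds per day
})

test_that("a 70%-blocked line converges with at most 5 aspirate corrections", {
  blocked <- fault_model(clog_prob = 1, retained_shape1 = 7e7,
                         retained_shape2 = 3e7, spontaneous_clear_prob = 0,
                         pull_clear_prob = 0)
  ex <- run_experiment(n_feeds = 6, faults = blocked, seed = 4)
  expect_true(all(ex$feeds$status == "within_tolerance"))
  expect_true(all(ex$feeds$iterations <= 5))
  fb <- ex$events[ex$events$origin == "feedback", ]
  expect_true(all(fb$kind == "aspirate"))
})

test_that("a mid-run reservoir swap is recognised as a tube change, not an alert", {
  ex <- run_experiment(seed = 2, tube_change_after_feed = 16)
  expect_equal(ex$alerts, 0)
  expect_equal(sum(ex$feeds$status == "tube_change"), 1)
  swap <- ex$trace[ex$trace$feed == 17 & ex$trace$iteration == 0, ]
  expect_gte(swap$expected_ul - swap$estimate_ul, 2000)  # the visible drop
  expect_lt(swap$estimate_ul, 2000)
  # the loop re-converges afterwards
  after <- ex$feeds[ex$feeds$feed > 17, ]
  expect_true(all(after$status == "within_tolerance"))
})

test_that("scenarios load from YAML and runs export as logs and traces", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_feeds: 4", "period_h: 6", "feed_volume_ul: 143", "seed: 9",
               "faults:", "  clog_prob: 0.2", "feedback:",
               "  tolerance_ul: 143"), path)
  args <- read_scenario(path)
  expect_equal(args$n_feeds, 4)
  expect_equal(args$faults$clog_prob, 0.2)
  ex <- run_scenario(path)
  expect_equal(nrow(ex$feeds), 4)

  log_path <- withr::local_tempfile(fileext = ".jsonl")
  write_experiment_log(ex, log_path)
  lines <- readLines(log_path)
  expect_equal(length(lines), nrow(ex$events))
  first <- jsonlite::fromJSON(lines[1])
  expect_equal(first$kind, "cycle")

  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(ex, csv_path)
  back <- read.csv(csv_path)
  expect_equal(nrow(back), nrow(ex$trace))
  expect_true(all(c("estimate_ul", "expected_ul", "category") %in% names(back)))
})
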