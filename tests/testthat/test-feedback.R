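# Feedback interpreter: classification, corrective-job planning, ledger
# bookkeeping and the closed loop's terminal states.

test_that("classification reproduces the study's worked examples", {
  cfg <- feedback_config()
  led <- expectation_ledger(expected_ul = 5000)
  expect_equal(classify_estimate(4900, led, cfg), "within_tolerance")
  expect_equal(classify_estimate(5143, led, cfg), "within_tolerance")
  expect_equal(classify_estimate(4856, led, cfg), "under_volume")
  expect_equal(classify_estimate(5200, led, cfg), "over_volume")
  expect_equal(classify_estimate(7500, led, cfg), "anomaly")   # +2500 >= 2000
  led$last_estimate_ul <- 9000
  expect_equal(classify_estimate(500, led, cfg), "tube_change")
  # a big drop to a level still >= 2000 is not a tube change
  expect_equal(classify_estimate(3000, led, cfg), "under_volume")
})

test_that("a category fuzz reaches all five outcomes", {
  cfg <- feedback_config()
  set.seed(12)
  seen <- character()
  for (i in 1:400) {
    led <- expectation_ledger(expected_ul = runif(1, 0, 9000))
    led$last_estimate_ul <- if (runif(1) < 0.5) NA_real_ else runif(1, 0, 11000)
    seen <- union(seen, classify_estimate(runif(1, 0, 11000), led, cfg))
  }
  expect_setequal(seen, c("within_tolerance", "under_volume", "over_volume",
                          "anomaly", "tube_change"))
})

test_that("escalation follows aspirate (1-5), pull (6-19), alert (20)", {
  cfg <- feedback_config()
  for (i in 1:5) {
    r <- next_jobs("under_volume", -500, i, cfg)
    expect_length(r$jobs, 1)
    expect_equal(r$jobs[[1]]$kind, "aspirate")
    expect_equal(r$jobs[[1]]$volume_ul, 500)
    expect_false(r$alert)
  }
  r6 <- next_jobs("under_volume", -500, 6, cfg)
  expect_equal(vapply(r6$jobs, function(j) j$kind, ""), "pull")
  expect_equal(r6$jobs[[1]]$volume_ul, 1000)
  expect_equal(r6$jobs[[1]]$speed_multiplier, 10)
  # incremental escalation: iteration 6 sends 1 pull, 7 sends 2, ...
  expect_length(next_jobs("under_volume", -500, 9, cfg)$jobs, 4)
  # single-pull convention stays available
  cfg1 <- feedback_config(pull_escalation = "single")
  expect_length(next_jobs("under_volume", -500, 9, cfg1)$jobs, 1)
  r20 <- next_jobs("under_volume", -500, 20, cfg)
  expect_length(r20$jobs, 0)
  expect_true(r20$alert)
  expect_true(r20$halt)
})

test_that("dispenses are capped at 200 uL and two feedback iterations", {
  cfg <- feedback_config()
  set.seed(13)
  for (d in runif(20, 144, 3000)) {
    r <- next_jobs("over_volume", d, 1, cfg, dispenses_used = 0)
    expect_length(r$jobs, 1)
    expect_equal(r$jobs[[1]]$kind, "dispense")
    expect_lte(r$jobs[[1]]$volume_ul, 200)
    expect_equal(r$jobs[[1]]$volume_ul, min(d, 200))
  }
  exhausted <- next_jobs("over_volume", 500, 3, cfg, dispenses_used = 2)
  expect_length(exhausted$jobs, 0)
  expect_true(exhausted$alert)
  expect_true(exhausted$halt)
  expect_error(next_jobs("over_volume", -5, 1, cfg), "positive")
  expect_error(next_jobs("under_volume", 5, 1, cfg), "negative")
  expect_error(next_jobs("within_tolerance", 0, 1, cfg), "under_volume")
})

test_that("the ledger sums scheduled reservoir-directed volumes", {
  led <- expectation_ledger()
  led <- update_ledger(led, pump_job("aspirate", 143))
  expect_equal(led$expected_ul, 143)
  for (i in 2:28) led <- update_ledger(led, pump_job("cycle", 143))
  expect_equal(led$expected_ul, 4004)   # 28 feeds of 143 uL, about 4 mL
  # corrective jobs restore the expectation rather than move it
  led <- update_ledger(led, pump_job("pull", origin = "feedback"))
  led <- update_ledger(led, pump_job("dispense", 200, origin = "feedback"))
  expect_equal(led$expected_ul, 4004)
  # well-directed dispense leaves the reservoir expectation unchanged
  led <- update_ledger(led, pump_job("dispense", 143, target = "well"))
  expect_equal(led$expected_ul, 4004)
})

test_that("ledger conservation matches a brute-force sum over random histories", {
  set.seed(14)
  for (rep in 1:10) {
    led <- expectation_ledger()
    total <- 0
    for (i in 1:40) {
      kind <- sample(c("aspirate", "dispense", "pull", "cycle"), 1)
      origin <- sample(c("scheduled", "feedback"), 1)
      vol <- if (kind == "pull") NULL else runif(1, 10, 300)
      job <- pump_job(kind, vol, origin = origin)
      led <- update_ledger(led, job)
      if (origin == "scheduled" && kind %in% c("aspirate", "pull", "cycle"))
        total <- total + job$volume_ul
    }
    expect_equal(led$expected_ul, total)
    expect_length(led$history, 40)
  }
})

test_that("a halted ledger refuses updates until reset", {
  led <- expectation_ledger()
  led$halted <- TRUE
  expect_error(update_ledger(led, pump_job("aspirate", 100)),
               class = "organoidrig_illegal_state")
  led <- reset_ledger_tube_change(expectation_ledger(5000), 120)
  expect_equal(led$expected_ul, 120)
})

test_that("a tube change resets the expectation to the current estimate", {
  led <- expectation_ledger(expected_ul = 4000)
  led$last_estimate_ul <- 4100
  cfg <- feedback_config()
  stub_pump <- function(job) invisible(job)
  imgs <- local({
    i <- 0
    function() { i <<- i + 1; i }
  })
  estimator <- function(img) 150  # fresh tube with residual media
  fb <- run_feedback_loop(stub_pump, imgs, estimator, led, cfg,
                          notifier = null_notifier)
  expect_equal(fb$status, "tube_change")
  expect_false(fb$alert)
  expect_equal(fb$ledger$expected_ul, 150)
})

test_that("the loop halts with an alert when the estimator keeps failing", {
  led <- expectation_ledger(1000)
  fb <- run_feedback_loop(function(job) NULL, function() NULL,
                          function(img) stop("camera offline"), led,
                          feedback_config(), notifier = null_notifier)
  expect_equal(fb$status, "halted")
  expect_true(fb$alert)
  expect_true(fb$ledger$halted)
})

test_that("feedback configuration loads from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("tolerance_ul: 143", "alert_iteration: 20",
               "pull_escalation: single"), path)
  cfg <- read_feedback_config(path)
  expect_equal(cfg$tolerance_ul, 143)
  expect_equal(cfg$pull_escalation, "single")
  expect_equal(cfg$dispense_cap_ul, 200)   # defaults fill the rest
})
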