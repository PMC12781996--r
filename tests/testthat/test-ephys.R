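# Sliding-window rates, contrast normalization, baseline z-scoring and the
# synthetic raster generator.

test_that("window rates match definitions and a brute-force count oracle", {
  r <- spike_raster(list(steady = seq(0.25, 599.75, by = 0.5),
                         silent = numeric(0)), 600)
  wr <- window_rates(r)
  expect_equal(ncol(wr$rates), floor((600 - 90) / 1) + 1)
  expect_true(all(wr$rates["steady", ] == 2))
  expect_true(all(wr$rates["silent", ] == 0))
  expect_error(window_rates(spike_raster(list(u = 1), 50)), "shorter")

  set.seed(70)
  times <- sort(runif(500, 0, 300))
  rr <- spike_raster(list(u = times), 300)
  wr2 <- window_rates(rr, window_s = 90, step_s = 7)
  oracle <- vapply(wr2$window_starts_s, function(t)
    sum(times >= t & times < t + 90) / 90, 0)
  expect_identical(unname(wr2$rates["u", ]), oracle)
})

test_that("window boundaries are half-open: boundary spikes count left", {
  r <- spike_raster(list(u = c(0, 90, 180)), 270)
  wr <- window_rates(r, window_s = 90, step_s = 90)
  # spikes at 0 and 90 fall in [0,90) and [90,180); the spike at 180 in [180,270)
  expect_equal(unname(wr$rates["u", ]), c(1, 1, 1) / 90)
})

test_that("contrast normalization reproduces the stated anchor values", {
  mk <- function(a_values) {
    wr <- list(rates = matrix(a_values, 1), window_starts_s = seq_along(a_values) - 1,
               window_s = 90, step_s = 1, feed = NULL)
    contrast_normalize(structure(wr, class = "windowed_rates"))
  }
  # a == m everywhere -> 0
  expect_true(all(mk(rep(3, 10))$norms == 0))
  # a = 2m -> +1/3 and a = 0 -> -1 (unit with rates c(0, 2m') has m = m')
  nr <- mk(c(0, 4))   # m = 2
  expect_equal(unname(nr$norms[1, ]), c(-1, 1 / 3))
  # a = m/2 -> -1/3: rates (1, 3) have m = 2, norm(1) = -1/3
  expect_equal(unname(mk(c(1, 3))$norms[1, 1]), -1 / 3)
  # silent unit: 0/0 defined as 0
  expect_true(all(mk(rep(0, 5))$norms == 0))
})

test_that("normalization is a bijection on positive rates", {
  set.seed(71)
  m <- 2.5
  a <- runif(50, 0.01, 20)
  n <- (a - m) / (a + m)
  expect_true(all(n > -1 & n < 1))
  expect_equal(m * (1 + n) / (1 - n), a, tolerance = 1e-12)
})

test_that("a recording z-scored against its own baseline has mean 0, sd 1", {
  set.seed(72)
  r <- generate_raster(cohort_config(n_units = 15, duration_s = 300))
  nr <- contrast_normalize(window_rates(r))
  base <- baseline_stats(list(nr))
  z <- zscore_feed(nr, base)
  expect_equal(max(abs(colMeans(z$z))), 0, tolerance = 1e-10)
  expect_equal(unname(apply(z$z, 2, sd)), rep(1, ncol(z$z)), tolerance = 1e-10)
})

test_that("pooled baselines equal per-window stats of the stacked norms", {
  set.seed(73)
  r1 <- contrast_normalize(window_rates(
    generate_raster(cohort_config(n_units = 8, duration_s = 200))))
  r2 <- contrast_normalize(window_rates(
    generate_raster(cohort_config(n_units = 8, duration_s = 200))))
  base <- baseline_stats(list(r1, r2))
  stacked <- rbind(r1$norms, r2$norms)
  expect_equal(base$mu, colMeans(stacked))
  expect_equal(base$sigma, apply(stacked, 2, sd))
  # relabeling units never changes the pooled baseline
  r1_shuffled <- r1
  r1_shuffled$norms <- r1$norms[sample(nrow(r1$norms)), ]
  base2 <- baseline_stats(list(r1_shuffled, r2))
  expect_equal(base2$mu, base$mu)
  expect_equal(base2$sigma, base$sigma)
  expect_error(baseline_stats(list()), "no baseline")
})

test_that("recording summaries match their definitions and a bin-count oracle", {
  # 10 units at 1 Hz, staggered so every 100 ms bin holds one spike
  ten <- spike_raster(setNames(lapply(1:10, function(i)
    seq(0.05 + (i - 1) / 10, 600, by = 1)), paste0("u", 1:10)), 600)
  s <- recording_summaries(ten)
  expect_equal(s$n_units, 10)
  expect_equal(s$median_rate_hz, 1)
  expect_equal(unique(round(s$population_rate_hz, 9)), 1)  # 1 Hz per unit

  two <- spike_raster(list(a = seq(0.5, 599.5, 1), b = seq(0.1, 599.9, 1 / 3)),
                      600)
  expect_equal(recording_summaries(two)$median_rate_hz, 2)

  set.seed(74)
  times <- sort(runif(400, 0, 60))
  rr <- spike_raster(list(u = times), 60)
  s2 <- recording_summaries(rr)
  oracle <- vapply(s2$bin_starts_s, function(t)
    sum(times >= t & times < t + 0.1), 0)
  expect_equal(s2$population_rate_hz, oracle / 1 / 0.1)

  empty <- recording_summaries(spike_raster(setNames(list(), character(0)), 10))
  expect_equal(empty$n_units, 0)
  expect_true(is.na(empty$median_rate_hz))
})

test_that("the generator is deterministic and Poisson-calibrated", {
  cfg <- cohort_config(n_units = 5, duration_s = 1000,
                       rate_meanlog = log(2), rate_sdlog = 0)
  set.seed(75); a <- generate_raster(cfg)
  set.seed(75); b <- generate_raster(cfg)
  expect_identical(a$spikes, b$spikes)
  # rate 2 Hz over 1000 s: counts within 3 sigma of 2000
  counts <- vapply(a$spikes, length, 0L)
  expect_true(all(abs(counts - 2000) <= 3 * sqrt(2000)))
})

test_that("a feed-locked multiplier raises rates only inside its window", {
  set.seed(76)
  cfg <- cohort_config(n_units = 30, duration_s = 600,
                       feed = list(onset_s = 200, cycles = 1, volume_ul = 300),
                       feed_effect = 3, feed_effect_duration_s = 100)
  r <- generate_raster(cfg)
  inside <- vapply(r$spikes, function(s) sum(s >= 200 & s < 300), 0)
  outside <- vapply(r$spikes, function(s) sum(s < 200 | s >= 300), 0)
  # inside rate ~ 3x base over 100 s vs base over 500 s
  expect_gt(sum(inside) / 100, 2 * sum(outside) / 500)
})

test_that("raster CSV round-trips with feed annotation", {
  set.seed(77)
  r <- generate_raster(cohort_config(n_units = 4, duration_s = 120,
                                     feed = list(onset_s = 30, cycles = 2,
                                                 volume_ul = 300)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_raster_csv(r, path)
  r2 <- read_raster_csv(path)
  expect_equal(r2$duration_s, r$duration_s)
  expect_equal(r2$feed$volume_ul, 300)
  expect_equal(r2$spikes[order(names(r2$spikes))],
               r$spikes[order(names(r$spikes))], tolerance = 1e-10)
})
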