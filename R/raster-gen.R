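# Synthetic spike-raster cohorts: inhomogeneous Poisson units with
# log-normal base rates and an optional multiplicative feed-locked rate
# perturbation.

#' Synthetic cohort configuration
#'
#' Defaults emulate the study's recording conditions: 15-minute recordings
#' with the feed beginning at minute 5, tens of units per chip, and unit
#' base rates around 2 Hz with log-normal spread.
#'
#' @param n_units units per recording.
#' @param duration_s recording duration (900 s = 15 min).
#' @param rate_meanlog,rate_sdlog log-normal parameters of per-unit base
#'   rates in Hz (defaults give a mean near 2 Hz).
#' @param feed optional feed annotation list (`onset_s`, `cycles`,
#'   `volume_ul`), or `NULL` for a no-feed recording.
#' @param feed_effect multiplicative rate factor during the feed effect
#'   window (1 = null effect).
#' @param feed_effect_duration_s length of the perturbed interval after
#'   feed onset.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_units = 40, duration_s = 900,
                          rate_meanlog = log(2) - 0.18, rate_sdlog = 0.6,
                          feed = NULL, feed_effect = 1,
                          feed_effect_duration_s = 60) {
  stopifnot(n_units >= 1, duration_s > 0, rate_sdlog >= 0, feed_effect >= 0,
            feed_effect_duration_s >= 0)
  structure(list(n_units = n_units, duration_s = duration_s,
                 rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog,
                 feed = feed, feed_effect = feed_effect,
                 feed_effect_duration_s = feed_effect_duration_s),
            class = "cohort_config")
}

sample_piecewise_poisson <- function(duration_s, base_rate, windows, factor) {
  # homogeneous Poisson at base_rate plus superposed/thinned modulation in
  # the given [start, end) windows
  n <- stats::rpois(1, base_rate * duration_s)
  times <- sort(stats::runif(n, 0, duration_s))
  if (is.null(windows) || factor == 1) return(times)
  in_win <- rep(FALSE, length(times))
  for (w in windows) in_win <- in_win | (times >= w[1] & times < w[2])
  if (factor < 1) {
    keep <- !in_win | stats::runif(length(times)) < factor
    times <- times[keep]
  } else {
    extra <- unlist(lapply(windows, function(w) {
      k <- stats::rpois(1, base_rate * (factor - 1) * (w[2] - w[1]))
      stats::runif(k, w[1], w[2])
    }))
    times <- sort(c(times, extra))
  }
  times
}

#' Generate a synthetic spike raster
#'
#' Each unit fires as a Poisson process at a log-normally drawn base rate;
#' when the configuration carries a feed annotation and a non-unit
#' `feed_effect`, rates are multiplied by that factor for
#' `feed_effect_duration_s` seconds from feed onset. Deterministic for a
#' fixed RNG seed.
#'
#' @param config a [cohort_config()].
#' @return a [spike_raster()].
#' @export
generate_raster <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$duration_s <= 0) stop_invalid("duration must be positive")
  rates <- stats::rlnorm(config$n_units, config$rate_meanlog, config$rate_sdlog)
  windows <- NULL
  if (!is.null(config$feed) && config$feed_effect != 1 &&
      config$feed_effect_duration_s > 0)
    windows <- list(c(config$feed$onset_s,
                      config$feed$onset_s + config$feed_effect_duration_s))
  spikes <- lapply(rates, function(r)
    sample_piecewise_poisson(config$duration_s, r, windows, config$feed_effect))
  names(spikes) <- sprintf("u%03d", seq_along(spikes))
  spike_raster(spikes, config$duration_s, config$feed)
}

#' Run the full feed-effect analysis on raster cohorts
#'
#' Computes windowed rates and contrast norms for every recording, pools the
#' no-feed baseline, z-scores each feed recording and averages by feed-volume
#' condition.
#'
#' @param nofeed list of no-feed [spike_raster()]s.
#' @param feed list of feed [spike_raster()]s (each annotated with its
#'   volume).
#' @param window_s,step_s sliding-window parameters.
#' @return list with `baseline` (a [baseline_stats()]), `traces` (list of
#'   [zscore_feed()] results) and `condition_average`
#'   (a [condition_average_z()] table).
#' @export
feed_effect_analysis <- function(nofeed, feed, window_s = 90, step_s = 1) {
  norm_of <- function(r) contrast_normalize(window_rates(r, window_s, step_s))
  base <- baseline_stats(lapply(nofeed, norm_of))
  traces <- lapply(feed, function(r) zscore_feed(norm_of(r), base))
  list(baseline = base, traces = traces,
       condition_average = condition_average_z(traces))
}
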