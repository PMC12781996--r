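# Feed-effect spike-train analysis: 90-s sliding-window firing rates,
# per-unit contrast normalization |x| = (a - m)/(a + m), no-feed baseline
# pooling, and z-scoring of feed recordings against that baseline.

#' Construct a spike raster
#'
#' @param spikes named list, one sorted numeric vector of spike times
#'   (seconds from recording start) per unit.
#' @param duration_s recording duration in seconds.
#' @param feed optional feed annotation: list with `onset_s`, `cycles`,
#'   `volume_ul` (the condition), or `NULL` for a no-feed recording.
#' @return object of class `spike_raster`.
#' @export
spike_raster <- function(spikes, duration_s, feed = NULL) {
  if (is.null(names(spikes)) || anyDuplicated(names(spikes)))
    stop_invalid("spikes must be a named list with unique unit ids")
  if (duration_s <= 0) stop_invalid("duration_s must be positive")
  for (u in names(spikes)) {
    s <- spikes[[u]]
    if (is.unsorted(s)) stop_invalid("spike times must be sorted (unit ", u, ")")
    if (length(s) && (s[1] < 0 || s[length(s)] > duration_s))
      stop_invalid("spike times must lie in [0, duration] (unit ", u, ")")
  }
  structure(list(spikes = spikes, duration_s = duration_s, feed = feed),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster: %d units, %.0f s%s>\n", length(x$spikes),
              x$duration_s,
              if (is.null(x$feed)) ", no feed"
              else sprintf(", feed at %.0f s (%g uL)", x$feed$onset_s,
                           x$feed$volume_ul)))
  invisible(x)
}

count_in_windows <- function(times, starts, window_s) {
  # spikes in [t, t + window): half-open, boundary spikes count left
  n_lt <- function(x) findInterval(x, times, left.open = TRUE)
  n_lt(starts + window_s) - n_lt(starts)
}

#' Sliding-window firing rates
#'
#' Windows are half-open intervals `[t, t + window_s)` starting at
#' `t = 0, step_s, 2 step_s, ...`; the number of windows is
#' `floor((duration - window) / step) + 1`.
#'
#' @param raster a [spike_raster()].
#' @param window_s window length in seconds (default 90).
#' @param step_s step in seconds (default 1).
#' @return object of class `windowed_rates`: `rates` (units x windows matrix,
#'   Hz), `window_starts_s`, `window_s`, `step_s`, `feed`.
#' @export
window_rates <- function(raster, window_s = 90, step_s = 1) {
  if (raster$duration_s < window_s)
    stop_invalid("duration shorter than the window")
  starts <- seq(0, raster$duration_s - window_s, by = step_s)
  rates <- t(vapply(raster$spikes, function(s)
    count_in_windows(s, starts, window_s) / window_s,
    numeric(length(starts))))
  rownames(rates) <- names(raster$spikes)
  structure(list(rates = rates, window_starts_s = starts,
                 window_s = window_s, step_s = step_s, feed = raster$feed),
            class = "windowed_rates")
}

#' Contrast-normalize windowed rates per unit
#'
#' For window rate `a` and the unit's mean window rate `m`,
#' `|x| = (a - m)/(a + m)`, which lies in \[-1, 1\]: 0 when the window rate
#' equals the unit mean, +1/3 when it is twice the mean, -1/3 at half the
#' mean, -1 for a silent window. A fully silent unit (`a = m = 0`) is
#' defined as 0.
#'
#' @param wr a [window_rates()] result.
#' @return object of class `normalized_rates`: `norms` (units x windows),
#'   `unit_means` (Hz), plus the window axis and feed annotation.
#' @export
contrast_normalize <- function(wr) {
  m <- rowMeans(wr$rates)
  a <- wr$rates
  denom <- a + m
  norms <- (a - m) / denom
  norms[denom == 0] <- 0
  structure(list(norms = norms, unit_means = m,
                 window_starts_s = wr$window_starts_s,
                 window_s = wr$window_s, step_s = wr$step_s, feed = wr$feed),
            class = "normalized_rates")
}

#' Pool a no-feed baseline across recordings
#'
#' For each window (relative to recording start) the mean and standard
#' deviation of the contrast-normalized rates are pooled over every unit of
#' every no-feed recording. Recordings of unequal length are truncated to
#' the shortest common window axis.
#'
#' @param nofeed list of [contrast_normalize()] results from no-feed
#'   recordings.
#' @return object of class `baseline_stats`: `mu`, `sigma` (per window),
#'   `n_units`, `window_starts_s`.
#' @export
baseline_stats <- function(nofeed) {
  if (!length(nofeed)) stop_invalid("no baseline recordings supplied")
  n_win <- min(vapply(nofeed, function(x) ncol(x$norms), 0L))
  pooled <- do.call(rbind, lapply(nofeed, function(x)
    x$norms[, seq_len(n_win), drop = FALSE]))
  if (nrow(pooled) < 2)
    stop_invalid("need at least 2 pooled units per window for a baseline sd")
  structure(list(mu = colMeans(pooled),
                 sigma = apply(pooled, 2, stats::sd),
                 n_units = nrow(pooled),
                 window_starts_s = nofeed[[1]]$window_starts_s[seq_len(n_win)]),
            class = "baseline_stats")
}

#' Z-score a feed recording against the no-feed baseline
#'
#' `z = (|x|_feed - mu_nofeed) / sigma_nofeed` per unit per window. Windows
#' with zero baseline sd are flagged NA.
#'
#' @param feed a [contrast_normalize()] result from a feed recording.
#' @param baseline a [baseline_stats()].
#' @return object of class `zscore_trace`: `z` (units x windows),
#'   `window_starts_s`, `feed`.
#' @export
zscore_feed <- function(feed, baseline) {
  n_win <- min(ncol(feed$norms), length(baseline$mu))
  x <- feed$norms[, seq_len(n_win), drop = FALSE]
  mu <- baseline$mu[seq_len(n_win)]
  sg <- baseline$sigma[seq_len(n_win)]
  z <- sweep(sweep(x, 2, mu), 2, sg, "/")
  z[, sg == 0] <- NA_real_
  structure(list(z = z,
                 window_starts_s = feed$window_starts_s[seq_len(n_win)],
                 feed = feed$feed),
            class = "zscore_trace")
}

#' Average z-score traces by feed-volume condition
#'
#' @param traces list of [zscore_feed()] results carrying feed annotations.
#' @return data.frame with `window_start_s`, one column per condition
#'   (`z_<volume>`), averaging over all units of all recordings sharing a
#'   feed volume.
#' @export
condition_average_z <- function(traces) {
  vols <- vapply(traces, function(t) t$feed$volume_ul %||% NA_real_, 0)
  if (anyNA(vols)) stop_invalid("every trace needs a feed volume annotation")
  n_win <- min(vapply(traces, function(t) ncol(t$z), 0L))
  out <- data.frame(window_start_s = traces[[1]]$window_starts_s[seq_len(n_win)])
  for (v in sort(unique(vols))) {
    stack <- do.call(rbind, lapply(traces[vols == v], function(t)
      t$z[, seq_len(n_win), drop = FALSE]))
    out[[paste0("z_", v)]] <- colMeans(stack)
  }
  out
}

#' Summarise a recording
#'
#' Unit count, the median of per-unit whole-recording firing rates, and the
#' population rate trace: total spikes per 100 ms bin divided by the unit
#' count and the bin width (Hz per unit).
#'
#' @param raster a [spike_raster()].
#' @param bin_s population-rate bin width in seconds.
#' @return list with `n_units`, `median_rate_hz` (NA for an empty raster),
#'   `population_rate_hz` (numeric vector) and `bin_starts_s`.
#' @export
recording_summaries <- function(raster, bin_s = 0.1) {
  n_units <- length(raster$spikes)
  edges <- seq(0, raster$duration_s, by = bin_s)
  starts <- edges[-length(edges)]
  if (n_units == 0)
    return(list(n_units = 0L, median_rate_hz = NA_real_,
                population_rate_hz = rep(0, length(starts)),
                bin_starts_s = starts))
  per_unit <- vapply(raster$spikes, length, 0L) / raster$duration_s
  all_times <- sort(unlist(raster$spikes, use.names = FALSE))
  counts <- count_in_windows(all_times, starts, bin_s)
  list(n_units = n_units, median_rate_hz = stats::median(per_unit),
       population_rate_hz = counts / n_units / bin_s,
       bin_starts_s = starts)
}

#' Export a condition-average z-score table to CSV
#'
#' @param z_table a [condition_average_z()] result.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_ztrace_csv <- function(z_table, path) {
  utils::write.csv(z_table, path, row.names = FALSE)
  invisible(path)
}

#' Read/write spike rasters as CSV
#'
#' Plain-text raster exchange format: columns `unit` and `time_s`, one row
#' per spike, with the duration (and optional feed annotation) in `#`-prefixed
#' header lines.
#'
#' @param raster a [spike_raster()].
#' @param path CSV file.
#' @return `write_raster_csv`: `path`, invisibly; `read_raster_csv`: a
#'   [spike_raster()].
#' @export
write_raster_csv <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_s=%.10g", raster$duration_s), con)
  if (!is.null(raster$feed))
    writeLines(sprintf("# feed onset_s=%.10g cycles=%d volume_ul=%.10g",
                       raster$feed$onset_s, raster$feed$cycles,
                       raster$feed$volume_ul), con)
  df <- data.frame(
    unit = rep(names(raster$spikes), vapply(raster$spikes, length, 0L)),
    time_s = unlist(raster$spikes, use.names = FALSE))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  duration <- as.numeric(sub(".*duration_s=([0-9.eE+-]+).*", "\\1",
                             hdr[grepl("duration_s=", hdr)][1]))
  feed <- NULL
  fh <- hdr[grepl("feed onset_s=", hdr)]
  if (length(fh)) {
    feed <- list(
      onset_s = as.numeric(sub(".*onset_s=([0-9.eE+-]+).*", "\\1", fh[1])),
      cycles = as.integer(sub(".*cycles=([0-9]+).*", "\\1", fh[1])),
      volume_ul = as.numeric(sub(".*volume_ul=([0-9.eE+-]+).*", "\\1", fh[1])))
  }
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  spikes <- lapply(split(df$time_s, df$unit), sort)
  spike_raster(spikes, duration, feed)
}
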