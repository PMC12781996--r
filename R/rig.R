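# Hardware stand-in for the pump/chamber/reservoir rig: conservative fluid
# bookkeeping with clog fault injection, and the full closed-loop experiment
# (scheduler -> pump -> renderer -> estimator -> feedback interpreter).

#' Rig fluid state
#'
#' Chamber ideal operating range is 350-700 uL with a hard aspiration floor
#' of 170 uL (below it the line draws air); the overflow catch protects up
#' to 1500 uL. A preheated 450 uL fresh-media reserve idles in the tubing.
#'
#' @param chamber_ul starting chamber volume (default 559, the upper ideal
#'   mark).
#' @param reservoir_ul starting collection-reservoir volume.
#' @param tubing_reserve_ul preheated reserve in the supply tubing.
#' @return object of class `rig_state`.
#' @export
rig_state <- function(chamber_ul = 559, reservoir_ul = 0,
                      tubing_reserve_ul = 450) {
  stopifnot(chamber_ul >= 0, reservoir_ul >= 0, tubing_reserve_ul >= 0)
  structure(list(chamber_ul = chamber_ul, reservoir_ul = reservoir_ul,
                 tubing_reserve_ul = tubing_reserve_ul,
                 chamber_floor_ul = 170, chamber_overflow_ul = 1500,
                 cum_aspirated_ul = 0, cum_dispensed_ul = 0,
                 clogged = FALSE, overflow = FALSE),
            class = "rig_state")
}

#' Fault model for pump actions
#'
#' A clog arises per aspiration-type action with probability `clog_prob` and
#' persists; while clogged, each aspiration retains a Beta-distributed
#' fraction of the commanded volume in the line. A clog clears spontaneously
#' with probability `spontaneous_clear_prob` per action, and a pull clears it
#' with probability `pull_clear_prob`. These statistics are this module's
#' invention: the study reports clogging as a failure mode but not its
#' distribution, so defaults were chosen to produce feedback-event counts of
#' the same order as the reported 7-day runs.
#'
#' @param clog_prob per-action probability a new clog forms.
#' @param retained_shape1,retained_shape2 Beta parameters of the retained
#'   fraction while clogged.
#' @param pull_clear_prob probability a pull clears the clog.
#' @param spontaneous_clear_prob per-action spontaneous clearing probability.
#' @param evaporation_ul_h chamber evaporation rate (default 0).
#' @return object of class `fault_model`.
#' @export
fault_model <- function(clog_prob = 0, retained_shape1 = 2,
                        retained_shape2 = 2, pull_clear_prob = 0.8,
                        spontaneous_clear_prob = 0.3, evaporation_ul_h = 0) {
  stopifnot(clog_prob >= 0, clog_prob <= 1, pull_clear_prob >= 0,
            pull_clear_prob <= 1, spontaneous_clear_prob >= 0,
            spontaneous_clear_prob <= 1, evaporation_ul_h >= 0)
  structure(list(clog_prob = clog_prob, retained_shape1 = retained_shape1,
                 retained_shape2 = retained_shape2,
                 pull_clear_prob = pull_clear_prob,
                 spontaneous_clear_prob = spontaneous_clear_prob,
                 evaporation_ul_h = evaporation_ul_h),
            class = "fault_model")
}

#' A fault model in which every aspiration and pull moves nothing
#'
#' Emulates a hard, unclearable clog; used to exercise the full feedback
#' escalation (aspirates, pulls, then the manual-intervention alert).
#'
#' @return a [fault_model()].
#' @export
hard_clog_faults <- function() {
  fault_model(clog_prob = 1, retained_shape1 = Inf, retained_shape2 = 1,
              pull_clear_prob = 0, spontaneous_clear_prob = 0)
}

draw_retained <- function(faults) {
  if (is.infinite(faults$retained_shape1)) return(1)  # hard clog: retain all
  stats::rbeta(1, faults$retained_shape1, faults$retained_shape2)
}

aspirate_once <- function(state, volume_ul, faults) {
  # clog dynamics happen per aspiration-type action
  if (state$clogged && stats::runif(1) < faults$spontaneous_clear_prob)
    state$clogged <- FALSE
  else if (!state$clogged && stats::runif(1) < faults$clog_prob)
    state$clogged <- TRUE
  frac <- if (state$clogged) 1 - draw_retained(faults) else 1
  avail <- max(state$chamber_ul - state$chamber_floor_ul, 0)
  moved <- min(volume_ul, avail) * frac
  state$chamber_ul <- state$chamber_ul - moved
  state$reservoir_ul <- state$reservoir_ul + moved
  state$cum_aspirated_ul <- state$cum_aspirated_ul + moved
  list(state = state, moved = moved)
}

#' Apply a pump job to the rig state
#'
#' Aspirations move media from the chamber to the collection reservoir,
#' bounded by the 170 uL chamber floor and reduced by the clog's retained
#' fraction; dispenses deliver fresh media to the chamber (raising overflow
#' beyond 1500 uL); a pull is a 1000 uL aspiration that can clear a clog; a
#' cycle is one aspirate followed by one dispense of equal volume. Volume is
#' conserved: chamber + reservoir - cumulative dispensed is constant.
#'
#' @param state a [rig_state()].
#' @param job a [pump_job()].
#' @param faults a [fault_model()].
#' @return list with the updated `state` and `moved_ul`, the volume actually
#'   transferred to the reservoir (aspiration side) or chamber (dispense).
#' @export
apply_job <- function(state, job, faults = fault_model()) {
  stopifnot(inherits(state, "rig_state"), inherits(job, "pump_job"))
  if (state$overflow)
    stop_illegal_state("rig is in overflow state; no further jobs accepted")
  moved <- 0
  if (job$kind %in% c("aspirate", "pull")) {
    r <- aspirate_once(state, job$volume_ul, faults)
    state <- r$state; moved <- r$moved
    if (job$kind == "pull" && state$clogged &&
        stats::runif(1) < faults$pull_clear_prob)
      state$clogged <- FALSE
  } else if (job$kind == "dispense") {
    state$chamber_ul <- state$chamber_ul + job$volume_ul
    state$cum_dispensed_ul <- state$cum_dispensed_ul + job$volume_ul
    moved <- job$volume_ul
    if (state$chamber_ul > state$chamber_overflow_ul) state$overflow <- TRUE
  } else if (job$kind == "cycle") {
    r <- aspirate_once(state, job$volume_ul, faults)
    state <- r$state; moved <- r$moved
    state$chamber_ul <- state$chamber_ul + job$volume_ul
    state$cum_dispensed_ul <- state$cum_dispensed_ul + job$volume_ul
    if (state$chamber_ul > state$chamber_overflow_ul) state$overflow <- TRUE
  }
  list(state = state, moved_ul = moved)
}

#' Run a closed-loop simulated feeding experiment
#'
#' Executes the scheduled feed cycles on the simulated rig, imaging the
#' collection reservoir with the renderer after every scheduled action and
#' letting the feedback interpreter issue corrective jobs until each feed
#' lands within tolerance (or escalation halts the run). A calibration is
#' fitted once, from noise-free rendered images, before the run.
#'
#' @param n_feeds number of scheduled feed cycles.
#' @param period_h hours between feeds.
#' @param feed_volume_ul volume aspirated and replaced per cycle.
#' @param faults a [fault_model()].
#' @param render_cfg a [render_config()].
#' @param fb_config a [feedback_config()].
#' @param seed RNG seed for the whole run (renderer noise and faults).
#' @param tube_change_after_feed if set, the collection reservoir is swapped
#'   for a fresh tube after this many completed feeds.
#' @param model optional [calibration_model()]; fitted from rendered images
#'   when `NULL`.
#' @param halt_stops_run stop at the first halted feed (default) or press on.
#' @return object of class `rig_experiment`: `feeds` (per-feed status),
#'   `trace` (expected vs estimated volume at every feedback estimate),
#'   `events` (every pump action with its day), `alerts`, `final_state`,
#'   `ledger`, `model`.
#' @export
run_experiment <- function(n_feeds = 28, period_h = 6, feed_volume_ul = 143,
                           faults = fault_model(),
                           render_cfg = render_config(),
                           fb_config = feedback_config(), seed = NULL,
                           tube_change_after_feed = NULL, model = NULL,
                           halt_stops_run = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model)) {
    clean_cfg <- render_cfg; clean_cfg$noise_sd <- 0; clean_cfg$blur_passes <- 0
    vols <- c(seq(60, 1400, length.out = 12), seq(1600, 12000, length.out = 28))
    model <- fit_calibration(render_calibration_dataset(vols, clean_cfg))
  }
  state <- rig_state()
  ledger <- expectation_ledger()
  events <- list(); trace <- list(); feeds <- list()
  alerts <- 0L

  log_event <- function(time_h, job, moved) {
    events[[length(events) + 1L]] <<- data.frame(
      time_h = time_h, day = floor(time_h / 24) + 1L, kind = job$kind,
      origin = job$origin, volume_ul = job$volume_ul, moved_ul = moved)
  }
  pump_exec <- function(time_h) function(job) {
    r <- apply_job(state, job, faults)
    state <<- r$state
    log_event(time_h, job, r$moved_ul)
    invisible(r$moved_ul)
  }
  imager <- function() render_reservoir(state$reservoir_ul, render_cfg)$image
  estimator <- function(img) estimate_image_volume(img, model)

  for (k in seq_len(n_feeds)) {
    t_k <- (k - 1) * period_h
    if (!is.null(tube_change_after_feed) && k == tube_change_after_feed + 1L) {
      state$reservoir_ul <- 0   # fresh empty conical tube
      events[[length(events) + 1L]] <- data.frame(
        time_h = t_k, day = floor(t_k / 24) + 1L, kind = "tube_change",
        origin = "scheduled", volume_ul = NA_real_, moved_ul = NA_real_)
    }
    job <- pump_job("cycle", feed_volume_ul, origin = "scheduled")
    pump_exec(t_k)(job)
    ledger <- update_ledger(ledger, job, t_k)
    fb <- run_feedback_loop(pump_exec(t_k), imager, estimator, ledger,
                            fb_config, notifier = function(msg) invisible(msg),
                            timestamp = t_k)
    ledger <- fb$ledger
    if (fb$alert) alerts <- alerts + 1L
    tr <- fb$log
    tr$time_h <- t_k; tr$feed <- k
    trace[[k]] <- tr
    feeds[[k]] <- data.frame(feed = k, time_h = t_k, status = fb$status,
                             iterations = fb$iterations, alert = fb$alert)
    if (fb$status == "halted" && halt_stops_run) break
  }
  structure(list(feeds = do.call(rbind, feeds),
                 trace = do.call(rbind, trace),
                 events = do.call(rbind, events),
                 alerts = alerts, final_state = state, ledger = ledger,
                 model = model), class = "rig_experiment")
}

#' Per-day histogram of pump events by kind
#'
#' Mirrors the stacked per-day event counts (Pull, Dispense, Aspirate,
#' Cycle) used to summarise a feeding run.
#'
#' @param experiment a [run_experiment()] result.
#' @return a day x kind contingency table.
#' @export
job_histogram <- function(experiment) {
  ev <- experiment$events
  ev <- ev[ev$kind != "tube_change", ]
  table(day = ev$day, kind = ev$kind)
}

#' @export
print.rig_experiment <- function(x, ...) {
  cat(sprintf("<rig_experiment: %d feeds, %d within tolerance, %d alerts>\n",
              nrow(x$feeds), sum(x$feeds$status == "within_tolerance"),
              x$alerts))
  invisible(x)
}

#' Load and run a simulated experiment scenario from YAML
#'
#' The YAML mirrors [run_experiment()] arguments: top-level `n_feeds`,
#' `period_h`, `feed_volume_ul`, `seed`, `tube_change_after_feed`, plus
#' optional `faults`, `render` and `feedback` blocks whose fields mirror
#' [fault_model()], [render_config()] and [feedback_config()] arguments.
#'
#' @param path YAML scenario file.
#' @return `read_scenario`: the argument list; `run_scenario`: a
#'   [run_experiment()] result.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("n_feeds", "period_h", "feed_volume_ul",
                                  "seed", "tube_change_after_feed"))]
  if (!is.null(y$faults)) args$faults <- do.call(fault_model, y$faults)
  if (!is.null(y$render)) args$render_cfg <- do.call(render_config, y$render)
  if (!is.null(y$feedback)) args$fb_config <- do.call(feedback_config, y$feedback)
  args
}

#' @rdname read_scenario
#' @export
run_scenario <- function(path) {
  do.call(run_experiment, read_scenario(path))
}

#' Export a simulated run as JSON-lines events and a CSV trace
#'
#' `write_experiment_log()` writes one JSON object per pump event
#' (timestamp, day, kind, origin, volumes); `write_trace_csv()` writes the
#' expected-vs-estimated volume trace with categories and iterations,
#' mirroring the per-feed feedback bookkeeping.
#'
#' @param experiment a [run_experiment()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_experiment_log <- function(experiment, path) {
  ev <- experiment$events
  lines <- vapply(seq_len(nrow(ev)), function(i)
    jsonlite::toJSON(as.list(ev[i, , drop = FALSE]), auto_unbox = TRUE,
                     digits = NA, na = "null"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_experiment_log
#' @export
write_trace_csv <- function(experiment, path) {
  utils::write.csv(experiment$trace, path, row.names = FALSE)
  invisible(path)
}
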