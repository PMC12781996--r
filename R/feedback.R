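# Volumetric feedback interpreter: expectation bookkeeping, estimate
# classification, corrective-job planning with the aspirate -> pull -> alert
# escalation, and the closed feedback loop.

#' Construct a pump job
#'
#' A `pull` is fixed at 1000 uL and 10x the standard syringe speed. A
#' `cycle` expands to one aspirate followed by one dispense of equal volume.
#'
#' @param kind one of `"aspirate"`, `"dispense"`, `"pull"`, `"cycle"`.
#' @param volume_ul positive volume in microlitres (forced to 1000 for pull).
#' @param target well/reservoir identifier the job acts on; defaults to the
#'   well for dispenses (fresh media) and the collection reservoir otherwise.
#' @param origin `"scheduled"` or `"feedback"`.
#' @return object of class `pump_job`.
#' @export
pump_job <- function(kind = c("aspirate", "dispense", "pull", "cycle"),
                     volume_ul = NULL, target = NULL,
                     origin = c("scheduled", "feedback")) {
  kind <- match.arg(kind)
  origin <- match.arg(origin)
  target <- target %||% if (kind == "dispense") "well" else "reservoir"
  if (kind == "pull") {
    volume_ul <- 1000
    speed <- 10
  } else {
    if (is.null(volume_ul) || !is.numeric(volume_ul) || volume_ul <= 0)
      stop_invalid("volume_ul must be a positive number")
    speed <- 1
  }
  structure(list(kind = kind, volume_ul = volume_ul,
                 speed_multiplier = speed, target = target, origin = origin),
            class = "pump_job")
}

#' Feedback interpreter configuration
#'
#' Study values: tolerance 143 uL; anomaly and tube-change thresholds
#' 2000 uL; difference-matched aspirations on iterations 1-5; pulls on
#' iterations 6-19; manual-intervention alert at iteration 20; dispenses
#' capped at 200 uL per action and 2 feedback iterations in total; safety
#' halt beyond 2 mL of feedback perfusion or 20 retries.
#'
#' @param tolerance_ul acceptance band around the expectation.
#' @param anomaly_excess_ul estimate-minus-expectation at or above which an
#'   anomaly is declared.
#' @param out_of_range_ul drop (and absolute level) thresholds for
#'   tube-change detection.
#' @param aspiration_phase_end last iteration of the aspirate phase.
#' @param pull_phase_start first pull iteration.
#' @param alert_iteration iteration at which manual intervention is requested.
#' @param dispense_cap_ul maximum single dispense.
#' @param dispense_max_iterations maximum dispense-bearing feedback
#'   iterations per trigger.
#' @param safety_total_perfusion_ul measured feedback perfusion per trigger
#'   beyond which the loop halts.
#' @param safety_max_retries retry bound per trigger.
#' @param pull_escalation `"incremental"` (iteration 6 sends 1 pull,
#'   7 sends 2, ...) or `"single"` (one pull per iteration).
#' @return object of class `feedback_config`.
#' @export
feedback_config <- function(tolerance_ul = 143, anomaly_excess_ul = 2000,
                            out_of_range_ul = 2000,
                            aspiration_phase_end = 5, pull_phase_start = 6,
                            alert_iteration = 20, dispense_cap_ul = 200,
                            dispense_max_iterations = 2,
                            safety_total_perfusion_ul = 2000,
                            safety_max_retries = 20,
                            pull_escalation = c("incremental", "single")) {
  stopifnot(tolerance_ul > 0, anomaly_excess_ul > 0, out_of_range_ul > 0,
            dispense_cap_ul > 0, safety_total_perfusion_ul > 0,
            aspiration_phase_end < pull_phase_start,
            pull_phase_start <= alert_iteration)
  structure(list(tolerance_ul = tolerance_ul,
                 anomaly_excess_ul = anomaly_excess_ul,
                 out_of_range_ul = out_of_range_ul,
                 aspiration_phase_end = aspiration_phase_end,
                 pull_phase_start = pull_phase_start,
                 alert_iteration = alert_iteration,
                 dispense_cap_ul = dispense_cap_ul,
                 dispense_max_iterations = dispense_max_iterations,
                 safety_total_perfusion_ul = safety_total_perfusion_ul,
                 safety_max_retries = safety_max_retries,
                 pull_escalation = match.arg(pull_escalation)),
            class = "feedback_config")
}

#' Read a feedback configuration from YAML
#'
#' Field names mirror [feedback_config()] arguments; volumes in microlitres.
#'
#' @param path YAML file.
#' @return a [feedback_config()].
#' @export
read_feedback_config <- function(path) {
  do.call(feedback_config, yaml::read_yaml(path))
}

#' Expectation ledger for the collection reservoir
#'
#' Tracks the running expected reservoir volume implied by the sum of
#' scheduled pump actions, the previously accepted estimate, and a history
#' of (timestamp, job, delta) entries.
#'
#' @param expected_ul starting expected volume.
#' @return object of class `expectation_ledger`.
#' @export
expectation_ledger <- function(expected_ul = 0) {
  stopifnot(expected_ul >= 0)
  structure(list(expected_ul = expected_ul, last_estimate_ul = NA_real_,
                 history = list(), halted = FALSE),
            class = "expectation_ledger")
}

#' Classify a volume estimate against the expectation
#'
#' Categories, checked in order: `tube_change` when the estimate dropped by
#' at least the out-of-range threshold from the previous estimate and the
#' level itself is below that threshold; `anomaly` when the estimate exceeds
#' the expectation by the anomaly threshold or more; `within_tolerance`
#' inside the tolerance band; otherwise `under_volume` / `over_volume` by
#' the sign of (estimate - expectation).
#'
#' @param estimate_ul nonnegative volume estimate.
#' @param ledger an [expectation_ledger()].
#' @param config a [feedback_config()].
#' @return category string.
#' @export
classify_estimate <- function(estimate_ul, ledger, config = feedback_config()) {
  if (estimate_ul < 0) stop_invalid("estimate_ul must be >= 0")
  disc <- estimate_ul - ledger$expected_ul
  if (!is.na(ledger$last_estimate_ul) &&
      ledger$last_estimate_ul - estimate_ul >= config$out_of_range_ul &&
      estimate_ul < config$out_of_range_ul)
    return("tube_change")
  if (disc >= config$anomaly_excess_ul) return("anomaly")
  if (abs(disc) <= config$tolerance_ul) return("within_tolerance")
  if (disc < 0) "under_volume" else "over_volume"
}

#' Plan corrective jobs for an out-of-tolerance estimate
#'
#' Under-volume: iterations 1-5 send one aspirate matching the discrepancy;
#' iterations 6-19 send pull jobs (count escalating by one per iteration
#' under the default convention); iteration 20 requests manual intervention
#' and halts. Over-volume: dispenses capped at 200 uL and at most 2
#' dispense-bearing iterations per trigger, after which the loop alerts and
#' halts.
#'
#' @param category `"under_volume"` or `"over_volume"`.
#' @param discrepancy_ul signed estimate-minus-expectation in microlitres.
#' @param iteration 1-based feedback iteration.
#' @param config a [feedback_config()].
#' @param dispenses_used dispense-bearing iterations already spent in this
#'   trigger.
#' @return object of class `interpretation_result`: `category`,
#'   `discrepancy_ul`, `jobs` (list of [pump_job()]), `alert`, `halt`.
#' @export
next_jobs <- function(category, discrepancy_ul, iteration,
                      config = feedback_config(), dispenses_used = 0) {
  if (!category %in% c("under_volume", "over_volume"))
    stop_invalid("next_jobs only plans for under_volume/over_volume")
  if (iteration < 1) stop_invalid("iteration must be >= 1")
  if (category == "under_volume" && discrepancy_ul >= 0)
    stop_invalid("under_volume requires a negative discrepancy")
  if (category == "over_volume" && discrepancy_ul <= 0)
    stop_invalid("over_volume requires a positive discrepancy")
  result <- function(jobs, alert = FALSE, halt = FALSE)
    structure(list(category = category, discrepancy_ul = discrepancy_ul,
                   jobs = jobs, alert = alert, halt = halt),
              class = "interpretation_result")
  if (iteration >= config$alert_iteration)
    return(result(list(), alert = TRUE, halt = TRUE))
  if (category == "under_volume") {
    if (iteration <= config$aspiration_phase_end)
      return(result(list(pump_job("aspirate", abs(discrepancy_ul),
                                  origin = "feedback"))))
    n_pulls <- if (config$pull_escalation == "incremental")
      iteration - config$pull_phase_start + 1L else 1L
    return(result(replicate(n_pulls, pump_job("pull", origin = "feedback"),
                            simplify = FALSE)))
  }
  # over_volume
  if (dispenses_used >= config$dispense_max_iterations)
    return(result(list(), alert = TRUE, halt = TRUE))
  result(list(pump_job("dispense",
                       min(abs(discrepancy_ul), config$dispense_cap_ul),
                       target = "well", origin = "feedback")))
}

#' Update the expectation ledger for an executed pump job
#'
#' Scheduled aspirations, pulls and the aspirate half of a cycle add their
#' commanded volume to the expected reservoir level; dispenses are
#' well-directed and leave the reservoir expectation unchanged. Corrective
#' (feedback-origin) jobs aim at restoring the existing expectation, so they
#' are recorded in the history with a zero delta.
#'
#' @param ledger an [expectation_ledger()].
#' @param job a [pump_job()].
#' @param timestamp seconds (or simulated hours) for the history entry.
#' @return the updated ledger.
#' @export
update_ledger <- function(ledger, job, timestamp = NA_real_) {
  if (ledger$halted)
    stop_illegal_state("ledger is halted; reset before further updates")
  delta <- 0
  if (job$origin == "scheduled") {
    if (job$kind %in% c("aspirate", "pull", "cycle")) delta <- job$volume_ul
    if (job$kind == "dispense" && identical(job$target, "reservoir"))
      delta <- job$volume_ul
  }
  ledger$expected_ul <- ledger$expected_ul + delta
  ledger$history[[length(ledger$history) + 1L]] <-
    list(timestamp = timestamp, job = job, delta = delta)
  ledger
}

#' Reset the ledger after a collection-reservoir change
#'
#' The expectation is reset to the current estimate (not zero), so residual
#' media in a swapped tube is tolerated.
#'
#' @param ledger an [expectation_ledger()].
#' @param estimate_ul the estimate that revealed the tube change.
#' @return the reset ledger.
#' @export
reset_ledger_tube_change <- function(ledger, estimate_ul) {
  ledger$expected_ul <- max(estimate_ul, 0)
  ledger$last_estimate_ul <- estimate_ul
  ledger$history[[length(ledger$history) + 1L]] <-
    list(timestamp = NA_real_, job = list(kind = "tube_change"),
         delta = NA_real_)
  ledger
}

#' Run the closed feedback loop for one trigger
#'
#' Iterates image -> estimate -> classify -> plan -> execute until the
#' estimate is within tolerance, a tube change is recognised, or the loop
#' halts (anomaly, escalation exhausted, or a safety bound: measured
#' feedback perfusion beyond the configured cap, or the retry bound).
#'
#' @param pump function(job) executing a [pump_job()] on the rig.
#' @param imager function() returning a [reservoir_image()].
#' @param estimator function(image) returning a volume estimate in uL (or a
#'   `volume_estimate`).
#' @param ledger an [expectation_ledger()].
#' @param config a [feedback_config()].
#' @param notifier function(message) used for alerts (default: a console
#'   message).
#' @param timestamp timestamp recorded on log entries.
#' @param estimator_retries re-captures allowed on imager/estimator failure
#'   before alerting.
#' @return list with `ledger` (updated), `status` (`"within_tolerance"`,
#'   `"tube_change"`, or `"halted"`), `alert`, `iterations`, and `log`
#'   (data.frame of per-iteration estimates, categories and job counts).
#' @export
run_feedback_loop <- function(pump, imager, estimator, ledger,
                              config = feedback_config(), notifier = NULL,
                              timestamp = NA_real_, estimator_retries = 2) {
  notifier <- notifier %||% function(msg) message("[alert] ", msg)
  log <- list()
  iteration <- 0L
  dispenses_used <- 0L
  perfusion_ul <- 0
  prev_est <- NA_real_
  alert <- FALSE
  status <- NULL

  take_estimate <- function() {
    for (k in seq_len(estimator_retries + 1L)) {
      est <- tryCatch({
        e <- estimator(imager())
        if (inherits(e, "volume_estimate")) {
          if (e$status != "ok") stop("estimate rejected by quality gates")
          e$volume_ul
        } else e
      }, error = function(err) NULL)
      if (!is.null(est)) return(est)
    }
    NULL
  }

  repeat {
    est <- take_estimate()
    if (is.null(est)) {
      notifier("imager/estimator failure; manual intervention requested")
      ledger$halted <- TRUE
      alert <- TRUE; status <- "halted"
      break
    }
    if (iteration > 0L && !is.na(prev_est))
      perfusion_ul <- perfusion_ul + abs(est - prev_est)
    prev_est <- est
    category <- classify_estimate(est, ledger, config)
    ledger$last_estimate_ul <- est
    log_row <- function(it, n_jobs) {
      log[[length(log) + 1L]] <<- data.frame(
        timestamp = timestamp, iteration = it, estimate_ul = est,
        expected_ul = ledger$expected_ul, category = category,
        n_jobs = n_jobs)
    }
    if (category == "within_tolerance") {
      log_row(iteration, 0L); status <- "within_tolerance"; break
    }
    if (category == "tube_change") {
      log_row(iteration, 0L)
      ledger <- reset_ledger_tube_change(ledger, est)
      status <- "tube_change"; break
    }
    if (category == "anomaly") {
      log_row(iteration, 0L)
      notifier("anomaly: estimate exceeds expectation by 2 mL or more")
      ledger$halted <- TRUE; alert <- TRUE; status <- "halted"; break
    }
    if (perfusion_ul > config$safety_total_perfusion_ul ||
        iteration >= config$safety_max_retries) {
      log_row(iteration, 0L)
      notifier("safety bound reached during feedback; halting")
      ledger$halted <- TRUE; alert <- TRUE; status <- "halted"; break
    }
    iteration <- iteration + 1L
    plan <- next_jobs(category, est - ledger$expected_ul, iteration, config,
                      dispenses_used)
    log_row(iteration, length(plan$jobs))
    if (plan$halt || plan$alert) {
      if (plan$alert) notifier("feedback escalation exhausted; manual intervention requested")
      ledger$halted <- ledger$halted || plan$halt
      alert <- alert || plan$alert
      status <- "halted"; break
    }
    if (any(vapply(plan$jobs, function(j) j$kind == "dispense", TRUE)))
      dispenses_used <- dispenses_used + 1L
    for (job in plan$jobs) {
      pump(job)
      ledger <- update_ledger(ledger, job, timestamp)
    }
  }
  list(ledger = ledger, status = status, alert = alert,
       iterations = iteration, log = do.call(rbind, log))
}
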