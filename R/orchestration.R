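# Device scheduling under simulated time: periodic schedules, a
# chronological job scheduler with recording exclusivity and cooperative,
# job-atomic pause/defer semantics, and device shadows updated on every
# transition.

#' Declare a device for the scheduler
#'
#' @param name device name.
#' @param commands declared command set; submissions with other commands are
#'   rejected.
#' @param exclusive logical; an exclusive device (e.g. the electrophysiology
#'   recording unit) pauses all other devices while its jobs run: it starts
#'   only once every device is idle (running jobs complete atomically), and
#'   no other job may start inside its window.
#' @return object of class `device_spec`.
#' @export
device_spec <- function(name, commands, exclusive = FALSE) {
  structure(list(name = name, commands = commands, exclusive = exclusive),
            class = "device_spec")
}

#' Build a periodic/one-shot schedule
#'
#' @param periodic list of entries from [periodic_entry()].
#' @param oneshot list of entries from [oneshot_entry()].
#' @return object of class `rig_schedule`.
#' @export
rig_schedule <- function(periodic = list(), oneshot = list()) {
  structure(list(periodic = periodic, oneshot = oneshot),
            class = "rig_schedule")
}

#' @rdname rig_schedule
#' @param device,command target device and command.
#' @param period_h period in hours.
#' @param phase_h offset of the first occurrence.
#' @param duration_h job duration in hours.
#' @param params job parameters (e.g. `volume_ul`).
#' @export
periodic_entry <- function(device, command, period_h, phase_h = 0,
                           duration_h = 0, params = list()) {
  stopifnot(period_h > 0, phase_h >= 0, duration_h >= 0)
  list(device = device, command = command, period_h = period_h,
       phase_h = phase_h, duration_h = duration_h, params = params)
}

#' @rdname rig_schedule
#' @param time_h execution time of the one-shot entry.
#' @export
oneshot_entry <- function(device, command, time_h, duration_h = 0,
                          params = list()) {
  list(device = device, command = command, time_h = time_h,
       duration_h = duration_h, params = params)
}

#' Expand a schedule over a horizon into job submissions
#'
#' Periodic entries fire at `phase_h + k * period_h` for every occurrence
#' strictly before `horizon_h`. A feed-every-6-h schedule over 7 days yields
#' 28 feed jobs; hourly recording over 36 h yields 36 record jobs.
#'
#' @param sched a [rig_schedule()].
#' @param horizon_h horizon in hours (exclusive).
#' @return data.frame of submissions: `device`, `command`, `ready_h`,
#'   `duration_h`.
#' @export
expand_schedule <- function(sched, horizon_h) {
  rows <- list()
  for (e in sched$periodic) {
    times <- seq(e$phase_h, horizon_h - 1e-9, by = e$period_h)
    times <- times[times < horizon_h]
    for (t in times)
      rows[[length(rows) + 1L]] <- data.frame(
        device = e$device, command = e$command, ready_h = t,
        duration_h = e$duration_h)
  }
  for (e in sched$oneshot)
    rows[[length(rows) + 1L]] <- data.frame(
      device = e$device, command = e$command, ready_h = e$time_h,
      duration_h = e$duration_h)
  out <- do.call(rbind, rows) %||% data.frame(device = character(),
                                              command = character(),
                                              ready_h = numeric(),
                                              duration_h = numeric())
  out[order(out$ready_h), , drop = FALSE]
}

#' Default job priorities
#'
#' Recording outranks feeding, feeding outranks imaging, imaging outranks
#' uploading; unknown commands get priority 0.
#'
#' @return named numeric vector.
#' @export
default_priorities <- function() {
  c(record = 4, feed = 3, image = 2, upload = 1)
}

#' Run submissions through the device scheduler under simulated time
#'
#' A deterministic chronological scheduler: among all queued jobs it
#' repeatedly commits the one with the earliest feasible start (ties broken
#' by exclusivity, then priority, then ready time, then submission order).
#' Exclusive-device jobs wait for every device to go idle and block all
#' other starts for their duration; a job already running when an exclusive
#' job becomes ready completes first (pause is cooperative and job-atomic).
#' Jobs whose start was pushed past an exclusive window are flagged
#' `deferred`. Every transition appends a device-shadow row.
#'
#' @param devices list of [device_spec()].
#' @param submissions data.frame with columns `device`, `command`, `ready_h`,
#'   `duration_h`, and optionally `fails` (logical fault injection).
#' @param priorities named priority vector as in [default_priorities()].
#' @return list with `jobs` (submissions plus `status`
#'   done/failed/rejected, `start_h`, `end_h`, `deferred`), `shadows`
#'   (data.frame of time, device, state, job id), and `windows` (committed
#'   exclusive windows).
#' @export
simulate_devices <- function(devices, submissions,
                             priorities = default_priorities()) {
  dev_names <- vapply(devices, function(d) d$name, "")
  names(devices) <- dev_names
  jobs <- submissions
  n <- nrow(jobs)
  jobs$id <- seq_len(n)
  if (is.null(jobs$fails)) jobs$fails <- FALSE
  jobs$priority <- unname(priorities[jobs$command])
  jobs$priority[is.na(jobs$priority)] <- 0
  jobs$status <- "queued"
  jobs$start_h <- NA_real_
  jobs$end_h <- NA_real_
  jobs$deferred <- FALSE

  unknown_dev <- !jobs$device %in% dev_names
  bad_cmd <- !unknown_dev & !mapply(function(d, cmd) cmd %in% devices[[d]]$commands,
                                    jobs$device, jobs$command)
  jobs$status[unknown_dev | bad_cmd] <- "rejected"

  busy_until <- stats::setNames(rep(0, length(dev_names)), dev_names)
  windows <- list()   # committed exclusive windows: list(start, end, device)
  shadows <- list()
  shadow <- function(time, device, state, job_id = NA_integer_) {
    shadows[[length(shadows) + 1L]] <<- data.frame(
      time_h = time, device = device, state = state, job_id = job_id)
  }
  for (d in dev_names) shadow(0, d, "idle")

  is_excl <- function(j) devices[[jobs$device[j]]]$exclusive

  feasible_start <- function(j) {
    dev <- jobs$device[j]
    if (is_excl(j)) {
      t0 <- max(jobs$ready_h[j], max(busy_until))
      list(t = t0, pushed = FALSE)
    } else {
      t0 <- max(jobs$ready_h[j], busy_until[[dev]])
      pushed <- FALSE
      repeat {
        hit <- FALSE
        for (w in windows) {
          if (w$device != dev && t0 >= w$start - 1e-12 && t0 < w$end - 1e-12) {
            t0 <- w$end; pushed <- TRUE; hit <- TRUE
          }
        }
        if (!hit) break
      }
      list(t = t0, pushed = pushed)
    }
  }

  repeat {
    queued <- which(jobs$status == "queued")
    if (!length(queued)) break
    starts <- lapply(queued, feasible_start)
    ts <- vapply(starts, function(s) s$t, 0)
    # a queued exclusive job blocks any non-exclusive start at or after its
    # ready time: it must be committed first
    excl_q <- vapply(queued, is_excl, TRUE)
    if (any(excl_q)) {
      earliest_excl_ready <- min(jobs$ready_h[queued[excl_q]])
      blocked <- !excl_q & ts >= earliest_excl_ready - 1e-12
      ts[blocked] <- Inf
      starts[blocked] <- lapply(starts[blocked], function(s) {
        s$pushed <- TRUE; s
      })
    }
    ord <- order(ts, !excl_q, -jobs$priority[queued], jobs$ready_h[queued],
                 queued)
    pick <- ord[1]
    j <- queued[pick]
    t0 <- ts[pick]
    stopifnot(is.finite(t0))
    dev <- jobs$device[j]
    t1 <- t0 + jobs$duration_h[j]
    jobs$start_h[j] <- t0
    jobs$end_h[j] <- t1
    jobs$status[j] <- if (jobs$fails[j]) "failed" else "done"
    jobs$deferred[j] <- starts[[pick]]$pushed
    busy_until[[dev]] <- t1
    shadow(t0, dev, "busy", jobs$id[j])
    if (is_excl(j)) {
      windows[[length(windows) + 1L]] <- list(start = t0, end = t1, device = dev)
      for (d in setdiff(dev_names, dev)) shadow(t0, d, "paused")
      for (d in setdiff(dev_names, dev)) shadow(t1, d, "idle")
    }
    shadow(t1, dev, "idle")
  }

  win_df <- do.call(rbind, lapply(windows, function(w)
    data.frame(start_h = w$start, end_h = w$end, device = w$device))) %||%
    data.frame(start_h = numeric(), end_h = numeric(), device = character())
  list(jobs = jobs, shadows = do.call(rbind, shadows), windows = win_df)
}
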