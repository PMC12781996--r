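# In-process publish/subscribe broker with MQTT topic semantics. The broker
# is the test-default implementation of the messaging contract; an external
# MQTT-compatible broker can stand behind the same publish/subscribe surface.

validate_topic <- function(topic, allow_wildcards = FALSE) {
  if (!is.character(topic) || length(topic) != 1L || !nzchar(topic))
    stop_invalid("topic must be a non-empty string")
  levels <- strsplit(topic, "/", fixed = TRUE)[[1]]
  if (length(levels) == 0L) stop_invalid("malformed topic: ", topic)
  if (!allow_wildcards && any(grepl("[+#]", levels)))
    stop_invalid("wildcards are not allowed in a publish topic: ", topic)
  if (allow_wildcards) {
    hash <- which(levels == "#")
    if (length(hash) > 1L || (length(hash) == 1L && hash != length(levels)))
      stop_invalid("'#' may only appear once, as the final level: ", topic)
    if (any(grepl("[+#]", levels) & !levels %in% c("+", "#")))
      stop_invalid("'+' and '#' must occupy a whole level: ", topic)
  }
  levels
}

#' Match a topic against an MQTT-style pattern
#'
#' `+` matches exactly one level; `#` (final level only) matches any
#' remainder, including none.
#'
#' @param pattern subscription pattern, e.g. `"rig/+/jobs/#"`.
#' @param topic concrete slash-delimited topic.
#' @return logical.
#' @examples
#' topic_matches("a/+", "a/b")    # TRUE
#' topic_matches("a/#", "a/b/c")  # TRUE
#' @export
topic_matches <- function(pattern, topic) {
  p <- validate_topic(pattern, allow_wildcards = TRUE)
  t <- validate_topic(topic, allow_wildcards = FALSE)
  i <- 1L
  repeat {
    if (i > length(p)) return(i > length(t))
    if (p[i] == "#") return(TRUE)
    if (i > length(t)) return(FALSE)
    if (p[i] != "+" && p[i] != t[i]) return(FALSE)
    i <- i + 1L
  }
}

#' Create an in-process message broker
#'
#' Delivery is synchronous and at-least-once: every subscription whose
#' pattern matches the published topic receives the message.
#'
#' @return an environment with functions `subscribe(pattern, callback)`,
#'   `unsubscribe(id)`, `publish(topic, payload)` (returns the number of
#'   deliveries) and `journal()` (data.frame of published messages).
#' @export
inproc_broker <- function() {
  self <- new.env(parent = emptyenv())
  self$subs <- list()
  self$next_id <- 1L
  self$log <- list()
  self$subscribe <- function(pattern, callback) {
    validate_topic(pattern, allow_wildcards = TRUE)
    stopifnot(is.function(callback))
    id <- self$next_id
    self$next_id <- id + 1L
    self$subs[[as.character(id)]] <- list(pattern = pattern, callback = callback)
    id
  }
  self$unsubscribe <- function(id) {
    self$subs[[as.character(id)]] <- NULL
    invisible(NULL)
  }
  self$publish <- function(topic, payload = NULL) {
    validate_topic(topic, allow_wildcards = FALSE)
    delivered <- 0L
    for (s in self$subs) {
      if (topic_matches(s$pattern, topic)) {
        s$callback(topic, payload)
        delivered <- delivered + 1L
      }
    }
    self$log[[length(self$log) + 1L]] <- list(topic = topic, delivered = delivered)
    delivered
  }
  self$journal <- function() {
    do.call(rbind, lapply(self$log, function(x)
      data.frame(topic = x$topic, delivered = x$delivered)))
  }
  class(self) <- "inproc_broker"
  self
}

#' Construct a job request message
#'
#' @param topic hierarchical slash-delimited topic.
#' @param command command name for the receiving device.
#' @param params named list of command parameters.
#' @param requester requesting device or user.
#' @param timestamp seconds (or simulated hours).
#' @return object of class `job_request`.
#' @export
job_request <- function(topic, command, params = list(), requester = "user",
                        timestamp = 0) {
  validate_topic(topic, allow_wildcards = FALSE)
  structure(list(topic = topic, command = command, params = params,
                 requester = requester, timestamp = timestamp),
            class = "job_request")
}

#' Connect a device to the broker
#'
#' The device subscribes to `devices/<name>/#` and accepts only its declared
#' commands; requests carrying any other command are rejected and logged,
#' never executed.
#'
#' @param broker an [inproc_broker()].
#' @param name device name.
#' @param commands declared command set.
#' @return an environment with the device `inbox` (accepted requests) and
#'   `rejected` (refused requests) plus the broker subscription id.
#' @export
device_connect <- function(broker, name, commands) {
  dev <- new.env(parent = emptyenv())
  dev$name <- name
  dev$commands <- commands
  dev$inbox <- list()
  dev$rejected <- list()
  dev$sub_id <- broker$subscribe(paste0("devices/", name, "/#"),
    function(topic, payload) {
      if (inherits(payload, "job_request") && !payload$command %in% dev$commands)
        dev$rejected[[length(dev$rejected) + 1L]] <- payload
      else
        dev$inbox[[length(dev$inbox) + 1L]] <- payload
    })
  class(dev) <- "rig_device"
  dev
}
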