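# Experiment metadata and the checksum-verified upload queue, against an
# S3-style blob store abstracted as a key/value interface with a
# local-directory implementation.

#' Initialise an experiment and its metadata record
#'
#' Writes `metadata.json` holding the experiment UUID, notes, device list
#' and an (initially empty) index of produced data, with raw and analyzed
#' files under distinct sub-keys. Refuses to overwrite an existing
#' experiment (UUID collision).
#'
#' @param dir experiment directory (created if needed).
#' @param uuid experiment identifier; generated when `NULL`.
#' @param notes free-text notes.
#' @param devices participating device names.
#' @return the metadata list, invisibly.
#' @export
init_experiment <- function(dir, uuid = NULL, notes = "",
                            devices = character()) {
  path <- file.path(dir, "metadata.json")
  if (file.exists(path))
    stop_illegal_state("experiment already initialised at ", path,
                       " (UUID collision refused)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  uuid <- uuid %||% paste0("exp-", paste(sample(c(letters, 0:9), 12,
                                                replace = TRUE),
                                         collapse = ""))
  meta <- list(uuid = uuid, notes = notes, devices = as.list(devices),
               data_index = list(raw = list(), analyzed = list()))
  write_metadata(meta, dir)
  invisible(meta)
}

#' @rdname init_experiment
#' @param meta a metadata list.
#' @export
write_metadata <- function(meta, dir) {
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "list")
  invisible(meta)
}

#' @rdname init_experiment
#' @export
read_metadata <- function(dir) {
  jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = FALSE)
}

#' Append a produced file to the experiment's data index
#'
#' The index is append-only: existing entries are never dropped.
#'
#' @param dir experiment directory.
#' @param key storage key of the produced file.
#' @param checksum file checksum (MD5).
#' @param kind `"raw"` or `"analyzed"`.
#' @return the updated metadata list, invisibly.
#' @export
add_data_record <- function(dir, key, checksum, kind = c("raw", "analyzed")) {
  kind <- match.arg(kind)
  meta <- read_metadata(dir)
  meta$data_index[[kind]][[length(meta$data_index[[kind]]) + 1L]] <-
    list(key = key, checksum = checksum)
  write_metadata(meta, dir)
  invisible(meta)
}

#' Local-directory blob store
#'
#' A key/value blob interface standing in for S3-style object storage:
#' `put(key, src)` copies a file under the key, `checksum(key)` returns the
#' MD5 of the stored object, `exists(key)` tests presence.
#'
#' @param root storage root directory.
#' @return an environment implementing the store interface.
#' @export
local_blob_store <- function(root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  self <- new.env(parent = emptyenv())
  self$path_for <- function(key) file.path(root, key)
  self$put <- function(key, src) {
    dest <- self$path_for(key)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    file.copy(src, dest, overwrite = TRUE)
    invisible(key)
  }
  self$checksum <- function(key) md5_file(self$path_for(key))
  self$exists <- function(key) file.exists(self$path_for(key))
  class(self) <- "blob_store"
  self
}

#' Create an upload-queue record
#'
#' @param path local file to upload (must exist and be closed).
#' @param key destination key (typically prefixed by the experiment UUID).
#' @param max_retries retry bound.
#' @return object of class `upload_record`.
#' @export
upload_record <- function(path, key, max_retries = 5) {
  if (!file.exists(path)) stop_invalid("file does not exist: ", path)
  structure(list(path = path, key = key, checksum = md5_file(path),
                 retries = 0L, max_retries = max_retries,
                 status = "pending", alert = FALSE),
            class = "upload_record")
}

#' Advance an upload record by one attempt
#'
#' Transfers the file, verifies the stored checksum against the local one,
#' and marks the record `uploaded` only on verification; a mismatch (or a
#' failed transfer) increments the retry count, and exhausting
#' `max_retries` marks the record `failed` with an alert.
#'
#' @param record an [upload_record()].
#' @param store a blob store (see [local_blob_store()]).
#' @return the updated record.
#' @export
upload_queue_step <- function(record, store) {
  if (record$status %in% c("uploaded", "failed")) return(record)
  ok <- tryCatch({
    store$put(record$key, record$path)
    identical(store$checksum(record$key), record$checksum)
  }, error = function(e) FALSE)
  if (ok) {
    record$status <- "uploaded"
  } else {
    record$retries <- record$retries + 1L
    if (record$retries >= record$max_retries) {
      record$status <- "failed"
      record$alert <- TRUE
    }
  }
  record
}

#' Drive an upload record to a terminal state
#'
#' @inheritParams upload_queue_step
#' @return the record, with status `"uploaded"` or `"failed"`.
#' @export
process_upload <- function(record, store) {
  while (!record$status %in% c("uploaded", "failed"))
    record <- upload_queue_step(record, store)
  record
}
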