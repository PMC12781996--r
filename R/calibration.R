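# Pixel-area to volume calibration: the piecewise cubic model, least-squares
# fitting, leave-one-out validation, and JSON/CSV persistence.

#' Piecewise cubic calibration model
#'
#' Maps segmented pixel area to volume in microlitres with one cubic for the
#' conical section of the tube and one for the cylindrical section,
#' switching at `breakpoint_area` pixels.
#'
#' @param conical_coeffs,cylindrical_coeffs numeric length-4 coefficient
#'   vectors in descending degree; output in microlitres.
#' @param breakpoint_area pixel area separating the two branches.
#' @param reference logical; `TRUE` for the published reference constants.
#' @param breakpoint_volume volume at the branch switch, if known.
#' @return object of class `calibration_model`.
#' @export
calibration_model <- function(conical_coeffs, cylindrical_coeffs,
                              breakpoint_area, reference = FALSE,
                              breakpoint_volume = NULL) {
  stopifnot(length(conical_coeffs) == 4, length(cylindrical_coeffs) == 4,
            is.numeric(breakpoint_area), breakpoint_area > 0)
  gap <- abs(polyval(conical_coeffs, breakpoint_area) -
             polyval(cylindrical_coeffs, breakpoint_area))
  if (gap >= 30)
    warning(sprintf("branch values differ by %.1f uL at the breakpoint (>= 30)", gap))
  structure(list(conical_coeffs = conical_coeffs,
                 cylindrical_coeffs = cylindrical_coeffs,
                 breakpoint_area = breakpoint_area,
                 reference = reference,
                 breakpoint_volume = breakpoint_volume),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model%s: breakpoint %.0f px>\n",
              if (x$reference) " (reference constants)" else "",
              x$breakpoint_area))
  cat("  conical:    ", paste(signif(x$conical_coeffs, 4), collapse = "  "), "\n")
  cat("  cylindrical:", paste(signif(x$cylindrical_coeffs, 4), collapse = "  "), "\n")
  invisible(x)
}

#' Published reference calibration constants
#'
#' The piecewise cubic with the printed study constants: conical branch for
#' pixel areas under 4446, cylindrical branch at or above.
#'
#' @return a [calibration_model()].
#' @examples
#' estimate_volume(4446, reference_calibration())  # ~1481 uL
#' @export
reference_calibration <- function() {
  calibration_model(conical_coeffs = c(5.09e-9, 2.39e-5, 0.13, -1.28),
                    cylindrical_coeffs = c(2.60e-11, 5.38e-7, 0.62, -1288.37),
                    breakpoint_area = 4446, reference = TRUE,
                    breakpoint_volume = 1500)
}

#' Convert pixel area to a volume estimate in microlitres
#'
#' Applies the conical branch below the model's breakpoint area and the
#' cylindrical branch at or above it. Negative polynomial output is clamped
#' to 0 uL.
#'
#' @param pixel_area nonnegative pixel count (vectorised).
#' @param model a [calibration_model()].
#' @return volume in microlitres, >= 0.
#' @export
estimate_volume <- function(pixel_area, model = reference_calibration()) {
  if (any(pixel_area < 0)) stop_invalid("pixel_area must be >= 0")
  v <- ifelse(pixel_area < model$breakpoint_area,
              polyval(model$conical_coeffs, pixel_area),
              polyval(model$cylindrical_coeffs, pixel_area))
  pmax(v, 0)
}

#' Calibration dataset of (pixel area, volume) pairs
#'
#' @param pixel_area numeric vector of segmented pixel areas.
#' @param volume_ul matched true volumes in microlitres, within
#'   \[0, 12000\].
#' @param source free-text provenance note.
#' @return a `calibration_dataset` (also a data.frame).
#' @export
calibration_dataset <- function(pixel_area, volume_ul, source = "") {
  stopifnot(length(pixel_area) == length(volume_ul))
  if (any(volume_ul < 0 | volume_ul > 12000))
    stop_invalid("true volumes must lie in [0, 12000] uL")
  structure(data.frame(pixel_area = pixel_area, volume_ul = volume_ul),
            source = source,
            class = c("calibration_dataset", "data.frame"))
}

fit_branch <- function(area, volume, degree) {
  fit <- try(stats::lm(volume ~ stats::poly(area, degree, raw = TRUE)),
             silent = TRUE)
  if (inherits(fit, "try-error") || anyNA(stats::coef(fit)))
    stop(structure(class = c("organoidrig_fit_failure", "error", "condition"),
                   list(message = "calibration fit failed: rank-deficient design",
                        call = sys.call())))
  rev(unname(stats::coef(fit)))          # descending degree
}

#' Fit the piecewise calibration from a dataset
#'
#' Entries with true volume below `breakpoint_volume` feed the conical cubic,
#' the rest the cylindrical cubic (each branch needs at least 8 entries). The
#' pixel-area breakpoint is the root of the conical fit at
#' `breakpoint_volume`.
#'
#' @param dataset a [calibration_dataset()].
#' @param breakpoint_volume volume (uL) separating the branches.
#' @param degree polynomial degree per branch (default 3, matching the
#'   reference model).
#' @return a [calibration_model()].
#' @export
fit_calibration <- function(dataset, breakpoint_volume = 1500, degree = 3) {
  con <- dataset$volume_ul < breakpoint_volume
  if (sum(con) < 8 || sum(!con) < 8)
    stop_invalid("need at least 8 entries per branch (have ",
                 sum(con), " conical, ", sum(!con), " cylindrical)")
  conical <- fit_branch(dataset$pixel_area[con], dataset$volume_ul[con], degree)
  cylindrical <- fit_branch(dataset$pixel_area[!con], dataset$volume_ul[!con], degree)
  pad <- function(co) c(rep(0, 4 - length(co)), co)
  # The breakpoint lies at or just beyond the conical branch's area range;
  # bracket the root there rather than trusting the cubic far outside it.
  f <- function(x) polyval(conical, x) - breakpoint_volume
  xs <- seq(0, 2 * max(dataset$pixel_area[con]) + 1, length.out = 2048)
  sgn <- sign(f(xs))
  flip <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (!length(flip))
    stop_invalid("could not locate the breakpoint area: conical fit never reaches ",
                 breakpoint_volume, " uL")
  bp <- stats::uniroot(f, c(xs[flip[1]], xs[flip[1] + 1]))$root
  calibration_model(pad(conical), pad(cylindrical), bp,
                    reference = FALSE, breakpoint_volume = breakpoint_volume)
}

#' Leave-one-out validation of the calibration
#'
#' Each entry is predicted by a model refit on all remaining entries. Errors
#' are aggregated in microlitres and as percentages under two documented
#' denominators: percent of the entry's true volume (entries with zero true
#' volume are excluded from that average) and percent of the full 12 mL
#' scale.
#'
#' @inheritParams fit_calibration
#' @param full_scale_ul denominator for the percent-of-full-scale metrics.
#' @return object of class `loo_metrics`: `mae_ul`, `mae_pct_true`,
#'   `mae_pct_fullscale`, `sd_ul`, `sd_pct_fullscale`, `rmse_ul`,
#'   `rmse_pct_fullscale`, `r2_conical`, `r2_cylindrical`, plus per-entry
#'   `predicted` and `error_ul`.
#' @export
loo_metrics <- function(dataset, breakpoint_volume = 1500, degree = 3,
                        full_scale_ul = 12000) {
  n <- nrow(dataset)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    m <- fit_calibration(dataset[-i, , drop = FALSE], breakpoint_volume, degree)
    pred[i] <- estimate_volume(dataset$pixel_area[i], m)
  }
  err <- pred - dataset$volume_ul
  con <- dataset$volume_ul < breakpoint_volume
  r2 <- function(truth, p) {
    if (length(truth) < 2) return(NA_real_)
    1 - sum((p - truth)^2) / sum((truth - mean(truth))^2)
  }
  pos <- dataset$volume_ul > 0
  structure(list(
    mae_ul = mean(abs(err)),
    mae_pct_true = if (any(pos)) 100 * mean(abs(err[pos]) / dataset$volume_ul[pos]) else NA_real_,
    mae_pct_fullscale = 100 * mean(abs(err)) / full_scale_ul,
    sd_ul = stats::sd(err),
    sd_pct_fullscale = 100 * stats::sd(err) / full_scale_ul,
    rmse_ul = sqrt(mean(err^2)),
    rmse_pct_fullscale = 100 * sqrt(mean(err^2)) / full_scale_ul,
    r2_conical = r2(dataset$volume_ul[con], pred[con]),
    r2_cylindrical = r2(dataset$volume_ul[!con], pred[!con]),
    predicted = pred, error_ul = err, n = n), class = "loo_metrics")
}

#' @export
print.loo_metrics <- function(x, ...) {
  cat(sprintf("Leave-one-out validation over %d entries\n", x$n))
  cat(sprintf("  MAE  %.1f uL (%.2f%% of true volume, %.2f%% of full scale)\n",
              x$mae_ul, x$mae_pct_true, x$mae_pct_fullscale))
  cat(sprintf("  RMSE %.1f uL (%.2f%% of full scale); error SD %.1f uL\n",
              x$rmse_ul, x$rmse_pct_fullscale, x$sd_ul))
  cat(sprintf("  R2: conical %.4f, cylindrical %.4f\n",
              x$r2_conical, x$r2_cylindrical))
  invisible(x)
}

#' Persist a calibration model as JSON
#'
#' @param model a [calibration_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(model, path) {
  jsonlite::write_json(list(conical_coeffs = model$conical_coeffs,
                            cylindrical_coeffs = model$cylindrical_coeffs,
                            breakpoint_area = model$breakpoint_area,
                            breakpoint_volume = model$breakpoint_volume,
                            reference = model$reference,
                            note = "pixel-area to microlitre piecewise cubic"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(j$conical_coeffs, j$cylindrical_coeffs, j$breakpoint_area,
                    reference = isTRUE(j$reference),
                    breakpoint_volume = j$breakpoint_volume)
}

#' Read a calibration table from CSV
#'
#' The CSV must carry a `volume_ul` column plus either `pixel_area` or
#' `image_path` (PNG paths, measured with [measure_pixel_area()]).
#'
#' @param path CSV file.
#' @param ... passed to [measure_pixel_area()] when areas are measured from
#'   images.
#' @return a [calibration_dataset()].
#' @export
read_calibration_csv <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"volume_ul" %in% names(df)) stop_invalid("CSV must have a volume_ul column")
  if ("pixel_area" %in% names(df)) {
    area <- df$pixel_area
  } else if ("image_path" %in% names(df)) {
    area <- vapply(file.path(dirname(path), df$image_path), function(p)
      as.numeric(measure_pixel_area(read_reservoir_png(p), ...)$pixel_area), 0)
  } else stop_invalid("CSV must have a pixel_area or image_path column")
  calibration_dataset(area, df$volume_ul, source = path)
}
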