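# The end-to-end volume estimator: quality gates -> profiles -> boundary ->
# segmentation -> calibrated piecewise cubic. Images failing quality are
# never passed to the volume model.

#' Estimate fluid volume from a reservoir image
#'
#' Runs the full pipeline. An image failing either quality gate is rejected
#' (`status = "rejected_quality"`, no volume). Flat profiles are interpreted
#' as an empty tube (pixel area 0).
#'
#' @param image a [reservoir_image()].
#' @param model a [calibration_model()].
#' @inheritParams check_quality
#' @inheritParams segment_fluid
#' @inheritParams detect_boundary
#' @return object of class `volume_estimate`: `status` (`"ok"` or
#'   `"rejected_quality"`), `volume_ul` (NA when rejected), `pixel_area`,
#'   `boundary_row`, `quality` (a `quality_report`).
#' @export
estimate_image_volume <- function(image, model = reference_calibration(),
                                  lighting_threshold = 20, blur_threshold = 50,
                                  lighting_roi = NULL,
                                  bounds = meniscus_hsv_bounds(),
                                  band_rows = 30, noise_floor = 0.5) {
  q <- check_quality(image, lighting_threshold, blur_threshold, lighting_roi)
  if (!q$lighting_pass || !q$blur_pass)
    return(structure(list(status = "rejected_quality", volume_ul = NA_real_,
                          pixel_area = NA_integer_, boundary_row = NA_integer_,
                          quality = q), class = "volume_estimate"))
  m <- measure_pixel_area(image, bounds, band_rows, noise_floor)
  structure(list(status = "ok",
                 volume_ul = estimate_volume(m$pixel_area, model),
                 pixel_area = m$pixel_area, boundary_row = m$boundary_row,
                 quality = q), class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("<volume_estimate: %.0f uL from %d px>\n", x$volume_ul, x$pixel_area))
  else
    cat("<volume_estimate: rejected by quality gates>\n")
  invisible(x)
}

#' Build a calibration dataset from rendered images
#'
#' Renders each volume, measures its pixel area with the vision pipeline and
#' optionally perturbs the measured areas with multiplicative uniform noise
#' (`area_noise = 0.01` means +/-1%). Uses the current RNG stream.
#'
#' @param volumes true volumes in microlitres.
#' @param config a [render_config()].
#' @param area_noise half-width of the relative uniform area perturbation.
#' @return a [calibration_dataset()].
#' @export
render_calibration_dataset <- function(volumes, config = render_config(),
                                       area_noise = 0) {
  area <- vapply(volumes, function(v) {
    r <- render_reservoir(v, config)
    as.numeric(measure_pixel_area(r$image)$pixel_area)
  }, 0)
  if (area_noise > 0)
    area <- area * (1 + stats::runif(length(area), -area_noise, area_noise))
  calibration_dataset(area, volumes, source = "rendered")
}
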