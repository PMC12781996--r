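# Fluid segmentation: image quality gates, HSV row profiles, meniscus
# detection, and the fill-level pixel-area segmentation.

#' Image quality report: lighting and blurriness gates
#'
#' Lighting is checked as the per-channel mean RGB over a designated lighting
#' ROI (all three means must exceed `lighting_threshold`, default 20/255).
#' Blurriness is checked as the variance of the Laplacian of the grayscale
#' patch, which must reach `blur_threshold` (default 50).
#'
#' @param image a [reservoir_image()].
#' @param lighting_threshold minimum per-channel mean (8-bit units).
#' @param blur_threshold minimum variance of the Laplacian.
#' @param lighting_roi optional `c(top, bottom, left, right)` rectangle for
#'   the lighting check; defaults to the image ROI.
#' @return an object of class `quality_report` with fields `mean_rgb`,
#'   `lighting_pass`, `laplacian_variance`, `blur_pass`.
#' @export
check_quality <- function(image, lighting_threshold = 20, blur_threshold = 50,
                          lighting_roi = NULL) {
  stopifnot(inherits(image, "reservoir_image"))
  lr <- lighting_roi %||% image$roi
  if (lr[1] > lr[2] || lr[3] > lr[4]) stop_invalid("lighting ROI is empty")
  sub <- image$pixels[lr[1]:lr[2], lr[3]:lr[4], , drop = FALSE]
  mean_rgb <- apply(sub, 3, mean)
  p <- image$patch
  gray <- 0.299 * image$pixels[p[1]:p[2], p[3]:p[4], 1] +
          0.587 * image$pixels[p[1]:p[2], p[3]:p[4], 2] +
          0.114 * image$pixels[p[1]:p[2], p[3]:p[4], 3]
  lap_var <- laplacian_variance(gray)
  structure(list(mean_rgb = mean_rgb,
                 lighting_pass = all(mean_rgb > lighting_threshold),
                 laplacian_variance = lap_var,
                 blur_pass = lap_var >= blur_threshold),
            class = "quality_report")
}

laplacian_variance <- function(gray) {
  n <- nrow(gray); m <- ncol(gray)
  if (n < 3 || m < 3) stop_invalid("patch too small for Laplacian")
  lap <- gray[1:(n - 2), 2:(m - 1)] + gray[3:n, 2:(m - 1)] +
         gray[2:(n - 1), 1:(m - 2)] + gray[2:(n - 1), 3:m] -
         4 * gray[2:(n - 1), 2:(m - 1)]
  stats::var(as.numeric(lap))
}

#' Row-wise HSV profiles of the tube patch
#'
#' Converts the profile patch to HSV and sums each channel across the patch
#' width, one entry per row, ordered bottom-to-top (entry 1 is the tube
#' bottom). Hue, saturation and value are on the \[0, 1\] scale.
#'
#' @param image a [reservoir_image()].
#' @return an object of class `hsv_profiles`: list of `hue`, `saturation`,
#'   `value` (numeric vectors) and `image_rows`, the image row each profile
#'   entry corresponds to.
#' @export
hsv_row_profiles <- function(image) {
  stopifnot(inherits(image, "reservoir_image"))
  p <- image$patch
  if (roi_width(p) < 3) stop_invalid("patch narrower than 3 px")
  sub <- image$pixels[p[1]:p[2], p[3]:p[4], , drop = FALSE]
  nr <- dim(sub)[1]; nc <- dim(sub)[2]
  rgb_mat <- rbind(as.numeric(sub[, , 1]), as.numeric(sub[, , 2]),
                   as.numeric(sub[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb_mat, maxColorValue = 255)
  sum_rows <- function(v) rowSums(matrix(v, nr, nc))
  bottom_to_top <- nr:1
  structure(list(hue = sum_rows(hsv[1, ])[bottom_to_top],
                 saturation = sum_rows(hsv[2, ])[bottom_to_top],
                 value = sum_rows(hsv[3, ])[bottom_to_top],
                 image_rows = (p[1]:p[2])[bottom_to_top]),
            class = "hsv_profiles")
}

#' Locate the air-liquid boundary from HSV row profiles
#'
#' The hue channel marks the boundary by its sharpest single-step rise
#' (maximum forward difference in bottom-to-top order), the saturation
#' channel by its absolute maximum, the value channel by its absolute
#' minimum. The boundary row is the arithmetic mean of the three channel
#' rows, rounded to the nearest integer with ties falling toward the tube
#' bottom (the larger image row).
#'
#' @param profiles an [hsv_row_profiles()] result, or a list with numeric
#'   `hue`, `saturation`, `value` of equal length (and optionally
#'   `image_rows`).
#' @param noise_floor minimum profile range (and minimum hue rise) required
#'   to accept a boundary; flat profiles signal a `boundary-not-found` error.
#' @return list with `boundary_row` (image row) and `channel_rows` (named
#'   hue/saturation/value image rows).
#' @export
detect_boundary <- function(profiles, noise_floor = 0.5) {
  hue <- profiles$hue; sat <- profiles$saturation; val <- profiles$value
  n <- length(hue)
  if (n < 3 || length(sat) != n || length(val) != n)
    stop_invalid("profiles must have equal length >= 3")
  rows <- profiles$image_rows %||% seq_len(n)
  d <- diff(hue)
  if (max(d) < noise_floor ||
      diff(range(sat)) < noise_floor || diff(range(val)) < noise_floor)
    stop(structure(class = c("organoidrig_boundary_not_found", "error", "condition"),
                   list(message = "boundary not found: profiles are flat",
                        call = sys.call())))
  hue_idx <- which.max(d) + 1L       # upper row of the sharpest rise
  sat_idx <- which.max(sat)
  val_idx <- which.min(val)
  channel_rows <- c(hue = rows[hue_idx], saturation = rows[sat_idx],
                    value = rows[val_idx])
  list(boundary_row = as.integer(round_half_down_row(mean(channel_rows))),
       channel_rows = channel_rows)
}

#' HSV bounds describing meniscus-colored pixels
#'
#' Defaults were chosen against rendered fixtures: a dark, strongly
#' saturated band. All components are on the \[0, 1\] scale.
#'
#' @param hue_range inclusive hue interval.
#' @param saturation_min minimum saturation.
#' @param value_max maximum value (brightness).
#' @return a named list used by [segment_fluid()].
#' @export
meniscus_hsv_bounds <- function(hue_range = c(0.60, 0.90),
                                saturation_min = 0.55, value_max = 0.55) {
  list(hue_range = hue_range, saturation_min = saturation_min,
       value_max = value_max)
}

#' Segment the fluid column given a boundary row
#'
#' The initial mask marks every ROI pixel strictly below `boundary_row` as
#' fluid (a fill-level rectangle). Pixels within a local band of
#' `band_rows` rows around the boundary whose HSV values fall inside
#' `bounds` are then added, incorporating the meniscus.
#'
#' @param image a [reservoir_image()].
#' @param boundary_row image row of the air-liquid interface; must lie
#'   within the ROI.
#' @param bounds a [meniscus_hsv_bounds()].
#' @param band_rows half-height of the meniscus refinement band.
#' @return object of class `fluid_segmentation`: `boundary_row`, `mask`
#'   (H x W logical), `pixel_area`.
#' @export
segment_fluid <- function(image, boundary_row, bounds = meniscus_hsv_bounds(),
                          band_rows = 30) {
  stopifnot(inherits(image, "reservoir_image"))
  roi <- image$roi
  if (boundary_row < roi[1] || boundary_row > roi[2])
    stop_invalid("boundary_row must lie within the roi")
  d <- dim(image$pixels)
  mask <- matrix(FALSE, d[1], d[2])
  if (boundary_row < roi[2])
    mask[(boundary_row + 1L):roi[2], roi[3]:roi[4]] <- TRUE
  band <- max(roi[1], boundary_row - band_rows):min(roi[2], boundary_row + band_rows)
  sub <- image$pixels[band, roi[3]:roi[4], , drop = FALSE]
  nr <- length(band); nc <- roi_width(roi)
  hsv <- grDevices::rgb2hsv(rbind(as.numeric(sub[, , 1]), as.numeric(sub[, , 2]),
                                  as.numeric(sub[, , 3])), maxColorValue = 255)
  in_bounds <- hsv[1, ] >= bounds$hue_range[1] & hsv[1, ] <= bounds$hue_range[2] &
               hsv[2, ] >= bounds$saturation_min & hsv[3, ] <= bounds$value_max
  mask[band, roi[3]:roi[4]] <- mask[band, roi[3]:roi[4]] | matrix(in_bounds, nr, nc)
  structure(list(boundary_row = as.integer(boundary_row), mask = mask,
                 pixel_area = as.integer(sum(mask))),
            class = "fluid_segmentation")
}

#' Measure the fluid pixel area of an image
#'
#' Convenience wrapper: profiles, boundary detection and segmentation in one
#' call. Flat profiles (an empty tube) yield a pixel area of 0.
#'
#' @inheritParams segment_fluid
#' @inheritParams detect_boundary
#' @return list with `pixel_area`, `boundary_row` (NA when no boundary was
#'   found) and `segmentation` (NULL for an empty tube).
#' @export
measure_pixel_area <- function(image, bounds = meniscus_hsv_bounds(),
                               band_rows = 30, noise_floor = 0.5) {
  prof <- hsv_row_profiles(image)
  b <- tryCatch(detect_boundary(prof, noise_floor = noise_floor),
                organoidrig_boundary_not_found = function(e) NULL)
  if (is.null(b))
    return(list(pixel_area = 0L, boundary_row = NA_integer_, segmentation = NULL))
  seg <- segment_fluid(image, b$boundary_row, bounds, band_rows)
  list(pixel_area = seg$pixel_area, boundary_row = b$boundary_row,
       segmentation = seg)
}
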