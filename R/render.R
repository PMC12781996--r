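# Synthetic reservoir-image renderer with known ground truth.
#
# The renderer draws a backlit 15 mL conical tube seen from the side: a
# bright, desaturated background (the LED panel), a fluid column whose height
# follows the conical-frustum / cylinder geometry, and a short dark,
# saturated meniscus band at the air-liquid interface. Colors are synthetic
# HSV triples chosen so the three channel profiles carry the signatures the
# boundary detector looks for; they are configurable and do not model real
# media color.

#' Renderer configuration
#'
#' @param px_per_mm image resolution in pixels per mm.
#' @param patch_width_px width of the central profile patch in pixels.
#' @param geom tube geometry, a [tube_geometry()].
#' @param fluid_hsv,meniscus_hsv,air_hsv HSV triples (each component in
#'   \[0, 1\]) for the fluid column, the meniscus band and the backlit air.
#' @param meniscus_band_rows number of meniscus rows drawn at the interface.
#' @param noise_sd Gaussian pixel noise, standard deviation in 8-bit units.
#' @param blur_passes number of 3 x 3 box-blur passes (0 = ideal sharp image).
#' @param lighting_scale multiplicative brightness factor (1 = nominal; small
#'   values emulate a failed LED panel).
#' @param margin_px `c(top, bottom, side)` margins around the tube ROI.
#' @return an object of class `render_config`.
#' @export
render_config <- function(px_per_mm = 6, patch_width_px = 12,
                          geom = tube_geometry(),
                          fluid_hsv = c(0.55, 0.50, 0.70),
                          meniscus_hsv = c(0.75, 0.85, 0.30),
                          air_hsv = c(0.10, 0.15, 0.95),
                          meniscus_band_rows = 3,
                          noise_sd = 4, blur_passes = 0, lighting_scale = 1,
                          margin_px = c(10L, 10L, 10L)) {
  stopifnot(px_per_mm > 0, patch_width_px >= 3, noise_sd >= 0,
            blur_passes >= 0, lighting_scale >= 0)
  structure(list(px_per_mm = px_per_mm, patch_width_px = as.integer(patch_width_px),
                 geom = geom, fluid_hsv = fluid_hsv, meniscus_hsv = meniscus_hsv,
                 air_hsv = air_hsv, meniscus_band_rows = as.integer(meniscus_band_rows),
                 noise_sd = noise_sd, blur_passes = as.integer(blur_passes),
                 lighting_scale = lighting_scale, margin_px = as.integer(margin_px)),
            class = "render_config")
}

hsv_to_rgb255 <- function(hsv_triple) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(hsv_triple[1], hsv_triple[2],
                                               hsv_triple[3])))
}

box_blur <- function(ch, passes) {
  for (i in seq_len(passes)) {
    p <- rbind(ch[1, ], ch, ch[nrow(ch), ])
    p <- cbind(p[, 1], p, p[, ncol(p)])
    n <- nrow(ch); m <- ncol(ch)
    ch <- (p[1:n, 1:m] + p[1:n, 2:(m + 1)] + p[1:n, 3:(m + 2)] +
           p[2:(n + 1), 1:m] + p[2:(n + 1), 2:(m + 1)] + p[2:(n + 1), 3:(m + 2)] +
           p[3:(n + 2), 1:m] + p[3:(n + 2), 2:(m + 1)] + p[3:(n + 2), 3:(m + 2)]) / 9
  }
  ch
}

render_layout <- function(config) {
  ppm <- config$px_per_mm
  g <- config$geom
  w_tube <- round(2 * g$radius_mm * ppm)
  h_max_px <- ceiling(fluid_height_mm(g$capacity_ul, g) * ppm)
  m <- config$margin_px
  roi_top <- m[1] + 1L
  roi_bottom <- roi_top + h_max_px + 10L       # 10 rows of headroom above 12 mL
  height <- roi_bottom + m[2]
  roi_left <- m[3] + 1L
  roi_right <- roi_left + w_tube - 1L
  width <- roi_right + m[3]
  pw <- config$patch_width_px
  c_mid <- (roi_left + roi_right) / 2
  p_left <- floor(c_mid - pw / 2 + 0.5)
  list(height = height, width = width,
       roi = c(roi_top, roi_bottom, roi_left, roi_right),
       patch = c(roi_top, roi_bottom, p_left, p_left + pw - 1L),
       apex_row = roi_bottom, c_mid = c_mid)
}

#' Render a reservoir image at a known fluid volume
#'
#' Draws the backlit tube with `volume_ul` of fluid and returns both the
#' image and the renderer's ground truth: the central meniscus row and the
#' fluid pixel area in the same fill-level convention the segmenter uses
#' (all ROI pixels strictly below the meniscus row, plus drawn meniscus
#' pixels at and above it). Uses the current RNG stream; seed with
#' [set.seed()] for reproducible images.
#'
#' @param volume_ul fluid volume in microlitres, within
#'   `[0, config$geom$capacity_ul]`.
#' @param config a [render_config()].
#' @inheritParams reservoir_image
#' @return a list with elements `image` (a [reservoir_image()]) and `truth`
#'   (list of `volume_ul`, `meniscus_row`, `pixel_area`).
#' @export
render_reservoir <- function(volume_ul, config = render_config(),
                             reservoir_id = "sim", timestamp = 0) {
  if (length(volume_ul) != 1 || !is.finite(volume_ul) || volume_ul < 0 ||
      volume_ul > config$geom$capacity_ul)
    stop_invalid("volume_ul must be a single value in [0, ",
                 config$geom$capacity_ul, "]")
  lay <- render_layout(config)
  ppm <- config$px_per_mm
  g <- config$geom
  air <- hsv_to_rgb255(config$air_hsv)
  fluid <- hsv_to_rgb255(config$fluid_hsv)
  meni <- hsv_to_rgb255(config$meniscus_hsv)

  px <- array(0, c(lay$height, lay$width, 3L))
  for (k in 1:3) px[, , k] <- air[k]

  meniscus_row <- NA_integer_
  men_px_at_or_above <- 0L
  if (volume_ul > 0) {
    h_mm <- fluid_height_mm(volume_ul, g)
    top_row <- lay$apex_row - round(h_mm * ppm)
    top_row <- max(top_row, lay$roi[1])
    band_end <- min(top_row + config$meniscus_band_rows - 1L, lay$apex_row)
    meniscus_row <- top_row + (band_end - top_row) %/% 2L
    cols <- seq_len(lay$width)
    for (r in top_row:lay$apex_row) {
      y_mm <- (lay$apex_row - r) / ppm
      hw_px <- tube_halfwidth_mm(y_mm, g) * ppm
      inside <- abs(cols - lay$c_mid) <= hw_px
      inside[cols < lay$roi[3] | cols > lay$roi[4]] <- FALSE
      if (!any(inside)) next
      col_ <- if (r <= band_end) meni else fluid
      for (k in 1:3) px[r, inside, k] <- col_[k]
      if (r <= meniscus_row && r <= band_end)
        men_px_at_or_above <- men_px_at_or_above + sum(inside)
    }
  }

  if (config$blur_passes > 0)
    for (k in 1:3) px[, , k] <- box_blur(px[, , k], config$blur_passes)
  if (config$noise_sd > 0)
    px <- px + array(stats::rnorm(length(px), 0, config$noise_sd), dim(px))
  px <- clamp(px * config$lighting_scale, 0, 255)
  px <- round(px)

  pixel_area <- if (is.na(meniscus_row)) 0L else
    roi_width(lay$roi) * (lay$roi[2] - meniscus_row) + men_px_at_or_above
  img <- reservoir_image(px, lay$roi, lay$patch, reservoir_id, timestamp)
  list(image = img,
       truth = list(volume_ul = volume_ul,
                    meniscus_row = meniscus_row,
                    pixel_area = as.integer(pixel_area)))
}
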