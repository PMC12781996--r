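# Reservoir photographs and their regions of interest.
#
# Coordinate convention: pixel arrays are indexed [row, col, channel] with
# row 1 at the TOP of the image (larger row = closer to the tube bottom).
# HSV row profiles are reported bottom-to-top, matching how the fluid column
# is read; the conversion happens at this type boundary and nowhere else.

#' Construct a reservoir image
#'
#' Wraps an 8-bit RGB pixel array together with the rectangular region of
#' interest (ROI) bounding the tube interior and the narrower vertical patch
#' used for HSV row profiles.
#'
#' @param pixels H x W x 3 numeric array of 8-bit RGB values (0-255).
#' @param roi integer vector `c(top, bottom, left, right)` (1-based,
#'   inclusive) bounding the tube interior.
#' @param patch integer vector `c(top, bottom, left, right)`; must lie inside
#'   `roi` and be horizontally centred within it (within one pixel).
#' @param reservoir_id identifier of the imaged reservoir.
#' @param timestamp seconds since epoch.
#' @return an object of class `reservoir_image`.
#' @export
reservoir_image <- function(pixels, roi, patch, reservoir_id = "reservoir",
                            timestamp = 0) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_invalid("pixels must be an H x W x 3 array")
  if (any(pixels < 0) || any(pixels > 255))
    stop_invalid("pixels must be 8-bit values in [0, 255]")
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  check_rect <- function(r, name) {
    if (length(r) != 4L || r[1] > r[2] || r[3] > r[4] ||
        r[1] < 1 || r[2] > h || r[3] < 1 || r[4] > w)
      stop_invalid(name, " must be c(top, bottom, left, right) within image bounds")
  }
  check_rect(roi, "roi"); check_rect(patch, "patch")
  if (patch[1] < roi[1] || patch[2] > roi[2] ||
      patch[3] < roi[3] || patch[4] > roi[4])
    stop_invalid("patch must lie within roi")
  if (abs((patch[3] + patch[4]) - (roi[3] + roi[4])) > 2)
    stop_invalid("patch must be horizontally centred within roi")
  structure(list(pixels = pixels, roi = as.integer(roi),
                 patch = as.integer(patch),
                 reservoir_id = reservoir_id, timestamp = timestamp),
            class = "reservoir_image")
}

#' @export
print.reservoir_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<reservoir_image %s: %dx%d px, roi rows %d-%d cols %d-%d>\n",
              x$reservoir_id, d[1], d[2], x$roi[1], x$roi[2], x$roi[3], x$roi[4]))
  invisible(x)
}

roi_height <- function(rect) rect[2] - rect[1] + 1L
roi_width <- function(rect) rect[4] - rect[3] + 1L

#' Read a reservoir image from a PNG file
#'
#' @param path PNG file path.
#' @param roi,patch rectangles as in [reservoir_image()]; when `NULL` the ROI
#'   defaults to the full image and the patch to the central fifth of columns.
#' @inheritParams reservoir_image
#' @return a [reservoir_image()].
#' @export
read_reservoir_png <- function(path, roi = NULL, patch = NULL,
                               reservoir_id = basename(path), timestamp = 0) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  px <- round(img[, , 1:3, drop = FALSE] * 255)
  h <- dim(px)[1]; w <- dim(px)[2]
  if (is.null(roi)) roi <- c(1L, h, 1L, w)
  if (is.null(patch)) {
    cw <- max(3L, w %/% 5); c0 <- (roi[3] + roi[4]) %/% 2 - cw %/% 2
    patch <- c(roi[1], roi[2], c0, c0 + cw - 1L)
  }
  reservoir_image(px, roi, patch, reservoir_id, timestamp)
}

#' Write a reservoir image to a PNG file
#'
#' @param image a [reservoir_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reservoir_png <- function(image, path) {
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}
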