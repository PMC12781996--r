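# HD-MEA electrode-grid alignment: the 4-point projective (homography)
# mapping from distorted culture images to the electrode coordinate frame,
# organoid-boundary electrode contact mapping, and overlay export aligned to
# activity-map axes.

#' HD-MEA electrode grid geometry
#'
#' 220 x 120 = 26,400 electrodes at 17.5 um center-to-center pitch
#' (electrode pad diameter 7.5 um), a 3.85 mm x 2.1 mm sensing area.
#' Electrode centers sit at `(col * pitch, row * pitch)` with the corner
#' electrode at the origin. The activity-map axis extent defaults to the
#' grid-derived 3850 x 2100 um; `axis_extent_um` can be overridden to
#' reproduce plots using other axis conventions.
#'
#' @param n_cols,n_rows electrode counts per row/column.
#' @param pitch_um center-to-center pitch.
#' @param diameter_um electrode pad diameter.
#' @param axis_extent_um overlay axis extent `c(x, y)` in um.
#' @return object of class `electrode_grid`.
#' @export
electrode_grid <- function(n_cols = 220, n_rows = 120, pitch_um = 17.5,
                           diameter_um = 7.5,
                           axis_extent_um = c(n_cols, n_rows) * pitch_um) {
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 pitch_um = pitch_um, diameter_um = diameter_um,
                 n_electrodes = as.integer(n_cols * n_rows),
                 sensing_area_um = c(n_cols, n_rows) * pitch_um,
                 axis_extent_um = axis_extent_um),
            class = "electrode_grid")
}

#' Electrode index to (x, y) position and back
#'
#' Indices are 1-based and row-major (index 1 is the corner electrode at
#' (0, 0) um).
#'
#' @param index electrode index (vectorised).
#' @param grid an [electrode_grid()].
#' @return `electrode_xy`: data.frame of `index`, `col`, `row`, `x_um`,
#'   `y_um`; `electrode_index`: integer indices.
#' @export
electrode_xy <- function(index, grid = electrode_grid()) {
  if (any(index < 1 | index > grid$n_electrodes))
    stop_invalid("electrode index out of range")
  col <- (index - 1L) %% grid$n_cols
  row <- (index - 1L) %/% grid$n_cols
  data.frame(index = index, col = col, row = row,
             x_um = col * grid$pitch_um, y_um = row * grid$pitch_um)
}

#' @rdname electrode_xy
#' @param col,row 0-based electrode column and row.
#' @export
electrode_index <- function(col, row, grid = electrode_grid()) {
  if (any(col < 0 | col >= grid$n_cols | row < 0 | row >= grid$n_rows))
    stop_invalid("electrode (col, row) out of range")
  as.integer(row * grid$n_cols + col + 1L)
}

solve_homography <- function(src, dst) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b), error = function(e)
    stop_invalid("degenerate correspondences (collinear points?): ",
                 conditionMessage(e)))
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Build the projective mapping from image pixels to the electrode frame
#'
#' Solves the 3 x 3 projective transform exactly from 4 point
#' correspondences. Destination points default to the four corners of the
#' sensing area in mm, computed from the grid's corner anchor and electrode
#' geometry; custom destinations may be supplied instead.
#'
#' @param source_px 4 x 2 matrix of source pixel points (non-collinear).
#' @param grid an [electrode_grid()] anchoring the destination corners.
#' @param dest_mm optional 4 x 2 matrix of destination points in mm.
#' @return object of class `plane_mapping` with the `transform` matrix and
#'   its `inverse`.
#' @export
build_mapping <- function(source_px, grid = electrode_grid(), dest_mm = NULL) {
  source_px <- as.matrix(source_px)
  stopifnot(all(dim(source_px) == c(4, 2)))
  if (is.null(dest_mm)) {
    ext <- grid$sensing_area_um / 1000
    dest_mm <- rbind(c(0, 0), c(ext[1], 0), c(ext[1], ext[2]), c(0, ext[2]))
  }
  dest_mm <- as.matrix(dest_mm)
  H <- solve_homography(source_px, dest_mm)
  structure(list(source_px = source_px, dest_mm = dest_mm,
                 transform = H, inverse = solve(H)),
            class = "plane_mapping")
}

#' Apply a plane mapping to points
#'
#' @param mapping a [build_mapping()] result (or a 3 x 3 matrix).
#' @param pts n x 2 matrix of points.
#' @param inverse map from the destination frame back to pixels.
#' @return n x 2 matrix of mapped points.
#' @export
apply_mapping <- function(mapping, pts, inverse = FALSE) {
  H <- if (is.matrix(mapping)) mapping
       else if (inverse) mapping$inverse else mapping$transform
  pts <- rbind(t(as.matrix(pts)), 1)
  out <- H %*% pts
  t(out[1:2, , drop = FALSE] / rep(out[3, ], each = 2))
}

mask_boundary_pixels <- function(mask) {
  # foreground pixels 4-adjacent to background, or on the frame edge
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mask
  interior <- pad[1:n, 2:(m + 1)] & pad[3:(n + 2), 2:(m + 1)] &
              pad[2:(n + 1), 1:m] & pad[2:(n + 1), 3:(m + 2)]
  which(mask & !interior, arr.ind = TRUE)
}

#' Map an organoid boundary onto contacted electrodes
#'
#' The mask's contour (foreground pixels with a 4-adjacent background
#' neighbour, frame edges included) is traced, and an electrode is marked
#' when the contour enters its pitch-sized cell (the 17.5 um square around
#' the electrode center): the cell, rather than the 7.5 um pad, guarantees
#' the contour marks a connected path of electrodes.
#'
#' @param mask logical (or 0/1) matrix, organoid = TRUE, already rectified
#'   to the electrode frame with pixel (1, 1) at the grid origin.
#' @param grid an [electrode_grid()].
#' @param um_per_px mask resolution.
#' @return sorted integer vector of contacted electrode indices (possibly
#'   empty).
#' @export
contact_map <- function(mask, grid = electrode_grid(), um_per_px = 10) {
  mask <- mask > 0
  if (!any(mask)) return(integer(0))
  b <- mask_boundary_pixels(mask)
  # pixel centers: x along columns, y along rows
  x_um <- (b[, 2] - 0.5) * um_per_px
  y_um <- (b[, 1] - 0.5) * um_per_px
  ext <- grid$sensing_area_um
  keep <- x_um >= 0 & x_um <= ext[1] & y_um >= 0 & y_um <= ext[2]
  # Voronoi partition of the sensing area: edge cells absorb the border strip
  col <- clamp(round(x_um[keep] / grid$pitch_um), 0, grid$n_cols - 1L)
  row <- clamp(round(y_um[keep] / grid$pitch_um), 0, grid$n_rows - 1L)
  sort(unique(electrode_index(col, row, grid)))
}

#' Export marked electrodes as an overlay aligned to activity-map axes
#'
#' Positions are emitted on the electrode coordinate axes so the overlay
#' aligns with activity heatmaps sharing those axis dimensions. Optionally
#' writes an SVG of circles at the electrode positions.
#'
#' @param marked integer vector of electrode indices.
#' @param grid an [electrode_grid()].
#' @param path optional SVG output file.
#' @return data.frame of `index`, `x_um`, `y_um` (invisibly when `path` is
#'   given).
#' @export
export_overlay <- function(marked, grid = electrode_grid(), path = NULL) {
  xy <- if (length(marked)) electrode_xy(marked, grid)[, c("index", "x_um", "y_um")]
        else data.frame(index = integer(), x_um = numeric(), y_um = numeric())
  if (is.null(path)) return(xy)
  ext <- grid$axis_extent_um
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 %g %g">',
            ext[1], ext[2]),
    sprintf('  <circle data-index="%d" cx="%.10g" cy="%.10g" r="%.4g"/>',
            xy$index, xy$x_um, xy$y_um, grid$diameter_um / 2),
    "</svg>")
  writeLines(lines, path)
  invisible(xy)
}

#' @rdname export_overlay
#' @export
read_overlay <- function(path) {
  lines <- readLines(path)
  hits <- regmatches(lines, regexec(
    'data-index="([0-9]+)" cx="([0-9.eE+-]+)" cy="([0-9.eE+-]+)"', lines))
  hits <- hits[vapply(hits, length, 0L) == 4L]
  data.frame(index = vapply(hits, function(h) as.integer(h[2]), 0L),
             x_um = vapply(hits, function(h) as.numeric(h[3]), 0),
             y_um = vapply(hits, function(h) as.numeric(h[4]), 0))
}

#' Read a binary organoid mask from PNG
#'
#' @param path PNG file; any channel value above `threshold` (0-1 scale) is
#'   foreground. Serves as the simple threshold fallback when an externally
#'   produced segmentation mask is not available.
#' @param threshold foreground threshold.
#' @return logical matrix.
#' @export
read_mask_png <- function(path, threshold = 0.5) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > threshold
}
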