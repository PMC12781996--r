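# Geometry of a nominal 15 mL conical collection tube: a cone (apex down)
# holding the first `cone_volume_ul` microlitres, then a cylinder of the same
# radius. Heights are measured in mm above the apex.

#' Tube geometry for a 15 mL conical collection reservoir
#'
#' Describes the conical-to-cylindrical geometry used both by the reservoir
#' image renderer and by volume/height conversions. The cone apex sits at
#' height 0; the cone holds `cone_volume_ul` microlitres and transitions into
#' a cylinder of radius `radius_mm`.
#'
#' @param radius_mm inner radius of the cylindrical section (mm).
#' @param cone_volume_ul volume held by the conical section (microlitres).
#' @param capacity_ul usable capacity considered by the renderer (microlitres).
#' @return an object of class `tube_geometry`.
#' @examples
#' g <- tube_geometry()
#' fluid_height_mm(1500, g)   # top of the cone
#' @export
tube_geometry <- function(radius_mm = 7.45, cone_volume_ul = 1500,
                          capacity_ul = 12000) {
  stopifnot(radius_mm > 0, cone_volume_ul > 0, capacity_ul > cone_volume_ul)
  area_mm2 <- pi * radius_mm^2  # 1 mm^3 == 1 microlitre
  cone_height_mm <- 3 * cone_volume_ul / area_mm2
  structure(list(radius_mm = radius_mm, cone_volume_ul = cone_volume_ul,
                 capacity_ul = capacity_ul, area_mm2 = area_mm2,
                 cone_height_mm = cone_height_mm),
            class = "tube_geometry")
}

#' Fluid column height above the cone apex for a given volume
#'
#' @param volume_ul volume in microlitres (vectorised).
#' @param geom a [tube_geometry()].
#' @return height in mm above the apex.
#' @export
fluid_height_mm <- function(volume_ul, geom = tube_geometry()) {
  if (any(volume_ul < 0)) stop_invalid("volume_ul must be nonnegative")
  h_cone <- geom$cone_height_mm
  ifelse(volume_ul <= geom$cone_volume_ul,
         h_cone * (volume_ul / geom$cone_volume_ul)^(1 / 3),
         h_cone + (volume_ul - geom$cone_volume_ul) / geom$area_mm2)
}

#' Tube half-width at a given height above the apex
#'
#' @inheritParams fluid_height_mm
#' @param height_mm height above the apex (mm).
#' @return half-width (radius of the tube cross-section) in mm.
#' @export
tube_halfwidth_mm <- function(height_mm, geom = tube_geometry()) {
  pmin(height_mm / geom$cone_height_mm, 1) * geom$radius_mm
}
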