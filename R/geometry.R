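#' Cylindrical microcavity geometry
#'
#' Describes one collagen microcavity of the stamp array. All morphometric
#' analysis works on the 2D projection, so the height is carried as metadata
#' only. Defaults match the standard array: 100 um diameter, 200 um height,
#' 600 um center-to-center pitch.
#'
#' @param diameter_um Cavity diameter in micrometres (> 0).
#' @param height_um Cavity height in micrometres (metadata only).
#' @param pitch_um Center-to-center spacing in micrometres (>= diameter).
#' @return An object of class `cavity_geometry` with fields `diameter_um`,
#'   `height_um`, `pitch_um` and the derived `projected_area_um2`.
#' @examples
#' geom <- cavity_geometry()
#' round(geom$projected_area_um2) # 7854
#' @export
cavity_geometry <- function(diameter_um = 100, height_um = 200,
                            pitch_um = 600) {
  if (!is.numeric(diameter_um) || diameter_um <= 0)
    stop("invalid geometry: `diameter_um` must be > 0", call. = FALSE)
  if (pitch_um < diameter_um)
    stop("invalid geometry: `pitch_um` must be >= `diameter_um`",
         call. = FALSE)
  structure(
    list(diameter_um = diameter_um, height_um = height_um,
         pitch_um = pitch_um,
         projected_area_um2 = pi * (diameter_um / 2)^2),
    class = "cavity_geometry")
}

#' Projected area of a circular microcavity
#'
#' The normalization constant for the non-invasive area: pi * (d/2)^2,
#' 7854 um^2 for the default 100 um cavity (to the nearest integer).
#'
#' @param geometry A [cavity_geometry()].
#' @return Area in um^2 (unrounded; round only for display).
#' @export
projected_cavity_area <- function(geometry = cavity_geometry()) {
  if (!inherits(geometry, "cavity_geometry"))
    stop("`geometry` must be a cavity_geometry object", call. = FALSE)
  pi * (geometry$diameter_um / 2)^2
}

#' Stamp-array layout
#'
#' The regular grid of microcavities molded by the PDMS stamp
#' (25 x 26 = 650 cavities by default).
#'
#' @param rows,cols Grid dimensions (>= 1).
#' @param origin_um Length-2 offset (x, y) of the first cavity center, um.
#' @param cavity A [cavity_geometry()].
#' @return An object of class `array_layout`.
#' @export
array_layout <- function(rows = 25, cols = 26, origin_um = c(0, 0),
                         cavity = cavity_geometry()) {
  if (!is.numeric(rows) || !is.numeric(cols) || rows < 1 || cols < 1)
    stop("invalid layout: `rows` and `cols` must be >= 1", call. = FALSE)
  if (length(origin_um) != 2L)
    stop("invalid layout: `origin_um` must have length 2", call. = FALSE)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         origin_um = as.numeric(origin_um), cavity = cavity),
    class = "array_layout")
}

#' Cavity center coordinates of an array layout
#'
#' @param layout An [array_layout()].
#' @return A data.frame with columns `row`, `col`, `x_um`, `y_um` in
#'   row-major order (`rows * cols` centers on a regular grid with pitch
#'   spacing).
#' @export
array_centers <- function(layout) {
  if (!inherits(layout, "array_layout"))
    stop("`layout` must be an array_layout object", call. = FALSE)
  pitch <- layout$cavity$pitch_um
  grid <- expand.grid(col = seq_len(layout$cols), row = seq_len(layout$rows))
  data.frame(
    row = grid$row, col = grid$col,
    x_um = layout$origin_um[1] + (grid$col - 1) * pitch,
    y_um = layout$origin_um[2] + (grid$row - 1) * pitch)
}

#' Pixel calibration
#'
#' Length-per-pixel calibration with the raster convention used throughout:
#' pixel centers at integer coordinates, origin at the top-left pixel,
#' x rightward (columns), y downward (rows).
#'
#' @param pixel_size_um Micrometres per pixel (> 0). Typical objective
#'   calibrations are 0.569 and 2.27 um/px.
#' @return An object of class `pixel_calibration`.
#' @export
pixel_calibration <- function(pixel_size_um = 2.27) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("invalid calibration: `pixel_size_um` must be > 0", call. = FALSE)
  structure(list(pixel_size_um = pixel_size_um), class = "pixel_calibration")
}

#' Convert between micrometres and pixels
#'
#' @param value_um,value_px Lengths to convert.
#' @param cal A [pixel_calibration()].
#' @return Converted lengths; `um_to_px` and `px_to_um` are exact inverses.
#' @export
um_to_px <- function(value_um, cal) {
  stopifnot(inherits(cal, "pixel_calibration"))
  value_um / cal$pixel_size_um
}

#' @rdname um_to_px
#' @export
px_to_um <- function(value_px, cal) {
  stopifnot(inherits(cal, "pixel_calibration"))
  value_px * cal$pixel_size_um
}

#' @export
print.cavity_geometry <- function(x, ...) {
  cat(sprintf(
    "Microcavity: d = %g um, h = %g um, pitch = %g um, A = %.0f um^2\n",
    x$diameter_um, x$height_um, x$pitch_um, x$projected_area_um2))
  invisible(x)
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf("Stamp array: %d x %d = %d cavities\n",
              x$rows, x$cols, x$rows * x$cols))
  print(x$cavity)
  invisible(x)
}
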