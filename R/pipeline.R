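as_stack_array <- function(stack) {
  if (inherits(stack, "image_stack")) return(stack$voxels)
  if (is.array(stack) && length(dim(stack)) == 3L) return(stack)
  stop("`stack` must be an image_stack or a 3D array (y, x, z)",
       call. = FALSE)
}

#' z-projections of an image stack
#'
#' `max_projection` takes the per-pixel maximum across z (the first pipeline
#' step consolidating 3D data into 2D); `sum_projection` the per-pixel sum
#' (used for replicate heatmaps); `std_projection` the per-pixel population
#' standard deviation (a single slice projects to zero).
#'
#' @param stack An `image_stack` or 3D array (y, x, z) with >= 1 slice.
#' @return A 2D numeric matrix.
#' @export
max_projection <- function(stack) {
  v <- as_stack_array(stack)
  if (dim(v)[3] == 0) stop("empty stack", call. = FALSE)
  out <- v[, , 1]
  for (k in seq_len(dim(v)[3])[-1]) out <- pmax(out, v[, , k])
  out
}

#' @rdname max_projection
#' @export
sum_projection <- function(stack) {
  v <- as_stack_array(stack)
  if (dim(v)[3] == 0) stop("empty stack", call. = FALSE)
  out <- v[, , 1]
  for (k in seq_len(dim(v)[3])[-1]) out <- out + v[, , k]
  out
}

#' @rdname max_projection
#' @export
std_projection <- function(stack) {
  v <- as_stack_array(stack)
  nz <- dim(v)[3]
  if (nz == 0) stop("empty stack", call. = FALSE)
  m <- sum_projection(v) / nz
  s2 <- v[, , 1]^2
  for (k in seq_len(nz)[-1]) s2 <- s2 + v[, , k]^2
  out <- s2 / nz - m^2
  out[out < 0] <- 0   # numerical guard
  sqrt(out)
}

#' Median-filter denoising
#'
#' Reduces background speckle while preserving edges; radius 0 is the
#' identity. Wraps the EBImage median filter on a rescaled copy so inputs
#' may have any intensity range.
#'
#' @param image 2D numeric matrix.
#' @param radius_px Filter radius in pixels (>= 0).
#' @return Filtered matrix of the same dimensions and intensity scale.
#' @export
denoise <- function(image, radius_px = 1) {
  stopifnot(is.matrix(image))
  if (radius_px < 0) stop("`radius_px` must be >= 0", call. = FALSE)
  if (radius_px == 0) return(image)
  rng <- range(image)
  if (rng[2] == rng[1]) return(image)
  scaled <- (image - rng[1]) / (rng[2] - rng[1])
  out <- EBImage::medianFilter(scaled, size = as.integer(radius_px))
  matrix(as.numeric(out), nrow(image), ncol(image)) *
    (rng[2] - rng[1]) + rng[1]
}

#' Otsu threshold of an intensity image
#'
#' Maximizes the between-class variance on a 256-bin histogram (computed by
#' EBImage on the image rescaled to \[0, 1\], then mapped back to the input
#' intensity scale). A constant image has a degenerate histogram and raises
#' an error.
#'
#' @param image 2D numeric matrix.
#' @return Threshold on the input intensity scale.
#' @export
otsu_threshold <- function(image) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (rng[2] == rng[1])
    stop("degenerate histogram: constant image has no Otsu threshold",
         call. = FALSE)
  scaled <- (image - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256)
  th * (rng[2] - rng[1]) + rng[1]
}

#' Binarize an intensity image
#'
#' A pixel is foreground iff its intensity exceeds the threshold, computed
#' by Otsu's method by default or supplied as a fixed per-image override
#' (mirroring manual threshold adjustments in interactive analysis).
#'
#' @param image 2D numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Required intensity threshold when `method = "fixed"`.
#' @return Logical matrix (`TRUE` = foreground).
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  th <- if (method == "fixed") {
    if (is.null(threshold))
      stop("fixed binarization requires `threshold`", call. = FALSE)
    threshold
  } else otsu_threshold(image)
  image > th
}

#' Crop a mask or image to a square window
#'
#' Extracts the window of the given half-width centred on `center` (pixel
#' coordinates `(x, y)`); for a [patternoid_mask()] the cavity center is
#' re-expressed in the cropped frame. The window is clipped to the grid; a
#' window fully outside raises an error.
#'
#' @param x A matrix or [patternoid_mask()].
#' @param center Length-2 `(x, y)` window center in pixel coordinates;
#'   defaults to the mask's cavity center.
#' @param half_width_um Window half-width in um.
#' @param cal A [pixel_calibration()] (taken from the mask when cropping a
#'   mask).
#' @return Cropped object of the same kind; the crop offset is attached as
#'   attribute `"offset_px"` (`c(x, y)`, 0-based).
#' @export
crop_to_window <- function(x, center = NULL, half_width_um, cal = NULL) {
  if (inherits(x, "patternoid_mask")) {
    cal <- x$cal
    if (is.null(center)) center <- x$center_px
    grid <- x$pixels
  } else {
    grid <- x
    if (is.null(center) || is.null(cal))
      stop("`center` and `cal` are required for plain matrices",
           call. = FALSE)
  }
  hw <- round(half_width_um / cal$pixel_size_um)
  jlo <- round(center[1]) - hw; jhi <- round(center[1]) + hw
  ilo <- round(center[2]) - hw; ihi <- round(center[2]) + hw
  if (jhi < 1 || ihi < 1 || jlo > ncol(grid) || ilo > nrow(grid))
    stop("crop window lies fully outside the grid", call. = FALSE)
  jlo <- max(1L, jlo); jhi <- min(ncol(grid), jhi)
  ilo <- max(1L, ilo); ihi <- min(nrow(grid), ihi)
  sub <- grid[ilo:ihi, jlo:jhi, drop = FALSE]
  if (inherits(x, "patternoid_mask")) {
    out <- list(pixels = sub, cal = cal,
                center_px = c(x$center_px[1] - (jlo - 1),
                              x$center_px[2] - (ilo - 1)),
                cavity_radius_um = x$cavity_radius_um)
    class(out) <- "patternoid_mask"
  } else out <- sub
  attr(out, "offset_px") <- c(jlo - 1, ilo - 1)
  out
}
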