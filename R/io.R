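#' Read and write patternoid masks as TIFF
#'
#' Masks are stored as 8-bit single-page TIFF (0/255); the calibration and
#' cavity metadata travel in the accompanying records/config files, so they
#' must be supplied when reading.
#'
#' @param mask A [patternoid_mask()].
#' @param path Output/input file path.
#' @return `write_mask_tiff` returns `path` invisibly; `read_mask_tiff`
#'   returns a [patternoid_mask()].
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "patternoid_mask"))
  tiff::writeTIFF(ifelse(mask$pixels, 1, 0), path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @param cal A [pixel_calibration()].
#' @param center_px,cavity_radius_um Cavity metadata for the mask read back.
#' @export
read_mask_tiff <- function(path, cal, center_px, cavity_radius_um) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  patternoid_mask(img > 0.5, cal, center_px, cavity_radius_um)
}

#' Write and read grayscale image stacks as multi-page TIFF
#'
#' Intensities are rescaled to \[0, 1\] for storage; the scale factor is
#' not preserved (downstream thresholding is scale-invariant after
#' background normalization).
#'
#' @param stack An `image_stack`.
#' @param path File path.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   an `image_stack`.
#' @export
write_stack_tiff <- function(stack, path) {
  v <- as_stack_array(stack)
  top <- max(v, 1e-12)
  pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param cal A [pixel_calibration()].
#' @param z_step_um z-spacing metadata.
#' @export
read_stack_tiff <- function(path, cal, z_step_um = 5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  v <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    v[, , k] <- p
  }
  image_stack(v, cal, z_step_um)
}

#' Load and validate an experiment configuration
#'
#' JSON or YAML (by extension) with the keys `diameter_um`, `height_um`,
#' `pitch_um`, `rows`, `cols`, `pixel_size_um`, and optionally `c0_targets`,
#' `c0_tol`, `seed`. Unknown keys are rejected so typos fail loudly.
#'
#' @param path Config file path.
#' @return List with `geometry` ([cavity_geometry()]), `layout`
#'   ([array_layout()]), `cal` ([pixel_calibration()]), `c0_targets`,
#'   `c0_tol`, `seed`, and the raw key-value list as `raw`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("diameter_um", "height_um", "pitch_um", "rows", "cols",
             "pixel_size_um", "c0_targets", "c0_tol", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  geom <- cavity_geometry(raw$diameter_um %||% 100, raw$height_um %||% 200,
                          raw$pitch_um %||% 600)
  list(geometry = geom,
       layout = array_layout(raw$rows %||% 25, raw$cols %||% 26,
                             cavity = geom),
       cal = pixel_calibration(raw$pixel_size_um %||% 2.27),
       c0_targets = raw$c0_targets %||% c(10, 20, 30),
       c0_tol = raw$c0_tol %||% 0.10,
       seed = raw$seed %||% 1L,
       raw = raw)
}

#' Echo an effective configuration to JSON
#'
#' @param config List as returned by [read_experiment_config()] (its `raw`
#'   element is written) or any serializable list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config_json <- function(config, path) {
  x <- config$raw %||% config
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write and read patternoid record tables
#'
#' CSV round-trip for record tables (`id`, `row`, `col`, `c0`, `c0_class`,
#' `qc_flags`, `included`, plus any metric columns).
#'
#' @param records data.frame.
#' @param path CSV path.
#' @return `write_records_csv` returns `path` invisibly;
#'   `read_records_csv` the data.frame.
#' @export
write_records_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("qc_flags" %in% names(df)) {
    df$qc_flags <- as.character(df$qc_flags)
    df$qc_flags[is.na(df$qc_flags)] <- ""
  }
  df
}
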