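#' Concentric ROI specification for time-lapse quantification
#'
#' The non-invasive signal is read inside a circle of `inner_diameter_um`
#' (default 100 um, the cavity diameter) centred on the patternoid; the
#' invasive signal over the XOR of that circle with a larger concentric
#' circle (`outer_factor` times the inner radius) encompassing the whole
#' structure; acquisition drift is corrected against a collagen-only
#' background disk that must not overlap the outer ROI.
#'
#' @param center_px `(x, y)` patternoid center in pixel coordinates.
#' @param cal A [pixel_calibration()].
#' @param inner_diameter_um Inner circle diameter, um.
#' @param outer_factor Outer radius as a multiple of the inner radius.
#' @param background_center_px `(x, y)` center of the background disk.
#' @param background_radius_um Background disk radius, um.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center_px, cal, inner_diameter_um = 100,
                     outer_factor = 3, background_center_px,
                     background_radius_um = 30) {
  stopifnot(inherits(cal, "pixel_calibration"), length(center_px) == 2L,
            length(background_center_px) == 2L)
  if (outer_factor <= 1)
    stop("outer ROI must strictly contain the inner ROI", call. = FALSE)
  r_in <- inner_diameter_um / 2
  r_out <- r_in * outer_factor
  gap_um <- sqrt(sum((background_center_px - center_px)^2)) *
    cal$pixel_size_um
  if (gap_um < r_out + background_radius_um)
    stop("background ROI overlaps the structure ROI", call. = FALSE)
  structure(list(center_px = as.numeric(center_px), cal = cal,
                 inner_radius_um = r_in, outer_radius_um = r_out,
                 background_center_px = as.numeric(background_center_px),
                 background_radius_um = background_radius_um),
            class = "roi_spec")
}

disk_mean <- function(frame, center_px, r_um, cal, exclude = NULL) {
  px <- cal$pixel_size_um
  dx <- (seq_len(ncol(frame)) - center_px[1])
  dy <- (seq_len(nrow(frame)) - center_px[2])
  d <- px * sqrt(outer(dy^2, dx^2, `+`))
  sel <- d <= r_um
  if (!is.null(exclude)) sel <- sel & !exclude
  if (!any(sel)) stop("ROI lies outside the frame", call. = FALSE)
  list(mean = mean(frame[sel]), sel = sel)
}

#' Estimate a rigid translation between two frames
#'
#' Integer-pixel shift maximizing the FFT cross-correlation of the two
#' (mean-subtracted) frames; used to keep ROIs on the structure when the
#' stage drifts between timepoints.
#'
#' @param ref,img Numeric matrices of identical dimensions.
#' @return `c(dx, dy)`: shift to apply to ROI centers for `img`.
#' @export
estimate_translation <- function(ref, img) {
  stopifnot(all(dim(ref) == dim(img)))
  a <- ref - mean(ref); b <- img - mean(img)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  nr <- nrow(ref); nc <- ncol(ref)
  dy <- peak[1] - 1; dx <- peak[2] - 1
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  c(dx = -unname(dx), dy = -unname(dy))
}

#' Extract raw ROI mean intensities over a time series
#'
#' Per timepoint: the mean intensity over the inner disk, over the
#' outer-minus-inner annulus (the XOR of the nested ROIs), and over the
#' background disk. With `align = "translate"` each frame's ROI centers are
#' shifted by the cross-correlation drift estimate against the first frame;
#' `align = "fixed"` keeps ROIs static.
#'
#' @param frames List of 2D numeric matrices, one per timepoint.
#' @param spec An [roi_spec()].
#' @param times_h Ascending acquisition times, hours.
#' @param align `"fixed"` or `"translate"`.
#' @return data.frame: `time_h`, `inner_mean`, `invasive_mean`,
#'   `background_mean`.
#' @export
roi_timeseries <- function(frames, spec, times_h,
                           align = c("fixed", "translate")) {
  align <- match.arg(align)
  stopifnot(inherits(spec, "roi_spec"),
            length(frames) == length(times_h))
  if (is.unsorted(times_h, strictly = TRUE))
    stop("`times_h` must be strictly ascending", call. = FALSE)
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    shift <- c(0, 0)
    if (align == "translate" && i > 1)
      shift <- estimate_translation(frames[[1]], fr)
    ctr <- spec$center_px + shift
    inner <- disk_mean(fr, ctr, spec$inner_radius_um, spec$cal)
    outer <- disk_mean(fr, ctr, spec$outer_radius_um, spec$cal,
                       exclude = inner$sel)
    bg <- disk_mean(fr, spec$background_center_px + shift,
                    spec$background_radius_um, spec$cal)
    data.frame(time_h = times_h[i], inner_mean = inner$mean,
               invasive_mean = outer$mean, background_mean = bg$mean)
  })
  do.call(rbind, rows)
}

#' Normalize ROI signals to the background
#'
#' Divides each timepoint's ROI means by that timepoint's collagen-only
#' background mean, removing global acquisition/illumination variability
#' (the pipeline is exactly invariant to per-frame intensity scaling).
#'
#' @param raw data.frame from [roi_timeseries()].
#' @return data.frame with `time_h`, `noninv_rel`, `inv_rel`.
#' @export
background_normalize <- function(raw) {
  if (any(raw$background_mean <= 0))
    stop("background mean must be > 0 at every timepoint", call. = FALSE)
  data.frame(time_h = raw$time_h,
             noninv_rel = raw$inner_mean / raw$background_mean,
             inv_rel = raw$invasive_mean / raw$background_mean)
}

#' Baseline-correct a relative invasive series
#'
#' Subtracts the value at the baseline timepoint (nearest timepoint to
#' `baseline_time_h` within `tol_h`) so all replicates start from a common
#' zero; the correction is idempotent.
#'
#' @param values Numeric series.
#' @param times_h Matching times, hours.
#' @param baseline_time_h Baseline time (default 3 h).
#' @param tol_h Nearest-timepoint matching tolerance, hours.
#' @return Corrected series (zero at the baseline timepoint).
#' @export
baseline_correct <- function(values, times_h, baseline_time_h = 3,
                             tol_h = 1) {
  stopifnot(length(values) == length(times_h))
  i <- which.min(abs(times_h - baseline_time_h))
  if (abs(times_h[i] - baseline_time_h) > tol_h)
    stop("series does not cover the baseline time within ", tol_h, " h",
         call. = FALSE)
  values - values[i]
}

#' Fit the longitudinal subtype-trend model
#'
#' Linear mixed-effects model of a relative-area signal with Time, Subtype
#' and their interaction as fixed effects and a per-replicate random
#' intercept for the repeated measurements; interaction contrasts test
#' whether subtypes differ in their temporal trend, intercept contrasts
#' whether baselines differ.
#'
#' @param records Long data.frame with columns `replicate_id`, `subtype`,
#'   `time_h`, `value`.
#' @param reml Fit by REML (default) or ML.
#' @return List: `model` (the `lmerMod` fit), `fixed` (coefficient table
#'   with Satterthwaite p-values), `slopes` (per-subtype time slope),
#'   `interaction_p` (named p-values of the subtype x time contrasts).
#' @export
fit_longitudinal_trend <- function(records, reml = TRUE) {
  need <- c("replicate_id", "subtype", "time_h", "value")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  records$subtype <- factor(records$subtype)
  if (nlevels(records$subtype) < 2)
    stop("singular design: need >= 2 subtypes", call. = FALSE)
  reps <- tapply(records$replicate_id, records$subtype,
                 function(x) length(unique(x)))
  if (any(reps < 2))
    stop("singular design: subtype ",
         paste(names(reps)[reps < 2], collapse = ", "),
         " has < 2 replicates", call. = FALSE)
  if (length(unique(records$time_h)) < 3)
    stop("singular design: need >= 3 timepoints", call. = FALSE)
  fit <- lmerTest::lmer(value ~ time_h * subtype + (1 | replicate_id),
                        data = records, REML = reml)
  coefs <- summary(fit)$coefficients
  base_slope <- coefs["time_h", "Estimate"]
  lev <- levels(records$subtype)
  slopes <- setNames(rep(base_slope, length(lev)), lev)
  ip <- c()
  for (l in lev[-1]) {
    nm <- paste0("time_h:subtype", l)
    if (nm %in% rownames(coefs)) {
      slopes[l] <- base_slope + coefs[nm, "Estimate"]
      ip[l] <- coefs[nm, "Pr(>|t|)"]
    }
  }
  list(model = fit, fixed = coefs, slopes = slopes, interaction_p = ip)
}
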