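#' Simulate cavity seeding counts
#'
#' Cell deposition into microcavities is subject to Poisson counting
#' statistics: each cavity receives an i.i.d. Poisson(`mean_cells`) count.
#'
#' @param layout An [array_layout()].
#' @param mean_cells Expected number of cells per cavity (>= 0).
#' @param seed Optional integer for reproducible draws.
#' @return Integer vector of length `rows * cols`, row-major cavity order.
#' @export
simulate_seeding <- function(layout, mean_cells, seed = NULL) {
  stopifnot(inherits(layout, "array_layout"))
  if (!is.numeric(mean_cells) || mean_cells < 0)
    stop("invalid parameter: `mean_cells` must be >= 0", call. = FALSE)
  with_seed(seed, rpois(layout$rows * layout$cols, mean_cells))
}

#' Render a grayscale image stack from a binary mask
#'
#' Distributes the mask's foreground over `n_slices` z-slices (each
#' foreground pixel lit in one randomly assigned slice) and adds Gaussian
#' background noise so that the foreground mean intensity over the
#' background noise SD equals `snr`. Maximum projection of the result
#' recovers the mask support.
#'
#' @param mask A [patternoid_mask()].
#' @param snr Signal-to-noise ratio (> 0); `Inf` renders noiselessly.
#' @param n_slices Number of z-slices.
#' @param seed Optional integer.
#' @param z_step_um z-spacing metadata, um.
#' @return An `image_stack`: list with `voxels` (array y, x, z), `cal`,
#'   `z_step_um`.
#' @export
render_intensity <- function(mask, snr = 10, n_slices = 5, seed = NULL,
                             z_step_um = 5) {
  stopifnot(inherits(mask, "patternoid_mask"))
  if (!is.numeric(snr) || snr <= 0)
    stop("`snr` must be > 0", call. = FALSE)
  with_seed(seed, {
    nr <- nrow(mask$pixels); nc <- ncol(mask$pixels)
    fg_level <- 200
    baseline <- 20
    noise_sd <- if (is.finite(snr)) fg_level / snr else 0
    vox <- array(baseline, dim = c(nr, nc, n_slices))
    idx <- which(mask$pixels)
    if (length(idx)) {
      slice <- if (n_slices > 1)
        sample.int(n_slices, length(idx), replace = TRUE) else
          rep(1L, length(idx))
      vox[idx + (slice - 1L) * nr * nc] <- baseline + fg_level
    }
    if (noise_sd > 0)
      vox <- vox + array(rnorm(length(vox), 0, noise_sd), dim = dim(vox))
    vox[vox < 0] <- 0
    image_stack(vox, mask$cal, z_step_um)
  })
}

#' Image stack container
#'
#' @param voxels Numeric 3D array (y, x, z) of non-negative intensities.
#' @param cal A [pixel_calibration()].
#' @param z_step_um z-spacing, um.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, cal, z_step_um = 5) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || any(dim(voxels) == 0))
    stop("`voxels` must be a non-empty 3D array (y, x, z)", call. = FALSE)
  if (any(!is.finite(voxels)) || any(voxels < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  stopifnot(inherits(cal, "pixel_calibration"))
  structure(list(voxels = voxels, cal = cal, z_step_um = z_step_um),
            class = "image_stack")
}

#' Simulate the time course of non-invasive and invasive signal
#'
#' The non-invasive (in-cavity) area fraction follows a saturating-growth
#' curve from the seeded baseline toward the profile's plateau,
#' `f(t) = plateau - (plateau - baseline) * exp(-r t)`; the invasive signal
#' is zero before the profile's invasion onset and then rises monotonically.
#' Additive Gaussian observation noise emulates brightfield proxy
#' measurement error; `noise_sd = 0` returns the noiseless curves.
#'
#' @param profile A [subtype_profile()].
#' @param t_grid Ascending times in hours within \[0, 72\].
#' @param seed Optional integer.
#' @param baseline_frac Non-invasive fraction at t = 0 (seeded cells).
#' @param noise_sd Additive observation noise SD.
#' @return data.frame with columns `time_h`, `noninv_frac`, `inv_rel`.
#' @export
generate_timeseries <- function(profile, t_grid = 0:72, seed = NULL,
                                baseline_frac = 0.2, noise_sd = 0.02) {
  stopifnot(inherits(profile, "subtype_profile"))
  if (is.unsorted(t_grid, strictly = TRUE) ||
      any(t_grid < 0) || any(t_grid > 72))
    stop("`t_grid` must be strictly ascending within [0, 72]", call. = FALSE)
  with_seed(seed, {
    plateau <- profile$noninv_plateau_frac
    r <- profile$growth_rate_r
    noninv <- plateau - (plateau - baseline_frac) * exp(-r * t_grid)
    onset <- profile$invasion_onset_h
    slope <- 0.35 / (72 - onset + 10)
    inv <- ifelse(t_grid <= onset, 0, slope * (t_grid - onset))
    if (noise_sd > 0) {
      noninv <- noninv + rnorm(length(t_grid), 0, noise_sd)
      inv <- pmax(0, inv + rnorm(length(t_grid), 0, noise_sd))
    }
    data.frame(time_h = t_grid, noninv_frac = noninv, inv_rel = inv)
  })
}

#' Expected response of a Hill dose-response curve
#'
#' Decreasing form: `bottom + (top - bottom) * ec50^h / (ec50^h + c^h)`;
#' increasing form swaps the roles of `c` and `ec50`.
#'
#' @param conc_nM Concentrations (>= 0).
#' @param top,bottom Asymptotes.
#' @param ec50_nM Half-maximal concentration.
#' @param hill_coef Hill coefficient.
#' @param direction `"decreasing"` (default) or `"increasing"`.
#' @return Expected responses.
#' @export
hill_response <- function(conc_nM, top, bottom, ec50_nM, hill_coef = 1,
                          direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  frac <- conc_nM^hill_coef / (ec50_nM^hill_coef + conc_nM^hill_coef)
  if (direction == "decreasing") top - (top - bottom) * frac
  else bottom + (top - bottom) * frac
}

#' Simulate a dose-response cohort
#'
#' Draws per-replicate metric values at each concentration from the truth's
#' decreasing Hill curve with mean-preserving multiplicative log-normal
#' noise of the stated coefficient of variation.
#'
#' @param profile A [subtype_profile()] (labels the cohort; its invasive
#'   area law supplies the default `top` when the truth's is 1).
#' @param truth A [dose_response_truth()].
#' @param concentrations_nM Dose levels (>= 0).
#' @param n_per_dose Replicates per dose.
#' @param seed Optional integer.
#' @return data.frame with `subtype`, `concentration_nM`, `replicate`,
#'   `value`.
#' @export
generate_dose_response_cohort <- function(profile, truth, concentrations_nM,
                                          n_per_dose = 20, seed = NULL) {
  stopifnot(inherits(profile, "subtype_profile"),
            inherits(truth, "dose_response_truth"))
  if (any(concentrations_nM < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  with_seed(seed, {
    mu <- hill_response(rep(concentrations_nM, each = n_per_dose),
                        truth$top, truth$bottom, truth$ec50_nM,
                        truth$hill_coef)
    sigma <- sqrt(log(1 + truth$noise_cv^2))
    noise <- exp(rnorm(length(mu), -sigma^2 / 2, sigma))  # mean-preserving
    data.frame(
      subtype = profile$name,
      concentration_nM = rep(concentrations_nM, each = n_per_dose),
      replicate = rep(seq_len(n_per_dose), times = length(concentrations_nM)),
      value = mu * noise)
  })
}

#' Simulate a day-0 overview scan with ground-truth records
#'
#' Renders a coarse grayscale image of the whole array (each cavity drawn
#' with its count of cell-sized dots) and returns the per-patternoid record
#' table with injected QC defects at the stated rates, flagged as ground
#' truth.
#'
#' @param layout An [array_layout()].
#' @param counts Integer seeding counts, length `rows * cols`
#'   (e.g. from [simulate_seeding()]).
#' @param qc_defect_rates Named numeric vector of per-flag Bernoulli rates;
#'   names must be valid QC flags (see [qc_flag_names()]).
#' @param seed Optional integer.
#' @param pixel_size_um Rendering scale of the overview image.
#' @return List with `image` (grayscale matrix in \[0, 1\]) and `records`
#'   (a patternoid record data.frame: `id`, `row`, `col`, `c0`, `qc_flags`).
#' @export
generate_overview_scan <- function(layout, counts,
                                   qc_defect_rates = default_defect_rates(),
                                   seed = NULL, pixel_size_um = 10) {
  stopifnot(inherits(layout, "array_layout"))
  n_cav <- layout$rows * layout$cols
  if (length(counts) != n_cav)
    stop("`counts` must have length rows * cols", call. = FALSE)
  bad <- setdiff(names(qc_defect_rates), qc_flag_names())
  if (length(bad))
    stop("unknown QC flag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  with_seed(seed, {
    centers <- array_centers(layout)
    px <- pixel_size_um
    pitch <- layout$cavity$pitch_um
    w_um <- (layout$cols - 1) * pitch + pitch
    h_um <- (layout$rows - 1) * pitch + pitch
    img <- matrix(0.05, ceiling(h_um / px), ceiling(w_um / px))
    r_cav_px <- (layout$cavity$diameter_um / 2) / px
    flags <- vector("list", n_cav)
    for (i in seq_len(n_cav)) {
      cx <- (centers$x_um[i] + pitch / 2) / px
      cy <- (centers$y_um[i] + pitch / 2) / px
      # cavity rim
      th <- seq(0, 2 * pi, length.out = 60)
      rim <- cbind(round(cy + r_cav_px * sin(th)),
                   round(cx + r_cav_px * cos(th)))
      rim <- rim[rim[, 1] >= 1 & rim[, 1] <= nrow(img) &
                   rim[, 2] >= 1 & rim[, 2] <= ncol(img), , drop = FALSE]
      img[rim] <- pmax(img[rim], 0.3)
      k <- counts[i]
      if (k > 0) {
        rr <- sqrt(runif(k)) * (r_cav_px - 1)
        tt <- runif(k, 0, 2 * pi)
        dots <- cbind(pmin(nrow(img), pmax(1, round(cy + rr * sin(tt)))),
                      pmin(ncol(img), pmax(1, round(cx + rr * cos(tt)))))
        img[dots] <- 1
      }
      f <- names(qc_defect_rates)[
        runif(length(qc_defect_rates)) < qc_defect_rates]
      flags[[i]] <- f
      if ("agglomeration_d0" %in% f) {
        # draw a bright blob: merged cells prevent counting
        bi <- round(cy) + (-1:1); bj <- round(cx) + (-1:1)
        bi <- bi[bi >= 1 & bi <= nrow(img)]
        bj <- bj[bj >= 1 & bj <= ncol(img)]
        img[bi, bj] <- 1
      }
    }
    records <- data.frame(
      id = sprintf("P%03d", seq_len(n_cav)),
      row = centers$row, col = centers$col,
      c0 = as.integer(counts),
      qc_flags = vapply(flags, paste, "", collapse = ";"),
      stringsAsFactors = FALSE)
    list(image = img, records = records)
  })
}

#' Valid QC flag names
#'
#' The exclusion reasons recorded at the day-0, day-1 (drug addition) and
#' day-3 quality-control stages.
#' @return Character vector of flag names.
#' @export
qc_flag_names <- function() {
  c("agglomeration_d0", "excess_cells_d0", "invasive_at_drug_add_d1",
    "staining_failure_d3", "conjoined_d3", "planar_growth_d3",
    "collapsed_d3")
}

#' Default QC defect rates
#'
#' Per-flag Bernoulli rates for the synthetic overview generator, chosen so
#' that after QC filtering and c0 classification the included fraction of
#' seeded cavities falls in the 10-25% range typical of the assay.
#' @return Named numeric vector.
#' @export
default_defect_rates <- function() {
  c(agglomeration_d0 = 0.25, excess_cells_d0 = 0.20,
    staining_failure_d3 = 0.15, conjoined_d3 = 0.15,
    planar_growth_d3 = 0.10, collapsed_d3 = 0.05)
}
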