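#' Subtype invasion profile
#'
#' Statistical description of one PDAC EMT subtype used by the synthetic-data
#' generator: distributions of invasive roots, branching factor (tips/roots),
#' maximum invasive distance, invasive area (log-normal), the non-invasive
#' (in-cavity) footprint, branch thickness, and the coarse dynamics of the
#' 72 h time course.
#'
#' Roots are drawn as a rounded normal truncated at zero; the branching
#' factor is drawn as `1 + Gamma` with moments matched to
#' (`branching_factor_mean` - 1, `branching_factor_sd`) so the cohort mean
#' and SD equal the configured values on the feasible support (every root
#' carries at least one tip, so the ratio cannot fall below 1).
#'
#' @param name Subtype label.
#' @param roots_mean,roots_sd Mean/SD of the number of invasive roots.
#' @param branching_factor_mean,branching_factor_sd Mean/SD of tips/roots
#'   (mean must be >= 1).
#' @param max_distance_mean_um,max_distance_sd_um Mean/SD of the maximum
#'   invasive distance beyond the cavity boundary, um.
#' @param invasive_area_logmean,invasive_area_logsd Log-normal parameters of
#'   the invasive area law (log um^2); used by area-valued cohort generators.
#' @param noninv_area_norm_mean Mean cell-covered fraction of the cavity's
#'   projected area at endpoint, in (0, 1).
#' @param branch_width_um Typical invasive branch thickness, um.
#' @param growth_rate_r Saturating-growth rate of the non-invasive area
#'   trajectory, per hour.
#' @param noninv_plateau_frac Plateau of the non-invasive area fraction.
#' @param invasion_onset_h Time at which the invasive signal starts, h.
#' @return An object of class `subtype_profile`.
#' @seealso [subtype_profiles()] for the three built-in subtype
#'   parameterizations.
#' @export
subtype_profile <- function(name,
                            roots_mean, roots_sd,
                            branching_factor_mean, branching_factor_sd,
                            max_distance_mean_um, max_distance_sd_um,
                            invasive_area_logmean, invasive_area_logsd,
                            noninv_area_norm_mean,
                            branch_width_um,
                            growth_rate_r,
                            noninv_plateau_frac,
                            invasion_onset_h) {
  if (roots_mean < 0 || roots_sd < 0)
    stop("invalid profile: roots_mean and roots_sd must be >= 0",
         call. = FALSE)
  if (branching_factor_mean < 1)
    stop("invalid profile: branching_factor_mean must be >= 1",
         call. = FALSE)
  if (branching_factor_sd < 0 || max_distance_sd_um < 0)
    stop("invalid profile: SDs must be >= 0", call. = FALSE)
  if (noninv_area_norm_mean <= 0 || noninv_area_norm_mean > 1 ||
      noninv_plateau_frac < 0 || noninv_plateau_frac > 1)
    stop("invalid profile: fractions must lie in (0, 1]", call. = FALSE)
  structure(
    list(name = name,
         roots_mean = roots_mean, roots_sd = roots_sd,
         branching_factor_mean = branching_factor_mean,
         branching_factor_sd = branching_factor_sd,
         max_distance_mean_um = max_distance_mean_um,
         max_distance_sd_um = max_distance_sd_um,
         invasive_area_logmean = invasive_area_logmean,
         invasive_area_logsd = invasive_area_logsd,
         noninv_area_norm_mean = noninv_area_norm_mean,
         branch_width_um = branch_width_um,
         growth_rate_r = growth_rate_r,
         noninv_plateau_frac = noninv_plateau_frac,
         invasion_onset_h = invasion_onset_h),
    class = "subtype_profile")
}

#' Built-in PDAC subtype profiles
#'
#' Parameterizations of the epithelial (E-9591), hybrid EMT (Mlow-8028) and
#' mesenchymal (M-16992) subtypes. Roots, branching factor, and the
#' mesenchymal maximum invasive distance and invasive-area law use the
#' published cohort means/SDs; quantities with no published value
#' (epithelial/hybrid distances, non-invasive footprints, branch widths,
#' dynamics) are fixed defaults chosen to reproduce the qualitative subtype
#' ordering (epithelial: many short thin protrusions, large in-cavity
#' footprint, late invasion onset; hybrid: few thick branches, early
#' in-cavity plateau near 40%; mesenchymal: fewer roots with high branching,
#' long thin fractal branches, early onset).
#'
#' @return Named list of three [subtype_profile()] objects
#'   (`"E-9591"`, `"Mlow-8028"`, `"M-16992"`).
#' @export
subtype_profiles <- function() {
  list(
    "E-9591" = subtype_profile(
      name = "E-9591",
      roots_mean = 7.5, roots_sd = 3.725,
      branching_factor_mean = 1.56, branching_factor_sd = 0.507,
      max_distance_mean_um = 120, max_distance_sd_um = 40,
      invasive_area_logmean = log(4000), invasive_area_logsd = 1.0,
      noninv_area_norm_mean = 0.80,
      branch_width_um = 6,
      growth_rate_r = 0.030,
      noninv_plateau_frac = 0.95,
      invasion_onset_h = 38),
    "Mlow-8028" = subtype_profile(
      name = "Mlow-8028",
      roots_mean = 4.15, roots_sd = 2.492,
      branching_factor_mean = 1.61, branching_factor_sd = 0.530,
      max_distance_mean_um = 320, max_distance_sd_um = 90,
      invasive_area_logmean = log(8000), invasive_area_logsd = 1.2,
      noninv_area_norm_mean = 0.55,
      branch_width_um = 11,
      growth_rate_r = 0.120,
      noninv_plateau_frac = 0.40,
      invasion_onset_h = 27),
    "M-16992" = subtype_profile(
      name = "M-16992",
      roots_mean = 4.8, roots_sd = 1.699,
      branching_factor_mean = 3.15, branching_factor_sd = 0.965,
      # log-normal matched to the printed mean 23971 and SD 102507 um^2
      invasive_area_logmean = log(23971) - 0.5 * log(1 + (102507 / 23971)^2),
      invasive_area_logsd = sqrt(log(1 + (102507 / 23971)^2)),
      max_distance_mean_um = 379.7, max_distance_sd_um = 96.1,
      noninv_area_norm_mean = 0.45,
      branch_width_um = 5,
      growth_rate_r = 0.055,
      noninv_plateau_frac = 0.65,
      invasion_onset_h = 8))
}

#' Ground truth of a simulated dose-response experiment
#'
#' @param ec50_nM Half-maximal concentration of the generating Hill curve,
#'   nM (> 0).
#' @param hill_coef Hill coefficient (> 0); defaults to 1.
#' @param top,bottom Response at zero and saturating dose
#'   (`top >= bottom >= 0`).
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   replicate noise.
#' @return An object of class `dose_response_truth`.
#' @export
dose_response_truth <- function(ec50_nM, hill_coef = 1, top = 1, bottom = 0,
                                noise_cv = 0.10) {
  if (ec50_nM <= 0 || hill_coef <= 0)
    stop("invalid truth: ec50_nM and hill_coef must be > 0", call. = FALSE)
  if (!(top >= bottom && bottom >= 0))
    stop("invalid truth: need top >= bottom >= 0", call. = FALSE)
  structure(list(ec50_nM = ec50_nM, hill_coef = hill_coef, top = top,
                 bottom = bottom, noise_cv = noise_cv),
            class = "dose_response_truth")
}

#' @export
print.subtype_profile <- function(x, ...) {
  cat(sprintf(
    paste0("Subtype profile %s: roots %.2f+-%.2f, BF %.2f+-%.2f, ",
           "max dist %.1f+-%.1f um\n"),
    x$name, x$roots_mean, x$roots_sd, x$branching_factor_mean,
    x$branching_factor_sd, x$max_distance_mean_um, x$max_distance_sd_um))
  invisible(x)
}
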