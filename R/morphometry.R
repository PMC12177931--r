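#' Invasive and non-invasive areas of a patternoid mask
#'
#' The non-invasive area is the foreground area whose pixel centers lie
#' inside the cavity circle; the invasive area is the foreground outside it.
#' The normalized non-invasive area divides by the cavity's projected area
#' (7854 um^2 for the standard 100 um cavity).
#'
#' @param mask A [patternoid_mask()].
#' @return List with `invasive_area_um2`, `noninvasive_area_um2`,
#'   `noninvasive_area_norm`.
#' @export
measure_areas <- function(mask) {
  stopifnot(inherits(mask, "patternoid_mask"))
  d <- mask_dist_um(mask)
  inside <- d < mask$cavity_radius_um
  px_area <- mask$cal$pixel_size_um^2
  noninv <- sum(mask$pixels & inside) * px_area
  inv <- sum(mask$pixels & !inside) * px_area
  list(invasive_area_um2 = inv,
       noninvasive_area_um2 = noninv,
       noninvasive_area_norm = noninv / (pi * mask$cavity_radius_um^2))
}

#' Maximum invasive distance
#'
#' The deepest penetration of foreground beyond the cavity boundary: the
#' maximum over foreground pixels outside the cavity of the Euclidean
#' distance from the cavity center minus the cavity radius (`from =
#' "boundary"`, the default), or the raw distance from the center
#' (`from = "center"`). Zero when nothing lies outside.
#'
#' @param mask A [patternoid_mask()].
#' @param from Reference: `"boundary"` (penetration depth) or `"center"`.
#' @return Distance in um.
#' @export
max_invasive_distance <- function(mask, from = c("boundary", "center")) {
  from <- match.arg(from)
  stopifnot(inherits(mask, "patternoid_mask"))
  d <- mask_dist_um(mask)
  outside <- mask$pixels & d >= mask$cavity_radius_um
  if (!any(outside)) return(0)
  dm <- max(d[outside])
  if (from == "boundary") dm - mask$cavity_radius_um else dm
}

#' Skeletonize a mask and prune short spurs
#'
#' Topology-preserving Zhang-Suen thinning to a 1-pixel-wide, 8-connected
#' skeleton, followed by morphological pruning: `min_branch_um` worth of
#' iterative endpoint removal, which eliminates terminal spurs shorter than
#' the pruning length (thinning artifacts much smaller than a cell) while
#' longer branches keep an endpoint.
#'
#' @param mask A [patternoid_mask()] or logical matrix.
#' @param min_branch_um Minimum surviving branch length, um (default 10).
#' @param cal Calibration when `mask` is a plain matrix.
#' @return Logical skeleton matrix.
#' @export
skeletonize_and_prune <- function(mask, min_branch_um = 10, cal = NULL) {
  if (inherits(mask, "patternoid_mask")) {
    px <- mask$cal$pixel_size_um
    m <- mask$pixels
  } else {
    px <- if (!is.null(cal)) cal$pixel_size_um else 1
    m <- mask
  }
  stopifnot(is.matrix(m), is.logical(m))
  skel <- clean_blunt_ends_cpp(thin_cpp(m))
  prune_spurs(skel, min_branch_um / px)
}

# Remove endpoint-to-junction paths shorter than min_px. Junctions are
# identified by crossing number (>= 3 neighbour groups), so staircase
# corners of the 8-connected skeleton are walked through, not mistaken for
# branch points.
prune_spurs <- function(skel, min_px) {
  prune_cpp(skel, min_px)
}

#' Count invasive roots
#'
#' A root is a distinct crossing of the cavity boundary: an 8-connected
#' component of the mask intersected with a thin annulus centred on the
#' boundary circle, counted only if it touches mask pixels strictly outside
#' the annulus (i.e. the crossing actually continues into the matrix).
#' Crossings closer than about one annulus width merge -- the operator's
#' resolution limit.
#'
#' @param mask A [patternoid_mask()].
#' @param annulus_width_um Full annulus width, um; default two pixels.
#' @return Integer root count.
#' @export
count_roots <- function(mask, annulus_width_um = NULL) {
  stopifnot(inherits(mask, "patternoid_mask"))
  px <- mask$cal$pixel_size_um
  w <- annulus_width_um %||% (2 * px)
  d <- mask_dist_um(mask)
  r <- mask$cavity_radius_um
  ann <- mask$pixels & abs(d - r) <= w / 2
  if (!any(ann)) return(0L)
  lab <- label8_cpp(ann)
  beyond <- mask$pixels & d > r + w / 2
  if (!any(beyond)) return(0L)
  # a component counts when one of its pixels is 8-adjacent to `beyond`
  near_beyond <- dilate8(beyond)
  cand <- unique(lab[ann & near_beyond])
  length(setdiff(cand, 0L))
}

# 8-neighbourhood binary dilation via shifted logical matrices
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  shift <- function(mm, di, dj) {
    res <- matrix(FALSE, nr, nc)
    si <- seq_len(nr) - di; sj <- seq_len(nc) - dj
    ok_i <- si >= 1 & si <= nr; ok_j <- sj >= 1 & sj <= nc
    res[ok_i, ok_j] <- mm[si[ok_i], sj[ok_j]]
    res
  }
  for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0) next
    out <- out | shift(m, di, dj)
  }
  out
}

#' Count invasive tips
#'
#' Tips are skeleton endpoints outside the cavity: skeleton pixels beyond
#' the cavity radius with exactly one skeleton 8-neighbour.
#'
#' @param mask A [patternoid_mask()].
#' @param skeleton Logical skeleton from [skeletonize_and_prune()]; computed
#'   if omitted.
#' @return Integer tip count.
#' @export
count_tips <- function(mask, skeleton = NULL) {
  stopifnot(inherits(mask, "patternoid_mask"))
  if (is.null(skeleton)) skeleton <- skeletonize_and_prune(mask)
  d <- mask_dist_um(mask)
  deg <- neighbor_count_cpp(skeleton)
  sum(skeleton & deg == 1L & d >= mask$cavity_radius_um)
}

#' Extract the full invasion metric set from a mask
#'
#' Composes [measure_areas()], [max_invasive_distance()], [count_roots()]
#' and [count_tips()] into the five-parameter readout. The branching factor
#' is tips/roots, reported as `NA` (undefined, excluded from cohort means)
#' when there are no roots.
#'
#' @param mask A [patternoid_mask()].
#' @param min_branch_um Skeleton pruning length, um.
#' @param annulus_width_um Root-counting annulus width, um (default two
#'   pixels).
#' @return An `invasion_metrics` list: `invasive_area_um2`,
#'   `noninvasive_area_um2`, `noninvasive_area_norm`,
#'   `max_invasive_distance_um`, `roots`, `tips`, `branching_factor`.
#' @export
measure_invasion <- function(mask, min_branch_um = 10,
                             annulus_width_um = NULL) {
  areas <- measure_areas(mask)
  dist <- max_invasive_distance(mask)
  roots <- count_roots(mask, annulus_width_um)
  tips <- if (roots > 0)
    count_tips(mask, skeletonize_and_prune(mask, min_branch_um)) else 0L
  out <- c(areas, list(
    max_invasive_distance_um = dist,
    roots = as.integer(roots), tips = as.integer(tips),
    branching_factor = if (roots > 0) tips / roots else NA_real_))
  class(out) <- "invasion_metrics"
  out
}

#' @export
print.invasion_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("Invasion metrics: inv %.0f um^2, noninv %.0f um^2 ",
           "(norm %.2f), max dist %.1f um, roots %d, tips %d, BF %s\n"),
    x$invasive_area_um2, x$noninvasive_area_um2, x$noninvasive_area_norm,
    x$max_invasive_distance_um, x$roots, x$tips,
    ifelse(is.na(x$branching_factor), "undefined",
           sprintf("%.2f", x$branching_factor))))
  invisible(x)
}

#' Aggregate aligned replicate masks into a count heatmap
#'
#' The per-pixel count of foreground across replicates (the binary-image
#' SUM projection used for phenotype-reproducibility heatmaps). All masks
#' must share the same shape and cavity alignment.
#'
#' @param masks List of [patternoid_mask()] objects or logical matrices of
#'   identical dimensions.
#' @return List with `counts` (integer matrix, max <= number of replicates)
#'   and `n_replicates`.
#' @export
build_heatmap <- function(masks) {
  if (!length(masks)) stop("no masks supplied", call. = FALSE)
  mats <- lapply(masks, function(m)
    if (inherits(m, "patternoid_mask")) m$pixels else m)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mask shape mismatch: all replicates must share dimensions",
         call. = FALSE)
  counts <- Reduce(`+`, lapply(mats, function(m) {
    storage.mode(m) <- "integer"; m
  }))
  list(counts = counts, n_replicates = length(mats))
}

#' Measure a cohort of generated patternoids
#'
#' Convenience driver: generates `n` masks from a profile and measures each,
#' returning ground truth and measured metrics side by side.
#'
#' @param profile A [subtype_profile()].
#' @param n Number of patternoids.
#' @param seed Integer; per-mask seeds are drawn from a stream seeded with
#'   it, so cohorts with different base seeds are independent.
#' @param geometry,cal Passed to [generate_patternoid_mask()].
#' @return data.frame with one row per patternoid: measured metrics
#'   (`roots`, `tips`, `branching_factor`, `max_invasive_distance_um`,
#'   areas) and the generator truth (`truth_*` columns).
#' @export
measure_cohort <- function(profile, n, seed,
                           geometry = cavity_geometry(),
                           cal = pixel_calibration(1.135)) {
  mask_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  rows <- lapply(seq_len(n), function(i) {
    sim <- generate_patternoid_mask(profile, geometry, cal,
                                    seed = mask_seeds[i])
    m <- measure_invasion(sim$mask)
    data.frame(
      id = i,
      roots = m$roots, tips = m$tips,
      branching_factor = m$branching_factor,
      max_invasive_distance_um = m$max_invasive_distance_um,
      invasive_area_um2 = m$invasive_area_um2,
      noninvasive_area_norm = m$noninvasive_area_norm,
      truth_roots = sim$truth$roots, truth_tips = sim$truth$tips,
      truth_branching_factor = sim$truth$branching_factor,
      truth_max_invasive_distance_um = sim$truth$max_invasive_distance_um)
  })
  do.call(rbind, rows)
}
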