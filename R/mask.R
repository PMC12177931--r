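#' Calibrated binary patternoid mask
#'
#' The unit of morphometric analysis: a 2D logical pixel grid with its pixel
#' calibration and the position/radius of the microcavity it grew in.
#' Pixel centers sit at integer coordinates (column = x, row = y, top-left
#' origin); a pixel belongs to a circle when its center is inside.
#'
#' @param pixels Logical matrix (rows = y, cols = x).
#' @param cal A [pixel_calibration()].
#' @param center_px Length-2 numeric `(x, y)` cavity center in pixel
#'   coordinates.
#' @param cavity_radius_um Cavity radius in um.
#' @return An object of class `patternoid_mask`.
#' @export
patternoid_mask <- function(pixels, cal, center_px, cavity_radius_um) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("`pixels` must be a logical matrix", call. = FALSE)
  stopifnot(inherits(cal, "pixel_calibration"), length(center_px) == 2L,
            cavity_radius_um > 0)
  r_px <- cavity_radius_um / cal$pixel_size_um
  if (center_px[1] - r_px < 0.5 || center_px[1] + r_px > ncol(pixels) + 0.5 ||
      center_px[2] - r_px < 0.5 || center_px[2] + r_px > nrow(pixels) + 0.5)
    stop("cavity circle must lie fully inside the pixel grid", call. = FALSE)
  structure(list(pixels = pixels, cal = cal,
                 center_px = as.numeric(center_px),
                 cavity_radius_um = cavity_radius_um),
            class = "patternoid_mask")
}

#' @export
print.patternoid_mask <- function(x, ...) {
  cat(sprintf(
    "Patternoid mask: %d x %d px at %g um/px, cavity r = %g um, %d fg px\n",
    nrow(x$pixels), ncol(x$pixels), x$cal$pixel_size_um,
    x$cavity_radius_um, sum(x$pixels)))
  invisible(x)
}

# Matrix of distances (um) from each pixel center to the cavity center.
mask_dist_um <- function(mask) {
  nr <- nrow(mask$pixels); nc <- ncol(mask$pixels)
  px <- mask$cal$pixel_size_um
  dx <- (seq_len(nc) - mask$center_px[1])
  dy <- (seq_len(nr) - mask$center_px[2])
  px * sqrt(outer(dy^2, dx^2, `+`))
}

# Rasterize a thick segment (stadium: points within w/2 of the segment) into
# a logical matrix, coordinates in pixel units.
fill_segment_px <- function(pixels, x0, y0, x1, y1, halfw) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  jlo <- max(1L, floor(min(x0, x1) - halfw - 1))
  jhi <- min(nc, ceiling(max(x0, x1) + halfw + 1))
  ilo <- max(1L, floor(min(y0, y1) - halfw - 1))
  ihi <- min(nr, ceiling(max(y0, y1) + halfw + 1))
  if (jlo > jhi || ilo > ihi) return(pixels)
  jj <- jlo:jhi; ii <- ilo:ihi
  px <- matrix(rep(jj, each = length(ii)), nrow = length(ii))
  py <- matrix(rep(ii, times = length(jj)), nrow = length(ii))
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  if (len2 < 1e-12) {
    d2 <- (px - x0)^2 + (py - y0)^2
  } else {
    t <- pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / len2))
    d2 <- (px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2
  }
  hit <- d2 <= halfw^2
  pixels[ii, jj] <- pixels[ii, jj] | hit
  pixels
}

# Recursively grow a binary branch tree from `node` towards the tip points.
# Tips are sorted by angle; splits pick a junction radius between the node
# and the nearest tip, guaranteeing every terminal segment is longer than
# the pruning length. Junctions sit on the ray of the subset's farthest tip
# (monopodial growth: a leader branch sheds side branches), which keeps
# every side tip at its full angular clearance from the leader -- centering
# junctions instead would halve the clearance of short side branches and
# let them merge with the leader in the rasterized mask. Returns a list of
# segments (x0, y0, x1, y1) in um relative to the cavity center.
grow_tree_um <- function(node_xy, node_r, tips, min_seg_um, jitter_hw) {
  n <- nrow(tips)
  if (n == 1L) {
    return(list(c(node_xy, tips$x[1], tips$y[1])))
  }
  r_min <- min(tips$r)
  gap <- r_min - node_r
  if (gap < 2 * min_seg_um) {
    # not enough radial room for a further junction: fan out
    return(lapply(seq_len(n), function(j)
      c(node_xy, tips$x[j], tips$y[j])))
  }
  split_r <- node_r + runif(1, 0.2, 0.4) * gap
  split_th <- tips$theta[which.max(tips$r)] +
    runif(1, -jitter_hw, jitter_hw)
  split_xy <- split_r * c(cos(split_th), sin(split_th))
  lead <- which.max(tips$r)
  cut <- if (lead == 1L) 1L else if (lead == n) n - 1L
  else sample(c(lead - 1L, lead), 1L)
  c(list(c(node_xy, split_xy)),
    grow_tree_um(split_xy, split_r, tips[seq_len(cut), , drop = FALSE],
                 min_seg_um, jitter_hw),
    grow_tree_um(split_xy, split_r, tips[(cut + 1L):n, , drop = FALSE],
                 min_seg_um, jitter_hw))
}

#' Generate a synthetic patternoid mask with known ground truth
#'
#' Constructs a binary invasion mask for one patternoid: a filled central
#' disk (the non-invasive body, radius set by the profile's in-cavity
#' footprint) plus a drawn number of branch trees rooted at well-separated
#' anchor angles on the cavity boundary. Each tree carries a drawn number of
#' terminal tips so that the realized tips/roots ratio follows the profile's
#' branching-factor law, and the farthest branch reaches exactly the drawn
#' maximum invasive distance beyond the cavity boundary. Because the mask is
#' built from explicit geometry, the exact realized morphometrics are
#' returned alongside it.
#'
#' Geometric guards keep the construction measurable: roots are confined to
#' disjoint angular sectors (so boundary crossings cannot merge), terminal
#' segments are longer than the default skeleton-pruning length, and tip
#' endpoints are spaced by at least one branch width plus a margin. Draws
#' exceeding what the geometry can hold (e.g. more tips than fit in a
#' sector) are truncated; the returned ground truth is always the realized
#' value.
#'
#' @param profile A [subtype_profile()].
#' @param geometry A [cavity_geometry()].
#' @param cal A [pixel_calibration()]. The default working calibration of
#'   1.135 um/px is chosen so the thinnest subtype branch (5 um) spans at
#'   least four pixels, the stability limit of topology-preserving
#'   thinning; coarser calibrations rasterize thin branches at least
#'   ~4.4 px wide instead.
#' @param seed Optional integer; draws are reproducible given
#'   (parameters, seed) and the caller's RNG state is untouched.
#' @param noninv_norm_sd SD of the normal draw of the in-cavity footprint
#'   fraction.
#' @param prune_min_um Skeleton pruning length the construction must stay
#'   measurable under (terminal segments are built longer than this).
#' @return A list of class `patternoid_sim` with elements `mask`
#'   (a [patternoid_mask()]), `truth` (an `invasion_metrics` list: realized
#'   roots, tips, branching factor, max invasive distance, areas) and
#'   `config` (the drawn construction parameters).
#' @export
generate_patternoid_mask <- function(profile,
                                     geometry = cavity_geometry(),
                                     cal = pixel_calibration(1.135),
                                     seed = NULL,
                                     noninv_norm_sd = 0.05,
                                     prune_min_um = 10) {
  stopifnot(inherits(profile, "subtype_profile"),
            inherits(geometry, "cavity_geometry"),
            inherits(cal, "pixel_calibration"))
  with_seed(seed, {
    r_cav <- geometry$diameter_um / 2
    px <- cal$pixel_size_um
    bw <- profile$branch_width_um
    # effective drawn width: strokes are rasterized at least ~4.4 px wide
    # (thinner diagonal strokes are unstable under thinning)
    bw_eff <- max(bw, 4.4 * px)
    spacing_um <- bw_eff + 10       # tip separation
    # --- draws ------------------------------------------------------------
    norm_max <- ((r_cav - px - 0.6 * px) / r_cav)^2   # disk clear of annulus
    noninv_norm <- min(norm_max, max(
      0.04, rnorm(1, profile$noninv_area_norm_mean, noninv_norm_sd)))
    disk_r <- r_cav * sqrt(noninv_norm)
    root_cap <- max(1L, floor(0.95 * 2 * pi * r_cav / (bw_eff + 7)))
    n_roots <- max(0L, min(root_cap,
                           as.integer(round(rnorm(1, profile$roots_mean,
                                                  profile$roots_sd)))))
    if (n_roots == 0L) {
      bf_draw <- NA_real_; n_tips <- 0L; dist_max <- 0
      segs <- list(); tips_per_root <- integer(0)
    } else {
      m1 <- profile$branching_factor_mean - 1
      if (profile$branching_factor_sd > 0 && m1 > 0) {
        shp <- (m1 / profile$branching_factor_sd)^2
        bf_draw <- 1 + rgamma(1, shape = shp,
                              rate = m1 / profile$branching_factor_sd^2)
      } else bf_draw <- profile$branching_factor_mean
      n_tips_target <- max(n_roots, as.integer(round(n_roots * bf_draw)))
      # shortest feasible tip distance: tips clamped here must still leave a
      # terminal skeleton run comfortably above the pruning length after
      # thick sibling branches merge near their junction
      min_d <- 48 + 2 * bw_eff + prune_min_um
      dist_max <- max(min_d + 6, rnorm(1, profile$max_distance_mean_um,
                                       profile$max_distance_sd_um))
      # per-root farthest distance; root 1 carries the global maximum
      d_root <- pmax(c(dist_max,
                       runif(max(0, n_roots - 1), 0.5, 0.95) * dist_max),
                     min_d + 6)
      # distribute tips, then draw per-root tip distances
      tips_per_root <- rep(1L, n_roots)
      extra <- n_tips_target - n_roots
      while (extra > 0L) {
        pick <- if (n_roots == 1L) 1L else sample(n_roots, 1L)
        tips_per_root[pick] <- tips_per_root[pick] + 1L
        extra <- extra - 1L
      }
      # side-tip radii stay within a narrow band of the root's leader so no
      # junction-to-leader ray can run quasi-collinear past a short tip
      d_tips <- lapply(seq_len(n_roots), function(k) {
        tk <- tips_per_root[k]
        if (tk > 1)
          c(d_root[k], pmin(d_root[k], pmax(min_d,
            runif(tk - 1, 0.7, 0.95) * d_root[k])))
        else d_root[k]
      })
      # angular budget: each root needs room for its tip fan at the tips'
      # radius plus trunk clearance at the cavity boundary; shed tips from
      # the most demanding roots if the circle cannot hold them all
      min_root_angle <- (bw_eff + 7) / r_cav
      need <- function(k) {
        r_tip_min <- r_cav + min(d_tips[[k]]) - bw_eff / 2
        fan <- (tips_per_root[k] - 1) * spacing_um / r_tip_min
        max(fan + min_root_angle, min_root_angle)
      }
      need_k <- vapply(seq_len(n_roots), need, numeric(1))
      while (sum(need_k) > 0.95 * 2 * pi && any(tips_per_root > 1L)) {
        k <- which.max(need_k * (tips_per_root > 1L))
        tips_per_root[k] <- tips_per_root[k] - 1L
        d_tips[[k]] <- d_tips[[k]][seq_len(tips_per_root[k])]
        need_k[k] <- need(k)
      }
      n_tips <- sum(tips_per_root)
      # sector centers: widths proportional to need, slack shared equally
      w_k <- need_k + (2 * pi - sum(need_k)) / n_roots
      rot <- runif(1, 0, 2 * pi)
      theta0 <- rot + cumsum(w_k) - w_k / 2
      # --- build branch trees ---------------------------------------------
      r_lo0 <- r_cav + 10 + bw_eff   # first junction radius floor
      # terminal segments must stay measurable after thick branches merge
      # near junctions: keep junctions well below the tips
      min_seg <- max(prune_min_um + bw_eff + 4, 35)
      segs <- list()
      for (k in seq_len(n_roots)) {
        tk <- tips_per_root[k]
        d <- d_tips[[k]]
        r_tip_min <- r_cav + min(d) - bw_eff / 2
        if (tk == 1L) {
          angles <- theta0[k] + runif(1, -0.05, 0.05)
        } else {
          sh <- min(0.6, (tk - 1) * spacing_um / (2 * r_tip_min))
          angles <- theta0[k] + seq(-sh, sh, length.out = tk) +
            runif(tk, -0.02, 0.02) * spacing_um / r_tip_min
        }
        if (length(d) > 1) d <- sample(d)  # decouple distance from angle order
        tip_r <- r_cav + d - bw_eff / 2
        tips <- data.frame(theta = angles, r = tip_r,
                           x = tip_r * cos(angles), y = tip_r * sin(angles))
        tips <- tips[order(tips$theta), , drop = FALSE]
        anchor_r <- max(disk_r - max(4, 2 * px), 2)
        anchor <- anchor_r * c(cos(theta0[k]), sin(theta0[k]))
        j0_r <- r_lo0 + runif(1, 0, 6)
        j0 <- j0_r * c(cos(theta0[k]), sin(theta0[k]))
        segs <- c(segs, list(c(anchor, j0)),
                  grow_tree_um(j0, j0_r, tips, min_seg, 0.02))
      }
    }
    # --- rasterize --------------------------------------------------------
    half_um <- r_cav + (if (n_roots > 0) dist_max else 0) + bw_eff + 10
    half_px <- ceiling(half_um / px)
    n <- 2L * half_px + 1L
    cx <- half_px + 1
    pixels <- matrix(FALSE, n, n)
    dxy <- (seq_len(n) - cx) * px
    dist_um <- sqrt(outer(dxy^2, dxy^2, `+`))   # symmetric: rows=y, cols=x
    pixels[dist_um <= disk_r] <- TRUE
    halfw_px <- (bw_eff / 2) / px
    for (s in segs)
      pixels <- fill_segment_px(pixels, cx + s[1] / px, cx + s[2] / px,
                                cx + s[3] / px, cx + s[4] / px, halfw_px)
    mask <- patternoid_mask(pixels, cal, c(cx, cx), r_cav)
    inside <- dist_um < r_cav
    px_area <- px^2
    noninv_area <- sum(pixels & inside) * px_area
    inv_area <- sum(pixels & !inside) * px_area
    truth <- list(
      invasive_area_um2 = inv_area,
      noninvasive_area_um2 = noninv_area,
      noninvasive_area_norm = noninv_area / (pi * r_cav^2),
      max_invasive_distance_um = if (n_roots > 0) dist_max else 0,
      roots = n_roots, tips = n_tips,
      branching_factor = if (n_roots > 0) n_tips / n_roots else NA_real_)
    class(truth) <- "invasion_metrics"
    structure(list(mask = mask, truth = truth,
                   config = list(profile = profile$name,
                                 pixel_size_um = px,
                                 noninv_norm = noninv_norm,
                                 disk_r_um = disk_r,
                                 tips_per_root = tips_per_root,
                                 segments_um = segs,
                                 seed = seed)),
              class = "patternoid_sim")
  })
}
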