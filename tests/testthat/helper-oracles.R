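# Independent brute-force reference implementations used as oracles.
# They share no code with the package internals: plain R loops and
# queue-based flood fill only.

# 8-connected component labeling by BFS flood fill
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dj in -1:1) for (di in -1:1) {
        if (di == 0 && dj == 0) next
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni < 1 || nj < 1 || ni > nr || nj > nc) next
        if (mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          queue <- c(queue, list(c(ni, nj)))
        }
      }
    }
  }
  lab
}

oracle_dist_um <- function(mask_obj) {
  nr <- nrow(mask_obj$pixels); nc <- ncol(mask_obj$pixels)
  px <- mask_obj$cal$pixel_size_um
  d <- matrix(0, nr, nc)
  for (j in seq_len(nc))
    d[, j] <- px * sqrt((j - mask_obj$center_px[1])^2 +
                          (seq_len(nr) - mask_obj$center_px[2])^2)
  d
}

# exhaustive pixel scan for areas and the maximum invasive distance
oracle_areas_dist <- function(mask_obj) {
  d <- oracle_dist_um(mask_obj)
  r <- mask_obj$cavity_radius_um
  px2 <- mask_obj$cal$pixel_size_um^2
  noninv <- 0; inv <- 0; dmax <- 0
  idx <- which(mask_obj$pixels)
  for (k in idx) {
    if (d[k] < r) noninv <- noninv + px2
    else {
      inv <- inv + px2
      if (d[k] - r > dmax) dmax <- d[k] - r
    }
  }
  list(noninv = noninv, inv = inv, dmax = dmax,
       norm = noninv / (pi * r^2))
}

# flood-fill root count: components of mask & annulus that touch mask
# pixels strictly outside the annulus
oracle_count_roots <- function(mask_obj, annulus_width_um = NULL) {
  px <- mask_obj$cal$pixel_size_um
  w <- if (is.null(annulus_width_um)) 2 * px else annulus_width_um
  d <- oracle_dist_um(mask_obj)
  r <- mask_obj$cavity_radius_um
  ann <- mask_obj$pixels & abs(d - r) <= w / 2
  if (!any(ann)) return(0L)
  lab <- oracle_label8(ann)
  beyond <- mask_obj$pixels & d > r + w / 2
  nr <- nrow(ann); nc <- ncol(ann)
  counted <- integer(0)
  for (k in which(lab > 0L)) {
    if (lab[k] %in% counted) next
    i <- (k - 1L) %% nr + 1L; j <- (k - 1L) %/% nr + 1L
    for (dj in -1:1) for (di in -1:1) {
      ni <- i + di; nj <- j + dj
      if (ni < 1 || nj < 1 || ni > nr || nj > nc) next
      if (beyond[ni, nj]) counted <- union(counted, lab[k])
    }
  }
  length(counted)
}

# endpoint count by explicit neighbour loop on a given skeleton
oracle_count_tips <- function(mask_obj, skeleton) {
  d <- oracle_dist_um(mask_obj)
  r <- mask_obj$cavity_radius_um
  nr <- nrow(skeleton); nc <- ncol(skeleton)
  tips <- 0L
  for (k in which(skeleton)) {
    i <- (k - 1L) %% nr + 1L; j <- (k - 1L) %/% nr + 1L
    if (d[i, j] < r) next
    deg <- 0L
    for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0) next
      ni <- i + di; nj <- j + dj
      if (ni >= 1 && nj >= 1 && ni <= nr && nj <= nc && skeleton[ni, nj])
        deg <- deg + 1L
    }
    if (deg == 1L) tips <- tips + 1L
  }
  tips
}

# per-pixel projection oracle by explicit triple loop
oracle_projection <- function(stack, fun) {
  v <- if (inherits(stack, "image_stack")) stack$voxels else stack
  out <- matrix(0, dim(v)[1], dim(v)[2])
  for (i in seq_len(dim(v)[1])) for (j in seq_len(dim(v)[2]))
    out[i, j] <- fun(v[i, j, ])
  out
}

# exhaustive-search Otsu threshold on a 256-bin histogram
oracle_otsu <- function(image) {
  rng <- range(image)
  edges <- seq(rng[1], rng[2], length.out = 257)
  counts <- tabulate(pmin(255L, findInterval(image, edges,
                                             rightmost.closed = TRUE)),
                     nbins = 256)
  mids <- (edges[-1] + edges[-257]) / 2
  best <- -Inf; best_t <- mids[1]
  total <- sum(counts)
  for (k in 1:255) {
    w0 <- sum(counts[1:k]); w1 <- total - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / w0
    m1 <- sum(counts[(k + 1):256] * mids[(k + 1):256]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; best_t <- mids[k] }
  }
  best_t
}

# build a simple synthetic mask directly from geometry primitives; arms are
# exact rectangles (no end caps) so analytic areas and lengths hold, and
# the disk uses the strict pixel-center rule matching the measurement side
fixture_mask <- function(n = 201, px = 1, radius = 50,
                         disk_r = 40, rays = list()) {
  cx <- (n + 1) / 2
  pix <- matrix(FALSE, n, n)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (sqrt((j - cx)^2 + (i - cx)^2) * px < disk_r) pix[i, j] <- TRUE
  }
  for (ray in rays) {
    # ray: c(angle_rad, length_beyond_boundary_um, halfwidth_um)
    th <- ray[1]; len <- ray[2]; hw <- ray[3]
    x0 <- (disk_r - 2) * cos(th); y0 <- (disk_r - 2) * sin(th)
    x1 <- (radius + len) * cos(th); y1 <- (radius + len) * sin(th)
    for (j in seq_len(n)) for (i in seq_len(n)) {
      pxx <- (j - cx) * px; pyy <- (i - cx) * px
      vx <- x1 - x0; vy <- y1 - y0
      t <- ((pxx - x0) * vx + (pyy - y0) * vy) / (vx^2 + vy^2)
      if (t < 0 || t > 1) next
      dd <- sqrt((pxx - (x0 + t * vx))^2 + (pyy - (y0 + t * vy))^2)
      if (dd <= hw) pix[i, j] <- TRUE
    }
  }
  patternoid_mask(pix, pixel_calibration(px), c(cx, cx), radius)
}
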