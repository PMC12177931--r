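test_that("areas are measured by the half-open pixel-center rule", {
  disk <- fixture_mask(n = 121, disk_r = 50, radius = 50)
  a <- measure_areas(disk)
  expect_equal(a$invasive_area_um2, 0)
  expect_lt(abs(a$noninvasive_area_norm - 1), 0.02)
  empty <- patternoid_mask(matrix(FALSE, 121, 121), pixel_calibration(1),
                           c(61, 61), 50)
  expect_equal(unlist(measure_areas(empty)), c(invasive_area_um2 = 0,
                                               noninvasive_area_um2 = 0,
                                               noninvasive_area_norm = 0))
  # disk + 10 x 100 um rectangular arm (tilted so rasterization dithers):
  # invasive area close to the analytic 1000 um^2
  arm <- fixture_mask(n = 321, disk_r = 50, radius = 50,
                      rays = list(c(0.4, 100, 5)))
  ainv <- measure_areas(arm)$invasive_area_um2
  expect_lt(abs(ainv - 1000) / 1000, 0.03)
  o <- oracle_areas_dist(arm)
  expect_equal(ainv, o$inv)
})

test_that("maximum invasive distance measures boundary penetration", {
  disk <- fixture_mask(n = 121, disk_r = 40, radius = 50)
  expect_equal(max_invasive_distance(disk), 0)
  ray <- fixture_mask(n = 441, disk_r = 40, radius = 50,
                      rays = list(c(0.7, 150, 3)))
  d <- max_invasive_distance(ray)
  expect_lt(abs(d - 150), 1.5)
  # rotation by 90 degrees leaves the result unchanged
  rot <- patternoid_mask(t(ray$pixels)[ncol(ray$pixels):1, ],
                         ray$cal, ray$center_px, ray$cavity_radius_um)
  expect_equal(max_invasive_distance(rot), d)
  # center-referenced variant differs by exactly the radius
  expect_equal(max_invasive_distance(ray, from = "center") - 50, d)
})

test_that("skeletonization thins bars and stays inside disks", {
  bar <- matrix(FALSE, 9, 40)
  bar[4:6, 3:38] <- TRUE
  sk <- skeletonize_and_prune(bar, min_branch_um = 0,
                              cal = pixel_calibration(1))
  # single 1-px path: every pixel has <= 2 neighbours, one row survives
  expect_true(all(rowSums(sk)[c(1:3, 7:9)] == 0))
  lab <- oracle_label8(sk)
  expect_equal(max(lab), 1)
  disk <- fixture_mask(n = 81, disk_r = 30, radius = 35)
  skd <- skeletonize_and_prune(disk)
  expect_true(all(oracle_dist_um(disk)[skd] <= 30))
})

test_that("pruning removes comb teeth shorter than the cutoff", {
  comb <- matrix(FALSE, 30, 60)
  comb[15, 1:59] <- TRUE             # long spine (ends exceed the cutoff)
  for (x in seq(10, 50, by = 10)) comb[10:14, x] <- TRUE  # 5-px teeth
  sk <- skeletonize_and_prune(comb, min_branch_um = 8,
                              cal = pixel_calibration(1))
  expect_true(all(which(sk, arr.ind = TRUE)[, 1] == 15))
  expect_equal(sum(sk), 59)          # spine untouched
  # teeth survive when the cutoff is below their length
  sk2 <- skeletonize_and_prune(comb, min_branch_um = 2,
                               cal = pixel_calibration(1))
  expect_gt(sum(sk2), sum(sk))
})

test_that("root counting matches the flood-fill oracle on fixtures", {
  disk <- fixture_mask(n = 121, disk_r = 40, radius = 50)
  expect_equal(count_roots(disk), 0L)
  three <- fixture_mask(n = 281, disk_r = 40, radius = 50,
                        rays = list(c(0, 60, 3), c(2.1, 60, 3),
                                    c(4.2, 60, 3)))
  expect_equal(count_roots(three), 3L)
  expect_equal(count_roots(three), oracle_count_roots(three))
  # two crossings closer than the annulus resolution merge into one
  close2 <- fixture_mask(n = 281, disk_r = 40, radius = 50,
                         rays = list(c(0, 60, 3), c(0.08, 60, 3)))
  expect_equal(count_roots(close2), 1L)
  expect_equal(count_roots(close2), oracle_count_roots(close2))
})

test_that("tip counting detects endpoints of known topologies", {
  ray <- fixture_mask(n = 281, disk_r = 40, radius = 50,
                      rays = list(c(0.5, 80, 3)))
  expect_equal(count_tips(ray), 1L)
  # Y-shape: one root, one bifurcation, two tips
  yshape <- fixture_mask(n = 321, disk_r = 40, radius = 50,
                         rays = list(c(0.5, 40, 3)))
  th0 <- 0.5
  split <- (50 + 40) * c(cos(th0), sin(th0))
  pix <- yshape$pixels
  cx <- yshape$center_px[1]
  for (dth in c(-0.35, 0.35)) {
    tip <- (50 + 95) * c(cos(th0 + dth), sin(th0 + dth))
    for (j in seq_len(ncol(pix))) for (i in seq_len(nrow(pix))) {
      p <- c(j - cx, i - cx)
      v <- tip - split
      t <- max(0, min(1, sum((p - split) * v) / sum(v^2)))
      if (sqrt(sum((split + t * v - p)^2)) <= 3) pix[i, j] <- TRUE
    }
  }
  ym <- patternoid_mask(pix, yshape$cal, yshape$center_px, 50)
  expect_equal(count_roots(ym), 1L)
  expect_equal(count_tips(ym), 2L)
  disk <- fixture_mask(n = 121, disk_r = 40, radius = 50)
  expect_equal(count_tips(disk), 0L)
})

test_that("measure_invasion matches oracles on random generator draws", {
  profs <- subtype_profiles()
  seeds <- 1:6
  for (pn in names(profs)) {
    for (s in seeds) {
      sim <- generate_patternoid_mask(profs[[pn]], seed = 4000 + s)
      m <- measure_invasion(sim$mask)
      o <- oracle_areas_dist(sim$mask)
      expect_equal(m$invasive_area_um2, o$inv)
      expect_equal(m$noninvasive_area_um2, o$noninv)
      expect_equal(m$max_invasive_distance_um, o$dmax)
      expect_equal(m$roots, oracle_count_roots(sim$mask))
      sk <- skeletonize_and_prune(sim$mask)
      expect_equal(count_tips(sim$mask, sk), oracle_count_tips(sim$mask, sk))
      expect_equal(m$roots, sim$truth$roots)
    }
  }
})

test_that("empty masks yield zero metrics with undefined branching", {
  empty <- patternoid_mask(matrix(FALSE, 121, 121), pixel_calibration(1),
                           c(61, 61), 50)
  m <- measure_invasion(empty)
  expect_equal(m$roots, 0L)
  expect_equal(m$tips, 0L)
  expect_equal(m$max_invasive_distance_um, 0)
  expect_true(is.na(m$branching_factor))
})

test_that("metrics agree across the two imaging calibrations", {
  p <- subtype_profiles()[["Mlow-8028"]]
  for (s in 1:3) {
    hi <- generate_patternoid_mask(p, cal = pixel_calibration(0.569),
                                   seed = 60 + s)
    lo <- generate_patternoid_mask(p, cal = pixel_calibration(2.27),
                                   seed = 60 + s)
    mh <- measure_invasion(hi$mask); ml <- measure_invasion(lo$mask)
    expect_equal(mh$roots, ml$roots)
    if (mh$roots > 0) {
      expect_lt(
        abs(mh$max_invasive_distance_um - ml$max_invasive_distance_um) /
          mh$max_invasive_distance_um, 0.05)
    }
    expect_lt(abs(mh$noninvasive_area_um2 - ml$noninvasive_area_um2) /
                mh$noninvasive_area_um2, 0.05)
  }
})

test_that("heatmaps count overlapping replicates exactly", {
  m <- matrix(runif(100) > 0.6, 10, 10)
  h <- build_heatmap(list(m, m, m))
  expect_equal(h$counts, 3 * (m * 1))
  expect_equal(h$n_replicates, 3)
  a <- matrix(FALSE, 4, 4); a[1, 1] <- TRUE
  b <- matrix(FALSE, 4, 4); b[4, 4] <- TRUE
  expect_equal(max(build_heatmap(list(a, b))$counts), 1)
  set.seed(5)
  reps <- lapply(1:5, function(i) matrix(runif(64) > 0.5, 8, 8))
  loop <- matrix(0L, 8, 8)
  for (i in 1:8) for (j in 1:8)
    loop[i, j] <- sum(vapply(reps, function(r) r[i, j], logical(1)))
  expect_equal(build_heatmap(reps)$counts, loop)
  expect_lte(max(loop), 5)
  expect_error(build_heatmap(list(a, matrix(FALSE, 3, 3))), "mismatch")
})
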