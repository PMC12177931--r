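cal1 <- pixel_calibration(1)

make_spec <- function(n = 400) {
  roi_spec(center_px = c(100, 200), cal = cal1,
           background_center_px = c(320, 200),
           background_radius_um = 25)
}

test_that("ROI means are exact on hand-built frames", {
  sp <- make_spec()
  flat <- matrix(7, 400, 400)
  ts <- roi_timeseries(list(flat, flat), sp, times_h = c(0, 1))
  expect_equal(ts$inner_mean, c(7, 7))
  expect_equal(ts$invasive_mean, c(7, 7))
  expect_equal(ts$background_mean, c(7, 7))
  # hand-computed 20x20 sub-problem: disk mean over known pixel values
  sp2 <- roi_spec(center_px = c(10, 10), cal = cal1,
                  inner_diameter_um = 6, outer_factor = 2,
                  background_center_px = c(10, 40),
                  background_radius_um = 3)
  fr <- matrix(seq_len(50 * 50), 50, 50)
  ts2 <- roi_timeseries(list(fr), sp2, times_h = 0)
  dx <- outer(rep(1, 50), 1:50) - 10
  dy <- outer(1:50, rep(1, 50)) - 10
  dd <- sqrt(dx^2 + dy^2)
  expect_equal(ts2$inner_mean, mean(fr[dd <= 3]))
  expect_equal(ts2$invasive_mean, mean(fr[dd > 3 & dd <= 6]))
  expect_error(
    roi_spec(center_px = c(10, 10), cal = cal1,
             background_center_px = c(12, 10)),
    "overlap")
})

test_that("background normalization cancels global intensity scaling", {
  sp <- make_spec()
  base <- matrix(10, 400, 400)
  base[190:210, 90:110] <- 30
  frames <- list(base, base * 1.5, base * 0.7)  # illumination drift
  ts <- roi_timeseries(frames, sp, times_h = c(0, 1, 2))
  rel <- background_normalize(ts)
  expect_equal(rel$noninv_rel, rep(rel$noninv_rel[1], 3))
  expect_equal(rel$inv_rel, rep(rel$inv_rel[1], 3))
  flat <- roi_timeseries(list(base), sp, 0)
  expect_equal(background_normalize(flat)$inv_rel, 1, tolerance = 1e-9)
  bad <- data.frame(time_h = 0, inner_mean = 1, invasive_mean = 1,
                    background_mean = 0)
  expect_error(background_normalize(bad), "background")
})

test_that("frame alignment recovers an integer stage drift", {
  set.seed(8)
  ref <- matrix(0, 120, 120)
  ref[40:60, 50:70] <- 1
  ref <- ref + matrix(rnorm(120^2, 0, 0.05), 120)
  shifted <- matrix(0, 120, 120)
  shifted[(40:60) + 7, (50:70) - 4] <- 1
  shifted <- shifted + matrix(rnorm(120^2, 0, 0.05), 120)
  sh <- estimate_translation(ref, shifted)
  expect_equal(unname(sh), c(-4, 7))
})

test_that("baseline correction zeroes the 3 h timepoint and is idempotent", {
  t <- c(3, 24)
  v <- c(0.2, 0.5)
  expect_equal(baseline_correct(v, t), c(0, 0.3))
  const <- rep(0.4, 5)
  expect_equal(baseline_correct(const, c(2, 3, 5, 8, 13)), rep(0, 5))
  once <- baseline_correct(v, t)
  expect_equal(baseline_correct(once, t), once)
  expect_error(baseline_correct(v, c(10, 24)), "baseline")
})

sim_records <- function(n_rep, slopes, noise = 0.03, seed = 1,
                        t_grid = seq(0, 72, by = 9)) {
  set.seed(seed)
  out <- list()
  for (s in seq_along(slopes)) {
    for (r in seq_len(n_rep)) {
      out[[length(out) + 1]] <- data.frame(
        replicate_id = sprintf("s%d_r%d", s, r),
        subtype = paste0("S", s),
        time_h = t_grid,
        value = 0.2 + slopes[s] * t_grid +
          rnorm(1, 0, 0.02) +                  # replicate intercept
          rnorm(length(t_grid), 0, noise))
    }
  }
  do.call(rbind, out)
}

test_that("the longitudinal model recovers slopes and flags singularity", {
  rec <- sim_records(6, c(0.004, 0.012), seed = 3)
  fit <- fit_longitudinal_trend(rec)
  expect_lt(abs(fit$slopes[["S1"]] - 0.004), 0.001)
  expect_lt(abs(fit$slopes[["S2"]] - 0.012), 0.001)
  expect_lt(fit$interaction_p[["S2"]], 0.05)   # 3x slope gap is detected
  expect_error(fit_longitudinal_trend(rec[rec$subtype == "S1", ]),
               ">= 2 subtypes")
  one_rep <- rec[rec$replicate_id %in% c("s1_r1", "s2_r1", "s2_r2"), ]
  expect_error(fit_longitudinal_trend(one_rep), "replicates")
  two_t <- rec[rec$time_h %in% c(0, 9), ]
  expect_error(fit_longitudinal_trend(two_t), "timepoints")
})

test_that("fitted subtype slope ordering reproduces the generator ordering", {
  profs <- subtype_profiles()
  t_grid <- seq(0, 72, by = 6)
  hits <- 0
  for (s in 1:10) {
    rec <- do.call(rbind, lapply(names(profs), function(pn) {
      nrep <- c("E-9591" = 4, "Mlow-8028" = 5, "M-16992" = 6)[[pn]]
      do.call(rbind, lapply(seq_len(nrep), function(r) {
        ts <- generate_timeseries(profs[[pn]], t_grid,
                                  seed = s * 1000 + r * 17 +
                                    match(pn, names(profs)) * 131)
        data.frame(replicate_id = paste(pn, r), subtype = pn,
                   time_h = ts$time_h, value = ts$noninv_frac)
      }))
    }))
    fit <- suppressMessages(fit_longitudinal_trend(rec))
    sl <- fit$slopes
    if (sl[["E-9591"]] > sl[["M-16992"]] &&
        sl[["M-16992"]] > sl[["Mlow-8028"]]) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
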