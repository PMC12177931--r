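layout650 <- array_layout(25, 26)

test_that("seeding counts follow the Poisson law", {
  expect_true(all(simulate_seeding(layout650, 0, seed = 1) == 0))
  expect_error(simulate_seeding(layout650, -2), "mean_cells")
  # CLT band on the sample mean at mean 20 over 650 cavities: individual
  # batch means stay within 3 sigma (rare excursions tolerated) and the
  # grand mean is tighter still
  means <- vapply(1:20, function(s)
    mean(simulate_seeding(layout650, 20, seed = s)), numeric(1))
  expect_lte(sum(abs(means - 20) > 3 * sqrt(20 / 650)), 1)
  expect_lt(abs(mean(means) - 20), 4 * sqrt(20 / (650 * 20)))
  # fraction of counts in [18, 22] matches the exact pmf sum
  counts <- unlist(lapply(1:30, function(s)
    simulate_seeding(layout650, 20, seed = s)))
  p_exact <- sum(dpois(18:22, 20))
  p_obs <- mean(counts >= 18 & counts <= 22)
  se <- sqrt(p_exact * (1 - p_exact) / length(counts))
  expect_lt(abs(p_obs - p_exact), 3 * se)
  # bit-reproducible under the seed
  expect_identical(simulate_seeding(layout650, 20, seed = 7),
                   simulate_seeding(layout650, 20, seed = 7))
})

test_that("degenerate profiles generate the promised mask topologies", {
  profs <- subtype_profiles()
  p0 <- subtype_profile("none", roots_mean = 0, roots_sd = 0,
                        branching_factor_mean = 1, branching_factor_sd = 0,
                        max_distance_mean_um = 100, max_distance_sd_um = 0,
                        invasive_area_logmean = 8, invasive_area_logsd = 1,
                        noninv_area_norm_mean = 0.5, branch_width_um = 6,
                        growth_rate_r = 0.05, noninv_plateau_frac = 0.5,
                        invasion_onset_h = 24)
  sim0 <- generate_patternoid_mask(p0, seed = 1)
  expect_equal(sim0$truth$roots, 0L)
  expect_equal(sim0$truth$tips, 0L)
  expect_equal(sim0$truth$invasive_area_um2, 0)
  expect_true(is.na(sim0$truth$branching_factor))
  # one unbranched ray at a fixed distance
  p1 <- subtype_profile("ray", roots_mean = 1, roots_sd = 0,
                        branching_factor_mean = 1, branching_factor_sd = 0,
                        max_distance_mean_um = 150, max_distance_sd_um = 0,
                        invasive_area_logmean = 8, invasive_area_logsd = 1,
                        noninv_area_norm_mean = 0.5, branch_width_um = 6,
                        growth_rate_r = 0.05, noninv_plateau_frac = 0.5,
                        invasion_onset_h = 24)
  sim1 <- generate_patternoid_mask(p1, seed = 2)
  expect_equal(sim1$truth$roots, 1L)
  expect_equal(sim1$truth$tips, 1L)
  expect_equal(sim1$truth$max_invasive_distance_um, 150)
  m1 <- measure_invasion(sim1$mask)
  expect_equal(m1$roots, 1L)
  expect_equal(m1$tips, 1L)
  expect_lt(abs(m1$max_invasive_distance_um - 150), 1.5 * 1.135)
})

test_that("generated masks match brute-force oracles and are reproducible", {
  profs <- subtype_profiles()
  for (pn in names(profs)) {
    for (s in 1:6) {
      sim <- generate_patternoid_mask(profs[[pn]], seed = 100 * s)
      o <- oracle_areas_dist(sim$mask)
      expect_equal(sim$truth$noninvasive_area_um2, o$noninv)
      expect_equal(sim$truth$invasive_area_um2, o$inv)
      if (sim$truth$roots > 0) {
        expect_lt(abs(sim$truth$max_invasive_distance_um - o$dmax),
                  1.5 * 1.135)
        expect_equal(oracle_count_roots(sim$mask), sim$truth$roots)
      }
    }
  }
  a <- generate_patternoid_mask(profs[["M-16992"]], seed = 5)
  b <- generate_patternoid_mask(profs[["M-16992"]], seed = 5)
  expect_identical(a$mask$pixels, b$mask$pixels)
  expect_identical(a$truth, b$truth)
})

test_that("generator moments converge towards the profile means", {
  p <- subtype_profiles()[["M-16992"]]
  co <- measure_cohort(p, 60, seed = 31)
  expect_lt(abs(mean(co$truth_roots) - p$roots_mean),
            3 * p$roots_sd / sqrt(60) + 0.15)
  expect_lt(abs(mean(co$truth_branching_factor, na.rm = TRUE) -
                  p$branching_factor_mean),
            3 * p$branching_factor_sd / sqrt(60) + 0.1)
})

test_that("rendered stacks honor the SNR contract and round-trip", {
  p <- subtype_profiles()[["Mlow-8028"]]
  sim <- generate_patternoid_mask(p, seed = 9)
  clean <- render_intensity(sim$mask, snr = Inf, n_slices = 4, seed = 1)
  mp <- max_projection(clean)
  expect_identical(binarize(mp, "fixed", threshold = 100), sim$mask$pixels)
  single <- render_intensity(sim$mask, snr = Inf, n_slices = 1, seed = 1)
  expect_equal(max_projection(single), single$voxels[, , 1])
  noisy <- render_intensity(sim$mask, snr = 5, n_slices = 4, seed = 2)
  rec <- binarize(denoise(max_projection(noisy), 1), "otsu")
  dice <- 2 * sum(rec & sim$mask$pixels) / (sum(rec) + sum(sim$mask$pixels))
  expect_gte(dice, 0.95)
})

test_that("time courses start at baseline, plateau, and stay monotone", {
  p <- subtype_profiles()[["Mlow-8028"]]
  ts0 <- generate_timeseries(p, 0:72, noise_sd = 0)
  expect_equal(ts0$noninv_frac[1], 0.2)
  expect_equal(ts0$inv_rel[ts0$time_h <= p$invasion_onset_h],
               rep(0, sum(ts0$time_h <= p$invasion_onset_h)))
  expect_lt(abs(ts0$noninv_frac[ts0$time_h == 72] - 0.40), 0.01 * 0.40)
  expect_true(all(diff(ts0$noninv_frac) > 0))
  expect_true(all(diff(ts0$inv_rel) >= 0))
  expect_error(generate_timeseries(p, c(3, 2)), "ascending")
})

test_that("dose-response cohorts follow the Hill expectation", {
  p <- subtype_profiles()[["M-16992"]]
  tr <- dose_response_truth(500, 1, top = 100, bottom = 0, noise_cv = 1e-9)
  d <- generate_dose_response_cohort(p, tr, c(0, 500, 1e7), 3, seed = 1)
  m <- tapply(d$value, d$concentration_nM, mean)
  expect_equal(unname(m[["0"]]), 100, tolerance = 1e-6)
  expect_equal(unname(m[["500"]]), 50, tolerance = 1e-6)
  expect_lt(unname(m[["1e+07"]]), 0.01 * 100)
})

test_that("overview scans carry QC ground truth at the configured rates", {
  small <- array_layout(5, 6)
  counts <- simulate_seeding(small, 20, seed = 3)
  clean <- generate_overview_scan(small, counts, qc_defect_rates = c(),
                                  seed = 1)
  expect_equal(nrow(clean$records), 30)
  expect_true(all(clean$records$qc_flags == ""))
  allbad <- generate_overview_scan(small, counts,
                                   qc_defect_rates = c(agglomeration_d0 = 1),
                                   seed = 1)
  d0 <- apply_inclusion_criteria(allbad$records, "d0")
  expect_equal(nrow(d0), 0)
  expect_error(
    generate_overview_scan(small, counts, qc_defect_rates = c(bogus = 0.1)),
    "unknown QC flag")
})
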