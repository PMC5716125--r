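make_profile <- function(values, label = "air", normalized = FALSE) {
  structure(list(values = values, label = label,
                 projections_averaged = c(0, 0), normalized = normalized),
            class = "transverse_profile")
}

test_that("exact modified-Gaussian data are recovered to high precision", {
  x <- 0:639
  y <- modified_gaussian(x, y0 = 0.1, a = 1, x0 = 320.4, b = 150, c = 3)
  fit <- fit_modified_gaussian(make_profile(y), window = 120:520)
  expect_equal(fit$x0, 320.4, tolerance = 1e-5)
  expect_equal(fit$y0, 0.1, tolerance = 1e-4)
  expect_equal(fit$a, 1, tolerance = 1e-4)
  expect_equal(fit$b, 150, tolerance = 1e-2)
  expect_equal(fit$c, 3, tolerance = 1e-4)
  expect_gt(fit$r2, 0.999999)
})

test_that("noisy modified-Gaussian centers stay within 0.3 channel", {
  x <- 0:639
  clean <- modified_gaussian(x, y0 = 0.1, a = 1, x0 = 320.4, b = 150, c = 3)
  errs <- vapply(1:20, function(s) {
    y <- withr::with_seed(s, clean * (1 + 0.005 * rnorm(length(x))))
    fit_modified_gaussian(make_profile(y), window = 120:520, seed = s)$x0 -
      320.4
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.3)
})

test_that("a c = 2 fit agrees with the moment-based Gaussian center", {
  x <- 0:639
  y <- modified_gaussian(x, y0 = 0.05, a = 0.8, x0 = 301.7, b = 40, c = 2)
  fit <- fit_modified_gaussian(make_profile(y), window = 150:450)
  w <- y[151:451] - 0.05
  moment_center <- sum((150:450) * w) / sum(w)
  expect_equal(fit$x0, moment_center, tolerance = 0.01)
  expect_equal(fit$c, 2, tolerance = 1e-3)
})

test_that("normalization to air isolates the wedge transmission window", {
  rig <- fitted_rig()
  profs <- extract_transverse_profiles(rig$acq, rig$fit)
  same <- normalize_to_air(profs$air, profs$air)
  expect_equal(same$values, rep(1, 640), tolerance = 1e-12)
  Tk <- rig$sim$truth$levels_transmission[2:6]
  for (k in c(1L, 5L)) {
    np <- normalize_to_air(profs[[paste0("step", k)]], profs$air)
    expect_equal(np$values[321], Tk[k], tolerance = 1e-9)   # inside shadow
    expect_equal(np$values[30], 1, tolerance = 1e-9)        # outside shadow
    # the ratio is invariant to a global output rescaling
    scaled <- profs[[paste0("step", k)]]
    scaled$values <- scaled$values * 5
    air5 <- profs$air
    air5$values <- air5$values * 5
    expect_equal(normalize_to_air(scaled, air5)$values, np$values,
                 tolerance = 1e-12)
  }
  zero_air <- profs$air
  zero_air$values[5] <- 0
  expect_error(normalize_to_air(profs$step1, zero_air), "air")
})

test_that("the three centers coincide for an aligned system", {
  rig <- fitted_rig(fast_scenario(noise_rel = 0.005, seed = 31))
  cr <- center_report(extract_transverse_profiles(rig$acq, rig$fit),
                      fast_geom(), seed = 31)
  expect_lt(abs(cr$detector_center_channel - 319.5), 0.3)
  expect_lt(abs(cr$sagittal_laser_channel - cr$detector_center_channel), 0.3)
  expect_false(cr$couch_walk_flag)
  expect_lt(max(abs(cr$pairwise_offsets_mm)), 1)
})

test_that("an induced lateral wedge offset is recovered at isocenter", {
  scn <- fast_scenario(noise_rel = 0.005, lateral_offset_mm = 3, seed = 33)
  rig <- fitted_rig(scn)
  cr <- center_report(extract_transverse_profiles(rig$acq, rig$fit),
                      fast_geom(), seed = 33)
  rec <- channels_to_isocenter_mm(
    cr$sagittal_laser_channel - cr$detector_center_channel, fast_geom())
  expect_equal(rec, 3.0, tolerance = 0.3)
  # the printed conversion: 2.6 channels of misalignment is 1.9 mm
  expect_equal(round(channels_to_isocenter_mm(2.6, fast_geom()), 1), 1.9)
})

test_that("the flank-inflection beam center is accurate and equivariant", {
  x <- 0:639
  air <- modified_gaussian(x, y0 = 0.08, a = 1, x0 = 320.0, b = 150, c = 4)
  prof <- make_profile(air)
  expect_equal(beam_center_second_derivative(prof), 320.0, tolerance = 0.1)
  shifted <- make_profile(c(rep(air[1], 4), head(air, -4)))
  expect_equal(beam_center_second_derivative(shifted),
               beam_center_second_derivative(prof) + 4, tolerance = 0.01)
  # dense-grid analytic inflection of the model curve: |x-x0|/b = (2(c-1)/c)^(1/c)
  z <- (2 * 3 / 4)^(1 / 4) * 150
  fine <- seq(0, 639, by = 0.01)
  g <- modified_gaussian(fine, 0.08, 1, 320.0, 150, 4)
  d2 <- diff(g, differences = 2)
  left <- which(diff(sign(d2[fine[-(1:2)] < 320])) != 0)[1] * 0.01
  expect_equal(320 - z, left, tolerance = 0.05)        # the formula itself
  expect_equal(beam_center_second_derivative(prof), 320, tolerance = 0.2)
  flat <- make_profile(rep(1, 640))
  expect_error(beam_center_second_derivative(flat), "flank",
               class = "stepwedge_fit_error")
})

test_that("the exponential PDD fit has its closed-form properties", {
  wedge <- step_wedge_spec()
  depths <- c(0, water_equivalent_depths(wedge))
  mu <- log(2) / 100
  levels <- 3 * exp(-mu * depths)
  fit <- fit_pdd_exponential(levels, depths)
  expect_equal(fit$d20_d10, 0.5, tolerance = 1e-6)
  expect_equal(fit$mu_eff_per_mm, mu, tolerance = 1e-9)
  expect_equal(pdd_value(fit, 50), 100, tolerance = 1e-9)
  # invariant under any positive rescaling of the levels
  fit5 <- fit_pdd_exponential(levels * 5, depths)
  expect_equal(fit5$d20_d10, fit$d20_d10, tolerance = 1e-12)
  expect_error(fit_pdd_exponential(rev(levels), depths), "decreasing")
  expect_error(fit_pdd_exponential(c(-1, levels[-1]), depths), "positive")
})

test_that("energy consistency reproduces the printed ratio differences", {
  ref <- make_reference_pdd(-log(0.535) / 100)
  meas <- list(d20_d10 = 0.536)
  expect_equal(round(energy_consistency(meas, ref), 1), 0.2)
  ref2 <- make_reference_pdd(-log(0.502) / 100)
  expect_equal(round(energy_consistency(list(d20_d10 = 0.499), ref2), 1), -0.6)
  expect_equal(energy_consistency(list(d20_d10 = 0.535), ref), 0,
               tolerance = 1e-9)
})

test_that("time-profile and transverse-profile PDD routes agree", {
  rig <- fitted_rig(fast_scenario(noise_rel = 0.005, seed = 35))
  wedge <- fast_wedge()
  depths <- c(0, water_equivalent_depths(wedge))
  route1 <- fit_pdd_exponential(rig$fit$s[1:6], depths)$d20_d10
  profs <- extract_transverse_profiles(rig$acq, rig$fit)
  centre <- 321
  levels2 <- vapply(profs, function(p) p$values[centre], numeric(1))
  route2 <- fit_pdd_exponential(unname(levels2), depths)$d20_d10
  expect_lt(abs(route1 / route2 - 1) * 100, 0.5)
  expect_equal(route1, rig$sim$truth$d20_d10, tolerance = 0.005)
})
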