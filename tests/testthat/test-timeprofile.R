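test_that("the schematic model evaluates flats and ramps exactly", {
  p <- c(100, 130, 220, 250, 340, 370, 460, 490, 580, 610, 700, 730)
  s <- c(1, 0.7, 0.5, 0.35, 0.25, 0.18, 1)
  expect_equal(evaluate_schematic(p, s, c(0, 50, 99.9)), rep(1, 3))
  expect_equal(evaluate_schematic(p, s, (100 + 130) / 2), (1 + 0.7) / 2)
  expect_equal(evaluate_schematic(p, s, 800), 1)
  # brute-force pointwise oracle over the whole grid
  t <- seq(0, 800, by = 0.5)
  oracle <- vapply(t, function(ti) {
    k <- findInterval(ti, p)
    if (k %% 2 == 0) return(s[k / 2 + 1])
    j <- (k + 1) / 2
    a <- p[2 * j - 1]; b <- p[2 * j]
    s[j] + (s[j + 1] - s[j]) * (ti - a) / (b - a)
  }, numeric(1))
  expect_equal(evaluate_schematic(p, s, t), oracle, tolerance = 1e-12)
  expect_error(evaluate_schematic(rev(p), s, t), "increasing")
  # the compiled objective agrees with the pure-R model
  v <- evaluate_schematic(p, s, 0:800) + 0.01
  expect_equal(stepwedge:::.sse_schematic_cpp(p, s, v),
               sum((v - evaluate_schematic(p, s, 0:800))^2),
               tolerance = 1e-12)
})

test_that("noiseless profiles are recovered to numerical precision", {
  rig <- fitted_rig(fast_scenario(noise_rel = 0, seed = 3))
  truth <- rig$sim$truth
  expect_lt(max(abs(rig$fit$p - truth$p_proj)), 0.05)
  # level ratios equal the generating transmissions (the absolute scale
  # carries the output-correction factor, which all metrics cancel)
  expect_equal(rig$fit$s / rig$fit$s[1], truth$levels_transmission[c(1:6, 7)],
               tolerance = 1e-6)
  cs <- couch_speed_deviation(rig$fit, fast_geom(), fast_wedge())
  expect_lt(abs(cs$couch_speed_dev_pct), 1e-4)
  expect_equal(field_width(rig$fit, fast_geom()), 10, tolerance = 1e-4)
  expect_equal(step_lengths(rig$fit, fast_geom()),
               c(29.9, 30, 30, 30, 30.1), tolerance = 0.01)
})

test_that("degenerate profiles are rejected with a structure error", {
  tp <- structure(list(values = rep(1, 1500), channel_index = 320L,
                       dt_s = 1 / 30), class = "time_profile")
  expect_error(fit_schematic_profile(tp, fast_geom(), fast_wedge()),
               "no step structure", class = "stepwedge_fit_error")
})

test_that("fits are scale-invariant and shift-equivariant", {
  rig <- fitted_rig(fast_scenario(noise_rel = 0.003, seed = 11))
  tp <- rig$profile
  scaled <- tp
  scaled$values <- tp$values * 3
  f2 <- fit_schematic_profile(scaled, fast_geom(), fast_wedge(),
                              restarts = 4L, seed = 11)
  expect_equal(f2$p, rig$fit$p, tolerance = 1e-4)
  expect_equal(f2$s, rig$fit$s * 3, tolerance = 1e-4)
  m1 <- couch_speed_deviation(rig$fit, fast_geom(), fast_wedge())
  m2 <- couch_speed_deviation(f2, fast_geom(), fast_wedge())
  expect_equal(m1$couch_speed_dev_pct, m2$couch_speed_dev_pct,
               tolerance = 1e-3)

  shifted <- tp
  k <- 40L
  shifted$values <- c(rep(tp$values[1], k), head(tp$values, -k))
  f3 <- fit_schematic_profile(shifted, fast_geom(), fast_wedge(),
                              restarts = 4L, seed = 11)
  expect_equal(f3$p, rig$fit$p + k, tolerance = 0.05)
  expect_equal(field_width(f3, fast_geom()), field_width(rig$fit, fast_geom()),
               tolerance = 0.01)
  # only the laser offset moves, by exactly the shift
  expect_equal(transverse_laser_offset(f3, rig$fit$p[1], fast_geom()),
               projections_to_mm(k, 1 / 30, 5), tolerance = 0.05)
})

test_that("couch-speed and step-length arithmetic follows the fit", {
  rig <- fitted_rig()
  fit <- rig$fit
  # stretching all transition times by 1.01 reads as couch slowed to 1/1.01
  slow <- fit
  slow$p <- fit$p * 1.01
  expect_equal(couch_speed_deviation(slow, fast_geom(),
                                     fast_wedge())$couch_speed_dev_pct,
               100 * (1 / 1.01 - 1), tolerance = 1e-3)
  expect_equal(step_lengths(slow, fast_geom()),
               step_lengths(fit, fast_geom()) * 1.01, tolerance = 1e-6)
  # field width is pure transition arithmetic
  fw <- fit
  fw$p[2] <- fw$p[1] + 400
  fw$dt_s <- 0.030
  expect_equal(field_width(fw, machine_geometry(dt_s = 0.030)), 12.0)
  # missing laser reference errors
  expect_error(transverse_laser_offset(fit, NULL, fast_geom()), "reference")
})

test_that("induced couch-speed and width deviations are recovered", {
  scn <- fast_scenario(noise_rel = 0.005, couch_speed_factor = 1.02, seed = 21)
  rig <- fitted_rig(scn)
  expect_equal(couch_speed_deviation(rig$fit, fast_geom(),
                                     fast_wedge())$couch_speed_dev_pct,
               2.00, tolerance = 0.05)
  scn2 <- fast_scenario(noise_rel = 0, field_width_mm = 10.4, seed = 22)
  rig2 <- fitted_rig(scn2)
  expect_equal(field_width(rig2$fit, fast_geom()), 10.40, tolerance = 0.01)
  scn3 <- fast_scenario(noise_rel = 0.005, longitudinal_offset_mm = 2, seed = 23)
  rig3 <- fitted_rig(scn3)
  ref_p1 <- fitted_rig(fast_scenario(noise_rel = 0.005, seed = 24))$fit$p[1]
  expect_equal(transverse_laser_offset(rig3$fit, ref_p1, fast_geom()),
               2.0, tolerance = 0.1)
})

test_that("fit quality exceeds 0.99 at realistic noise", {
  rig <- fitted_rig(fast_scenario(noise_rel = 0.005, seed = 7))
  expect_gt(rig$fit$r2, 0.99)
})
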