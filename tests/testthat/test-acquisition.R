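test_that("acquisition files round-trip bit-identically", {
  acq <- tiny_acquisition()
  path <- withr::local_tempfile(fileext = ".csv")
  write_acquisition(acq, path)
  back <- read_acquisition(path, n_channels = ncol(acq$signal))
  expect_identical(back$signal, acq$signal)
  expect_identical(back$monitor, acq$monitor)
  expect_identical(back$dt_s, acq$dt_s)
  expect_identical(back$meta$machine_id, acq$meta$machine_id)
})

test_that("malformed acquisition files raise typed parse errors", {
  acq <- tiny_acquisition(nch = 8L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_acquisition(acq, path)
  expect_error(read_acquisition(path, n_channels = 9L), "channel count",
               class = "stepwedge_parse_error")
  file.create(empty <- withr::local_tempfile(fileext = ".csv"))
  expect_error(read_acquisition(empty), "empty",
               class = "stepwedge_parse_error")
  # negative signal names the offending row
  lines <- readLines(path)
  lines[4] <- sub("^2,([^,]*),[^,]*", "2,\\1,-4.0", lines[4])
  writeLines(lines, path)
  expect_error(read_acquisition(path, n_channels = 8L), "row",
               class = "stepwedge_parse_error")
})

test_that("10:1 down-sampling is an exact block mean", {
  n <- 120L
  acq <- tiny_acquisition(n = n, nch = 5L, seed = 3L, dt_s = 1 / 300)
  ds <- downsample_10to1(acq)
  expect_equal(nrow(ds$signal), 12L)
  expect_equal(ds$dt_s, 1 / 30)
  # independent block-mean oracle
  oracle <- apply(acq$signal, 2L, function(col)
    tapply(col, rep(1:12, each = 10L), mean))
  dimnames(oracle) <- NULL
  expect_equal(ds$signal, oracle, tolerance = 1e-12)
  expect_equal(ds$monitor,
               as.numeric(tapply(acq$monitor, rep(1:12, each = 10L), mean)),
               tolerance = 1e-12)
  # total signal x dt is preserved
  expect_equal(sum(ds$signal) * ds$dt_s, sum(acq$signal) * acq$dt_s,
               tolerance = 1e-9 * sum(acq$signal) * acq$dt_s)
  # constants stay constant; alternating 0/2 averages to 1
  flat <- detector_acquisition(matrix(2, 20, 3), rep(1, 20), 1 / 300)
  expect_true(all(downsample_10to1(flat)$signal == 2))
  alt <- detector_acquisition(matrix(rep(c(0, 2), 10), 20, 3), rep(1, 20),
                              1 / 300)
  expect_true(all(downsample_10to1(alt)$signal == 1))
  # remainder dropped with warning; too-short input errors
  expect_warning(downsample_10to1(tiny_acquisition(n = 25L, nch = 3L)),
                 "trailing")
  expect_error(downsample_10to1(tiny_acquisition(n = 9L, nch = 3L)),
               "fewer than 10")
})

test_that("output correction removes shared output fluctuations", {
  # constant monitor: signal unchanged
  acq <- tiny_acquisition(n = 30L, nch = 4L)
  acq$monitor <- rep(1.3, 30L)
  cor1 <- output_correct(acq)
  expect_equal(cor1$signal, acq$signal, tolerance = 1e-12)
  # signal equal to monitor: corrected to the constant monitor mean
  m <- runif(30L, 0.8, 1.2)
  acq2 <- detector_acquisition(matrix(m, 30L, 4L), m, 1 / 30)
  cor2 <- output_correct(acq2)
  expect_equal(unname(cor2$signal[, 1]), rep(mean(m), 30L), tolerance = 1e-12)
  # idempotence
  cor3 <- output_correct(cor2)
  expect_equal(cor3$signal, cor2$signal, tolerance = 1e-12)
  # simulated 2% sinusoidal ripple is suppressed below 0.1% of the mean
  scn <- fast_scenario(noise_rel = 0, seed = 5,
                       output_ripple = c(amplitude_rel = 0.02, period_s = 6))
  sim <- simulate_acquisition(scn)
  corrected <- output_correct(sim$acquisition)
  air_rows <- 40:200                 # flat air segment of the fast rig
  trace <- corrected$signal[air_rows, 321]
  expect_lt((max(trace) - min(trace)) / 2, 0.001 * mean(trace))
  raw <- sim$acquisition$signal[air_rows, 321]
  expect_gt((max(raw) - min(raw)) / 2, 0.015 * mean(raw))
  # non-positive monitor inside the beam-on span is rejected
  bad <- tiny_acquisition(n = 30L, nch = 4L)
  bad$monitor[15] <- 0
  expect_error(output_correct(bad), "monitor")
})

test_that("time profiles come from the requested channel", {
  rig <- fitted_rig()
  expect_error(extract_time_profile(rig$sim$acquisition), "output-corrected")
  tp <- extract_time_profile(rig$acq, channel_index = 100L)
  expect_equal(tp$values, rig$acq$signal[, 101L])
  expect_equal(extract_time_profile(rig$acq)$channel_index, 320L)
  expect_error(extract_time_profile(rig$acq, channel_index = 640L),
               "out of range")
})

test_that("transverse profiles average only rows inside flat segments", {
  rig <- fitted_rig()
  profs <- extract_transverse_profiles(rig$acq, rig$fit)
  expect_named(profs, c("air", paste0("step", 1:5)))
  p <- rig$fit$p
  # margins respected: no averaged row within 10% of a segment of a slope
  for (k in 1:5) {
    rng <- profs[[paste0("step", k)]]$projections_averaged
    lo <- p[2 * k]
    hi <- p[2 * k + 1]
    expect_gte(rng[1], lo + 0.1 * (hi - lo) - 1)
    expect_lte(rng[2], hi - 0.1 * (hi - lo) + 1)
  }
  # noiseless: each step profile equals air times the level transmission
  # inside the wedge shadow (up to the shared output ripple correction)
  Tk <- rig$sim$truth$levels_transmission[2:6]
  centre <- 321
  for (k in 1:5) {
    expect_equal(profs[[paste0("step", k)]]$values[centre],
                 profs$air$values[centre] * Tk[k], tolerance = 1e-9)
  }
  # a fit whose flats are too short errors
  squeezed <- rig$fit
  squeezed$p <- cumsum(rep(3, 12))
  expect_error(extract_transverse_profiles(rig$acq, squeezed),
               "segment too short")
})

test_that("per-channel noise of an averaged transverse profile shrinks as 1/sqrt(rows)", {
  scn <- fast_scenario(noise_rel = 0.02, seed = 8)
  sim <- simulate_acquisition(scn)
  acq <- output_correct(sim$acquisition)
  rows_all <- 40:199                      # air flat
  sub <- 40:79                            # quarter of the rows
  truth <- colMeans(output_correct(
    simulate_acquisition(fast_scenario(noise_rel = 0, seed = 8))$acquisition
  )$signal[rows_all, ])
  err_all <- colMeans(acq$signal[rows_all, ]) - truth
  err_sub <- colMeans(acq$signal[sub, ]) - truth
  ratio <- sd(err_sub) / sd(err_all)
  expect_gt(ratio, 1.4)                   # expected 2
  expect_lt(ratio, 2.8)
})
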