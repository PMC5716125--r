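qa_fast <- function(scn, ...) {
  sim <- simulate_acquisition(scn)
  run_stepwedge_qa(sim$acquisition, geom = scn$geom, wedge = scn$wedge,
                   reference_pdd = make_reference_pdd(scn$mu_eff_per_mm),
                   restarts = 4L, ...)
}

test_that("a nominal delivery passes every tolerance comfortably", {
  scn <- fast_scenario(noise_rel = 0, seed = 41)
  ref_p1 <- simulate_acquisition(scn)$truth$p_proj[1]
  rep <- qa_fast(scn, reference_p1 = ref_p1, seed = 41)
  expect_true(qa_passed(rep))
  expect_false(any(rep$flags == "fail"))
  tol <- tolerance_set()
  m <- rep$metrics
  expect_lt(abs(m$couch_speed_dev_pct), 0.05 * tol$couch_speed_pct)
  expect_lt(abs(m$field_width_dev_mm), 0.05 * tol$field_width_mm)
  expect_lt(abs(m$transverse_laser_offset_mm), 0.05 * tol$laser_mm)
  expect_lt(abs(m$sagittal_laser_offset_mm), 0.05 * tol$laser_mm)
  expect_lt(abs(m$energy_dev_pct), 0.05 * tol$energy_ratio_pct)
})

test_that("an out-of-tolerance field width is flagged as fail", {
  scn <- fast_scenario(noise_rel = 0, field_width_mm = 10.4, seed = 43)
  rep <- qa_fast(scn, seed = 43)
  expect_identical(unname(rep$flags["field_width"]), "fail")
  expect_false(qa_passed(rep))
  expect_equal(rep$metrics$field_width_dev_mm, 0.4, tolerance = 0.02)
})

test_that("repeated analysis of one dataset is reproducible across restart seeds", {
  scn <- fast_scenario(noise_rel = 0.005, seed = 47)
  sim <- simulate_acquisition(scn)
  acq <- output_correct(sim$acquisition)
  tp <- extract_time_profile(acq)
  fits <- lapply(1:6, function(s)
    fit_schematic_profile(tp, scn$geom, scn$wedge, restarts = 4L, seed = s))
  devs <- vapply(fits, function(f)
    couch_speed_deviation(f, scn$geom, scn$wedge)$couch_speed_dev_pct,
    numeric(1))
  widths <- vapply(fits, function(f) field_width(f, scn$geom), numeric(1))
  expect_lt(sd(devs), 0.03)
  expect_lt(sd(widths), 0.04)
})

test_that("trend ledger appends, summarizes and matches a streaming oracle", {
  ledger <- withr::local_tempfile(fileext = ".jsonl")
  scn <- fast_scenario(noise_rel = 0, seed = 41)
  rep <- qa_fast(scn, seed = 41)
  append_trend(rep, ledger)
  one <- trend_summary(ledger)
  expect_equal(one$sd[one$metric == "couch_speed_dev_pct"], 0)
  expect_equal(one$n[1], 1L)

  # synthetic drift entries: summary must match an independent
  # streaming-mean/variance (Welford) oracle
  vals <- withr::with_seed(7, rnorm(65, mean = 0.4, sd = 0.1))
  for (v in vals) {
    fake <- rep
    fake$metrics$couch_speed_dev_pct <- v
    append_trend(fake, ledger)
  }
  s <- trend_summary(ledger)
  row <- s[s$metric == "couch_speed_dev_pct", ]
  all_vals <- c(rep$metrics$couch_speed_dev_pct, vals)
  wm <- 0; ws <- 0
  for (i in seq_along(all_vals)) {
    d <- all_vals[i] - wm
    wm <- wm + d / i
    ws <- ws + d * (all_vals[i] - wm)
  }
  expect_equal(row$mean, wm, tolerance = 1e-9)
  expect_equal(row$sd, sqrt(ws / (length(all_vals) - 1)), tolerance = 1e-9)
  expect_equal(row$n, length(all_vals))
  # the generating distribution is recovered within standard error
  expect_equal(row$mean, 0.4, tolerance = 3 * 0.1 / sqrt(65) + 0.01)

  # corrupt lines are skipped with a warning, not fatal
  cat("{broken json\n", file = ledger, append = TRUE)
  expect_warning(s2 <- trend_summary(ledger), "corrupt")
  expect_equal(s2[s2$metric == "couch_speed_dev_pct", "n"], row$n)

  # empty ledger gives an empty summary
  empty <- withr::local_tempfile(fileext = ".jsonl")
  file.create(empty)
  expect_equal(nrow(trend_summary(empty)), 0L)
})

test_that("QA reports survive a serialization round trip", {
  scn <- fast_scenario(noise_rel = 0, seed = 41)
  rep <- qa_fast(scn, seed = 41)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(rep$metrics, path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("couch_speed_dev_pct", "field_width_mm", "d20_d10",
               "sagittal_laser_offset_mm")) {
    expect_equal(back[[nm]], rep$metrics[[nm]], tolerance = 1e-12)
  }
})
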