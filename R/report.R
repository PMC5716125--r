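#' Tolerance set for QA flagging
#'
#' Default action levels: 1% couch speed (overall and per step), 1% beam
#' quality (D20/D10), 0.2 mm field width (a 0.2 mm change of the 10 mm slit
#' moves the delivered dose by about 2%), 1 mm lasers, 0.5 mm abutment.
#'
#' @param couch_speed_pct,step_length_pct,energy_ratio_pct,field_width_mm,laser_mm,abutment_mm
#'   Positive tolerance values.
#' @return An object of class `tolerance_set`.
#' @export
tolerance_set <- function(couch_speed_pct = 1.0, step_length_pct = 1.0,
                          energy_ratio_pct = 1.0, field_width_mm = 0.2,
                          laser_mm = 1.0, abutment_mm = 0.5) {
  vals <- c(couch_speed_pct = couch_speed_pct,
            step_length_pct = step_length_pct,
            energy_ratio_pct = energy_ratio_pct,
            field_width_mm = field_width_mm, laser_mm = laser_mm,
            abutment_mm = abutment_mm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    sw_error("all tolerances must be positive")
  structure(as.list(vals), class = "tolerance_set")
}

# pass / warn (above 80% of tolerance) / fail; skip for unavailable metrics.
flag_against <- function(value, tol) {
  if (!length(value) || !is.finite(value)) return("skip")
  a <- abs(value)
  if (a > tol) "fail" else if (a > 0.8 * tol) "warn" else "pass"
}

#' Run the full step-wedge QA analysis
#'
#' Orchestrates the whole pipeline on one acquisition: 10:1 down-sampling when
#' the data are still at the raw sampling rate, monitor-chamber output
#' correction, schematic time-profile fit on the centric channel (refit on the
#' detector center channel once the transverse analysis has located it), couch
#' speed and uniformity, field width, transverse laser offset (when a
#' reference `p1` is supplied), the three-center transverse report, the
#' exponential PDD with its D20/D10 ratio and, when a reference PDD is given,
#' the beam-energy consistency. Every metric is flagged against the
#' tolerances. Deterministic for a fixed `seed`.
#'
#' @param acquisition A [detector_acquisition()] or a path readable by
#'   [read_acquisition()].
#' @param geom A [machine_geometry()].
#' @param wedge A [step_wedge_spec()].
#' @param tolerances A [tolerance_set()].
#' @param reference_p1 Calibration first-transition coordinate (projections),
#'   or `NULL` to skip the transverse-laser check.
#' @param reference_pdd A [make_reference_pdd()] (or water-tank PDD with
#'   `depth_mm`/`dose_rel`), or `NULL` to report D20/D10 without comparison.
#' @param completion A [estimate_abutment_shift()] result to include, or
#'   `NULL`.
#' @param seed Seed of all fit restart randomness.
#' @param restarts Schematic-fit restarts.
#' @return An object of class `qa_report`.
#' @export
run_stepwedge_qa <- function(acquisition, geom = machine_geometry(),
                             wedge = step_wedge_spec(),
                             tolerances = tolerance_set(),
                             reference_p1 = NULL, reference_pdd = NULL,
                             completion = NULL, seed = 0L, restarts = 10L) {
  acq <- if (is.character(acquisition))
    read_acquisition(acquisition, n_channels = geom$n_channels)
  else acquisition
  stopifnot(inherits(acq, "detector_acquisition"))
  stage <- function(what, expr) {
    tryCatch(expr, stepwedge_error = function(e) {
      sw_error(sprintf("[%s] %s", what, conditionMessage(e)), class(e)[1L])
    })
  }
  if (acq$dt_s < 0.01)
    acq <- stage("downsample", downsample_10to1(acq))
  acq <- stage("output correction", output_correct(acq))
  fit <- stage("schematic fit",
               fit_schematic_profile(extract_time_profile(acq), geom, wedge,
                                     restarts = restarts, seed = seed))
  profiles <- stage("transverse extraction",
                    extract_transverse_profiles(acq, fit))
  centers <- stage("transverse fits", center_report(profiles, geom, seed = seed))
  det_ch <- as.integer(round(centers$detector_center_channel))
  if (det_ch != extract_time_profile(acq)$channel_index) {
    acq$meta$detector_center_channel <- det_ch
    fit <- stage("schematic refit on detector center channel",
                 fit_schematic_profile(extract_time_profile(acq), geom, wedge,
                                       restarts = restarts, seed = seed))
  }
  speed <- stage("couch speed", couch_speed_deviation(fit, geom, wedge))
  width <- stage("field width", field_width(fit, geom))
  pdd <- stage("PDD fit",
               fit_pdd_exponential(fit$s[1:6],
                                   c(0, water_equivalent_depths(wedge))))
  laser_mm <- if (!is.null(reference_p1))
    stage("transverse laser", transverse_laser_offset(fit, reference_p1, geom))
  else NA_real_
  energy_pct <- if (!is.null(reference_pdd))
    stage("energy consistency", energy_consistency(pdd, reference_pdd))
  else NA_real_
  sag_mm <- channels_to_isocenter_mm(
    centers$sagittal_laser_channel - centers$detector_center_channel, geom)

  metrics <- list(
    couch_speed_dev_pct = speed$couch_speed_dev_pct,
    per_step_dev_pct = speed$per_step_dev_pct,
    step_lengths_mm = speed$step_lengths_mm,
    field_width_mm = width,
    field_width_dev_mm = width - geom$field_width_mm,
    transverse_laser_offset_mm = laser_mm,
    sagittal_laser_offset_mm = sag_mm,
    d20_d10 = pdd$d20_d10,
    energy_dev_pct = energy_pct,
    detector_center_channel = centers$detector_center_channel,
    beam_center_channel = centers$beam_center_channel,
    abutment_shift_mm = if (!is.null(completion)) completion$shift_mm
    else NA_real_)
  flags <- c(
    couch_speed = flag_against(metrics$couch_speed_dev_pct,
                               tolerances$couch_speed_pct),
    step_lengths = flag_against(max(abs(metrics$per_step_dev_pct)),
                                tolerances$step_length_pct),
    field_width = flag_against(metrics$field_width_dev_mm,
                               tolerances$field_width_mm),
    transverse_laser = flag_against(metrics$transverse_laser_offset_mm,
                                    tolerances$laser_mm),
    sagittal_laser = flag_against(metrics$sagittal_laser_offset_mm,
                                  tolerances$laser_mm),
    energy = flag_against(metrics$energy_dev_pct,
                          tolerances$energy_ratio_pct),
    abutment = flag_against(metrics$abutment_shift_mm,
                            tolerances$abutment_mm))
  structure(list(metrics = metrics, flags = flags,
                 fit_quality = c(schematic_r2 = fit$r2,
                                 air_dip_r2 = centers$air_fit$r2),
                 tolerances = unclass(tolerances),
                 references = list(
                   p1 = reference_p1,
                   pdd_mu = reference_pdd$mu_eff_per_mm %||% NULL),
                 meta = list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                             machine_id = acq$meta$machine_id %||% NA,
                             procedure = acq$meta$procedure %||% NA,
                             seed = seed)),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  m <- x$metrics
  cat("stepwedge QA report", if (!is.na(x$meta$machine_id))
    paste0("(machine ", x$meta$machine_id, ")"), "\n")
  line <- function(label, value, unit, flag)
    cat(sprintf("  %-28s %8s %-4s [%s]\n", label, value, unit, flag))
  line("couch speed deviation", sprintf("%+.3f", m$couch_speed_dev_pct), "%",
       x$flags["couch_speed"])
  line("worst step-length deviation",
       sprintf("%+.3f", m$per_step_dev_pct[which.max(abs(m$per_step_dev_pct))]),
       "%", x$flags["step_lengths"])
  line("field width", sprintf("%.2f", m$field_width_mm), "mm",
       x$flags["field_width"])
  line("transverse laser offset",
       if (is.na(m$transverse_laser_offset_mm)) "n/a"
       else sprintf("%+.2f", m$transverse_laser_offset_mm), "mm",
       x$flags["transverse_laser"])
  line("sagittal laser offset", sprintf("%+.2f", m$sagittal_laser_offset_mm),
       "mm", x$flags["sagittal_laser"])
  line("D20/D10", sprintf("%.4f", m$d20_d10), "", "-")
  line("energy deviation", if (is.na(m$energy_dev_pct)) "n/a"
       else sprintf("%+.2f", m$energy_dev_pct), "%", x$flags["energy"])
  line("abutment shift", if (is.na(m$abutment_shift_mm)) "n/a"
       else sprintf("%+.1f", m$abutment_shift_mm), "mm", x$flags["abutment"])
  invisible(x)
}

#' @rdname run_stepwedge_qa
#' @param report A `qa_report`.
#' @return `qa_passed()` returns `TRUE` when no flag is `"fail"`.
#' @export
qa_passed <- function(report) !any(report$flags == "fail")

# Flatten the scalar metrics of a report for trending.
flatten_report <- function(report) {
  m <- report$metrics
  c(couch_speed_dev_pct = m$couch_speed_dev_pct,
    setNames(m$per_step_dev_pct, paste0("step", 1:5, "_dev_pct")),
    field_width_mm = m$field_width_mm,
    field_width_dev_mm = m$field_width_dev_mm,
    transverse_laser_offset_mm = m$transverse_laser_offset_mm,
    sagittal_laser_offset_mm = m$sagittal_laser_offset_mm,
    d20_d10 = m$d20_d10, energy_dev_pct = m$energy_dev_pct,
    abutment_shift_mm = m$abutment_shift_mm)
}

#' Append a QA report to a trend ledger
#'
#' The ledger is append-only JSON lines: one report per line with its
#' timestamp, machine id, flattened metrics and flags. Diff-able and free of
#' any database dependency.
#'
#' @param report A [run_stepwedge_qa()] report.
#' @param ledger_path Ledger file path (created if absent).
#' @return The ledger path, invisibly.
#' @export
append_trend <- function(report, ledger_path) {
  stopifnot(inherits(report, "qa_report"))
  entry <- list(timestamp = report$meta$timestamp,
                machine_id = report$meta$machine_id,
                metrics = as.list(flatten_report(report)),
                flags = as.list(report$flags))
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA,
                           na = "null")
  cat(line, "\n", sep = "", file = ledger_path, append = TRUE)
  invisible(ledger_path)
}

#' Summarize a trend ledger
#'
#' Per-metric mean, standard deviation, number of observations and
#' out-of-tolerance (`"fail"` flag) counts over all parseable ledger lines.
#' Corrupt lines are skipped with a warning carrying their count.
#'
#' @param ledger_path Ledger file path.
#' @return A data.frame with columns `metric`, `mean`, `sd`, `n`, `n_fail`.
#' @export
trend_summary <- function(ledger_path) {
  if (!file.exists(ledger_path) || file.size(ledger_path) == 0L)
    return(data.frame(metric = character(), mean = numeric(), sd = numeric(),
                      n = integer(), n_fail = integer()))
  lines <- readLines(ledger_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  entries <- lapply(lines, function(l)
    tryCatch(jsonlite::fromJSON(l), error = function(e) NULL))
  bad <- sum(vapply(entries, is.null, logical(1)))
  if (bad > 0)
    sw_warning(sprintf("skipped %d corrupt ledger line(s)", bad))
  entries <- entries[!vapply(entries, is.null, logical(1))]
  if (!length(entries))
    return(data.frame(metric = character(), mean = numeric(), sd = numeric(),
                      n = integer(), n_fail = integer()))
  metric_names <- unique(unlist(lapply(entries, function(e) names(e$metrics))))
  flag_map <- c(couch_speed_dev_pct = "couch_speed",
                setNames(rep("step_lengths", 5), paste0("step", 1:5, "_dev_pct")),
                field_width_dev_mm = "field_width",
                transverse_laser_offset_mm = "transverse_laser",
                sagittal_laser_offset_mm = "sagittal_laser",
                energy_dev_pct = "energy", abutment_shift_mm = "abutment")
  rows <- lapply(metric_names, function(nm) {
    vals <- vapply(entries, function(e) {
      x <- e$metrics[[nm]]
      if (is.null(x)) NA_real_ else as.numeric(x)
    }, numeric(1))
    vals <- vals[is.finite(vals)]
    fl <- flag_map[nm]
    nfail <- if (is.na(fl)) NA_integer_ else
      sum(vapply(entries, function(e)
        identical(e$flags[[fl]], "fail"), logical(1)))
    data.frame(metric = nm,
               mean = if (length(vals)) mean(vals) else NA_real_,
               sd = if (length(vals) > 1) sd(vals) else
                 if (length(vals) == 1) 0 else NA_real_,
               n = length(vals), n_fail = nfail)
  })
  do.call(rbind, rows)
}
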