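#' Induced-deviation recovery studies
#'
#' Each study replays one arm of the method-validation design: a machine
#' parameter is deliberately varied over its induced range, synthetic
#' acquisitions are generated at the stated detector noise, the full analysis
#' chain is run, and the recovered value is compared with the generating
#' truth. They are the in-silico counterparts of the commissioning
#' experiments in which couch speed (+/- 2%), slit width (9.7-11.1 mm), wedge
#' lateral position (+/- 3 mm), beam energy (D20/D10 0.499-0.536) and
#' completion mismatches (+/- 1 mm) were varied on the machine.
#'
#' @param factors Couch-speed factors (actual/nominal).
#' @param noise_rel Relative detector noise sigma.
#' @param seed Base seed; scenario `i` uses `seed * 100 + i`.
#' @param restarts Schematic-fit restarts.
#' @param geom A [machine_geometry()].
#' @param wedge A [step_wedge_spec()].
#' @return A data.frame with the induced truth, the recovered value and the
#'   recovery error per scenario.
#' @name recovery_studies
NULL

study_fit <- function(scn, geom, wedge, restarts) {
  acq <- output_correct(simulate_acquisition(scn)$acquisition)
  fit_schematic_profile(extract_time_profile(acq), geom, wedge,
                        restarts = restarts, seed = scn$seed)
}

#' @rdname recovery_studies
#' @export
recovery_study_couch_speed <- function(factors = seq(0.98, 1.02, by = 0.005),
                                       noise_rel = 0.005, seed = 1L,
                                       restarts = 10L,
                                       geom = machine_geometry(),
                                       wedge = step_wedge_spec()) {
  rows <- lapply(seq_along(factors), function(i) {
    scn <- simulation_scenario(geom, wedge, couch_speed_factor = factors[i],
                               noise_rel = noise_rel,
                               seed = seed * 100L + i)
    fit <- study_fit(scn, geom, wedge, restarts)
    est <- couch_speed_deviation(fit, geom, wedge)$couch_speed_dev_pct
    truth <- 100 * (factors[i] - 1)
    data.frame(couch_speed_factor = factors[i], true_dev_pct = truth,
               est_dev_pct = est, error_pct = est - truth)
  })
  do.call(rbind, rows)
}

#' @rdname recovery_studies
#' @param widths True slit widths, mm.
#' @export
recovery_study_field_width <- function(widths = seq(9.7, 11.1, by = 0.2),
                                       noise_rel = 0.005, seed = 1L,
                                       restarts = 10L,
                                       geom = machine_geometry(),
                                       wedge = step_wedge_spec()) {
  rows <- lapply(seq_along(widths), function(i) {
    scn <- simulation_scenario(geom, wedge, field_width_mm = widths[i],
                               noise_rel = noise_rel,
                               seed = seed * 100L + i)
    fit <- study_fit(scn, geom, wedge, restarts)
    est <- field_width(fit, geom)
    data.frame(true_width_mm = widths[i], est_width_mm = est,
               error_mm = est - widths[i])
  })
  do.call(rbind, rows)
}

#' @rdname recovery_studies
#' @param offsets Induced lateral wedge offsets at isocenter, mm.
#' @export
recovery_study_sagittal <- function(offsets = seq(-3, 3, by = 1),
                                    noise_rel = 0.005, seed = 1L,
                                    restarts = 10L,
                                    geom = machine_geometry(),
                                    wedge = step_wedge_spec()) {
  rows <- lapply(seq_along(offsets), function(i) {
    scn <- simulation_scenario(geom, wedge, lateral_offset_mm = offsets[i],
                               noise_rel = noise_rel,
                               seed = seed * 100L + i)
    acq <- output_correct(simulate_acquisition(scn)$acquisition)
    fit <- fit_schematic_profile(extract_time_profile(acq), geom, wedge,
                                 restarts = restarts, seed = scn$seed)
    centers <- center_report(extract_transverse_profiles(acq, fit), geom,
                             seed = scn$seed)
    est <- channels_to_isocenter_mm(
      centers$sagittal_laser_channel - centers$detector_center_channel, geom)
    data.frame(true_offset_mm = offsets[i], est_offset_mm = est,
               error_mm = est - offsets[i])
  })
  do.call(rbind, rows)
}

#' @rdname recovery_studies
#' @param ratios True D20/D10 ratios spanning the induced energy range.
#' @export
recovery_study_pdd <- function(ratios = seq(0.499, 0.536, length.out = 5),
                               noise_rel = 0.005, seed = 1L,
                               wedge = step_wedge_spec()) {
  depths <- c(0, water_equivalent_depths(wedge))
  rows <- lapply(seq_along(ratios), function(i) {
    mu <- -log(ratios[i]) / 100
    levels <- with_local_seed(seed * 100L + i,
                              exp(-mu * depths) *
                                (1 + noise_rel * rnorm(length(depths))))
    est <- fit_pdd_exponential(levels, depths)$d20_d10
    data.frame(true_d20_d10 = ratios[i], est_d20_d10 = est,
               rel_error_pct = 100 * (est - ratios[i]) / ratios[i])
  })
  do.call(rbind, rows)
}

#' @rdname recovery_studies
#' @param mismatches Induced abutment mismatches, mm (positive = overlap).
#' @param seeds_each Replicates per mismatch.
#' @param interrupt_fraction Fraction of the beam-on time at which delivery
#'   is interrupted (must fall on a slope).
#' @param refine Sub-projection parabolic refinement of the shift.
#' @export
recovery_study_abutment <- function(mismatches = c(-1, -0.5, 0, 0.5, 1),
                                    seeds_each = 3L, noise_rel = 0.005,
                                    seed = 1L, interrupt_fraction = 0.15,
                                    refine = FALSE,
                                    geom = machine_geometry(),
                                    wedge = step_wedge_spec()) {
  grid <- expand.grid(mismatch = mismatches, rep = seq_len(seeds_each))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    scn <- simulation_scenario(geom, wedge, noise_rel = noise_rel,
                               seed = seed * 1000L + i)
    pair <- simulate_completion_pair(scn, interrupt_fraction,
                                     induced_mismatch_mm = grid$mismatch[i])
    p1 <- extract_time_profile(output_correct(pair$first))
    p2 <- extract_time_profile(output_correct(pair$second))
    res <- estimate_abutment_shift(p1, p2, geom, refine = refine)
    data.frame(induced_mm = grid$mismatch[i], rep = grid$rep[i],
               est_mm = res$shift_mm,
               error_mm = res$shift_mm - grid$mismatch[i])
  })
  do.call(rbind, rows)
}
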