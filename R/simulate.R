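#' Simulation scenario with known ground truth
#'
#' Describes one synthetic step-wedge delivery: the machine/phantom geometry,
#' the actual (as opposed to nominal) couch speed and slit width, the
#' effective attenuation coefficient that sets the beam energy, wedge
#' placement errors emulating laser misalignment, the detector noise level and
#' the machine output ripple. Every parameter the analysis estimates is a
#' field here, so estimator recovery can be checked against exact truth.
#'
#' @param geom A [machine_geometry()].
#' @param wedge A [step_wedge_spec()].
#' @param couch_speed_factor Actual/nominal couch speed, in (0.9, 1.1).
#' @param field_width_mm Actual longitudinal slit width, mm, in (5, 15).
#' @param mu_eff_per_mm Effective attenuation per mm of water-equivalent
#'   depth; sets the PDD and thus D20/D10 (`exp(-100 * mu)`).
#' @param lateral_offset_mm Left-right wedge misplacement at isocenter
#'   (sagittal-laser surrogate), mm.
#' @param longitudinal_offset_mm In-out wedge misplacement (transverse-laser
#'   surrogate), mm; positive enters the beam late.
#' @param noise_rel Relative (multiplicative) Gaussian noise sigma per
#'   detector reading.
#' @param output_ripple `c(amplitude_rel, period_s)` sinusoidal machine
#'   output ripple applied to monitor and detector alike.
#' @param seed Integer seed; every stochastic element derives from it.
#' @param wedge_entry_mm Couch travel before the wedge front reaches the slit
#'   (40 mm puts the first transition at projection 1200 under nominal
#'   timing).
#' @param leakage_rel Closed-leaf transmission relative to the open beam.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(geom = machine_geometry(),
                                wedge = step_wedge_spec(),
                                couch_speed_factor = 1.0,
                                field_width_mm = 10.0,
                                mu_eff_per_mm = 0.00655,
                                lateral_offset_mm = 0.0,
                                longitudinal_offset_mm = 0.0,
                                noise_rel = 0.005,
                                output_ripple = c(amplitude_rel = 0.01,
                                                  period_s = 7),
                                seed = 1L,
                                wedge_entry_mm = 40,
                                leakage_rel = 0.02) {
  if (couch_speed_factor <= 0.9 || couch_speed_factor >= 1.1)
    sw_error("'couch_speed_factor' must lie in (0.9, 1.1)")
  if (field_width_mm <= 5 || field_width_mm >= 15)
    sw_error("'field_width_mm' must lie in (5, 15)")
  stopifnot_scalar_num(mu_eff_per_mm, "mu_eff_per_mm")
  if (noise_rel < 0) sw_error("'noise_rel' must be non-negative")
  if (length(seed) != 1L || !is.finite(seed))
    sw_error("a scalar integer 'seed' is required")
  structure(list(geom = geom, wedge = wedge,
                 couch_speed_factor = couch_speed_factor,
                 field_width_mm = field_width_mm,
                 mu_eff_per_mm = mu_eff_per_mm,
                 lateral_offset_mm = lateral_offset_mm,
                 longitudinal_offset_mm = longitudinal_offset_mm,
                 noise_rel = noise_rel,
                 output_ripple = c(amplitude_rel = unname(output_ripple[1]),
                                   period_s = unname(output_ripple[2])),
                 seed = as.integer(seed),
                 wedge_entry_mm = wedge_entry_mm,
                 leakage_rel = leakage_rel),
            class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat("simulation_scenario: speed factor", x$couch_speed_factor,
      "| width", x$field_width_mm, "mm | mu", x$mu_eff_per_mm, "/mm",
      "| noise", x$noise_rel, "| seed", x$seed, "\n")
  invisible(x)
}

#' Synthetic reference percentage depth dose
#'
#' An exact exponential PDD, `100 * exp(-mu * (d - 50))`, normalized to 100 at
#' 50 mm water depth. It plays the role of the water-tank commissioning PDD in
#' energy-consistency checks; being closed-form, D20/D10 is known exactly
#' (`exp(-100 * mu)`).
#'
#' @param mu_eff_per_mm Attenuation coefficient per mm of water.
#' @param depth_mm Depth grid, mm.
#' @return An object of class `reference_pdd` with fields `depth_mm`,
#'   `dose_rel`, `mu_eff_per_mm`.
#' @export
make_reference_pdd <- function(mu_eff_per_mm, depth_mm = seq(0, 350, by = 1)) {
  stopifnot_scalar_num(mu_eff_per_mm, "mu_eff_per_mm")
  structure(list(depth_mm = depth_mm,
                 dose_rel = 100 * exp(-mu_eff_per_mm * (depth_mm - 50)),
                 mu_eff_per_mm = mu_eff_per_mm),
            class = "reference_pdd")
}

#' @export
print.reference_pdd <- function(x, ...) {
  cat("reference_pdd: mu", x$mu_eff_per_mm, "/mm, D20/D10",
      round(exp(-100 * x$mu_eff_per_mm), 4), "\n")
  invisible(x)
}

# --- internal generative model -----------------------------------------------

# Transmission factors of the five wedge levels.
level_transmissions <- function(scn)
  exp(-scn$mu_eff_per_mm * water_equivalent_depths(scn$wedge))

# Slit-averaged longitudinal transmission at times t_s (seconds). The slit of
# width w integrates over the wedge boundaries; each boundary crossing is a
# linear ramp of duration w/v, reproducing the 7-flat/6-slope schematic shape.
longitudinal_transmission <- function(t_s, scn, u_shift_mm = 0) {
  v <- scn$geom$couch_speed_mm_s * scn$couch_speed_factor
  u <- v * t_s - (scn$wedge_entry_mm + scn$longitudinal_offset_mm) + u_shift_mm
  w <- scn$field_width_mm
  Tk <- level_transmissions(scn)
  Tseq <- c(1, Tk, 1)                        # air, 5 levels, trailing air
  b <- c(0, cumsum(scn$wedge$step_lengths_mm))
  out <- rep(1, length(t_s))
  for (j in seq_along(b)) {
    frac <- pmin(pmax(u - b[j], 0) / w, 1)
    out <- out + frac * (Tseq[j + 1L] - Tseq[j])
  }
  out
}

# Air transverse profile: broad modified Gaussian times the narrow central
# detector dip at the channel opposing the focus.
air_transverse_values <- function(scn) {
  nch <- scn$geom$n_channels
  x <- seq_len(nch) - 1
  xc <- (nch - 1) / 2
  broad <- modified_gaussian(x, y0 = 0.08, a = 1.0, x0 = xc, b = 150, c = 4)
  dip <- 1 - 0.05 * exp(-0.5 * ((x - xc) / 3)^2)
  broad * dip
}

# Smoothed lateral indicator of the wedge shadow (1 inside the 69.7 mm wide
# window back-projected to channels, 0 outside, 2-channel soft edges).
wedge_window_weights <- function(scn) {
  nch <- scn$geom$n_channels
  x <- seq_len(nch) - 1
  ch_mm <- channels_to_isocenter_mm(1, scn$geom)  # mm at iso per channel
  xc <- (nch - 1) / 2 + scn$lateral_offset_mm / ch_mm
  hw <- (scn$wedge$width_mm / 2) / ch_mm
  pnorm((x - (xc - hw)) / 2) * pnorm(((xc + hw) - x) / 2)
}

# Assemble the noiseless signal matrix for given per-projection longitudinal
# transmissions, then apply output factor and multiplicative noise.
assemble_signal <- function(Tl, scn, t_s, leaf_open = NULL) {
  A <- air_transverse_values(scn)
  W <- wedge_window_weights(scn)
  S <- (1 + outer(Tl - 1, W)) * rep(A, each = length(Tl))
  if (!is.null(leaf_open)) S <- S * ifelse(leaf_open, 1, scn$leakage_rel)
  ripple <- scn$output_ripple
  o <- 1 + ripple[["amplitude_rel"]] * sin(2 * pi * t_s / ripple[["period_s"]])
  S <- S * o
  if (scn$noise_rel > 0)
    S <- S * (1 + scn$noise_rel * matrix(rnorm(length(S)), nrow = nrow(S)))
  S[S < 0] <- 0
  list(signal = S, monitor = o)
}

# Exact transition projections p1..p12 and flat levels implied by a scenario.
scenario_truth <- function(scn) {
  geom <- scn$geom
  v <- geom$couch_speed_mm_s * scn$couch_speed_factor
  b <- c(0, cumsum(scn$wedge$step_lengths_mm))
  starts_s <- (scn$wedge_entry_mm + scn$longitudinal_offset_mm + b) / v
  ends_s <- starts_s + scn$field_width_mm / v
  p_s <- as.numeric(rbind(starts_s, ends_s))
  A <- air_transverse_values(scn)
  W <- wedge_window_weights(scn)
  ch <- geom$n_channels %/% 2L
  levels <- c(1, level_transmissions(scn), 1)
  s_center <- A[ch + 1L] * (1 + W[ch + 1L] * (levels - 1))
  list(p_proj = p_s / geom$dt_s, p_s = p_s,
       levels_transmission = levels, s_center_channel = s_center,
       center_channel = (geom$n_channels - 1) / 2,
       couch_speed_mm_s = v,
       d20_d10 = exp(-100 * scn$mu_eff_per_mm))
}

#' Simulate a step-wedge detector acquisition
#'
#' Generates the full `projections x channels` signal matrix of one delivery:
#' the slit beam integrates the wedge transmission as the phantom moves
#' through it (linear ramps of duration `width / speed` between seven flat
#' levels), laterally shaped by the air profile and the wedge shadow window;
#' monitor and detector share a sinusoidal output ripple and the detector adds
#' multiplicative Gaussian noise. The exact transition times and levels are
#' returned alongside as ground truth.
#'
#' @param scn A [simulation_scenario()].
#' @return A list with elements `acquisition` (a [detector_acquisition()])
#'   and `truth` (scenario parameters plus exact `p` coordinates and levels).
#' @export
simulate_acquisition <- function(scn) {
  stopifnot(inherits(scn, "simulation_scenario"))
  geom <- scn$geom
  v <- geom$couch_speed_mm_s * scn$couch_speed_factor
  needed <- scn$wedge_entry_mm + scn$longitudinal_offset_mm +
    sum(scn$wedge$step_lengths_mm) + scn$field_width_mm
  # 5% couch overtravel margin beyond the programmed travel
  if (needed > scn$wedge$travel_mm * 1.05 + 1e-9)
    sw_error(sprintf(
      "wedge travel inconsistent with acquisition: %.1f mm needed, %.1f mm programmed",
      needed, scn$wedge$travel_mm))
  if (needed / v > geom$acquisition_s)
    sw_error("wedge does not fully traverse the slit within the beam-on time")
  n <- round(geom$acquisition_s / geom$dt_s)
  t_s <- (seq_len(n) - 1) * geom$dt_s
  acq <- with_local_seed(scn$seed, {
    parts <- assemble_signal(longitudinal_transmission(t_s, scn), scn, t_s)
    detector_acquisition(parts$signal, parts$monitor, geom$dt_s,
                         meta = list(procedure = "stepwedge",
                                     synthetic = TRUE, seed = scn$seed,
                                     couch_speed_mm_s = v))
  })
  truth <- c(scenario_truth(scn),
             list(scenario = scn, synthetic_dip = "stand-in notch (amplitude 0.05, sigma 3 channels); real detector dip shape unpublished"))
  list(acquisition = acq, truth = truth)
}

#' Simulate an interrupted delivery and its completion
#'
#' The first acquisition stops at `interrupt_fraction` of the beam-on time,
#' which must fall on a slope of the time profile. The completion starts with
#' a 10 s closed-leaf flat segment (leakage only), then resumes delivery with
#' the couch start position offset by `induced_mismatch_mm` (positive =
#' overlap, negative = gap) and includes the brief all-leaves-closed transient
#' dip seen in regenerated procedures shortly after resumption.
#'
#' @param scn A [simulation_scenario()].
#' @param interrupt_fraction Fraction of the beam-on time at which delivery is
#'   interrupted.
#' @param induced_mismatch_mm Abutment mismatch, |mm| <= 2.
#' @param preamble_s Closed-leaf stabilization time of the completion, s.
#' @return A list with `first`, `second` (both [detector_acquisition()]) and
#'   `truth` (interrupt row, mismatch, scenario truth).
#' @export
simulate_completion_pair <- function(scn, interrupt_fraction = 0.15,
                                     induced_mismatch_mm = 0,
                                     preamble_s = 10) {
  stopifnot(inherits(scn, "simulation_scenario"))
  if (abs(induced_mismatch_mm) > 2)
    sw_error("|induced_mismatch_mm| must be <= 2 mm")
  geom <- scn$geom
  v <- geom$couch_speed_mm_s * scn$couch_speed_factor
  n <- round(geom$acquisition_s / geom$dt_s)
  n_int <- floor(interrupt_fraction * n)
  t_int <- n_int * geom$dt_s
  u_int <- v * t_int - (scn$wedge_entry_mm + scn$longitudinal_offset_mm)
  b <- c(0, cumsum(scn$wedge$step_lengths_mm))
  on_slope <- any(u_int - b > 1e-9 & u_int - b < scn$field_width_mm - 1e-9)
  if (!on_slope)
    sw_error("must interrupt on slope: the chosen time lies on a flat segment")

  t1 <- (seq_len(n_int) - 1) * geom$dt_s
  first <- with_local_seed(scn$seed, {
    parts <- assemble_signal(longitudinal_transmission(t1, scn), scn, t1)
    detector_acquisition(parts$signal, parts$monitor, geom$dt_s,
                         meta = list(procedure = "stepwedge_interrupted",
                                     synthetic = TRUE, seed = scn$seed))
  })

  n_pre <- round(preamble_s / geom$dt_s)
  n2 <- n_pre + (n - n_int)
  t2 <- (seq_len(n2) - 1) * geom$dt_s
  tau <- t_int + (t2 - preamble_s)          # delivery time of each row
  leaf_open <- t2 >= preamble_s
  # transient all-leaves-closed dip 0.5 s after resumption (3 projections)
  dip_rows <- t2 >= preamble_s + 0.5 & t2 < preamble_s + 0.5 + 3 * geom$dt_s
  leaf_open[dip_rows] <- FALSE
  Tl <- longitudinal_transmission(tau, scn, u_shift_mm = -induced_mismatch_mm)
  Tl[!leaf_open] <- 1                        # shadow irrelevant when closed
  second <- with_local_seed(scn$seed + 1L, {
    parts <- assemble_signal(Tl, scn, t2, leaf_open = leaf_open)
    detector_acquisition(parts$signal, parts$monitor, geom$dt_s,
                         meta = list(procedure = "stepwedge_completion",
                                     synthetic = TRUE, seed = scn$seed + 1L,
                                     preamble_s = preamble_s))
  })
  list(first = first, second = second,
       truth = list(n_interrupt = n_int, t_interrupt_s = t_int,
                    induced_mismatch_mm = induced_mismatch_mm,
                    preamble_projections = n_pre,
                    scenario = scenario_truth(scn)))
}
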