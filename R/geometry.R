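#' Machine geometry and timing constants
#'
#' Bundles the fixed geometry of a tomotherapy ring relevant to step-wedge
#' analysis: source-axis distance (SAD), source-detector distance (SDD), MVCT
#' detector curvature, channel layout, projection timing and the nominal
#' delivery parameters of the QA procedure. The SAD/SDD ratio back-projects
#' detector-plane distances to isocenter scale; the nominal couch speed and
#' field width define the expected time-profile shape.
#'
#' Two timing conventions coexist in practice: a 30 Hz sampling rate
#' (`dt_s = 1/30`, giving 9000 projections in the 300 s acquisition) and a
#' rounded 30 ms per projection (`dt_s = 0.030`, used when reproducing
#' historically printed millimetre conversions). `dt_s` is an explicit field so
#' an analysis uses exactly one convention throughout.
#'
#' @param sad_cm Source-axis distance, cm.
#' @param sdd_cm Source-detector distance at the detector center, cm.
#' @param detector_radius_cm Radius of curvature of the MVCT detector arc, cm.
#' @param n_channels Number of detector channels (even).
#' @param channel_pitch_mm Physical lateral width of one channel, mm.
#' @param channel_length_mm Longitudinal cavity length of one channel, mm.
#' @param dt_s Time per projection, s.
#' @param couch_speed_mm_s Nominal couch speed, mm/s.
#' @param field_width_mm Nominal longitudinal slit width at isocenter, mm.
#' @param acquisition_s Beam-on time of the procedure, s.
#' @return An object of class `machine_geometry`.
#' @examples
#' geom <- machine_geometry()
#' channels_to_isocenter_mm(2.6, geom)
#' @export
machine_geometry <- function(sad_cm = 85, sdd_cm = 142,
                             detector_radius_cm = 110,
                             n_channels = 640L, channel_pitch_mm = 1.2,
                             channel_length_mm = 42, dt_s = 1 / 30,
                             couch_speed_mm_s = 1.0, field_width_mm = 10.0,
                             acquisition_s = 300) {
  for (nm in c("sad_cm", "sdd_cm", "detector_radius_cm", "channel_pitch_mm",
               "channel_length_mm", "dt_s", "couch_speed_mm_s",
               "field_width_mm", "acquisition_s"))
    stopifnot_scalar_num(get(nm), nm)
  n_channels <- as.integer(n_channels)
  if (n_channels <= 0L || n_channels %% 2L != 0L)
    sw_error("'n_channels' must be a positive even integer")
  if (sad_cm >= sdd_cm)
    sw_error("'sad_cm' must be smaller than 'sdd_cm'")
  structure(list(sad_cm = sad_cm, sdd_cm = sdd_cm,
                 detector_radius_cm = detector_radius_cm,
                 n_channels = n_channels,
                 channel_pitch_mm = channel_pitch_mm,
                 channel_length_mm = channel_length_mm, dt_s = dt_s,
                 couch_speed_mm_s = couch_speed_mm_s,
                 field_width_mm = field_width_mm,
                 acquisition_s = acquisition_s),
            class = "machine_geometry")
}

#' @export
print.machine_geometry <- function(x, ...) {
  cat("machine_geometry: SAD", x$sad_cm, "cm, SDD", x$sdd_cm, "cm,",
      x$n_channels, "channels x", x$channel_pitch_mm, "mm\n")
  cat("  dt", signif(x$dt_s, 6), "s | couch", x$couch_speed_mm_s,
      "mm/s | field width", x$field_width_mm, "mm | beam-on",
      x$acquisition_s, "s\n")
  invisible(x)
}

#' Step-wedge phantom specification
#'
#' Dimensions and material of the five-level aluminum staircase phantom. The
#' five step thicknesses, multiplied by the bulk density (water density taken
#' as 1), give the water-equivalent depths probed by the beam.
#'
#' @param step_lengths_mm Longitudinal lengths of the five steps, mm.
#' @param step_thicknesses_mm Thicknesses of the five steps, mm (strictly
#'   increasing).
#' @param density_g_cm3 Bulk density of the wedge material, g/cm3.
#' @param width_mm Lateral width of the wedge, mm.
#' @param travel_mm Programmed couch travel of the procedure, mm.
#' @return An object of class `step_wedge_spec`.
#' @examples
#' water_equivalent_depths(step_wedge_spec())
#' @export
step_wedge_spec <- function(step_lengths_mm = c(29.9, 30.0, 30.0, 30.0, 30.1),
                            step_thicknesses_mm = c(19.5, 39.0, 58.5, 78.0, 97.6),
                            density_g_cm3 = 2.69, width_mm = 69.7,
                            travel_mm = 200) {
  if (length(step_lengths_mm) != 5L || length(step_thicknesses_mm) != 5L)
    sw_error("five step lengths and five thicknesses are required")
  if (any(!is.finite(step_lengths_mm)) || any(step_lengths_mm <= 0))
    sw_error("step lengths must be finite and positive")
  if (any(diff(step_thicknesses_mm) <= 0))
    sw_error("step thicknesses must be strictly increasing")
  if (abs(sum(step_lengths_mm) - 150) > 1e-9)
    sw_error("step lengths must sum to 150 mm")
  stopifnot_scalar_num(density_g_cm3, "density_g_cm3")
  if (density_g_cm3 <= 1)
    sw_error("'density_g_cm3' must exceed 1 (denser than water)")
  stopifnot_scalar_num(width_mm, "width_mm")
  stopifnot_scalar_num(travel_mm, "travel_mm")
  structure(list(step_lengths_mm = step_lengths_mm,
                 step_thicknesses_mm = step_thicknesses_mm,
                 density_g_cm3 = density_g_cm3, width_mm = width_mm,
                 travel_mm = travel_mm),
            class = "step_wedge_spec")
}

#' @export
print.step_wedge_spec <- function(x, ...) {
  cat("step_wedge_spec:", sum(x$step_lengths_mm), "mm long,", x$width_mm,
      "mm wide, density", x$density_g_cm3, "g/cm3\n")
  cat("  thicknesses (mm):", paste(x$step_thicknesses_mm, collapse = ", "), "\n")
  cat("  water-equivalent depths (mm):",
      paste(round(water_equivalent_depths(x), 1), collapse = ", "), "\n")
  invisible(x)
}

#' Back-project a channel distance to isocenter millimetres
#'
#' A lateral distance of `delta_channels` detector channels corresponds to
#' `delta_channels * channel_pitch_mm * sad_cm / sdd_cm` millimetres at
#' isocenter level. Linear; the sign is preserved.
#'
#' @param delta_channels Signed distance in channels.
#' @param geom A [machine_geometry()].
#' @return Millimetres at isocenter.
#' @export
channels_to_isocenter_mm <- function(delta_channels, geom) {
  delta_channels * geom$channel_pitch_mm * geom$sad_cm / geom$sdd_cm
}

#' Convert a projection count to couch travel
#'
#' `n_projections * dt_s * couch_speed_mm_s` millimetres of couch travel.
#' The inverse is [mm_to_projections()].
#'
#' @param n_projections Number (possibly fractional) of projections.
#' @param dt_s Time per projection, s.
#' @param couch_speed_mm_s Couch speed, mm/s.
#' @return Millimetres of couch travel.
#' @export
projections_to_mm <- function(n_projections, dt_s, couch_speed_mm_s) {
  stopifnot_scalar_num(dt_s, "dt_s")
  stopifnot_scalar_num(couch_speed_mm_s, "couch_speed_mm_s")
  n_projections * dt_s * couch_speed_mm_s
}

#' @rdname projections_to_mm
#' @param mm Millimetres of couch travel.
#' @export
mm_to_projections <- function(mm, dt_s, couch_speed_mm_s) {
  stopifnot_scalar_num(dt_s, "dt_s")
  stopifnot_scalar_num(couch_speed_mm_s, "couch_speed_mm_s")
  mm / (dt_s * couch_speed_mm_s)
}

#' Water-equivalent depths of the wedge steps
#'
#' Each aluminum thickness is scaled by the bulk density ratio (water density
#' 1), the scaling implied by the phantom's published depth table. No
#' energy-dependent stopping-power correction is applied.
#'
#' @param wedge A [step_wedge_spec()].
#' @return Five depths in mm of water.
#' @export
water_equivalent_depths <- function(wedge) {
  wedge$step_thicknesses_mm * wedge$density_g_cm3
}

#' Read or write a machine configuration file
#'
#' `machine.json` holds every [machine_geometry()] and [step_wedge_spec()]
#' field under keys `geometry` and `wedge`. Fields are validated by the
#' constructors on read; unknown keys are rejected.
#'
#' @param path File path.
#' @return `read_machine_config()` returns `list(geometry, wedge)`.
#' @export
read_machine_config <- function(path) {
  if (!file.exists(path)) sw_error(paste("config file not found:", path),
                                   "stepwedge_parse_error")
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    sw_error(paste("malformed config JSON:", conditionMessage(e)),
                             "stepwedge_parse_error"))
  for (part in c("geometry", "wedge"))
    if (is.null(cfg[[part]]))
      sw_error(sprintf("config is missing the '%s' section", part),
               "stepwedge_parse_error")
  check_known <- function(given, allowed, part) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      sw_error(sprintf("unknown %s field(s): %s", part,
                       paste(bad, collapse = ", ")), "stepwedge_parse_error")
  }
  check_known(cfg$geometry, names(formals(machine_geometry)), "geometry")
  check_known(cfg$wedge, names(formals(step_wedge_spec)), "wedge")
  list(geometry = do.call(machine_geometry, cfg$geometry),
       wedge = do.call(step_wedge_spec, cfg$wedge))
}

#' @rdname read_machine_config
#' @param geom A [machine_geometry()].
#' @param wedge A [step_wedge_spec()].
#' @export
write_machine_config <- function(geom, wedge, path) {
  jsonlite::write_json(list(geometry = unclass(geom), wedge = unclass(wedge)),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
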