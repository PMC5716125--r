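# Shared fixtures, built in code.
#
# The "fast rig" shortens a delivery for unit tests by running the couch at a
# higher nominal speed over a longer programmed travel: same wedge, same
# 30 Hz timing, 1500 instead of 9000 projections. Full-scale (nominal 1 mm/s,
# 300 s) scenarios are reserved for the acceptance-level checks.

fast_geom <- function(...) {
  machine_geometry(couch_speed_mm_s = 5, acquisition_s = 50, ...)
}

fast_wedge <- function() step_wedge_spec(travel_mm = 250)

fast_scenario <- function(...) {
  simulation_scenario(geom = fast_geom(), wedge = fast_wedge(), ...)
}

# Simulate, output-correct and fit in one call (fast rig by default).
fitted_rig <- function(scn = fast_scenario(noise_rel = 0, seed = 1),
                       restarts = 4L) {
  sim <- simulate_acquisition(scn)
  acq <- output_correct(sim$acquisition)
  tp <- extract_time_profile(acq)
  list(sim = sim, acq = acq, profile = tp,
       fit = fit_schematic_profile(tp, scn$geom, scn$wedge,
                                   restarts = restarts, seed = scn$seed))
}

# Small random acquisition for IO and arithmetic tests.
tiny_acquisition <- function(n = 40L, nch = 8L, seed = 99L, dt_s = 1 / 30) {
  withr::with_seed(seed, {
    detector_acquisition(matrix(runif(n * nch, 0.1, 2), n, nch),
                         monitor = runif(n, 0.9, 1.1), dt_s = dt_s,
                         meta = list(machine_id = "unitA", note = "fixture"))
  })
}
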