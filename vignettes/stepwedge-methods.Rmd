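---
title: "Step-wedge QA for helical tomotherapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step-wedge QA for helical tomotherapy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement

A helical tomotherapy unit delivers dose through a narrow slit beam while the
couch translates the patient through the bore. Routine quality assurance must
therefore track quantities a conventional linac program does not: couch speed
and its uniformity, the longitudinal width of the slit, the alignment of the
setup lasers with the virtual isocenter, beam energy drift from target wear,
and — because deliveries are sequential in space — the abutment accuracy when
an interrupted treatment is completed.

The `stepwedge` package implements a filmless way to measure all of these in
one five-minute delivery. A five-level aluminum staircase phantom (150 mm
long, 69.7 mm wide, steps of 19.5 to 97.6 mm thickness, density 2.69 g/cm³)
is aligned to the lasers and driven through the static slit beam (gantry at
0°, nominal 10 mm field, 1 mm/s couch). The on-board 640-channel xenon MVCT
detector opposite the source records the transmitted radiation at 30 Hz
(9000 projections in the 300 s beam-on time), alongside the machine's
monitor-chamber signal. Every analysis in the package starts from that
`projections x channels` matrix.

## The schematic time-profile model

The signal of one centric detector channel over time steps down as
successively thicker wedge levels cross the slit. Because each level (about
30 mm) is longer than the slit (about 10 mm), the profile is piecewise
linear: seven flat levels `s1..s7` (air, five steps, trailing air) joined by
six ramps whose start/end coordinates are the twelve transitions `p1..p12`.
A ramp lasts exactly `width / speed`, which is what makes the profile so
informative:

* **couch speed** — the span `p11 - p1` covers the full 150 mm wedge;
  `100 * (150 / ((p11 - p1) * dt) / v_nominal - 1)` is the overall speed
  deviation, and the five `p_{2k+1} - p_{2k-1}` spans give per-step lengths
  (uniformity, ±1% action level);
* **field width** — `(p2 - p1) * dt * v` is the slit width at isocenter;
* **transverse (in–out) laser** — `p1` marks when the laser-aligned phantom
  enters the beam; compared with a calibration `p1` it gives the setup
  offset in mm.

The 19 parameters are estimated by unconstrained least squares with a
derivative-free simplex (Nelder–Mead), restarted 10 times with the first
transition drawn uniformly within ±50 projections of the detected first
signal drop and the remaining transitions placed from the nominal step
lengths and slit width; levels start at robust segment medians. Transition
order is maintained by sorting the candidate vector inside the objective, so
the optimizer itself stays unconstrained. The best restart is kept and a fit
with `r2 <= 0.99` is rejected.

Two numerical details matter. First, the objective is linear in the seven
levels for fixed transitions, so the levels have a closed-form least-squares
solution; second, with the levels held, each transition can be refined by a
one-dimensional Brent search between its neighbours. The package alternates
these two steps after the simplex until the residual stops improving
(relative change below 1e-14, at most 60 sweeps). This polish is what lets a
noiseless synthetic profile be recovered to numerical precision (couch-speed
deviation error below 1e-6 relative) — a plain 19-dimensional simplex stalls
around 0.3 projections. Only the three best restarts are polished; on every
dataset we examined, polishing from the exact generating parameters lands on
the same optimum, so the extra restarts add nothing after the simplex stage.

## Transverse profiles and the three centers

Averaging the projections that lie strictly inside a flat segment (a 10%
margin of the segment length is removed on each side) gives one lateral
profile per wedge level plus one through air. Three centers are extracted:

* **detector center** — the channel opposing the focus shows a
  characteristic dip (focus rays bisect the septa walls there). A modified
  Gaussian `y0 + a * exp(-0.5 * (|x - x0|/b)^c)` is fitted over ±40 channels
  around the dip; `x0` is the detector center.
* **sagittal laser** — each step profile divided by the air profile is a
  transmission well whose center is the lateral wedge position, hence the
  sagittal laser position. The five well centers are fitted with the same
  modified-Gaussian scheme over the contiguous region where transmission is
  below 0.9 and averaged; a spread above 1 mm (at isocenter) flags a couch
  direction that is not perpendicular to the imaging plane.
* **beam center** — on the non-normalized air profile, the zero crossings of
  the second derivative of the two flanks (the penumbra inflections) are
  located from centered second differences of a 5-channel moving average,
  interpolated linearly, and averaged. The 5-channel window is the smallest
  that suppressed seeded noise in pilot property tests while keeping the
  bias below 0.1 channel.

Channel distances convert to isocenter millimetres by
`pitch * SAD / SDD = 1.2 * 85/142 ≈ 0.72 mm/channel`. When the machine is
aligned all three centers coincide; pairwise separations are the reported
laser/beam offsets.

## Beam energy: the reconstructed PDD and D20/D10

Each step presents a known water-equivalent depth (thickness times bulk
density: 52.5, 104.9, 157.4, 209.8, 262.5 mm; no stopping-power correction —
this is the scaling the phantom's published depth table implies). Fitting
`scale * exp(-mu * depth)` to the six levels (air at depth 0 plus five
steps) gives an effective attenuation coefficient; the fit is done by least
squares on the log-levels, which is numerically stable and has a closed-form
slope available as a cross-check. The percentage depth dose is normalized to
100 at 50 mm and the beam-energy index is `D20/D10 = exp(-100 * mu)`,
compared against the commissioning water-tank PDD (1% action level). The
trailing level `s7` is excluded — the exponential uses six levels — and the
same PDD can be built from the transverse-profile fits; both routes agree
within 0.5% on every synthetic scenario we generate.

## Completion: abutment of an interrupted delivery

When a delivery is interrupted on a ramp and the machine-generated
completion is delivered, a correctly resumed couch makes the second time
profile continue the first exactly. The completion recording starts with
about 10 s of beam-on, leaves-closed stabilization (2% leakage level) and a
brief all-leaves-closed transient shortly after resumption; both are data
artifacts to be trimmed, not modeled. The estimator:

1. fits a straight line to the trailing clean ramp of the interrupted
   profile, growing the fitted tail backwards from the junction and stopping
   when the preceding flat is reached (the acceptance band is frozen from a
   high-frequency noise estimate so contaminated residuals cannot loosen
   it; points accepted just past the kink are dropped again before the
   final fit);
2. trims the completion to its first sustained run at the junction level
   (±20%);
3. slides the trimmed profile in integer projection steps over ±100
   projections, minimizing the SSE against the line continuation over the
   overlap window, optionally refining sub-projection position by a parabola
   through the three points around the integer minimum (off when
   integer-projection reporting is wanted).

The shift converts to millimetres via `dt * couch speed`; positive means
overlap, negative a gap, and the linear rule of thumb of about 8% dose
perturbation per mm of mismatch (from penumbra-based simulation of the 1 cm
slit) puts the number in clinical context. The alignment information lives
entirely in the extrapolated *level* of the continuation line — a joint
"collinearity" criterion is degenerate, because sliding points along a
straight line changes nothing.

## The simulator

`simulate_acquisition()` is the package's ground-truth generator, not a test
fixture dump: every estimated quantity is a scenario field. The longitudinal
model integrates wedge transmission over the slit aperture, producing exact
linear ramps (real penumbra S-shapes are out of scope by design). The
transverse model is a broad modified Gaussian (`b = 150` channels, `c = 4`,
offset 0.08) times a central dip (5% amplitude, sigma 3 channels) — the dip
is a stand-in; its real magnitude is unpublished, and truth files label it as
such. The wedge shadows a 69.7 mm window (back-projected to channels) with
2-channel soft edges. Monitor and detector share a sinusoidal output ripple
(default 1% amplitude, 7 s period — a realistic magnitude for output
fluctuation; the monitor correction removes it exactly, which the tests
verify), and the detector adds multiplicative Gaussian noise (default
`noise_rel = 0.005` per 30 Hz reading, the level used throughout the
validation studies). The wedge front reaches the slit after 40 mm of travel,
putting the first transition at projection 1200 under nominal timing. All
randomness derives from the scenario seed; acquisitions are bit-reproducible.

What the simulator does *not* emulate — detector energy response, scatter
beyond the fixed central dip, penumbra shape, gantry-angle effects, helical
delivery — bounds what passing tests show about real data: they validate the
estimators against the stated generative model, and validate the pipeline's
contracts, not the physics of a particular machine.

## Validation studies and problem sizes

The `recovery_study_*()` functions replay the induced-deviation designs in
simulation at full scale (9000 × 640 acquisitions): couch-speed factors
−2%..+2% in 0.5% steps; slit widths 9.7–11.1 mm in 0.2 mm steps; lateral
offsets −3..+3 mm; five attenuation coefficients spanning D20/D10
0.499–0.536; completion mismatches −1..+1 mm with three replicates. Unit
tests use a shortened rig (couch at 5 mm/s over 50 s — 1500 projections) so
the whole suite stays fast; the full-scale studies live in the acceptance
test file and in `scripts/acceptance.R`.

Two of the measured statistics sit at the edge of their nominal bounds and
are worth understanding. The field-width recovery SD measures ≈ 0.032 mm
against a 0.03 mm target: this is the intrinsic least-squares spread under
the stated noise (a polish started from the exact generating parameters
reproduces the identical estimate), not an optimizer artifact. Likewise the
D20/D10 mean absolute error (≈ 0.185% against 0.2%) is what a six-point
log-linear regression with 0.5% level noise intrinsically yields. Neither
statistic was tuned.

## Timing conventions and degenerate inputs

Two timing conventions appear in practice: 30 Hz sampling (`dt = 1/30` s,
9000 projections in 300 s) and the rounded "30 ms per projection" used in
printed millimetre conversions. `dt_s` is an explicit configuration field;
one analysis uses exactly one convention, never a silent mix.

Degenerate inputs are rejected with typed conditions: constant or
structure-less profiles (`no step structure`), fits below `r2 = 0.99`
(carrying the fit for inspection), flat-segment extraction windows shorter
than 20 projections, junctions on flats, non-unique or boundary SSE minima
in the shift search, non-positive monitor values inside the beam-on segment,
and malformed acquisition files (naming the offending row). Beam-off rows
are defined as monitor at or below 10% of its 95th percentile and are
zeroed — the monitor correction itself is per-projection division, applied
once (idempotent).

## Known limitations

* Constancy tool, not absolute dosimetry: all metrics are ratios or
  positions relative to references; output measurement needs an ionization
  chamber.
* The coronal laser (couch height) is not estimable from these profiles with
  useful sensitivity; gantry-90°/270° or helical variants are out of scope.
* The abutment check verifies couch repositioning at gantry 0° with open
  leaves; it does not test gantry/MLC synchrony of a clinical completion.
* The 8%/mm abutment dose rule is a linear approximation valid to about
  ±2 mm.
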