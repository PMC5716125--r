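#' Modified Gaussian peak model
#'
#' `y0 + a * exp(-0.5 * (|x - x0| / b)^c)`: offset, amplitude (negative for a
#' dip), center, width and shape exponent. With `c = 2` this is a Gaussian;
#' larger `c` flattens the top towards a box profile.
#'
#' @param x Independent variable (channel coordinate).
#' @param y0,a,x0,b,c Model parameters; `b > 0`, `c > 0`.
#' @return Model values.
#' @export
modified_gaussian <- function(x, y0, a, x0, b, c) {
  y0 + a * exp(-0.5 * (abs(x - x0) / b)^c)
}

#' Fit a modified Gaussian to a transverse profile window
#'
#' Least squares by the same multi-start simplex scheme as the time-profile
#' fit: ten restarts with the center jittered +/- 10 channels around a
#' depth-weighted initial estimate, Nelder-Mead on the summed squared
#' residual, best restart kept, rejection when `r2 <= 0.99`. Works for peaks
#' (air profile) and dips/wells (detector dip, normalized step profiles)
#' alike; the orientation is detected from the data.
#'
#' @param profile A `transverse_profile` (or plain numeric vector of channel
#'   values).
#' @param window Integer range of 0-based channel indices to fit (at least 20
#'   points).
#' @param restarts Number of random starts.
#' @param seed Seed of the restart randomness.
#' @param r2_min Minimum accepted coefficient of determination.
#' @return An object of class `modified_gaussian_fit` with fields `y0`, `a`,
#'   `x0`, `b`, `c`, `r2`, `sse`, `window`.
#' @export
fit_modified_gaussian <- function(profile, window, restarts = 10L, seed = 0L,
                                  r2_min = 0.99) {
  values <- if (inherits(profile, "transverse_profile")) profile$values else profile
  window <- as.integer(round(window))
  window <- seq(min(window), max(window))
  if (min(window) < 0L || max(window) >= length(values))
    sw_error("fit window outside the profile")
  if (length(window) < 20L)
    sw_error("fit window must contain at least 20 points")
  x <- as.numeric(window)
  y <- values[window + 1L]
  edge <- c(head(y, 2L), tail(y, 2L))
  # dip if the window interior runs below its edges, peak otherwise
  third <- length(y) %/% 3L
  dip <- mean(y[(third + 1L):(2L * third)]) < mean(edge)
  y0_init <- if (dip) max(edge) else min(edge)
  a_init <- if (dip) min(y) - y0_init else max(y) - y0_init
  depth <- abs(y - y0_init)
  x0_init <- sum(x * depth) / sum(depth)
  half <- which(depth > 0.5 * max(depth))
  b_init <- max((x[max(half)] - x[min(half)]) / 2, 1)
  obj <- function(par) {
    yy <- modified_gaussian(x, par[1], par[2], par[3], abs(par[4]),
                            abs(par[5]))
    if (any(!is.finite(yy))) return(.Machine$double.xmax)
    sum((y - yy)^2)
  }
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(restarts)) {
      start <- c(y0_init, a_init, x0_init + runif(1, -10, 10), b_init,
                 if (r %% 2L == 0L) 2 else 4)
      res <- optim(start, obj, method = "Nelder-Mead",
                   control = list(maxit = 5000L, reltol = 1e-12))
      res <- optim(res$par, obj, method = "Nelder-Mead",
                   control = list(maxit = 5000L, reltol = 1e-12))
      if (is.null(best) || res$value < best$value) best <- res
    }
  })
  par <- best$par
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - best$value / sst
  fit <- structure(list(y0 = par[1], a = par[2], x0 = par[3], b = abs(par[4]),
                        c = abs(par[5]), r2 = r2, sse = best$value,
                        window = range(window)),
                   class = "modified_gaussian_fit")
  if (!(r2 > r2_min))
    sw_error(sprintf("modified-Gaussian fit rejected on all restarts: r2 = %.4f",
                     r2), "stepwedge_fit_error", data = fit)
  fit
}

#' @export
print.modified_gaussian_fit <- function(x, ...) {
  cat(sprintf("modified_gaussian_fit: x0 %.3f, a %.4g, y0 %.4g, b %.3f, c %.3f, r2 %.5f\n",
              x$x0, x$a, x$y0, x$b, x$c, x$r2))
  invisible(x)
}

#' Normalize a step profile to the air profile
#'
#' Pointwise ratio of a step transverse profile to the air profile, isolating
#' the wedge's lateral attenuation window from the beam shape and detector
#' response.
#'
#' @param step_profile,air_profile `transverse_profile` objects of equal
#'   length.
#' @return A normalized `transverse_profile`.
#' @export
normalize_to_air <- function(step_profile, air_profile) {
  sv <- step_profile$values
  av <- air_profile$values
  if (length(sv) != length(av))
    sw_error("profiles must have the same number of channels")
  if (any(av <= 0))
    sw_error("zero or negative air value: cannot normalize")
  structure(list(values = sv / av,
                 label = step_profile$label,
                 projections_averaged = step_profile$projections_averaged,
                 normalized = TRUE),
            class = "transverse_profile")
}

# Window of the central detector dip: +/- 40 channels around the narrow
# minimum of the air profile relative to its slowly varying background (wide
# running median, which a ~10-channel notch cannot survive).
dip_window <- function(air_profile, halfwidth = 40L) {
  v <- air_profile$values
  n <- length(v)
  bg <- stats::runmed(v, 31L)
  ratio <- v / pmax(bg, .Machine$double.eps)
  central <- seq(n %/% 3L + 1L, 2L * (n %/% 3L))
  c0 <- central[which.min(ratio[central])]    # R index of dip bottom
  lo <- max(0L, c0 - 1L - halfwidth)
  hi <- min(n - 1L, c0 - 1L + halfwidth)
  c(lo, hi)
}

#' Fit the central detector dip of the air profile
#'
#' The channel opposing the focus sees the septa walls edge-on and records a
#' characteristic dip; a modified-Gaussian fit over +/- 40 channels around the
#' dip locates it precisely.
#'
#' @param air_profile Non-normalized air `transverse_profile`.
#' @param ... Passed to [fit_modified_gaussian()].
#' @return A `modified_gaussian_fit` of the dip region.
#' @export
fit_air_dip <- function(air_profile, ...) {
  w <- dip_window(air_profile)
  fit_modified_gaussian(air_profile, seq(w[1], w[2]), ...)
}

#' Detector center channel
#'
#' The center of the dip-region fit on the non-normalized air profile: the
#' channel for which the focus rays bisect the detector septa, i.e. the
#' channel opposing the focus.
#'
#' @param air_fit A [fit_air_dip()] result.
#' @return Channel coordinate (0-based, fractional).
#' @export
detector_center_channel <- function(air_fit) {
  stopifnot(inherits(air_fit, "modified_gaussian_fit"))
  air_fit$x0
}

#' Sagittal laser position from the normalized step profiles
#'
#' The centers of the five normalized transverse profiles all estimate the
#' lateral wedge position, hence the sagittal laser position the wedge was
#' aligned to. Their mean is returned; a spread (max - min, back-projected to
#' isocenter) above 1 mm raises a couch-walk warning, since it indicates the
#' couch direction is not perpendicular to the imaging plane.
#'
#' @param normalized_fits List of five `modified_gaussian_fit`s of the
#'   normalized step profiles.
#' @param geom A [machine_geometry()].
#' @return A list with `channel` (mean center), `per_step_channels`,
#'   `spread_mm` and `couch_walk_flag`.
#' @export
sagittal_laser_channel <- function(normalized_fits, geom = machine_geometry()) {
  x0s <- vapply(normalized_fits, function(f) f$x0, numeric(1))
  spread_mm <- abs(channels_to_isocenter_mm(max(x0s) - min(x0s), geom))
  flag <- spread_mm > 1
  if (flag)
    sw_warning(sprintf(
      "step centers spread %.2f mm at isocenter: couch direction may not be perpendicular to the imaging plane",
      spread_mm), "stepwedge_couch_walk_warning")
  list(channel = mean(x0s), per_step_channels = x0s,
       spread_mm = spread_mm, couch_walk_flag = flag)
}

#' Radiation beam center from flank inflections
#'
#' The non-normalized air profile is smoothed with a centered moving average,
#' central second differences are formed, and on each flank the zero crossing
#' of the second derivative (the inflection of the penumbra) is located by
#' linear interpolation. The beam center is the midpoint of the left and
#' right crossings; unlike the fitted centers it makes no symmetry assumption
#' about the profile interior.
#'
#' @param air_profile Non-normalized air `transverse_profile`.
#' @param smooth_window Moving-average window, channels (odd).
#' @return Channel coordinate of the beam center (0-based, fractional).
#' @export
beam_center_second_derivative <- function(air_profile, smooth_window = 5L) {
  v <- air_profile$values
  n <- length(v)
  k <- as.integer(smooth_window)
  if (k < 3L || k %% 2L == 0L) sw_error("'smooth_window' must be odd and >= 3")
  ys <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2L))
  ok <- which(!is.na(ys))
  peak <- ok[which.max(ys[ok])]
  base <- min(ys[ok])
  half <- base + 0.5 * (max(ys[ok]) - base)
  d2 <- c(NA, diff(ys, differences = 2L), NA)   # d2[i] ~ y''(channel i-1)
  find_crossing <- function(side) {
    idx <- if (side == "left") ok[ok < peak] else rev(ok[ok > peak])
    hx <- idx[which(ys[idx] <= half)]
    if (!length(hx))
      sw_error(sprintf("no %s flank found", side), "stepwedge_fit_error")
    target <- hx[which.min(abs(hx - peak))]     # half-max channel on this flank
    cand <- which(!is.na(d2[-n]) & !is.na(d2[-1]) &
                    d2[-n] * d2[-1] < 0)         # sign change between i, i+1
    if (!length(cand))
      sw_error(sprintf("no second-derivative sign change on the %s flank", side),
               "stepwedge_fit_error")
    i <- cand[which.min(abs(cand - target))]
    if (abs(i - target) > 25)
      sw_error(sprintf("no second-derivative zero near the %s flank", side),
               "stepwedge_fit_error")
    (i - 1) + d2[i] / (d2[i] - d2[i + 1L])      # 0-based crossing coordinate
  }
  (find_crossing("left") + find_crossing("right")) / 2
}

#' Exponential percentage-depth-dose fit to step levels
#'
#' Fits `scale * exp(-mu * depth)` to the six (depth, level) points -- air at
#' depth 0 plus the five water-equivalent step depths -- by least squares on
#' the log values. The PDD is `100 * exp(-mu * (d - 50))`, normalized to 100
#' at 50 mm depth, and the beam-energy index is `D20/D10 = exp(-100 * mu)`.
#'
#' @param levels Six positive, strictly decreasing signal levels (`s1..s6`).
#' @param depths Six depths in mm of water (0 plus
#'   [water_equivalent_depths()]).
#' @return An object of class `pdd_fit` with `mu_eff_per_mm`, `scale`,
#'   `d20_d10`.
#' @export
fit_pdd_exponential <- function(levels,
                                depths = c(0, water_equivalent_depths(step_wedge_spec()))) {
  if (length(levels) != length(depths))
    sw_error("'levels' and 'depths' must have the same length")
  if (any(levels <= 0))
    sw_error("levels must be positive")
  if (any(diff(levels) >= 0))
    sw_error("levels must be strictly decreasing with depth")
  fit <- lm(log(levels) ~ depths)
  mu <- -unname(coef(fit)[2])
  ly <- log(levels)
  structure(list(mu_eff_per_mm = mu, scale = exp(unname(coef(fit)[1])),
                 d20_d10 = exp(-100 * mu),
                 r2 = 1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)),
            class = "pdd_fit")
}

#' @export
print.pdd_fit <- function(x, ...) {
  cat(sprintf("pdd_fit: mu %.6f /mm, D20/D10 %.4f\n", x$mu_eff_per_mm,
              x$d20_d10))
  invisible(x)
}

#' @rdname fit_pdd_exponential
#' @param fit A `pdd_fit`.
#' @param depth_mm Depths at which to evaluate the PDD.
#' @return `pdd_value()` returns PDD values normalized to 100 at 50 mm.
#' @export
pdd_value <- function(fit, depth_mm) {
  100 * exp(-fit$mu_eff_per_mm * (depth_mm - 50))
}

#' Beam energy consistency against a reference PDD
#'
#' Percent difference of the measured D20/D10 ratio from the ratio of the
#' reference (water-tank) PDD at 200 and 100 mm. Routine tolerance for beam
#' quality variations: 1%.
#'
#' @param pdd A [fit_pdd_exponential()] result.
#' @param reference A [make_reference_pdd()] (any object with `depth_mm` and
#'   `dose_rel` covering 100-200 mm).
#' @return Percent difference, `100 * (measured/reference - 1)`.
#' @export
energy_consistency <- function(pdd, reference) {
  if (min(reference$depth_mm) > 100 || max(reference$depth_mm) < 200)
    sw_error("reference PDD must cover depths 100-200 mm")
  at <- function(d) stats::approx(reference$depth_mm, reference$dose_rel,
                                  xout = d)$y
  ratio_ref <- at(200) / at(100)
  100 * (pdd$d20_d10 / ratio_ref - 1)
}

#' Three-center report of a transverse analysis
#'
#' Runs the full transverse pipeline on the six extracted profiles: detector
#' center (air-dip fit), sagittal laser (mean center of the five normalized
#' step profiles) and radiation beam center (flank inflections), with all
#' pairwise separations back-projected to isocenter. When the system is
#' perfectly aligned all three coincide.
#'
#' @param profiles List returned by [extract_transverse_profiles()].
#' @param geom A [machine_geometry()].
#' @param seed Seed of the fit restart randomness.
#' @return An object of class `center_report`.
#' @export
center_report <- function(profiles, geom = machine_geometry(), seed = 0L) {
  air <- profiles[["air"]]
  air_fit <- fit_air_dip(air, seed = seed)
  det <- detector_center_channel(air_fit)
  norm_fits <- lapply(profiles[paste0("step", 1:5)], function(p) {
    np <- normalize_to_air(p, air)
    fit_modified_gaussian(np, transmission_window(np$values), seed = seed)
  })
  sag <- sagittal_laser_channel(norm_fits, geom)
  beam <- beam_center_second_derivative(air)
  off <- function(d) channels_to_isocenter_mm(d, geom)
  structure(list(detector_center_channel = det,
                 sagittal_laser_channel = sag$channel,
                 beam_center_channel = beam,
                 per_step_channels = sag$per_step_channels,
                 spread_mm = sag$spread_mm,
                 couch_walk_flag = sag$couch_walk_flag,
                 pairwise_offsets_mm = c(
                   sagittal_vs_detector = off(sag$channel - det),
                   sagittal_vs_beam = off(sag$channel - beam),
                   detector_vs_beam = off(det - beam)),
                 air_fit = air_fit, normalized_fits = norm_fits),
            class = "center_report")
}

#' @export
print.center_report <- function(x, ...) {
  cat(sprintf("center_report: detector %.2f | sagittal %.2f | beam %.2f (channels)\n",
              x$detector_center_channel, x$sagittal_laser_channel,
              x$beam_center_channel))
  cat("  pairwise offsets (mm at iso):",
      paste(sprintf("%s %.2f", names(x$pairwise_offsets_mm),
                    x$pairwise_offsets_mm), collapse = ", "), "\n")
  invisible(x)
}

# Largest contiguous run of channels with transmission below 0.9: the fit
# window of a normalized step profile.
transmission_window <- function(values, threshold = 0.9) {
  below <- values < threshold
  if (!any(below)) sw_error("no wedge shadow found in normalized profile",
                            "stepwedge_fit_error")
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)[which.max(r$lengths[r$values])]
  seq(starts[i] - 1L, ends[i] - 1L)           # 0-based
}
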