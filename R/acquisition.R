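#' Detector acquisition container
#'
#' One step-wedge delivery as seen by the MVCT detector: a `projections x
#' channels` matrix of non-negative readings, the per-projection monitor
#' chamber signal used for output correction, the projection time and
#' free-form metadata.
#'
#' @param signal Numeric matrix, `n_projections x n_channels`, non-negative.
#' @param monitor Numeric vector of length `n_projections`.
#' @param dt_s Time per projection, s.
#' @param meta Named list of metadata (machine id, date, procedure, seed, ...).
#' @return An object of class `detector_acquisition`.
#' @export
detector_acquisition <- function(signal, monitor, dt_s, meta = list()) {
  if (!is.matrix(signal) || !is.numeric(signal))
    sw_error("'signal' must be a numeric matrix")
  if (length(monitor) != nrow(signal))
    sw_error("monitor length must equal the number of projections")
  if (any(!is.finite(signal)))
    sw_error("signal contains non-finite values")
  if (any(signal < 0)) {
    row <- which(apply(signal < 0, 1L, any))[1L]
    sw_error(sprintf("negative detector signal in projection row %d (0-based %d)",
                     row, row - 1L), "stepwedge_parse_error")
  }
  stopifnot_scalar_num(dt_s, "dt_s")
  structure(list(signal = signal, monitor = as.numeric(monitor), dt_s = dt_s,
                 meta = meta),
            class = "detector_acquisition")
}

#' @export
print.detector_acquisition <- function(x, ...) {
  cat("detector_acquisition:", nrow(x$signal), "projections x",
      ncol(x$signal), "channels, dt", signif(x$dt_s, 6), "s",
      if (isTRUE(x$meta$output_corrected)) "(output-corrected)" else "", "\n")
  invisible(x)
}

#' @export
dim.detector_acquisition <- function(x) dim(x$signal)

acquisition_meta_path <- function(path)
  paste0(tools::file_path_sans_ext(path), ".meta.json")

#' Read or write a detector acquisition
#'
#' The open on-disk dialect is a UTF-8 CSV with header
#' `projection,monitor,ch0000..chNNNN` plus a JSON sidecar
#' `<name>.meta.json` carrying `dt_s` and free-form metadata. Values are
#' written with 17 significant digits so a write/read cycle is lossless.
#'
#' @param path CSV file path; the sidecar path is derived from it.
#' @param n_channels Expected channel count (header is checked against it).
#' @return `read_acquisition()` returns a [detector_acquisition()].
#' @export
read_acquisition <- function(path, n_channels = 640L) {
  if (!file.exists(path))
    sw_error(paste("acquisition file not found:", path), "stepwedge_parse_error")
  if (file.size(path) == 0L)
    sw_error("empty acquisition file", "stepwedge_parse_error")
  dt <- tryCatch(
    data.table::fread(path, sep = ",", header = TRUE, fill = FALSE,
                      data.table = FALSE, showProgress = FALSE),
    error = function(e)
      sw_error(paste("malformed acquisition CSV:", conditionMessage(e)),
               "stepwedge_parse_error"))
  if (nrow(dt) == 0L)
    sw_error("acquisition file has a header but no projections",
             "stepwedge_parse_error")
  nch <- ncol(dt) - 2L
  expected <- c("projection", "monitor", sprintf("ch%04d", seq_len(max(nch, 0L)) - 1L))
  if (nch != n_channels)
    sw_error(sprintf("channel count mismatch: file has %d channel columns, expected %d",
                     nch, n_channels), "stepwedge_parse_error")
  if (!identical(names(dt), expected))
    sw_error("malformed header: expected 'projection,monitor,ch0000..'",
             "stepwedge_parse_error")
  if (anyNA(dt)) {
    row <- which(apply(is.na(dt), 1L, any))[1L]
    sw_error(sprintf("non-numeric or missing value in data row %d", row),
             "stepwedge_parse_error")
  }
  mpath <- acquisition_meta_path(path)
  if (!file.exists(mpath))
    sw_error(paste("missing metadata sidecar:", mpath), "stepwedge_parse_error")
  side <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (is.null(side$dt_s))
    sw_error("sidecar lacks 'dt_s'", "stepwedge_parse_error")
  sig <- as.matrix(dt[, -(1:2), drop = FALSE])
  dimnames(sig) <- NULL
  detector_acquisition(sig, dt$monitor, side$dt_s,
                       meta = side$meta %||% list())
}

#' @rdname read_acquisition
#' @param acq A [detector_acquisition()].
#' @export
write_acquisition <- function(acq, path) {
  stopifnot(inherits(acq, "detector_acquisition"))
  n <- nrow(acq$signal)
  header <- paste(c("projection", "monitor",
                    sprintf("ch%04d", seq_len(ncol(acq$signal)) - 1L)),
                  collapse = ",")
  body <- cbind(seq_len(n) - 1L, acq$monitor, acq$signal)
  txt <- matrix(formatC(body, digits = 17, format = "g"), nrow = n)
  txt[, 1L] <- as.character(seq_len(n) - 1L)
  lines <- c(header, do.call(paste, c(split(txt, col(txt)), sep = ",")))
  writeLines(lines, path)
  jsonlite::write_json(list(dt_s = acq$dt_s, meta = acq$meta),
                       acquisition_meta_path(path),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Down-sample an acquisition 10:1 by block averaging
#'
#' Raw system signals are sampled at 300 Hz and reduced to 30 Hz by averaging
#' ten consecutive projections (signal and monitor alike); `dt_s` is
#' multiplied by 10. A trailing remainder of fewer than 10 rows is dropped
#' with a warning.
#'
#' @param acq A [detector_acquisition()].
#' @return A down-sampled [detector_acquisition()].
#' @export
downsample_10to1 <- function(acq) {
  stopifnot(inherits(acq, "detector_acquisition"))
  n <- nrow(acq$signal)
  if (n < 10L)
    sw_error("fewer than 10 projections: cannot down-sample 10:1")
  keep <- (n %/% 10L) * 10L
  if (keep < n)
    sw_warning(sprintf("dropping %d trailing projection(s) not filling a block",
                       n - keep))
  grp <- rep(seq_len(keep %/% 10L), each = 10L)
  sig <- rowsum(acq$signal[seq_len(keep), , drop = FALSE], grp,
                reorder = FALSE) / 10
  mon <- as.numeric(rowsum(acq$monitor[seq_len(keep)], grp,
                           reorder = FALSE)) / 10
  dimnames(sig) <- NULL
  detector_acquisition(sig, mon, acq$dt_s * 10, meta = acq$meta)
}

# Projections considered beam-on: monitor above 10% of its 95th percentile.
beam_on_mask <- function(monitor) {
  monitor > 0.10 * quantile(monitor, 0.95, names = FALSE, type = 7)
}

#' Correct detector signals for machine output fluctuations
#'
#' Each beam-on projection row is scaled by `mean(monitor) / monitor[i]`, the
#' per-projection output correction measured by the machine's monitor chamber.
#' Beam-off rows (monitor at or below 10% of its 95th percentile) are zeroed;
#' the monitor trace is replaced by its beam-on mean. The operation is
#' idempotent.
#'
#' @param acq A [detector_acquisition()].
#' @return A corrected [detector_acquisition()] with
#'   `meta$output_corrected = TRUE`.
#' @export
output_correct <- function(acq) {
  stopifnot(inherits(acq, "detector_acquisition"))
  on <- beam_on_mask(acq$monitor)
  if (!any(on))
    sw_error("no beam-on projections detected (monitor always near zero)")
  span <- seq(which(on)[1L], tail(which(on), 1L))
  if (any(acq$monitor[span] <= 0))
    sw_error("non-positive monitor value inside the beam-on segment")
  m <- mean(acq$monitor[on])
  sig <- acq$signal
  sig[on, ] <- sig[on, , drop = FALSE] * (m / acq$monitor[on])
  sig[!on, ] <- 0
  mon <- ifelse(on, m, 0)
  meta <- acq$meta
  meta$output_corrected <- TRUE
  detector_acquisition(sig, mon, acq$dt_s, meta = meta)
}

#' Time profile of one detector channel
#'
#' Extracts the output-corrected signal course over time of a single MVCT
#' channel, the input of the schematic step-wedge profile fit. The default
#' channel is the detector center channel recorded in the acquisition metadata
#' when a transverse analysis has provided one, falling back to
#' `n_channels / 2`.
#'
#' @param acq An output-corrected [detector_acquisition()].
#' @param channel_index 0-based channel index, or `NULL` for the default.
#' @return An object of class `time_profile` with fields `values`,
#'   `channel_index`, `dt_s`.
#' @export
extract_time_profile <- function(acq, channel_index = NULL) {
  stopifnot(inherits(acq, "detector_acquisition"))
  if (!isTRUE(acq$meta$output_corrected))
    sw_error("acquisition must be output-corrected first (see output_correct())")
  nch <- ncol(acq$signal)
  if (is.null(channel_index))
    channel_index <- as.integer(round(acq$meta$detector_center_channel %||%
                                        (nch %/% 2L)))
  channel_index <- as.integer(channel_index)
  if (channel_index < 0L || channel_index >= nch)
    sw_error(sprintf("channel index %d out of range [0, %d)", channel_index, nch))
  if (nrow(acq$signal) <= 100L)
    sw_error("time profile too short (need > 100 projections)")
  structure(list(values = acq$signal[, channel_index + 1L],
                 channel_index = channel_index, dt_s = acq$dt_s),
            class = "time_profile")
}

#' @export
print.time_profile <- function(x, ...) {
  cat("time_profile: channel", x$channel_index, "-", length(x$values),
      "projections, dt", signif(x$dt_s, 6), "s\n")
  invisible(x)
}

#' Transverse detector profiles under each flat profile segment
#'
#' For the air segment (before the first transition `p1`) and each wedge step
#' (between consecutive slope ends/starts), the projections strictly inside
#' the flat interval -- after removing a 10% margin of the segment length on
#' each side -- are averaged per channel. The result is the lateral beam
#' profile seen through air and through each of the five constant-thickness
#' levels.
#'
#' @param acq An output-corrected [detector_acquisition()].
#' @param fit A [fit_schematic_profile()] result supplying `p1..p12`.
#' @param margin_frac Margin removed from each end of a flat segment.
#' @return A list of 6 `transverse_profile` objects, labels
#'   `"air", "step1".."step5"`.
#' @export
extract_transverse_profiles <- function(acq, fit, margin_frac = 0.10) {
  stopifnot(inherits(acq, "detector_acquisition"))
  if (!isTRUE(acq$meta$output_corrected))
    sw_error("acquisition must be output-corrected first (see output_correct())")
  p <- fit$p
  n <- nrow(acq$signal)
  # Flat k occupies [p_{2k-2}, p_{2k-1}] (0-based projection coordinates),
  # with flat 1 running from the first beam-on row to p1.
  lo <- c(0, p[c(2, 4, 6, 8, 10)])
  hi <- c(p[c(1, 3, 5, 7, 9, 11)])
  labels <- c("air", paste0("step", 1:5))
  out <- vector("list", 6L)
  for (k in seq_len(6L)) {
    len <- hi[k] - lo[k]
    a <- ceiling(lo[k] + margin_frac * len)
    b <- floor(hi[k] - margin_frac * len)
    if (b - a + 1 < 20)
      sw_error(sprintf("segment too short: flat '%s' has %d projections inside margins",
                       labels[k], max(0, b - a + 1)))
    rows <- seq(a, b) + 1L            # 0-based coords -> R rows
    rows <- rows[rows >= 1L & rows <= n]
    out[[k]] <- structure(
      list(values = colMeans(acq$signal[rows, , drop = FALSE]),
           label = labels[k], projections_averaged = c(a, b),
           normalized = FALSE),
      class = "transverse_profile")
  }
  names(out) <- labels
  out
}

#' @export
print.transverse_profile <- function(x, ...) {
  cat("transverse_profile:", x$label,
      if (isTRUE(x$normalized)) "(normalized)" else "",
      "- rows", x$projections_averaged[1], "..", x$projections_averaged[2], "\n")
  invisible(x)
}
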