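#' Velocity-time curve container
#'
#' One cardiac cycle of maximal lumen velocity versus time at one aortic
#' sampling site, on a uniform time grid starting at the R-wave trigger.
#'
#' @param time numeric vector, ms from the R-wave trigger; strictly
#'   increasing, uniformly spaced (within 1e-6 relative), at least 10
#'   samples, last sample not beyond `rr_interval`.
#' @param velocity numeric vector, cm/s, same length as `time`.
#' @param rr_interval RR interval in ms.
#' @param site_label free-text label of the sampling site.
#' @return An object of class `velocity_time_curve`: a list with fields
#'   `time`, `velocity`, `rr_interval`, `site_label` and the derived
#'   `sampling_interval` (ms).
#' @export
velocity_time_curve <- function(time, velocity, rr_interval,
                                site_label = "") {
  if (!is.numeric(time) || !is.numeric(velocity))
    config_error("time/velocity", "must be numeric vectors")
  n <- length(time)
  if (n < 10L)
    config_error("time", "curve must contain at least 10 samples")
  if (length(velocity) != n)
    config_error("velocity", "length must match `time`")
  if (anyNA(time) || anyNA(velocity))
    config_error("time/velocity", "missing values are not allowed")
  dt <- diff(time)
  if (any(dt <= 0))
    config_error("time", "must be strictly increasing")
  if ((max(dt) - min(dt)) > 1e-6 * mean(dt))
    config_error("time", "sampling must be uniform (1e-6 relative)")
  assert_scalar_number(rr_interval, "rr_interval", lower = 0,
                       strict_lower = TRUE)
  if (time[n] > rr_interval + 1e-9)
    config_error("time", "last sample exceeds rr_interval")
  structure(
    list(time = as.numeric(time), velocity = as.numeric(velocity),
         rr_interval = as.numeric(rr_interval),
         site_label = as.character(site_label),
         sampling_interval = mean(dt)),
    class = "velocity_time_curve")
}

#' @export
print.velocity_time_curve <- function(x, ...) {
  cat(sprintf(
    "<velocity_time_curve> %s: %d samples @ %.3f ms, RR %.1f ms, v in [%.1f, %.1f] cm/s\n",
    if (nzchar(x$site_label)) x$site_label else "(unlabelled)",
    length(x$time), x$sampling_interval, x$rr_interval,
    min(x$velocity), max(x$velocity)))
  invisible(x)
}

#' Maximal-velocity curve from a velocity image series
#'
#' Reduces a per-frame 2D velocity series to the maximal velocity over a
#' lumen mask, one value per reconstructed phase, reproducing the
#' maximal-velocity-time curves used for wave-propagation analysis.
#'
#' @param series numeric 3D array `[rows, cols, frames]` of velocities
#'   (cm/s), one frame per reconstructed phase.
#' @param mask logical matrix `[rows, cols]` marking lumen pixels, or a
#'   two-column integer matrix of (row, col) indices.
#' @param rr_interval RR interval in ms.
#' @param sampling_interval frame spacing in ms; defaults to
#'   `rr_interval / nframes` so that `time[i] = (i-1) * sampling_interval`.
#' @param site_label passed to [velocity_time_curve()].
#' @return A [velocity_time_curve()].
#' @export
max_velocity_curve <- function(series, mask, rr_interval,
                               sampling_interval = NULL, site_label = "") {
  if (!is.array(series) || length(dim(series)) != 3L)
    config_error("series", "must be a 3D array [rows, cols, frames]")
  d <- dim(series)
  if (is.matrix(mask) && is.numeric(mask) && ncol(mask) == 2L) {
    idx <- mask
  } else if (is.logical(mask) && is.matrix(mask)) {
    if (!all(dim(mask) == d[1:2]))
      config_error("mask", "mask dimensions exceed image bounds")
    idx <- which(mask, arr.ind = TRUE)
  } else config_error("mask", "must be a logical matrix or (row, col) index matrix")
  if (nrow(idx) == 0L)
    config_error("mask", "lumen mask is empty")
  if (any(idx[, 1] < 1L | idx[, 1] > d[1] | idx[, 2] < 1L | idx[, 2] > d[2]))
    config_error("mask", "mask exceeds image bounds")
  nfr <- d[3]
  dt <- sampling_interval %||% (rr_interval / nfr)
  flat <- matrix(series, nrow = d[1] * d[2], ncol = nfr)
  lin <- (idx[, 2] - 1L) * d[1] + idx[, 1]
  v <- apply(flat[lin, , drop = FALSE], 2, max)
  velocity_time_curve(time = (seq_len(nfr) - 1) * dt, velocity = v,
                      rr_interval = rr_interval, site_label = site_label)
}
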