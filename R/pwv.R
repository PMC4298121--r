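#' Diastolic flow level of a velocity-time curve
#'
#' The horizontal line modelling diastolic flow: the arithmetic mean of all
#' samples in the final 250 ms of the cycle, i.e. samples with
#' `time > rr_interval - 250`.
#'
#' @param curve a [velocity_time_curve()].
#' @param window window length in ms (default 250).
#' @return Diastolic level in cm/s.
#' @export
diastolic_level <- function(curve, window = 250) {
  stopifnot(inherits(curve, "velocity_time_curve"))
  n <- length(curve$time)
  if ((curve$time[n] - curve$time[1]) < window)
    stop_vascmr(sprintf("curve spans less than %g ms", window),
                "vascmr_resolution_error")
  sel <- curve$time > (curve$rr_interval - window)
  mean(curve$velocity[sel])
}

#' Linear fit of the systolic upslope
#'
#' Identifies the systolic peak (global maximum; earliest sample on ties),
#' walks backward from the peak to the last sample at or below the diastolic
#' baseline (the wave foot), and fits ordinary least squares of velocity on
#' time through all upslope samples whose velocity lies within 20 to 80
#' percent (inclusive) of the range `peak - baseline` above the baseline.
#' Upslope samples are those strictly between the foot sample and the peak
#' sample. If the curve never returns to the baseline before the peak, the
#' search window starts at the first sample and the result is flagged
#' (`foot_fallback = TRUE`).
#'
#' @param curve a [velocity_time_curve()].
#' @param baseline diastolic level in cm/s (see [diastolic_level()]).
#' @param band lower/upper band fractions of the range (default `c(0.2, 0.8)`).
#' @return A list of class `onset_fit` (partial: no `onset_time` yet) with
#'   `baseline_level`, `upslope_slope`, `upslope_intercept`,
#'   `n_upslope_points`, `foot_fallback`.
#' @export
upslope_fit <- function(curve, baseline, band = c(0.2, 0.8)) {
  stopifnot(inherits(curve, "velocity_time_curve"))
  assert_scalar_number(baseline, "baseline")
  v <- curve$velocity; t <- curve$time
  ipk <- which.max(v)              # earliest global maximum
  vpk <- v[ipk]
  if (vpk <= baseline)
    stop_vascmr("no systolic peak above the diastolic baseline",
                "vascmr_fit_error")
  below <- which(v[seq_len(ipk - 1L)] <= baseline)
  foot_fallback <- length(below) == 0L
  ifoot <- if (foot_fallback) 1L else max(below)
  seg <- seq.int(ifoot + 1L, ipk - 1L)
  seg <- seg[seg >= 1L & seg < ipk]
  R <- vpk - baseline
  lo <- baseline + band[1] * R
  hi <- baseline + band[2] * R
  sel <- seg[v[seg] >= lo & v[seg] <= hi]
  if (length(sel) < 2L)
    stop_vascmr(sprintf(
      "only %d samples in the %g-%g%% upslope band; temporal resolution insufficient",
      length(sel), 100 * band[1], 100 * band[2]), "vascmr_resolution_error")
  x <- t[sel]; y <- v[sel]
  xm <- mean(x); ym <- mean(y)
  slope <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  if (!is.finite(slope) || slope <= 0)
    stop_vascmr("fitted upslope is not positive", "vascmr_fit_error")
  structure(list(baseline_level = baseline, upslope_slope = slope,
                 upslope_intercept = ym - slope * xm, onset_time = NA_real_,
                 n_upslope_points = length(sel),
                 foot_fallback = foot_fallback),
            class = "onset_fit")
}

#' Wave-foot onset time of a flow curve
#'
#' The onset of the wave front: the intersection of the horizontal diastolic
#' line (mean over the final 250 ms) with the regression line through the
#' 20-80 percent systolic upslope band. The intersection is analytic, so the
#' onset has sub-sample resolution.
#'
#' @inheritParams upslope_fit
#' @param window diastolic averaging window, ms.
#' @return An `onset_fit` with `onset_time` filled in (ms).
#' @export
wave_onset <- function(curve, window = 250, band = c(0.2, 0.8)) {
  base <- diastolic_level(curve, window = window)
  fit <- upslope_fit(curve, base, band = band)
  onset <- (base - fit$upslope_intercept) / fit$upslope_slope
  if (onset < 0 || onset > curve$rr_interval)
    stop_vascmr(sprintf("computed onset %.2f ms outside [0, %.0f]",
                        onset, curve$rr_interval),
                "vascmr_fit_error", onset = onset)
  fit$onset_time <- onset
  fit
}

#' @export
print.onset_fit <- function(x, ...) {
  cat(sprintf("<onset_fit> onset %.2f ms; baseline %.2f cm/s; slope %.3f cm/s/ms (%d pts%s)\n",
              x$onset_time, x$baseline_level, x$upslope_slope,
              x$n_upslope_points,
              if (isTRUE(x$foot_fallback)) ", foot fallback" else ""))
  invisible(x)
}

#' Transit time between two sampling sites
#'
#' Difference of the wave-foot onsets, distal minus proximal. A
#' non-positive transit time signals mislabelled sites or a failed onset
#' fit and raises a propagation error.
#'
#' @param proximal_curve,distal_curve [velocity_time_curve()] objects.
#' @param ... passed to [wave_onset()].
#' @return Transit time in ms (> 0).
#' @export
transit_time <- function(proximal_curve, distal_curve, ...) {
  dt <- wave_onset(distal_curve, ...)$onset_time -
    wave_onset(proximal_curve, ...)$onset_time
  if (dt <= 0)
    stop_vascmr(sprintf(
      "non-positive transit time (%.3f ms): check site labelling / onset fits", dt),
      "vascmr_propagation_error", transit_time = dt)
  dt
}

#' Aortic path length from centerline polylines
#'
#' Sum of Euclidean segment lengths along an ordered centerline polyline;
#' when several repeated tracings are supplied, their lengths are averaged
#' (the standard duplicate-and-average protocol).
#'
#' @param polylines a numeric matrix of ordered (x, y) or (x, y, z) points
#'   in mm, or a list of such matrices (repeated measurements).
#' @return Mean path length in mm.
#' @export
aortic_path_length <- function(polylines) {
  if (is.matrix(polylines) || is.data.frame(polylines))
    polylines <- list(polylines)
  if (!is.list(polylines) || length(polylines) < 1L)
    config_error("polylines", "need at least one centerline polyline")
  lens <- vapply(polylines, function(p) {
    p <- as.matrix(p)
    if (!is.numeric(p) || nrow(p) < 2L || !ncol(p) %in% c(2L, 3L))
      config_error("polylines",
                   "each polyline needs >= 2 points with 2 or 3 coordinates")
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
  mean(lens)
}

#' Pulse wave velocity from path length and transit time
#'
#' `pwv = delta_x / delta_t`; with `delta_x` in mm and `delta_t` in ms this
#' is already m/s (no conversion factor).
#'
#' @param delta_x path length, mm (> 0).
#' @param delta_t transit time, ms (> 0).
#' @param site_pair free-text label, e.g. `"thoracic-abdominal"`.
#' @param sampling_interval optional frame spacing in ms; when given and
#'   `delta_t` is below it, the result is flagged `sub_sample_transit`
#'   (transit shorter than one frame: the estimate is unreliable and
#'   diverges as the true transit goes to zero).
#' @return An object of class `pwv_result` with `path_length`,
#'   `transit_time`, `pwv` (m/s), `site_pair`, `sub_sample_transit`.
#' @export
pulse_wave_velocity <- function(delta_x, delta_t, site_pair = "",
                                sampling_interval = NULL) {
  assert_scalar_number(delta_x, "delta_x", lower = 0, strict_lower = TRUE)
  assert_scalar_number(delta_t, "delta_t", lower = 0, strict_lower = TRUE)
  flag <- !is.null(sampling_interval) && delta_t < sampling_interval
  structure(list(path_length = delta_x, transit_time = delta_t,
                 pwv = delta_x / delta_t, site_pair = site_pair,
                 sub_sample_transit = flag),
            class = "pwv_result")
}

#' @export
print.pwv_result <- function(x, ...) {
  cat(sprintf("<pwv_result> %s: dx %.1f mm / dt %.3f ms = %.2f m/s%s\n",
              if (nzchar(x$site_pair)) x$site_pair else "(unlabelled)",
              x$path_length, x$transit_time, x$pwv,
              if (isTRUE(x$sub_sample_transit)) " [sub-sample transit]" else ""))
  invisible(x)
}

#' Transit-time PWV from a curve pair
#'
#' Convenience composition: onsets, transit time, and division by the path
#' length, with the sub-sample-transit quality flag taken from the proximal
#' curve's sampling interval.
#'
#' @param proximal_curve,distal_curve [velocity_time_curve()] objects.
#' @param path_length centerline path length in mm, or a polyline / list of
#'   polylines accepted by [aortic_path_length()].
#' @param site_pair label for the result.
#' @param ... passed to [wave_onset()].
#' @return A `pwv_result`.
#' @export
estimate_pwv <- function(proximal_curve, distal_curve, path_length,
                         site_pair = "", ...) {
  dx <- if (is.numeric(path_length) && length(path_length) == 1L)
    path_length else aortic_path_length(path_length)
  dt <- transit_time(proximal_curve, distal_curve, ...)
  pulse_wave_velocity(dx, dt, site_pair = site_pair,
                      sampling_interval = proximal_curve$sampling_interval)
}
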