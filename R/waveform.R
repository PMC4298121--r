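#' Parameters of a synthetic systolic flow waveform
#'
#' The synthetic waveform family is piecewise: a flat diastolic baseline up
#' to `onset_time`, a linear systolic upstroke of slope `upslope` up to
#' `peak_velocity`, then an exponential decay back toward the baseline with
#' time constant `decay_time_constant`. The family is deliberately simple so
#' the true wave foot (`onset_time`) is analytically known, which is what
#' makes transit-time ground truth possible.
#'
#' @param baseline_velocity diastolic baseline, cm/s.
#' @param onset_time wave-foot time, ms from the R-wave.
#' @param upslope systolic upstroke slope, cm/s per ms.
#' @param peak_velocity systolic peak, cm/s; must exceed the baseline.
#' @param decay_time_constant exponential decay time constant, ms.
#' @param rr_interval RR interval, ms.
#' @param sampling_interval frame spacing, ms (default 9.8, i.e. 2xTR of a
#'   retrospectively gated gradient-echo acquisition).
#' @param noise_sd additive Gaussian noise SD, cm/s (>= 0).
#' @param seed optional integer seed for the noise draw.
#' @return A validated list of class `waveform_params`.
#' @export
waveform_params <- function(baseline_velocity = 5, onset_time = 100,
                            upslope = 0.75, peak_velocity = 65,
                            decay_time_constant = 100, rr_interval = 980,
                            sampling_interval = 9.8, noise_sd = 0,
                            seed = NULL) {
  assert_scalar_number(baseline_velocity, "baseline_velocity")
  assert_scalar_number(onset_time, "onset_time", lower = 0)
  assert_scalar_number(upslope, "upslope", lower = 0, strict_lower = TRUE)
  assert_scalar_number(peak_velocity, "peak_velocity")
  assert_scalar_number(decay_time_constant, "decay_time_constant",
                       lower = 0, strict_lower = TRUE)
  assert_scalar_number(rr_interval, "rr_interval", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(sampling_interval, "sampling_interval", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (peak_velocity <= baseline_velocity)
    config_error("peak_velocity", "must exceed baseline_velocity")
  rise <- (peak_velocity - baseline_velocity) / upslope
  if (onset_time + rise >= rr_interval)
    config_error("onset_time",
                 "onset_time + rise duration must be below rr_interval")
  structure(list(baseline_velocity = baseline_velocity,
                 onset_time = onset_time, upslope = upslope,
                 peak_velocity = peak_velocity,
                 decay_time_constant = decay_time_constant,
                 rr_interval = rr_interval,
                 sampling_interval = sampling_interval,
                 noise_sd = noise_sd, seed = seed),
            class = "waveform_params")
}

# noiseless waveform evaluated at arbitrary times
waveform_value <- function(params, t) {
  p <- params
  rise <- (p$peak_velocity - p$baseline_velocity) / p$upslope
  t_peak <- p$onset_time + rise
  v <- rep(p$baseline_velocity, length(t))
  up <- t >= p$onset_time & t <= t_peak
  v[up] <- p$baseline_velocity + p$upslope * (t[up] - p$onset_time)
  dec <- t > t_peak
  v[dec] <- p$baseline_velocity +
    (p$peak_velocity - p$baseline_velocity) *
    exp(-(t[dec] - t_peak) / p$decay_time_constant)
  v
}

#' Generate a synthetic velocity-time curve
#'
#' Samples the waveform described by `params` on the uniform grid
#' `0, dt, 2 dt, ...` with `floor(rr_interval / sampling_interval)` samples
#' and adds seeded Gaussian noise.
#'
#' @param params a [waveform_params()] object.
#' @param site_label passed through to the curve.
#' @return A [velocity_time_curve()].
#' @export
generate_flow_curve <- function(params, site_label = "") {
  if (!inherits(params, "waveform_params"))
    params <- do.call(waveform_params, as.list(params))
  # tolerance-aware floor: 980 / 9.8 must count as exactly 100 frames
  n <- floor(params$rr_interval / params$sampling_interval + 1e-9)
  t <- (seq_len(n) - 1) * params$sampling_interval
  v <- waveform_value(params, t)
  if (params$noise_sd > 0)
    v <- v + with_seed(params$seed, rnorm(n, 0, params$noise_sd))
  velocity_time_curve(t, v, rr_interval = params$rr_interval,
                      site_label = site_label)
}

#' Generate a proximal/distal curve pair with known true PWV
#'
#' The distal curve is the proximal waveform delayed by
#' `path_length / true_pwv` (mm divided by m/s gives ms, the mm/ms identity
#' used throughout), with independent noise.
#'
#' @param true_pwv ground-truth pulse wave velocity, m/s (> 0).
#' @param path_length aortic path length between the sites, mm (> 0).
#' @param base [waveform_params()] shared by both sites; the distal site
#'   only differs in `onset_time` (and in its noise seed, `seed + 1`, when a
#'   seed is set).
#' @return A list with elements `proximal`, `distal` (both
#'   [velocity_time_curve()]), `true_pwv`, `path_length`, and the implied
#'   `onset_shift` in ms.
#' @export
generate_curve_pair <- function(true_pwv, path_length,
                                base = waveform_params()) {
  assert_scalar_number(true_pwv, "true_pwv", lower = 0, strict_lower = TRUE)
  assert_scalar_number(path_length, "path_length", lower = 0,
                       strict_lower = TRUE)
  if (!inherits(base, "waveform_params"))
    base <- do.call(waveform_params, as.list(base))
  shift <- path_length / true_pwv
  distal <- base
  distal$onset_time <- base$onset_time + shift
  if (!is.null(base$seed)) distal$seed <- base$seed + 1
  rise <- (base$peak_velocity - base$baseline_velocity) / base$upslope
  if (distal$onset_time + rise >= base$rr_interval)
    config_error("true_pwv",
                 "implied distal onset exceeds rr_interval for this path length")
  distal <- do.call(waveform_params, distal[setdiff(names(distal), "")])
  list(proximal = generate_flow_curve(base, site_label = "proximal"),
       distal = generate_flow_curve(distal, site_label = "distal"),
       true_pwv = true_pwv, path_length = path_length, onset_shift = shift)
}
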