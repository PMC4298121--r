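test_that("max_velocity_curve takes the lumen maximum per frame", {
  nfr <- 100L
  set.seed(3)
  target <- 5 + 60 * exp(-((seq_len(nfr) - 30)^2) / 200)
  series <- array(0, dim = c(6, 6, nfr))
  mask <- matrix(FALSE, 6, 6); mask[2:4, 2:4] <- TRUE
  for (i in seq_len(nfr)) series[2:4, 2:4, i] <- target[i]
  cur <- max_velocity_curve(series, mask, rr_interval = 980)
  expect_equal(cur$velocity, target)
  expect_equal(cur$time[100], 970.2)

  # one hot pixel dominates the max
  series[3, 3, ] <- 2 * target
  cur2 <- max_velocity_curve(series, mask, rr_interval = 980)
  expect_equal(cur2$velocity, 2 * target)

  expect_error(max_velocity_curve(series, matrix(FALSE, 6, 6), 980),
               "empty", class = "vascmr_config_error")
  expect_error(max_velocity_curve(series, cbind(7, 2), 980),
               "bounds", class = "vascmr_config_error")
})

test_that("diastolic level averages the final 250 ms window", {
  # velocity = sample index makes the window membership visible
  cur <- velocity_time_curve((0:99) * 9.8, as.numeric(1:100), 980)
  # time > 730 ms: samples 76..100 (1-based), i.e. 25 samples
  expect_equal(diastolic_level(cur), mean(76:100))
  # identity on a constant curve
  con <- velocity_time_curve((0:99) * 9.8, rep(7.5, 100), 980)
  expect_equal(diastolic_level(con), 7.5)
  # fully decayed synthetic curve returns the true baseline
  cur2 <- generate_flow_curve(clean_params())
  expect_equal(diastolic_level(cur2), 5, tolerance = 1e-6)
  # too-short curve
  short <- velocity_time_curve((0:19) * 9.8, rnorm(20), 200)
  expect_error(diastolic_level(short), class = "vascmr_resolution_error")
})

test_that("upslope fit recovers an exact linear rise to machine precision", {
  p <- clean_params(onset = 100, upslope = 10, peak_velocity = 505,
                    baseline_velocity = 5)
  cur <- generate_flow_curve(p)
  fit <- upslope_fit(cur, baseline = 5)
  expect_equal(fit$upslope_slope, 10, tolerance = 1e-9)
  expect_equal(fit$upslope_intercept, 5 - 10 * 100, tolerance = 1e-7)
  expect_false(fit$foot_fallback)
  on <- wave_onset(cur)
  expect_equal(on$onset_time, 100, tolerance = 1e-6)
})

test_that("upslope fit errors are typed", {
  # flat curve: no peak above baseline
  con <- velocity_time_curve((0:99) * 9.8, rep(5, 100), 980)
  expect_error(upslope_fit(con, 5), class = "vascmr_fit_error")
  # one-sample rise: resolution error
  p <- waveform_params(upslope = 50, peak_velocity = 200,
                       decay_time_constant = 30)
  expect_error(upslope_fit(generate_flow_curve(p), 5),
               class = "vascmr_resolution_error")
})

test_that("median slope over seeded noisy replicates is unbiased within 2%", {
  p0 <- clean_params()
  noise <- 0.02 * p0$peak_velocity
  slopes <- vapply(1:500, function(s) {
    p <- clean_params()
    p$noise_sd <- noise; p$seed <- s
    p <- do.call(waveform_params, unclass(p))
    cur <- generate_flow_curve(p)
    upslope_fit(cur, diastolic_level(cur))$upslope_slope
  }, numeric(1))
  expect_lt(abs(median(slopes) / p0$upslope - 1), 0.02)
})

test_that("onset is time-shift equivariant and velocity-scale invariant", {
  for (onset in c(80, 120, 160)) {
    c1 <- generate_flow_curve(clean_params(onset = onset))
    c2 <- generate_flow_curve(clean_params(onset = onset + 30))
    expect_equal(wave_onset(c2)$onset_time - wave_onset(c1)$onset_time, 30,
                 tolerance = 1e-6)
    # scaling baseline and peak together leaves the intersection fixed
    c3 <- velocity_time_curve(c1$time, 2 * c1$velocity, c1$rr_interval)
    expect_equal(wave_onset(c3)$onset_time, wave_onset(c1)$onset_time,
                 tolerance = 1e-9)
  }
})

test_that("transit time is positive distal minus proximal", {
  pair <- generate_curve_pair(7, 140, clean_params())
  expect_equal(transit_time(pair$proximal, pair$distal), 20,
               tolerance = 1e-4)
  # identical curves: dt = 0 must raise the propagation error
  expect_error(transit_time(pair$proximal, pair$proximal),
               class = "vascmr_propagation_error")
  # swapped sites: dt < 0
  expect_error(transit_time(pair$distal, pair$proximal),
               class = "vascmr_propagation_error")
})

test_that("path length sums segments and averages repeats", {
  expect_equal(aortic_path_length(rbind(c(0, 0), c(0, 140))), 140)
  expect_equal(aortic_path_length(list(rbind(c(0, 0), c(0, 140)),
                                       rbind(c(0, 0), c(0, 142)))), 141)
  th <- seq(0, pi / 2, length.out = 1000)
  quarter <- cbind(100 * cos(th), 100 * sin(th))
  expect_equal(aortic_path_length(quarter), 100 * pi / 2,
               tolerance = 1e-3)
  # 3D polyline
  expect_equal(aortic_path_length(cbind(0, 0, c(0, 50, 100))), 100)
  expect_error(aortic_path_length(list()), class = "vascmr_config_error")
  expect_error(aortic_path_length(rbind(c(0, 0))),
               class = "vascmr_config_error")
})

test_that("pwv is the mm/ms ratio with a sub-sample transit flag", {
  expect_equal(pulse_wave_velocity(140, 20)$pwv, 7)
  expect_equal(pulse_wave_velocity(186, 20)$pwv, 9.3)
  out <- pulse_wave_velocity(140, 3.09, sampling_interval = 9.8)
  expect_equal(out$pwv, 140 / 3.09)     # the 45.3 m/s outlier scale
  expect_true(out$sub_sample_transit)
  expect_error(pulse_wave_velocity(-1, 10), class = "vascmr_config_error")
  expect_error(pulse_wave_velocity(140, 0), class = "vascmr_config_error")
})

test_that("estimated PWV decreases strictly with injected onset shift", {
  base <- clean_params()
  shifts <- seq(8, 60, by = 4)
  est <- vapply(shifts, function(sh) {
    p2 <- clean_params(onset = 100 + sh)
    estimate_pwv(generate_flow_curve(base), generate_flow_curve(p2), 140)$pwv
  }, numeric(1))
  expect_true(all(diff(est) < 0))
})

test_that("noisy median bias stays within 10% for PWV <= 15 m/s", {
  p0 <- clean_params()
  noise <- 0.05 * p0$peak_velocity
  for (true_pwv in c(6, 12, 15)) {
    est <- vapply(1:170, function(s) {
      p <- clean_params()
      p$noise_sd <- noise; p$seed <- 1000 * true_pwv + s
      p <- do.call(waveform_params, unclass(p))
      pair <- generate_curve_pair(true_pwv, 186, p)
      tryCatch(estimate_pwv(pair$proximal, pair$distal, 186)$pwv,
               vascmr_error = function(e) NA_real_)
    }, numeric(1))
    expect_lt(abs(median(est, na.rm = TRUE) / true_pwv - 1), 0.10)
  }
})
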