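# Calibrated defaults for the synthetic cohort. The segment model draws a
# per-patient latent severity s ~ N(0,1); segment j has latent
# z_j = lambda * s + sqrt(1 - lambda^2) * e_j and its class is the ordinal
# bin of z_j under thresholds qnorm(cumsum(class_probs)). Averaging 27
# ordinal classes attenuates any correlation with s by a factor
# kappa = cor(MeanSC, s); the generator therefore encodes *observed*
# correlation targets and divides the severity ones by kappa when building
# the latent Gaussian. class_probs, lambda and kappa come from the
# coordinate search in scripts/calibrate.R (n = 2e6 Monte Carlo).
.vascmr_defaults <- list(
  segment_class_probs = c(0.75, 0.10, 0.04, 0.02, 0.09),
  segment_loading = 0.47,
  attenuation_kappa = 0.8498
)

#' Synthetic cohort configuration
#'
#' All defaults encode the calibrated "clean cohort" world: marginals match
#' the printed cohort characteristics (age 64 +/- 10 y, distal PWV
#' 9.3 +/- 3.8 m/s, proximal PWV 9.3 +/- 3.5 m/s with outliers removed,
#' NWI 0.46 +/- 0.07, 23/42 male) and the latent correlation structure
#' reproduces the published association pattern (Mean SC vs distal PWV
#' r = 0.64, standardized beta = 0.46 with age 0.30 and gender -0.06 in the
#' three-predictor regression). Severity-side correlations are
#' de-attenuated by `attenuation_kappa` (see package vignette).
#'
#' @param n_patients cohort size (>= 3).
#' @param seed integer seed; `NULL` consumes the current RNG stream.
#' @param age_mean,age_sd age marginal, years.
#' @param pwv_distal_mean,pwv_distal_sd distal aortic PWV marginal, m/s.
#' @param pwv_proximal_mean,pwv_proximal_sd proximal aortic PWV marginal, m/s.
#' @param nwi_mean,nwi_sd carotid NWI marginal (dimensionless).
#' @param gender_fraction_male Bernoulli probability of male (coded 1;
#'   female = 0).
#' @param target_correlations named vector of target *observed* pairwise
#'   correlations; names are
#'   `meansc_age`, `meansc_pwv_distal`, `meansc_pwv_proximal`,
#'   `meansc_nwi`, `pwv_distal_age`, `pwv_proximal_age`,
#'   `pwv_distal_pwv_proximal`, `nwi_age`, `nwi_pwv_distal`,
#'   `nwi_pwv_proximal`.
#' @param attenuation_kappa calibrated cor(Mean SC, latent severity); the
#'   `meansc_*` targets are divided by this when building the latent
#'   correlation matrix.
#' @param segment_loading lambda, loading of each segment latent on the
#'   patient severity (segment noise SD is `sqrt(1 - lambda^2)`).
#' @param segment_class_probs marginal probabilities of classes 1-5 for a
#'   single segment; the ordinal thresholds are
#'   `qnorm(cumsum(probs)[1:4])` and must be strictly increasing.
#' @param n_segments number of arterial segments (27).
#' @param outlier_injection if `TRUE`, replace one record's severity-driving
#'   segments so its Mean SC is the extreme 3.6 (over 25 available
#'   segments) and another record's proximal PWV with the extreme
#'   45.3 m/s, mirroring the two published outlier patients.
#' @param curve_baseline_velocity,curve_peak_velocity,curve_upslope,curve_onset_time,curve_decay_time_constant,curve_noise_sd
#'   waveform parameters used when the pipeline synthesizes per-patient
#'   flow curves (cm/s, cm/s, cm/s per ms, ms, ms, cm/s).
#' @param rr_interval,sampling_interval cycle length and frame spacing, ms.
#' @param path_length_distal_mean,path_length_distal_sd,path_length_proximal_mean,path_length_proximal_sd
#'   per-patient centerline path lengths, mm.
#' @param contour_n_vertices,outer_radius_mean,outer_radius_sd,slice_radius_jitter,contour_center_jitter
#'   carotid contour synthesis: vertices per ring, outer radius marginal
#'   (mm), relative per-slice radius jitter, per-slice center jitter SD (mm).
#' @param pwv_physical_range,nwi_physical_range clamping ranges applied only
#'   when synthesizing waveforms/contours (a speed or wall area cannot be
#'   negative); cohort marker columns keep the configured Gaussian
#'   marginals.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 42,
                          seed = NULL,
                          age_mean = 64, age_sd = 10,
                          pwv_distal_mean = 9.3, pwv_distal_sd = 3.8,
                          pwv_proximal_mean = 9.3, pwv_proximal_sd = 3.5,
                          nwi_mean = 0.46, nwi_sd = 0.07,
                          gender_fraction_male = 23 / 42,
                          target_correlations = c(
                            meansc_age = 0.58,
                            meansc_pwv_distal = 0.64,
                            meansc_pwv_proximal = 0.48,
                            meansc_nwi = 0.17,
                            pwv_distal_age = 0.60,
                            pwv_proximal_age = 0.46,
                            pwv_distal_pwv_proximal = 0.50,
                            nwi_age = 0.35,
                            nwi_pwv_distal = 0.21,
                            nwi_pwv_proximal = 0.22),
                          attenuation_kappa = .vascmr_defaults$attenuation_kappa,
                          segment_loading = .vascmr_defaults$segment_loading,
                          segment_class_probs = .vascmr_defaults$segment_class_probs,
                          n_segments = 27,
                          outlier_injection = FALSE,
                          curve_baseline_velocity = 5,
                          curve_peak_velocity = 65,
                          curve_upslope = 0.75,
                          curve_onset_time = 100,
                          curve_decay_time_constant = 100,
                          curve_noise_sd = 0,
                          rr_interval = 980,
                          sampling_interval = 9.8,
                          path_length_distal_mean = 186,
                          path_length_distal_sd = 12,
                          path_length_proximal_mean = 140,
                          path_length_proximal_sd = 10,
                          contour_n_vertices = 64,
                          outer_radius_mean = 4.0,
                          outer_radius_sd = 0.25,
                          slice_radius_jitter = 0.02,
                          contour_center_jitter = 0.5,
                          pwv_physical_range = c(1.5, 40),
                          nwi_physical_range = c(0.05, 0.95)) {
  cfg <- as.list(environment())
  assert_scalar_number(n_patients, "n_patients", lower = 3)
  for (f in c("age_sd", "pwv_distal_sd", "pwv_proximal_sd", "nwi_sd"))
    assert_scalar_number(cfg[[f]], f, lower = 0, strict_lower = TRUE)
  assert_scalar_number(gender_fraction_male, "gender_fraction_male", 0, 1)
  assert_scalar_number(attenuation_kappa, "attenuation_kappa", lower = 0,
                       upper = 1, strict_lower = TRUE)
  assert_scalar_number(segment_loading, "segment_loading", lower = 0,
                       upper = 1)
  assert_scalar_number(n_segments, "n_segments", lower = 1, upper = 27)
  if (length(segment_class_probs) != 5L || any(segment_class_probs < 0) ||
      abs(sum(segment_class_probs) - 1) > 1e-8)
    config_error("segment_class_probs",
                 "must be 5 non-negative probabilities summing to 1")
  th <- qnorm(cumsum(segment_class_probs)[1:4])
  if (any(!is.finite(th)) || any(diff(th) <= 0))
    config_error("segment_class_probs",
                 "implied ordinal thresholds must be finite and strictly increasing")
  need <- c("meansc_age", "meansc_pwv_distal", "meansc_pwv_proximal",
            "meansc_nwi", "pwv_distal_age", "pwv_proximal_age",
            "pwv_distal_pwv_proximal", "nwi_age", "nwi_pwv_distal",
            "nwi_pwv_proximal")
  if (!all(need %in% names(target_correlations)))
    config_error("target_correlations",
                 paste("missing:", paste(setdiff(need, names(target_correlations)),
                                         collapse = ", ")))
  cfg$segment_thresholds <- th
  cfg <- structure(cfg, class = "cohort_config")
  # PSD checked at load
  latent_correlation_matrix(cfg)
  cfg
}

#' Latent correlation matrix implied by a cohort configuration
#'
#' Variables in order: severity, age, distal PWV, proximal PWV, NWI.
#' Severity rows are the `meansc_*` targets divided by the attenuation
#' factor. A non-positive-definite implied matrix is a configuration error.
#'
#' @param config a [cohort_config()].
#' @return 5x5 correlation matrix with a `cholesky` attribute (upper
#'   triangular factor, the latent path coefficients).
#' @export
latent_correlation_matrix <- function(config) {
  tc <- config$target_correlations
  k <- config$attenuation_kappa
  vars <- c("severity", "age", "pwv_distal", "pwv_proximal", "nwi")
  R <- diag(5)
  dimnames(R) <- list(vars, vars)
  fill <- function(a, b, v) {
    R[a, b] <<- v; R[b, a] <<- v
  }
  fill("severity", "age", tc[["meansc_age"]] / k)
  fill("severity", "pwv_distal", tc[["meansc_pwv_distal"]] / k)
  fill("severity", "pwv_proximal", tc[["meansc_pwv_proximal"]] / k)
  fill("severity", "nwi", tc[["meansc_nwi"]] / k)
  fill("age", "pwv_distal", tc[["pwv_distal_age"]])
  fill("age", "pwv_proximal", tc[["pwv_proximal_age"]])
  fill("age", "nwi", tc[["nwi_age"]])
  fill("pwv_distal", "pwv_proximal", tc[["pwv_distal_pwv_proximal"]])
  fill("pwv_distal", "nwi", tc[["nwi_pwv_distal"]])
  fill("pwv_proximal", "nwi", tc[["nwi_pwv_proximal"]])
  if (any(abs(R) > 1))
    config_error("target_correlations",
                 "a de-attenuated latent correlation exceeds 1 in magnitude")
  L <- tryCatch(chol(R), error = function(e)
    config_error("target_correlations",
                 "implied latent correlation matrix is not positive definite"))
  attr(R, "cholesky") <- L
  R
}

# segment-class replacement vectors for the two injected outlier records;
# Mean SC 3.6 and 1.6 are exact over 25 available segments (90/25, 40/25)
.outlier_segments_a <- c(rep(5L, 14), rep(4L, 2), 3L, 2L, rep(1L, 7),
                         NA_integer_, NA_integer_)
.outlier_segments_b <- c(5L, 4L, rep(3L, 3), rep(2L, 2), rep(1L, 18),
                         NA_integer_, NA_integer_)
.outlier_pwv_proximal <- 45.3

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-patient latent Gaussians (severity, age, both PWVs, NWI) from
#' the configured correlation structure, simulates 27 ordinal segment
#' classes from the severity latent, and aggregates them to Mean SC /
#' Max SC through [patient_summary_matrix()] so the stenosis module is
#' exercised on every cohort. Gender is independent Bernoulli.
#'
#' @param config a [cohort_config()].
#' @return List of class `vascmr_cohort` with
#'   \describe{
#'     \item{cohort}{data.frame: `patient_id`, `age`, `gender`, `mean_sc`,
#'       `max_sc`, `n_segments_available`, `nwi`, `pwv_proximal`,
#'       `pwv_distal`, with an all-valid cell validity attribute
#'       (see [remove_outlier_cells()]).}
#'     \item{truth}{ground-truth record: latent draws, segment class
#'       matrix, latent correlation matrix and its Cholesky path
#'       coefficients, thresholds, outlier row indices, and the config.}
#'   }
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- as.integer(config$n_patients)
    R <- latent_correlation_matrix(config)
    L <- attr(R, "cholesky")
    Z <- matrix(rnorm(n * 5L), n, 5L) %*% L
    colnames(Z) <- colnames(R)
    lam <- config$segment_loading
    th <- config$segment_thresholds
    ns <- as.integer(config$n_segments)
    zseg <- lam * Z[, "severity"] +
      sqrt(1 - lam^2) * matrix(rnorm(n * ns), n, ns)
    cls <- 1L + (zseg > th[1]) + (zseg > th[2]) + (zseg > th[3]) +
      (zseg > th[4])
    pwv_proximal <- config$pwv_proximal_mean +
      config$pwv_proximal_sd * Z[, "pwv_proximal"]
    outlier_rows <- integer(0)
    if (isTRUE(config$outlier_injection)) {
      if (ns != 27L)
        config_error("outlier_injection", "requires n_segments = 27")
      cls[1L, ] <- .outlier_segments_a
      pwv_proximal[2L] <- .outlier_pwv_proximal
      outlier_rows <- c(mean_sc = 1L, pwv_proximal = 2L)
    }
    summ <- patient_summary_matrix(cls)
    cohort <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      age = config$age_mean + config$age_sd * Z[, "age"],
      gender = rbinom(n, 1L, config$gender_fraction_male),
      mean_sc = summ$mean_sc,
      max_sc = summ$max_sc,
      n_segments_available = summ$n_segments_available,
      nwi = config$nwi_mean + config$nwi_sd * Z[, "nwi"],
      pwv_proximal = pwv_proximal,
      pwv_distal = config$pwv_distal_mean +
        config$pwv_distal_sd * Z[, "pwv_distal"])
    cohort <- as_cohort_table(cohort)
    structure(list(
      cohort = cohort,
      truth = list(latents = as.data.frame(Z),
                   segment_classes = cls,
                   latent_correlations = R,
                   path_coefficients = L,
                   segment_thresholds = th,
                   segment_noise_sd = sqrt(1 - lam^2),
                   outlier_rows = outlier_rows,
                   config = config)),
      class = "vascmr_cohort")
  })
}

#' @export
print.vascmr_cohort <- function(x, ...) {
  cat(sprintf("<vascmr_cohort> %d patients; markers: %s\n",
              nrow(x$cohort),
              paste(setdiff(names(x$cohort), "patient_id"), collapse = ", ")))
  invisible(x)
}

#' Deterministic 42-patient cohort with the two published outlier records
#'
#' A fixed-seed synthetic cohort of 42 patients whose two outlier rows carry
#' the exact printed marker values of both outlier patients: P001 with
#' Mean SC 3.6, proximal PWV 8.8 m/s, distal PWV 9.2 m/s, NWI 0.48, and
#' P002 with Mean SC 1.6, proximal PWV 45.3 m/s, distal PWV 13.2 m/s,
#' NWI 0.57. All other rows are synthetic. Used to exercise cell-wise
#' outlier removal and the pairwise-complete N pattern.
#'
#' @return A cohort table (data.frame) as in [generate_cohort()], with
#'   attribute `outlier_rows = c(mean_sc = 1, pwv_proximal = 2)`.
#' @export
fixture_paper_cohort <- function() {
  gen <- generate_cohort(cohort_config(n_patients = 42, seed = 20150095 %% 2^31,
                                       outlier_injection = TRUE))
  cohort <- gen$cohort
  cls <- gen$truth$segment_classes
  cls[2L, ] <- .outlier_segments_b
  summ <- patient_summary_matrix(cls)
  cohort$mean_sc <- summ$mean_sc
  cohort$max_sc <- summ$max_sc
  cohort$n_segments_available <- summ$n_segments_available
  cohort$pwv_proximal[1L] <- 8.8
  cohort$pwv_distal[1L] <- 9.2
  cohort$nwi[1L] <- 0.48
  cohort$pwv_distal[2L] <- 13.2
  cohort$nwi[2L] <- 0.57
  # the injected rows must be the extremes they are meant to be
  stopifnot(which.max(cohort$mean_sc) == 1L,
            which.max(cohort$pwv_proximal) == 2L)
  attr(cohort, "outlier_rows") <- c(mean_sc = 1L, pwv_proximal = 2L)
  as_cohort_table(cohort)
}
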