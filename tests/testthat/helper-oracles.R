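# Independent oracles used across the suite. These deliberately take a
# different route than the package implementation (closed forms,
# stats::cor.test, explicit normal equations) so each check is dual-route.

# area of a regular n-gon of circumradius r (closed form)
oracle_ngon_area <- function(n, r) 0.5 * n * r^2 * sin(2 * pi / n)

# OLS by explicit normal equations: b, se, beta, p
oracle_ols <- function(X, y) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  n <- nrow(X); p <- ncol(X)
  s2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(solve(XtX)) * s2)
  tt <- b / se
  pval <- 2 * pt(-abs(tt), df = n - p)
  beta <- c(NA, b[-1] * apply(X[, -1, drop = FALSE], 2, sd) / sd(y))
  list(b = as.numeric(b), se = as.numeric(se), beta = as.numeric(beta),
       p = as.numeric(pval))
}

# noiseless default-shaped waveform with a fast decay, so the diastolic
# window sits exactly on the baseline and onsets are analytically exact
clean_params <- function(onset = 100, ...) {
  waveform_params(onset_time = onset, decay_time_constant = 30,
                  noise_sd = 0, ...)
}

# random patient-by-segment class matrix with missing segments
random_class_matrix <- function(n, n_seg = 27, p_na = 0.1) {
  m <- matrix(sample(1:5, n * n_seg, replace = TRUE,
                     prob = c(.6, .2, .1, .05, .05)), n, n_seg)
  m[matrix(runif(n * n_seg) < p_na, n, n_seg)] <- NA
  # guarantee availability
  m[, 1][is.na(m[, 1])] <- 1L
  m
}
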