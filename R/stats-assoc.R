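# marker columns carrying a per-cell validity flag
.cohort_markers <- c("age", "gender", "mean_sc", "max_sc", "nwi",
                     "pwv_proximal", "pwv_distal")

#' Cohort table with per-cell validity flags
#'
#' Attaches (or preserves) a logical patient-by-marker validity matrix;
#' cells start valid. Invalid cells are excluded pair- or case-wise by the
#' association routines, without dropping the rest of the record.
#'
#' @param df data.frame with `patient_id` and the marker columns `age`,
#'   `gender`, `mean_sc`, `max_sc`, `nwi`, `pwv_proximal`, `pwv_distal`
#'   (missing marker columns are allowed and simply not flagged).
#' @return `df` with class `cohort_table` and a `validity` attribute.
#' @export
as_cohort_table <- function(df) {
  if (!is.data.frame(df) || !"patient_id" %in% names(df))
    config_error("df", "must be a data.frame with a patient_id column")
  if (anyDuplicated(df$patient_id))
    config_error("patient_id", "must be unique")
  markers <- intersect(.cohort_markers, names(df))
  v <- attr(df, "validity")
  if (is.null(v)) {
    v <- matrix(TRUE, nrow(df), length(markers),
                dimnames = list(df$patient_id, markers))
  } else if (length(new <- setdiff(markers, colnames(v)))) {
    # marker columns added after construction start out valid
    ext <- matrix(TRUE, nrow(df), length(new),
                  dimnames = list(df$patient_id, new))
    v <- cbind(v, ext)[, intersect(.cohort_markers, c(colnames(v), new)),
                       drop = FALSE]
  }
  attr(df, "validity") <- v
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

cohort_validity <- function(cohort) {
  v <- attr(cohort, "validity")
  if (is.null(v)) {
    markers <- intersect(.cohort_markers, names(cohort))
    v <- matrix(TRUE, nrow(cohort), length(markers),
                dimnames = list(cohort$patient_id, markers))
  }
  v
}

#' Invalidate individual marker cells (cell-wise outlier removal)
#'
#' Flags invalidate single cells, not whole records: all other markers of a
#' flagged patient stay in the analysis. This is what produces the
#' pairwise-complete N pattern in which different correlations of the same
#' outlier-removed dataset have different N.
#'
#' @param cohort a [as_cohort_table()] data.frame.
#' @param flags data.frame with columns `patient_id` and `variable` naming
#'   the cells to invalidate.
#' @return The cohort with an updated validity attribute.
#' @export
remove_outlier_cells <- function(cohort, flags) {
  cohort <- as_cohort_table(cohort)
  if (!is.data.frame(flags) ||
      !all(c("patient_id", "variable") %in% names(flags)))
    config_error("flags", "needs columns patient_id and variable")
  v <- cohort_validity(cohort)
  for (i in seq_len(nrow(flags))) {
    pid <- as.character(flags$patient_id[i])
    var <- as.character(flags$variable[i])
    if (!pid %in% rownames(v))
      stop_vascmr(sprintf("unknown patient_id `%s`", pid),
                  "vascmr_input_error")
    if (!var %in% colnames(v))
      stop_vascmr(sprintf("unknown variable `%s`", var),
                  "vascmr_input_error")
    v[pid, var] <- FALSE
  }
  attr(cohort, "validity") <- v
  cohort
}

#' Pearson product-moment correlation
#'
#' Pairwise-complete product-moment correlation with a two-sided p-value
#' from the t approximation `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y numeric vectors.
#' @return List with `estimate`, `p_value`, `n`, `method`.
#' @export
pearson <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop_vascmr("need at least 3 complete pairs", "vascmr_input_error")
  if (var(x) == 0 || var(y) == 0)
    stop_vascmr("zero variance in one of the variables",
                "vascmr_degenerate_error")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(estimate = r, p_value = p, n = n, method = "pearson")
}

#' Spearman rank correlation
#'
#' Product-moment correlation of midranks (ties get average ranks), with
#' the same two-sided t approximation for the p-value.
#'
#' @inheritParams pearson
#' @return List with `estimate`, `p_value`, `n`, `method`.
#' @export
spearman <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop_vascmr("need at least 3 complete pairs", "vascmr_input_error")
  out <- pearson(rank(x, ties.method = "average"),
                 rank(y, ties.method = "average"))
  out$method <- "spearman"
  out
}

#' Lilliefors-style Kolmogorov-Smirnov normality test
#'
#' One-sample KS statistic against a normal with the sample mean and SD
#' plugged in. Because parameters are estimated, the classical KS null
#' distribution does not apply; the p-value is calibrated by Monte Carlo:
#' `n_sim` standard-normal samples of the same size are drawn, the
#' statistic recomputed with re-estimated parameters, and
#' `p = (1 + #\{D_sim >= D\}) / (n_sim + 1)`.
#'
#' @param values numeric vector, n >= 5, non-constant.
#' @param n_sim Monte-Carlo replicates for the p-value (default 500).
#' @return List with `statistic` (D), `p_value`, `n`.
#' @export
ks_normality <- function(values, n_sim = 500) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 5L)
    stop_vascmr("need at least 5 observations", "vascmr_input_error")
  if (var(values) == 0)
    stop_vascmr("constant vector: normality test undefined",
                "vascmr_degenerate_error")
  D_of <- function(x) {
    x <- sort(x)
    f <- pnorm(x, mean(x), sd(x))
    i <- seq_along(x)
    max(i / length(x) - f, f - (i - 1) / length(x))
  }
  D <- D_of(values)
  sims <- vapply(seq_len(n_sim), function(b) D_of(rnorm(n)), numeric(1))
  list(statistic = D, p_value = (1 + sum(sims >= D)) / (n_sim + 1), n = n)
}

# the eight marker/severity pairs of the published correlation table
.association_pairs <- data.frame(
  marker = rep(c("pwv_proximal", "pwv_distal", "nwi"), c(3L, 3L, 2L)),
  variable = c("mean_sc", "max_sc", "nwi",
               "mean_sc", "max_sc", "nwi",
               "mean_sc", "max_sc"),
  method = c("pearson", "spearman", "pearson",
             "pearson", "spearman", "pearson",
             "pearson", "spearman"),
  stringsAsFactors = FALSE)

#' Association matrix between stenosis severity and vascular markers
#'
#' Computes the eight pairwise associations of the published layout
#' (proximal PWV, distal PWV and NWI against Mean SC, Max SC and NWI):
#' Pearson for all-continuous pairs, Spearman whenever the ordinal Max SC
#' is involved. Each coefficient uses pairwise-complete records under the
#' cell validity flags, so different pairs may have different N. Both the
#' full data (all cells) and the outlier-removed data (validity applied)
#' variants are reported; they coincide when no cell is flagged.
#'
#' @param cohort a cohort table (see [as_cohort_table()]).
#' @return data.frame of class `association_report` with columns `dataset`
#'   (`full` / `outliers_removed`), `marker`, `variable`, `method`,
#'   `estimate`, `p_value`, `n_pairs`, `note`.
#' @export
association_matrix <- function(cohort) {
  cohort <- as_cohort_table(cohort)
  v <- cohort_validity(cohort)
  one <- function(dataset, apply_flags) {
    do.call(rbind, lapply(seq_len(nrow(.association_pairs)), function(i) {
      pr <- .association_pairs[i, ]
      if (is.null(cohort[[pr$marker]]) || is.null(cohort[[pr$variable]]))
        return(data.frame(dataset = dataset, marker = pr$marker,
                          variable = pr$variable, method = pr$method,
                          estimate = NA_real_, p_value = NA_real_,
                          n_pairs = 0L, note = "column absent",
                          stringsAsFactors = FALSE))
      x <- cohort[[pr$marker]]
      y <- cohort[[pr$variable]]
      if (apply_flags) {
        x[!v[, pr$marker]] <- NA
        y[!v[, pr$variable]] <- NA
      }
      res <- tryCatch(
        if (pr$method == "pearson") pearson(x, y) else spearman(x, y),
        vascmr_error = function(e)
          list(estimate = NA_real_, p_value = NA_real_,
               n = sum(complete.cases(x, y)), method = pr$method,
               note = conditionMessage(e)))
      data.frame(dataset = dataset, marker = pr$marker,
                 variable = pr$variable, method = pr$method,
                 estimate = res$estimate, p_value = res$p_value,
                 n_pairs = res$n, note = res$note %||% "",
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(one("full", FALSE), one("outliers_removed", TRUE))
  rownames(out) <- NULL
  class(out) <- c("association_report", class(out))
  out
}

#' Multiple linear regression with standardized coefficients
#'
#' Ordinary least squares of the outcome on the given predictors plus an
#' intercept, solved by QR decomposition. Standard errors come from the
#' residual variance; the standardized coefficient of predictor j is
#' `beta_j = B_j * SD(x_j) / SD(y)`; p-values are two-sided t tests.
#' Cells invalidated on the cohort are treated as missing; incomplete
#' cases are dropped.
#'
#' @param cohort a cohort table (or plain data.frame).
#' @param outcome name of the outcome column (default `"mean_sc"`).
#' @param predictors character vector of predictor columns.
#' @return data.frame of class `regression_fit` with one row per term
#'   (intercept first): `term`, `b`, `se`, `beta`, `p`; attributes
#'   `sigma`, `r_squared`, `n`, `outcome`.
#' @export
fit_linear_model <- function(cohort, outcome = "mean_sc",
                             predictors = c("age", "gender", "pwv_distal")) {
  cohort <- as_cohort_table(cohort)
  v <- cohort_validity(cohort)
  cols <- c(outcome, predictors)
  dat <- cohort[, cols, drop = FALSE]
  for (cl in intersect(cols, colnames(v))) dat[[cl]][!v[, cl]] <- NA
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  p <- length(predictors) + 1L
  if (n <= p)
    stop_vascmr("not enough complete cases for the model",
                "vascmr_input_error")
  X <- cbind(`(Intercept)` = 1, as.matrix(dat[, predictors, drop = FALSE]))
  y <- dat[[outcome]]
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop_vascmr("rank-deficient design: collinear predictors",
                "vascmr_degenerate_error")
  b <- qr.coef(qx, y)
  res <- y - X %*% b
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  XtX_inv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(XtX_inv) * sigma2)
  tt <- b / se
  pval <- 2 * pt(-abs(tt), df = n - p)
  sdy <- sd(y)
  beta <- c(NA_real_, b[-1] * apply(X[, -1, drop = FALSE], 2, sd) / sdy)
  out <- data.frame(term = colnames(X), b = as.numeric(b), se = se,
                    beta = beta, p = pval, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "sigma") <- sqrt(sigma2)
  attr(out, "r_squared") <- 1 - rss / sum((y - mean(y))^2)
  attr(out, "n") <- n
  attr(out, "outcome") <- outcome
  class(out) <- c("regression_fit", class(out))
  out
}

#' Scan all pairwise predictor interactions
#'
#' For each pair of predictors, refits the main-effects model with the
#' product of the two (each mean-centered before multiplying, which
#' decouples the product from the main effects) and reports the product
#' term's two-sided p-value.
#'
#' @inheritParams fit_linear_model
#' @return data.frame with `predictor_a`, `predictor_b`, `p_interaction`.
#' @export
interaction_scan <- function(cohort, outcome = "mean_sc",
                             predictors = c("age", "gender", "pwv_distal")) {
  cohort <- as_cohort_table(cohort)
  pairs <- utils::combn(predictors, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    aug <- cohort
    prod_col <- paste0(a, "_x_", b)
    aug[[prod_col]] <- (aug[[a]] - mean(aug[[a]], na.rm = TRUE)) *
      (aug[[b]] - mean(aug[[b]], na.rm = TRUE))
    fit <- fit_linear_model(aug, outcome = outcome,
                            predictors = c(predictors, prod_col))
    data.frame(predictor_a = a, predictor_b = b,
               p_interaction = fit$p[fit$term == prod_col],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
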