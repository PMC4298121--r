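clamp <- function(x, range) pmin(pmax(x, range[1]), range[2])

# Synthesize raw inputs for one patient from the latent record and push
# them through the measurement operators. Consumes the current RNG stream.
measure_patient <- function(i, cohort, cfg) {
  base <- waveform_params(
    baseline_velocity = cfg$curve_baseline_velocity,
    onset_time = cfg$curve_onset_time,
    upslope = cfg$curve_upslope,
    peak_velocity = cfg$curve_peak_velocity,
    decay_time_constant = cfg$curve_decay_time_constant,
    rr_interval = cfg$rr_interval,
    sampling_interval = cfg$sampling_interval,
    noise_sd = cfg$curve_noise_sd)
  measure_site <- function(true_pwv, len_mean, len_sd, label) {
    dx <- max(rnorm(1, len_mean, len_sd), len_mean / 2)
    pair <- generate_curve_pair(clamp(true_pwv, cfg$pwv_physical_range),
                                dx, base)
    # the duplicate-and-average path-length protocol
    dx_meas <- aortic_path_length(list(rbind(c(0, 0), c(0, dx)),
                                       rbind(c(0, 0), c(0, dx))))
    estimate_pwv(pair$proximal, pair$distal, dx_meas, site_pair = label)
  }
  pd <- measure_site(cohort$pwv_distal[i], cfg$path_length_distal_mean,
                     cfg$path_length_distal_sd, "thoracic-abdominal")
  pp <- measure_site(cohort$pwv_proximal[i], cfg$path_length_proximal_mean,
                     cfg$path_length_proximal_sd, "ascending-descending")
  nwi_t <- clamp(cohort$nwi[i], cfg$nwi_physical_range)
  r_out <- max(rnorm(1, cfg$outer_radius_mean, cfg$outer_radius_sd), 1) *
    (1 + rnorm(8, 0, cfg$slice_radius_jitter))
  r_in <- r_out * sqrt(1 - nwi_t) * (1 + rnorm(8, 0, cfg$slice_radius_jitter))
  stack <- generate_carotid_stack(pmin(r_in, 0.98 * r_out), r_out,
                                  n_vertices = cfg$contour_n_vertices,
                                  center_jitter = cfg$contour_center_jitter)
  list(pwv_distal = pd$pwv, pwv_proximal = pp$pwv,
       nwi = carotid_nwi(stack)$nwi,
       flags = c(distal_sub_sample = pd$sub_sample_transit,
                 proximal_sub_sample = pp$sub_sample_transit))
}

#' Measure a synthetic cohort through the imaging operators
#'
#' For every patient, synthesizes the raw inputs implied by the latent
#' record (proximal/distal flow-curve pairs at the patient's true PWV,
#' an 8-slice carotid contour stack at the patient's true NWI) and
#' re-derives the markers through [estimate_pwv()] and [carotid_nwi()].
#' Mean SC / Max SC already flow through the stenosis module inside
#' [generate_cohort()]. Consumes the current RNG stream; seed at the
#' caller (see [run_synthetic()]).
#'
#' @param gen a `vascmr_cohort` from [generate_cohort()].
#' @param continue_on_error keep going when a patient fails (the failure is
#'   recorded) instead of aborting with the stage and patient id.
#' @return List with `cohort` (measured marker columns) and `failures`
#'   (data.frame patient_id, stage, message).
#' @export
measure_cohort <- function(gen, continue_on_error = FALSE) {
  stopifnot(inherits(gen, "vascmr_cohort"))
  cfg <- gen$truth$config
  cohort <- gen$cohort
  n <- nrow(cohort)
  failures <- list()
  for (i in seq_len(n)) {
    res <- tryCatch(measure_patient(i, cohort, cfg),
                    vascmr_error = function(e) e)
    if (inherits(res, "condition")) {
      rec <- data.frame(patient_id = cohort$patient_id[i],
                        stage = class(res)[1],
                        message = conditionMessage(res))
      if (!continue_on_error)
        stop_vascmr(sprintf("measurement failed at stage %s for patient %s: %s",
                            rec$stage, rec$patient_id, rec$message),
                    "vascmr_pipeline_error")
      failures[[length(failures) + 1L]] <- rec
      cohort$pwv_distal[i] <- NA
      cohort$pwv_proximal[i] <- NA
      cohort$nwi[i] <- NA
    } else {
      cohort$pwv_distal[i] <- res$pwv_distal
      cohort$pwv_proximal[i] <- res$pwv_proximal
      cohort$nwi[i] <- res$nwi
    }
  }
  if (isTRUE(cfg$outlier_injection) && length(gen$truth$outlier_rows)) {
    # injected raw extreme survives measurement verbatim (45.3 m/s came
    # from a sub-sample transit; re-measuring it would just re-flag it)
    cohort$pwv_proximal[gen$truth$outlier_rows[["pwv_proximal"]]] <-
      .outlier_pwv_proximal
  }
  list(cohort = as_cohort_table(cohort),
       failures = if (length(failures)) do.call(rbind, failures)
                  else data.frame(patient_id = character(),
                                  stage = character(), message = character()))
}

run_association <- function(cohort, outlier_flags = NULL) {
  if (!is.null(outlier_flags) && nrow(outlier_flags))
    cohort <- remove_outlier_cells(cohort, outlier_flags)
  # regressions need the full covariate set; partial (file-based) runs
  # may only carry the measured markers
  markers <- intersect(c("pwv_distal", "pwv_proximal", "nwi"),
                       names(cohort))
  can_fit <- all(c("age", "gender", "mean_sc") %in% names(cohort)) &&
    length(markers) > 0L
  fits <- if (can_fit) {
    f <- lapply(markers, function(m)
      fit_linear_model(cohort, outcome = "mean_sc",
                       predictors = c("age", "gender", m)))
    names(f) <- markers
    f
  } else list()
  inter <- if (can_fit) {
    i <- lapply(markers, function(m)
      interaction_scan(cohort, outcome = "mean_sc",
                       predictors = c("age", "gender", m)))
    names(i) <- markers
    i
  } else list()
  list(association = association_matrix(cohort), regressions = fits,
       interactions = inter)
}

default_outlier_flags <- function(cohort) {
  rows <- attr(cohort, "outlier_rows")
  if (is.null(rows)) return(NULL)
  data.frame(patient_id = cohort$patient_id[rows],
             variable = names(rows), stringsAsFactors = FALSE)
}

#' Run the full synthetic pipeline
#'
#' Generates a cohort, synthesizes and measures all per-patient raw inputs,
#' computes the association report (correlations for the full and
#' outlier-removed data, three alternating-marker regressions, interaction
#' scans) and, when `out_dir` is given, writes the cohort table,
#' JSON report, human-readable tables and a run manifest with file
#' checksums. Identical config + seed gives byte-identical outputs.
#'
#' @param config a [cohort_config()]; its `seed` drives every draw.
#' @param out_dir optional output directory (created if missing).
#' @param continue_on_error see [measure_cohort()].
#' @return List of class `run_manifest`: `manifest`, `cohort`, `truth`,
#'   `association`, `regressions`, `interactions`, `failures`.
#' @export
run_synthetic <- function(config = cohort_config(), out_dir = NULL,
                          continue_on_error = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- config$seed
  run <- with_seed(seed, {
    cfg2 <- config
    cfg2$seed <- NULL
    gen <- generate_cohort(cfg2)
    meas <- measure_cohort(gen, continue_on_error = continue_on_error)
    flags <- if (isTRUE(config$outlier_injection))
      default_outlier_flags_from_truth(gen) else NULL
    stats <- run_association(meas$cohort, flags)
    list(gen = gen, meas = meas, stats = stats)
  })
  out <- list(cohort = run$meas$cohort, truth = run$gen$truth,
              association = run$stats$association,
              regressions = run$stats$regressions,
              interactions = run$stats$interactions,
              failures = run$meas$failures)
  out$manifest <- build_manifest(config, seed, out, out_dir)
  class(out) <- "run_manifest"
  out
}

default_outlier_flags_from_truth <- function(gen) {
  rows <- gen$truth$outlier_rows
  if (!length(rows)) return(NULL)
  data.frame(patient_id = gen$cohort$patient_id[rows],
             variable = names(rows), stringsAsFactors = FALSE)
}

#' Run the pipeline on user-supplied files
#'
#' Accepts any combination of a cohort table, a long-format segment grade
#' table, a per-patient curve-pair manifest and a per-patient contour
#' manifest; measured values override the corresponding cohort columns and
#' the association analysis is run on the result.
#'
#' @param paths list with any of:
#'   \describe{
#'     \item{cohort}{path of a cohort CSV (see [read_cohort()]).}
#'     \item{grades}{path of a grade CSV (see [read_grades()]); summarized
#'       into `mean_sc` / `max_sc` / `n_segments_available`.}
#'     \item{curves}{path of a manifest CSV with columns `patient_id`,
#'       `site` (`proximal` or `distal`, the aortic segment being measured),
#'       `proximal_file`, `distal_file`, `path_length_mm`.}
#'     \item{contours}{path of a manifest CSV with columns `patient_id`,
#'       `file` pointing at contour stacks (see [read_contours()]).}
#'   }
#' @param outlier_flags optional data.frame (`patient_id`, `variable`) of
#'   cells to invalidate before the outlier-removed analysis.
#' @param out_dir optional output directory.
#' @param continue_on_error record per-patient failures instead of aborting.
#' @return As [run_synthetic()] (without `truth`).
#' @export
run_from_files <- function(paths, outlier_flags = NULL, out_dir = NULL,
                           continue_on_error = FALSE) {
  if (!is.list(paths) || !length(paths))
    config_error("paths", "must be a non-empty list of input paths")
  unknown <- setdiff(names(paths), c("cohort", "grades", "curves", "contours"))
  if (length(unknown))
    config_error(unknown[1], "unknown input kind")
  cohort <- if (!is.null(paths$cohort)) read_cohort(paths$cohort) else NULL
  failures <- list()
  attempt <- function(pid, stage, expr) {
    tryCatch(expr, vascmr_error = function(e) {
      if (!continue_on_error)
        stop_vascmr(sprintf("stage %s failed for patient %s: %s",
                            stage, pid, conditionMessage(e)),
                    "vascmr_pipeline_error")
      failures[[length(failures) + 1L]] <<-
        data.frame(patient_id = pid, stage = stage,
                   message = conditionMessage(e))
      NULL
    })
  }
  ensure_cohort <- function(ids) {
    if (is.null(cohort))
      cohort <<- as_cohort_table(data.frame(patient_id = as.character(ids)))
  }
  if (!is.null(paths$grades)) {
    grades <- read_grades(paths$grades)
    summ <- patient_summary(grades)
    ensure_cohort(summ$patient_id)
    m <- match(cohort$patient_id, summ$patient_id)
    cohort$mean_sc <- summ$mean_sc[m]
    cohort$max_sc <- summ$max_sc[m]
    cohort$n_segments_available <- summ$n_segments_available[m]
  }
  if (!is.null(paths$curves)) {
    man <- read_checked(paths$curves,
                        c("patient_id", "site", "proximal_file",
                          "distal_file", "path_length_mm"))
    ensure_cohort(unique(man$patient_id))
    for (col in c("pwv_proximal", "pwv_distal"))
      if (is.null(cohort[[col]])) cohort[[col]] <- NA_real_
    for (i in seq_len(nrow(man))) {
      pid <- as.character(man$patient_id[i])
      res <- attempt(pid, "pwv", {
        prox <- read_curve(man$proximal_file[i], site_label = "proximal")
        dist <- read_curve(man$distal_file[i], site_label = "distal")
        estimate_pwv(prox, dist, man$path_length_mm[i],
                     site_pair = man$site[i])
      })
      if (!is.null(res))
        cohort[cohort$patient_id == pid,
               paste0("pwv_", man$site[i])] <- res$pwv
    }
  }
  if (!is.null(paths$contours)) {
    man <- read_checked(paths$contours, c("patient_id", "file"))
    ensure_cohort(unique(man$patient_id))
    if (is.null(cohort$nwi)) cohort$nwi <- NA_real_
    for (i in seq_len(nrow(man))) {
      pid <- as.character(man$patient_id[i])
      res <- attempt(pid, "nwi", carotid_nwi(read_contours(man$file[i])))
      if (!is.null(res)) cohort$nwi[cohort$patient_id == pid] <- res$nwi
    }
  }
  cohort <- as_cohort_table(as.data.frame(cohort))
  flags <- outlier_flags %||% default_outlier_flags(cohort)
  stats <- run_association(cohort, flags)
  out <- list(cohort = cohort, association = stats$association,
              regressions = stats$regressions,
              interactions = stats$interactions,
              failures = if (length(failures)) do.call(rbind, failures)
                         else data.frame(patient_id = character(),
                                         stage = character(),
                                         message = character()))
  out$manifest <- build_manifest(NULL, NULL, out, out_dir,
                                 inputs = unlist(paths))
  class(out) <- "run_manifest"
  out
}

build_manifest <- function(config, seed, run, out_dir, inputs = character()) {
  digest <- if (!is.null(config)) {
    lst <- unclass(config)
    lst$segment_thresholds <- NULL
    tmp <- tempfile()
    on.exit(unlink(tmp))
    jsonlite::write_json(Filter(Negate(is.null), lst), tmp,
                         auto_unbox = TRUE, digits = NA)
    unname(tools::md5sum(tmp))
  } else NA_character_
  manifest <- list(
    config_digest = digest,
    seed = seed %||% NA,
    inputs = if (length(inputs))
      data.frame(path = unname(inputs),
                 md5 = unname(tools::md5sum(unname(inputs))))
      else NULL,
    stages = c(generate = "ok", measure =
                 if (nrow(run$failures)) "partial" else "ok",
               associate = "ok"),
    n_patients = nrow(run$cohort),
    outputs = NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(cohort = file.path(out_dir, "cohort.csv"),
               report = file.path(out_dir, "association.json"),
               tables = file.path(out_dir, "tables.txt"))
    write_cohort(run$cohort, paths[["cohort"]])
    jsonlite::write_json(
      list(association = run$association,
           regressions = lapply(run$regressions, as.data.frame),
           interactions = run$interactions),
      paths[["report"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(format_association_table(run$association), "",
                 format_regression_tables(run$regressions)),
               paths[["tables"]])
    manifest$outputs <- data.frame(path = unname(paths),
                                   md5 = unname(tools::md5sum(unname(paths))))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  manifest
}

format_association_table <- function(report) {
  fmt <- function(d) {
    rows <- report[report$dataset == d, ]
    c(sprintf("-- %s --", d),
      sprintf("%-14s %-9s %-9s r=%+.2f  p=%.3g  N=%d",
              rows$marker, rows$variable, rows$method, rows$estimate,
              rows$p_value, rows$n_pairs))
  }
  c("Correlations (Pearson continuous / Spearman vs ordinal Max SC)",
    fmt("full"), fmt("outliers_removed"))
}

format_regression_tables <- function(fits) {
  unlist(lapply(names(fits), function(m) {
    f <- fits[[m]]
    c(sprintf("Regression: mean_sc ~ age + gender + %s (n=%d, R2=%.3f)",
              m, attr(f, "n"), attr(f, "r_squared")),
      sprintf("  %-12s B=%+.4f SE=%.4f beta=%+.3f p=%.3g",
              f$term, f$b, f$se, ifelse(is.na(f$beta), 0, f$beta), f$p), "")
  }))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d patients, %d failures; stages: %s\n",
              nrow(x$cohort), nrow(x$failures),
              paste(names(x$manifest$stages), x$manifest$stages,
                    sep = "=", collapse = ", ")))
  invisible(x)
}
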