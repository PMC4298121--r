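# Delimited-text readers/writers for all pipeline inputs and outputs.
# Everything is comma-separated, header row, UTF-8, "." decimal.

#' Read / write a velocity-time curve file
#'
#' Two-column files `time_ms, velocity_cms`. On reading, the RR interval
#' defaults to one sampling interval past the last sample (a curve covers
#' exactly one cycle).
#'
#' @param path file path.
#' @param rr_interval optional RR interval in ms.
#' @param site_label site label for the curve.
#' @return A [velocity_time_curve()].
#' @export
read_curve <- function(path, rr_interval = NULL, site_label = "") {
  df <- read_checked(path, c("time_ms", "velocity_cms"))
  dt <- mean(diff(df$time_ms))
  velocity_time_curve(df$time_ms, df$velocity_cms,
                      rr_interval %||% (df$time_ms[nrow(df)] + dt),
                      site_label = site_label)
}

#' @param curve a [velocity_time_curve()].
#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  write.csv(data.frame(time_ms = curve$time, velocity_cms = curve$velocity),
            path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a carotid contour stack file
#'
#' Long-format files `slice, ring, vertex_index, x_mm, y_mm` with
#' `ring` in `inner` / `outer` and slices 1-8. A slice missing either ring
#' is stored as `NULL` contours and will be rejected by [carotid_nwi()]
#' (naming the slice) if it is among the analyzed slices.
#'
#' @param path file path.
#' @return A [contour_stack()].
#' @export
read_contours <- function(path) {
  df <- read_checked(path, c("slice", "ring", "vertex_index", "x_mm", "y_mm"))
  if (!all(df$ring %in% c("inner", "outer")))
    parse_error(path, "ring", "values must be `inner` or `outer`")
  if (!all(df$slice %in% 1:8))
    parse_error(path, "slice", "slice indices must be in 1..8")
  slices <- lapply(1:8, function(i) {
    ring <- function(r) {
      d <- df[df$slice == i & df$ring == r, , drop = FALSE]
      if (nrow(d) == 0L) return(NULL)
      d <- d[order(d$vertex_index), , drop = FALSE]
      cbind(x = d$x_mm, y = d$y_mm)
    }
    list(inner = ring("inner"), outer = ring("outer"))
  })
  contour_stack(slices)
}

#' @param stack a [contour_stack()].
#' @rdname read_contours
#' @export
write_contours <- function(stack, path) {
  rows <- do.call(rbind, lapply(seq_along(stack$slices), function(i) {
    s <- stack$slices[[i]]
    do.call(rbind, lapply(c("inner", "outer"), function(r) {
      p <- s[[r]]
      if (is.null(p)) return(NULL)
      data.frame(slice = i, ring = r, vertex_index = seq_len(nrow(p)),
                 x_mm = p[, 1], y_mm = p[, 2])
    }))
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a segment grade table
#'
#' Long-format `patient_id, segment_id, reading_type, value` as consumed by
#' [patient_summary()].
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_grades <- function(path) {
  df <- read_checked(path, c("patient_id", "segment_id", "reading_type",
                             "value"))
  df$patient_id <- as.character(df$patient_id)
  df
}

#' @param grades long-format grade table.
#' @rdname read_grades
#' @export
write_grades <- function(grades, path) {
  write.csv(grades, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a cohort table
#'
#' @param path file path.
#' @return A cohort table (see [as_cohort_table()]).
#' @export
read_cohort <- function(path) {
  df <- read_checked(path, "patient_id")
  df$patient_id <- as.character(df$patient_id)
  as_cohort_table(df)
}

#' @param cohort cohort table.
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a run configuration file
#'
#' JSON with snake_case keys matching the arguments of [cohort_config()];
#' unknown keys are rejected.
#'
#' @param path JSON file.
#' @return A [cohort_config()].
#' @export
read_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown))
    config_error(unknown[1], "unknown configuration key")
  if (!is.null(lst$target_correlations))
    lst$target_correlations <- unlist(lst$target_correlations)
  do.call(cohort_config, lst)
}

#' @param config a [cohort_config()].
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  lst <- unclass(config)
  lst$segment_thresholds <- NULL   # derived
  # jsonlite drops names of named atomic vectors; store as an object
  lst$target_correlations <- as.list(lst$target_correlations)
  lst <- Filter(Negate(is.null), lst)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_checked <- function(path, required_cols) {
  if (!file.exists(path))
    parse_error(path, "", "file not found")
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8"),
                 error = function(e) parse_error(path, "", conditionMessage(e)))
  miss <- setdiff(required_cols, names(df))
  if (length(miss))
    parse_error(path, miss[1], "required column missing")
  df
}

parse_error <- function(path, field, msg) {
  stop_vascmr(sprintf("%s: %s%s", path,
                      if (nzchar(field)) paste0("field `", field, "`: ") else "",
                      msg),
              "vascmr_parse_error", path = path, field = field)
}
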