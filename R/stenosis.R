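#' Map percent stenosis to the five-class scale
#'
#' The visual grading scale: class 1 (0 percent), 2 (1-50), 3 (51-75),
#' 4 (76-99) and 5 (100, occlusion). Percent readings are accepted as
#' continuous and classed by the half-open boundaries `0 -> 1`,
#' `(0, 50] -> 2`, `(50, 75] -> 3`, `(75, 100) -> 4`, `100 -> 5`.
#'
#' @param percent numeric vector of percent stenosis in \[0, 100\].
#' @return Integer vector of classes 1-5.
#' @export
stenosis_class <- function(percent) {
  if (!is.numeric(percent) || anyNA(percent))
    config_error("percent", "must be numeric without missing values")
  if (any(percent < 0 | percent > 100))
    config_error("percent", "values must lie in [0, 100]")
  cls <- ifelse(percent == 0, 1L,
         ifelse(percent <= 50, 2L,
         ifelse(percent <= 75, 3L,
         ifelse(percent < 100, 4L, 5L))))
  as.integer(cls)
}

#' Highest stenosis class within one arterial segment
#'
#' A segment may contain several stenoses; its class is the highest class
#' among them. Readings may be given as classes (1-5) or percent values
#' (converted via [stenosis_class()]).
#'
#' @param readings numeric vector of readings for one segment.
#' @param reading_type `"class"` or `"percent"`, recycled over `readings`.
#' @return The segment class (integer 1-5), or `NA_integer_` for an empty
#'   reading set (unavailable segment).
#' @export
segment_class <- function(readings, reading_type = "class") {
  if (length(readings) == 0L) return(NA_integer_)
  reading_type <- rep_len(reading_type, length(readings))
  cls <- integer(length(readings))
  is_pct <- reading_type == "percent"
  if (any(is_pct)) cls[is_pct] <- stenosis_class(readings[is_pct])
  if (any(!is_pct)) {
    cc <- readings[!is_pct]
    if (anyNA(cc) || !all(cc %in% 1:5))
      config_error("readings", "class readings must be integers in 1..5")
    cls[!is_pct] <- as.integer(cc)
  }
  max(cls)
}

# vectorized core: per-patient Max SC / Mean SC from an n x 27 class matrix
# (NA marks unavailable segments); shared by patient_summary() and the
# cohort generator so segment aggregation always flows through this module.
#' Summarize a patient-by-segment class matrix
#'
#' @param class_matrix integer matrix, one row per patient, one column per
#'   segment (up to 27); `NA` marks unavailable segments.
#' @return data.frame with `max_sc`, `mean_sc`, `n_segments_available`.
#' @export
patient_summary_matrix <- function(class_matrix) {
  m <- as.matrix(class_matrix)
  if (ncol(m) > 27L)
    config_error("class_matrix", "at most 27 segments are defined")
  ok <- !is.na(m)
  if (any(rowSums(ok) == 0L))
    stop_vascmr("at least one patient has no available segment",
                "vascmr_input_error")
  vals <- m[ok]
  if (!all(vals == trunc(vals)) || any(vals < 1 | vals > 5))
    config_error("class_matrix", "classes must be integers in 1..5")
  neg <- m; neg[!ok] <- -Inf
  max_sc <- as.integer(do.call(pmax, as.data.frame(neg)))
  data.frame(max_sc = max_sc,
             mean_sc = rowMeans(m, na.rm = TRUE),
             n_segments_available = as.integer(rowSums(ok)))
}

#' Per-patient stenosis summary from a segment grade table
#'
#' Aggregates a long-format grade table (one row per reading) into one
#' summary row per patient: the highest class over all available segments
#' (Max SC) and the mean class over all available segments (Mean SC).
#' Segments are first reduced to their highest class via [segment_class()];
#' segments marked `unavailable` (or absent from the table) are excluded
#' from both summaries.
#'
#' @param table data.frame with columns `patient_id`, `segment_id` (1-27),
#'   `reading_type` (`"class"`, `"percent"` or `"unavailable"`) and `value`.
#' @return data.frame with one row per patient: `patient_id`, `max_sc`,
#'   `mean_sc`, `n_segments_available`.
#' @export
patient_summary <- function(table) {
  req <- c("patient_id", "segment_id", "reading_type", "value")
  if (!is.data.frame(table) || !all(req %in% names(table)))
    config_error("table", paste("needs columns", paste(req, collapse = ", ")))
  if (!all(table$segment_id %in% 1:27))
    config_error("segment_id", "segment ids must be in 1..27")
  bad <- setdiff(unique(table$reading_type),
                 c("class", "percent", "unavailable"))
  if (length(bad))
    config_error("reading_type",
                 paste("unknown reading_type:", paste(bad, collapse = ", ")))
  avail <- table[table$reading_type != "unavailable", , drop = FALSE]
  ids <- unique(table$patient_id)
  if (nrow(avail) == 0L)
    stop_vascmr("no available segments in the table", "vascmr_input_error")
  key <- interaction(avail$patient_id, avail$segment_id, drop = TRUE)
  seg_cls <- vapply(split(seq_len(nrow(avail)), key), function(i)
    segment_class(avail$value[i], avail$reading_type[i]), integer(1))
  seg_pat <- vapply(split(avail$patient_id, key), `[`, avail$patient_id[1], 1)
  out <- do.call(rbind, lapply(ids, function(pid) {
    cls <- seg_cls[seg_pat == pid]
    if (length(cls) == 0L)
      stop_vascmr(sprintf("patient %s has no available segment", pid),
                  "vascmr_input_error", patient_id = pid)
    data.frame(patient_id = pid, max_sc = max(cls), mean_sc = mean(cls),
               n_segments_available = length(cls))
  }))
  rownames(out) <- NULL
  out
}
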