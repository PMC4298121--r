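#' Polygon area by the shoelace formula
#'
#' Absolute (orientation-independent) area of a simple closed polygon given
#' as an ordered vertex list; the closing edge back to the first vertex is
#' implicit (a duplicated final vertex is tolerated).
#'
#' @param polygon two-column numeric matrix (or data frame) of vertices, mm.
#' @return Area in mm^2.
#' @export
contour_area <- function(polygon) {
  p <- as.matrix(polygon)
  if (!is.numeric(p) || ncol(p) != 2L)
    config_error("polygon", "must be a two-column numeric matrix")
  # drop explicit closure
  if (nrow(p) > 1L && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (nrow(unique(p)) < 3L)
    stop_vascmr("degenerate polygon: fewer than 3 distinct vertices",
                "vascmr_geometry_error")
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# ray-casting point-in-polygon (even-odd rule)
point_in_polygon <- function(pt, polygon) {
  p <- as.matrix(polygon)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crosses <- ((y > pt[2]) != (yn > pt[2])) &
    (pt[1] < (xn - x) * (pt[2] - y) / (yn - y) + x)
  sum(crosses) %% 2L == 1L
}

#' Wall and total vessel area of one cross-section
#'
#' `total_area` is the area inside the outer wall contour; the vessel wall
#' area (VWA) is outer minus inner (lumen) area. The outer contour must
#' strictly contain the inner one, checked cheaply via the area ordering and
#' the inner centroid lying inside the outer polygon (adequate for
#' near-circular wall contours).
#'
#' @param inner,outer two-column vertex matrices, mm.
#' @return List with `vwa` and `total_area`, mm^2.
#' @export
slice_wall_measures <- function(inner, outer) {
  a_in <- contour_area(inner)
  a_out <- contour_area(outer)
  centroid <- colMeans(as.matrix(inner))
  if (a_out <= a_in || !point_in_polygon(centroid, outer))
    stop_vascmr("outer contour does not contain the inner contour",
                "vascmr_geometry_error")
  list(vwa = a_out - a_in, total_area = a_out)
}

#' Carotid contour stack container
#'
#' Eight contiguous 2 mm cross-sections of the common carotid artery, slice
#' 1 most caudal and slice 8 adjacent to the flow divider, each with a
#' closed inner (lumen) and outer wall polygon.
#'
#' @param slices list of 8 lists, each with elements `inner` and `outer`
#'   (two-column vertex matrices, mm).
#' @param thickness slice thickness in mm (default 2).
#' @return Object of class `contour_stack`.
#' @export
contour_stack <- function(slices, thickness = 2) {
  if (!is.list(slices) || length(slices) != 8L)
    config_error("slices", "a contour stack has exactly 8 slices")
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (!is.list(s) || is.null(s$inner) || is.null(s$outer))
      config_error("slices",
                   sprintf("slice %d must have `inner` and `outer` contours", i))
  }
  structure(list(slices = slices, thickness = thickness),
            class = "contour_stack")
}

#' Normalized wall index of a carotid contour stack
#'
#' Mean VWA and mean total vessel area over the analyzed slices (2 to 5 of
#' 8 by default), then `NWI = mean VWA / mean total area` - the ratio of
#' the means, not the mean of per-slice ratios. Slices outside
#' `slices_used` are ignored entirely, so corruption there does not affect
#' the result.
#'
#' @param stack a [contour_stack()].
#' @param slices_used integer slice indices entering the analysis
#'   (default `2:5`).
#' @return Object of class `nwi_result`: `mean_vwa`, `mean_total_area`
#'   (mm^2), `nwi`, `slices_used`.
#' @export
carotid_nwi <- function(stack, slices_used = 2:5) {
  stopifnot(inherits(stack, "contour_stack"))
  if (any(slices_used < 1L | slices_used > 8L))
    config_error("slices_used", "slice indices must be in 1..8")
  meas <- lapply(slices_used, function(i) {
    s <- stack$slices[[i]]
    if (is.null(s$inner) || is.null(s$outer) ||
        NROW(s$inner) < 3L || NROW(s$outer) < 3L)
      stop_vascmr(sprintf("slice %d contour missing or degenerate", i),
                  "vascmr_geometry_error", slice = i)
    tryCatch(slice_wall_measures(s$inner, s$outer),
             vascmr_geometry_error = function(e)
               stop_vascmr(sprintf("slice %d: %s", i, conditionMessage(e)),
                           "vascmr_geometry_error", slice = i))
  })
  mean_vwa <- mean(vapply(meas, `[[`, numeric(1), "vwa"))
  mean_tot <- mean(vapply(meas, `[[`, numeric(1), "total_area"))
  nwi <- mean_vwa / mean_tot
  if (!(nwi > 0 && nwi < 1))
    stop_vascmr(sprintf("NWI %.4f outside (0, 1)", nwi),
                "vascmr_geometry_error")
  structure(list(mean_vwa = mean_vwa, mean_total_area = mean_tot,
                 nwi = nwi, slices_used = as.integer(slices_used)),
            class = "nwi_result")
}

#' @export
print.nwi_result <- function(x, ...) {
  cat(sprintf("<nwi_result> NWI %.3f (VWA %.2f mm^2 / total %.2f mm^2, slices %s)\n",
              x$nwi, x$mean_vwa, x$mean_total_area,
              paste(x$slices_used, collapse = ",")))
  invisible(x)
}
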