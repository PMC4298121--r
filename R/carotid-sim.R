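#' Generate a synthetic carotid contour stack
#'
#' Builds an 8-slice stack of concentric near-circular inner/outer wall
#' polygons with the given per-slice radii. Because inner and outer rings
#' are regular polygons with the same vertex count, the polygonal NWI
#' equals the circle closed form `1 - (r_in/r_out)^2` exactly, independent
#' of the vertex count; the vertex count only matters for absolute areas.
#'
#' @param inner_radii,outer_radii numeric length-8 vectors of lumen / outer
#'   wall radii per slice, mm; `outer_radii > inner_radii > 0` elementwise.
#' @param n_vertices vertices per polygon (default 64).
#' @param center_jitter SD of a Gaussian per-slice center offset, mm.
#' @param seed optional seed for the jitter.
#' @return A [contour_stack()].
#' @export
generate_carotid_stack <- function(inner_radii, outer_radii,
                                   n_vertices = 64, center_jitter = 0,
                                   seed = NULL) {
  inner_radii <- rep_len(as.numeric(inner_radii), 8L)
  outer_radii <- rep_len(as.numeric(outer_radii), 8L)
  if (any(!is.finite(inner_radii)) || any(!is.finite(outer_radii)) ||
      any(inner_radii <= 0) || any(outer_radii <= inner_radii))
    config_error("outer_radii",
                 "need outer_radii > inner_radii > 0 for every slice")
  assert_scalar_number(n_vertices, "n_vertices", lower = 3)
  assert_scalar_number(center_jitter, "center_jitter", lower = 0)
  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  ux <- cos(theta); uy <- sin(theta)
  centers <- with_seed(seed, matrix(rnorm(16, 0, center_jitter), 8L, 2L))
  if (center_jitter == 0) centers[] <- 0
  slices <- lapply(1:8, function(i) {
    list(inner = cbind(x = centers[i, 1] + inner_radii[i] * ux,
                       y = centers[i, 2] + inner_radii[i] * uy),
         outer = cbind(x = centers[i, 1] + outer_radii[i] * ux,
                       y = centers[i, 2] + outer_radii[i] * uy))
  })
  contour_stack(slices)
}
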