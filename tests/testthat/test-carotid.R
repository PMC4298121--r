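ngon <- function(n, r, cx = 0, cy = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

test_that("shoelace area: squares, circle limit, orientation invariance", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(contour_area(sq), 1)
  expect_equal(contour_area(sq[4:1, ]), 1)         # reversed orientation
  expect_equal(contour_area(rbind(sq, sq[1, ])), 1) # explicit closure
  # 256-gon of radius 4 approaches pi * 16 and matches the n-gon closed form
  p <- ngon(256, 4)
  expect_equal(contour_area(p), pi * 16, tolerance = 1e-3)
  expect_equal(contour_area(p), oracle_ngon_area(256, 4), tolerance = 1e-12)
  expect_error(contour_area(rbind(c(0, 0), c(1, 1), c(0, 0), c(1, 1))),
               class = "vascmr_geometry_error")
})

test_that("slice wall measures: vwa = outer - inner, containment enforced", {
  m <- slice_wall_measures(ngon(256, 2), ngon(256, 4))
  expect_equal(m$total_area, pi * 16, tolerance = 1e-3)
  expect_equal(m$vwa, pi * (16 - 4), tolerance = 1e-3)
  expect_error(slice_wall_measures(ngon(64, 4), ngon(64, 2)),
               class = "vascmr_geometry_error")   # inner larger
  expect_error(slice_wall_measures(ngon(64, 4), ngon(64, 4)),
               class = "vascmr_geometry_error")   # equal areas
  # disjoint rings of the right area ordering still fail containment
  expect_error(slice_wall_measures(ngon(64, 1, cx = 10), ngon(64, 2)),
               class = "vascmr_geometry_error")
})

test_that("NWI on concentric circles matches 1 - (rin/rout)^2", {
  st <- generate_carotid_stack(rep(2, 8), rep(4, 8), n_vertices = 128)
  res <- carotid_nwi(st)
  expect_equal(res$nwi, 0.75, tolerance = 1e-3)
  expect_identical(res$slices_used, 2:5)
  # vanishing wall limit
  st2 <- generate_carotid_stack(rep(3.999, 8), rep(4, 8), n_vertices = 128)
  expect_lt(carotid_nwi(st2)$nwi, 1e-3)
  # closed-form property across random radii (per-slice)
  set.seed(5)
  for (k in 1:10) {
    r_out <- runif(8, 3, 5)
    r_in <- r_out * sqrt(1 - runif(8, 0.2, 0.6))
    st3 <- generate_carotid_stack(r_in, r_out, n_vertices = 128)
    expected <- 1 - sum(r_in[2:5]^2) / sum(r_out[2:5]^2)
    expect_equal(carotid_nwi(st3)$nwi, expected, tolerance = 1e-3)
  }
})

test_that("aggregation is the ratio of means, not the mean of ratios", {
  r_in <- c(3, 2, 1, 3, 2, 3, 3, 3)
  r_out <- c(4, 4, 4, 3.5, 4, 4, 4, 4)
  st <- generate_carotid_stack(r_in, r_out, n_vertices = 256)
  ratio_of_means <- 1 - sum(r_in[2:5]^2) / sum(r_out[2:5]^2)
  mean_of_ratios <- mean(1 - (r_in[2:5] / r_out[2:5])^2)
  got <- carotid_nwi(st)$nwi
  expect_equal(got, ratio_of_means, tolerance = 1e-6)
  expect_gt(abs(got - mean_of_ratios), 0.01)  # heterogeneous stacks differ
})

test_that("only slices 2-5 enter the analysis; corruption elsewhere is ignored", {
  st <- generate_carotid_stack(rep(2, 8), rep(4, 8), n_vertices = 64)
  st$slices[[1]]$inner <- NULL
  st$slices[[6]]$outer <- ngon(64, 1)     # inner would not fit
  st$slices[[7]] <- list(inner = ngon(64, 2), outer = ngon(64, 2))
  st$slices[[8]]$inner <- ngon(2, 1)
  expect_equal(carotid_nwi(st)$nwi, 0.75, tolerance = 1e-3)
  # but a missing analyzed slice errors, naming it
  st$slices[[3]]$outer <- NULL
  err <- tryCatch(carotid_nwi(st), vascmr_geometry_error = function(e) e)
  expect_s3_class(err, "vascmr_geometry_error")
  expect_match(conditionMessage(err), "slice 3")
})

test_that("affine scaling multiplies areas by k^2 and leaves NWI fixed", {
  st <- generate_carotid_stack(c(2, 2.2, 1.9, 2.1, 2, 2, 2, 2),
                               c(4, 4.1, 3.9, 4, 4, 4, 4, 4),
                               n_vertices = 64)
  base <- carotid_nwi(st)
  for (k in c(0.5, 3)) {
    st_k <- st
    st_k$slices <- lapply(st$slices, function(s)
      list(inner = s$inner * k, outer = s$outer * k))
    scaled <- carotid_nwi(st_k)
    expect_equal(scaled$mean_vwa, base$mean_vwa * k^2, tolerance = 1e-9)
    expect_equal(scaled$nwi, base$nwi, tolerance = 1e-9)
  }
})

test_that("stack generation validates radii and is seed-deterministic", {
  expect_error(generate_carotid_stack(rep(4, 8), rep(2, 8)),
               class = "vascmr_config_error")
  expect_error(generate_carotid_stack(rep(0, 8), rep(2, 8)),
               class = "vascmr_config_error")
  a <- generate_carotid_stack(rep(2, 8), rep(4, 8), center_jitter = 0.5,
                              seed = 9)
  b <- generate_carotid_stack(rep(2, 8), rep(4, 8), center_jitter = 0.5,
                              seed = 9)
  expect_identical(a, b)
})
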