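test_that("polygon-seeded contour recovers the analytic lumen area", {
  blk <- .clean_block
  ph <- blk$stack$meta$phantom
  frame1 <- blk$stack$data[, , 1]
  cl <- centerline(ph$axis_polyline, spacing_mm = 5)
  n <- nrow(frame1)
  # generous hull around the tube: nodes offset +/- (radius + 6 mm)
  off <- (30 + 6) / 2
  up <- cbind(cl$x_mm + off * cl$nx, cl$y_mm + off * cl$ny)
  dn <- cbind(cl$x_mm - off * cl$nx, cl$y_mm - off * cl$ny)
  # extend beyond the rounded caps
  ext <- function(p, q, d) p + d * (p - q) / sqrt(sum((p - q)^2))
  poly_mm <- rbind(ext(up[1, ], up[2, ], 20), up, ext(up[nrow(up), ], up[nrow(up) - 1, ], 20),
                   ext(dn[nrow(dn), ], dn[nrow(dn) - 1, ], 20), dn[rev(seq_len(nrow(dn))), ],
                   ext(dn[1, ], dn[2, ], 20))
  poly_px <- poly_mm / ph$pixel_mm + (n + 1) / 2
  mask <- initial_contour(frame1, poly_px)
  # analytic area at t = 0: integral of the instantaneous diameter profile
  # plus the rounded end caps (whose radii also follow the wave at t = 0)
  L <- attr(cl, "length_mm")
  s <- seq(0, L, by = 0.1)
  w <- blk$truth$true_wave_params
  area_mm2 <- sum(true_diameter(s, 0, ph, w)) * 0.1 +
    pi / 2 * ((true_diameter(0, 0, ph, w) / 2)^2 +
              (true_diameter(L, 0, ph, w) / 2)^2)
  measured <- sum(mask) * ph$pixel_mm^2
  expect_lt(abs(measured - area_mm2) / area_mm2, 0.05)
})

test_that("auto threshold matches the polygon seed up to boundary pixels", {
  blk <- .clean_block
  frame1 <- blk$stack$data[, , 1]
  auto <- initial_contour(frame1, "auto")
  # direct half-level count as the reference lumen
  ph <- blk$stack$meta$phantom
  lev <- (ph$intensities[["lumen"]] + ph$intensities[["wall"]]) / 2
  ref <- frame1 >= lev
  symdiff <- sum(xor(auto, ref))
  expect_lt(symdiff / sum(ref), 0.05)
})

test_that("degenerate polygons and empty masks are rejected", {
  frame1 <- .clean_block$stack$data[, , 1]
  expect_error(initial_contour(frame1, matrix(c(1, 1, 2, 2), 2, 2)), "3 vertices")
  expect_error(initial_contour(frame1, 100), "empty")
})

test_that("propagation through a static stack reproduces the seed mask", {
  blk <- generate_cine(clean_phantom(96, 12), quiet_wave(), no_resp(), seed = 31)
  m0 <- initial_contour(blk$stack$data[, , 1], "auto")
  masks <- propagate_contours(blk$stack, m0)
  for (k in 2:12)
    expect_lt(sum(xor(masks[[k]], m0)) / sum(m0), 0.02)
  expect_length(attr(masks, "flagged_frames"), 0)
})

test_that("static noisy stack keeps boundary jitter within one pixel", {
  blk <- generate_cine(phantom_config(grid_size = 96, n_frames = 12),
                       quiet_wave(), no_resp(), seed = 32)
  m0 <- initial_contour(blk$stack$data[, , 1], "auto")
  masks <- propagate_contours(blk$stack, m0)
  for (k in c(5, 12))
    expect_lt(sum(xor(masks[[k]], m0)) / sum(m0), 0.08)
})

test_that("a pure-noise frame is flagged and bridged by the previous mask", {
  blk <- generate_cine(phantom_config(grid_size = 96, n_frames = 12),
                       wave_config(occlusion_frac = 0.4), no_resp(), seed = 33)
  set.seed(1)
  blk$stack$data[, , 6] <- matrix(rnorm(96 * 96, 0.1, 0.05), 96, 96)
  m0 <- initial_contour(blk$stack$data[, , 1], "auto")
  masks <- propagate_contours(blk$stack, m0)
  expect_true(6 %in% attr(masks, "flagged_frames"))
  expect_identical(masks[[6]], masks[[5]])
  expect_length(masks, 12)
})

test_that("propagated diameters track ground truth within one pixel", {
  blk <- .clean_block
  ph <- blk$stack$meta$phantom
  m0 <- initial_contour(blk$stack$data[, , 1], "auto")
  masks <- propagate_contours(blk$stack, m0)
  cl <- centerline(ph$axis_polyline)
  dm <- measure_diameters(masks, cl, ph$pixel_mm, stack = blk$stack)
  interior <- cl$s_mm > 10 & cl$s_mm < max(cl$s_mm) - 10
  err <- abs(dm$D - blk$truth$true_diameter_map)[interior, ]
  expect_lt(max(err), ph$pixel_mm)
})
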