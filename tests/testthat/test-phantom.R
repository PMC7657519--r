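test_that("config validation rejects out-of-range parameters", {
  expect_error(wave_config(occlusion_frac = 1.2), "occlusion_frac")
  expect_error(wave_config(occlusion_frac = -0.1), "occlusion_frac")
  expect_error(wave_config(freq_cpm = 0), "freq_cpm")
  expect_error(phantom_config(axis_polyline = matrix(c(0, 0), 1, 2)),
               "axis_polyline")
  expect_error(phantom_config(baseline_diameter_mm = c(30, -2)), "positive")
  expect_error(manometry_config(hydro_gain_mmHg_per_mm = 5,
                                contact_gain_mmHg_per_mm = 2), "contact_gain")
  expect_error(respiration_config(direction = c(0, 0)), "non-zero")
})

test_that("default block timing matches the 3.5-minute acquisition", {
  ph <- phantom_config()
  block_s <- ph$n_frames * ph$frame_dt_s
  expect_gte(block_s, 210)
  expect_lte(block_s, 225)
  expect_equal(ph$pixel_mm, 1.56)
})

test_that("no-motion, noise-free phantom renders identical frames", {
  blk <- generate_cine(clean_phantom(64, n_frames = 4), quiet_wave(),
                       no_resp(), seed = 1)
  d <- blk$stack$data
  for (k in 2:4) expect_equal(d[, , k], d[, , 1])
  expect_equal(blk$truth$true_diameter_map[, 1],
               blk$truth$true_diameter_map[, 4])
  expect_true(all(blk$truth$true_diameter_map > 0))
})

test_that("wave train delivers freq * duration crests past a fixed node", {
  w <- wave_config(freq_cpm = 3, occlusion_frac = 0.5)
  tt <- seq(0, 59 * 3.7, by = 0.1)           # frame-grid extent, fine sampling
  g <- wave_profile(rep(60, length(tt)), tt, w)
  episodes <- rle(g > 0.5)
  n_crests <- sum(episodes$values)
  expect_gte(n_crests, 10)                    # (3/60 Hz) * 218.3 s ~ 10.9
  expect_lte(n_crests, 12)
  expect_true(all(g >= 0 & g <= 1))
})

test_that("rendered lumen width matches ground truth within one pixel", {
  blk <- .clean_block
  ph <- blk$stack$meta$phantom
  cl <- centerline(ph$axis_polyline)
  interior <- which(cl$s_mm > 10 & cl$s_mm < max(cl$s_mm) - 10)
  for (k in c(1, 17, 42)) {
    for (i in interior[c(2, 8, 14)]) {
      measured <- pixel_count_diameter(blk$stack$data[, , k], cl[i, ], ph,
                                       step_frac = 0.5)
      expect_lt(abs(measured - blk$truth$true_diameter_map[i, k]),
                ph$pixel_mm + 1e-9)
    }
  }
})

test_that("generation is bit-reproducible given the seed", {
  a <- generate_cine(clean_phantom(48, 4), wave_config(), respiration_config(),
                     seed = 7)
  b <- generate_cine(clean_phantom(48, 4), wave_config(), respiration_config(),
                     seed = 7)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$true_diameter_map, b$truth$true_diameter_map)
})

test_that("respiration displacement is recorded and applied", {
  blk <- generate_cine(clean_phantom(64, 6),
                       quiet_wave(), respiration_config(amplitude_mm = 5),
                       seed = 3)
  d <- blk$truth$displacement_px
  expect_equal(dim(d), c(6, 2))
  expect_gt(max(abs(d)), 0.5)
  # frames with different displacement differ; truth map does not
  expect_false(isTRUE(all.equal(blk$stack$data[, , 1], blk$stack$data[, , 2])))
  expect_equal(blk$truth$true_diameter_map[, 1], blk$truth$true_diameter_map[, 2])
})
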