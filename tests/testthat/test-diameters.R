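straight_axis <- function(half = 40) cbind(x = c(-half, half), y = c(0, 0))

band_mask <- function(n = 64, pixel_mm = 1.56, half_width_mm = 10) {
  y_mm <- (seq_len(n) - (n + 1) / 2) * pixel_mm
  matrix(rep(abs(y_mm) <= half_width_mm, each = n), n, n)
}

test_that("a straight 20 mm tube measures 20 mm at interior nodes", {
  masks <- replicate(12, band_mask(), simplify = FALSE)
  cl <- centerline(straight_axis(), spacing_mm = 5)
  dm <- measure_diameters(masks, cl, 1.56)
  interior <- cl$s_mm > 5 & cl$s_mm < max(cl$s_mm) - 5
  expect_true(all(abs(dm$D[interior, ] - 20) <= 1.56))
  expect_false(any(dm$flagged[interior, ]))
})

test_that("a fully occluded node reads zero and is flagged", {
  m <- band_mask()
  m[28:36, ] <- FALSE  # occlude a central stretch (x rows)
  masks <- replicate(12, m, simplify = FALSE)
  cl <- centerline(straight_axis(), spacing_mm = 5)
  dm <- measure_diameters(masks, cl, 1.56)
  mid <- which.min(abs(cl$s_mm - max(cl$s_mm) / 2))
  expect_equal(dm$D[mid, 1], 0)
  expect_true(dm$flagged[mid, 1])
})

test_that("the measured trough passes a node at the analytic crest time", {
  blk <- .clean_block
  ph <- blk$stack$meta$phantom
  res <- analyze_cine_block(blk$stack, register = FALSE)
  w <- blk$truth$true_wave_params
  lambda <- w$speed_mm_s / (w$freq_cpm / 60)
  cl <- centerline(ph$axis_polyline)
  times <- (seq_len(ph$n_frames) - 1) * ph$frame_dt_s
  for (i in c(8, 13, 18)) {
    k_min <- which.min(res$diameter_map$D[i, ])
    crest_times <- (cl$s_mm[i] %% lambda) / w$speed_mm_s +
      (0:20) * lambda / w$speed_mm_s
    expect_lt(min(abs(times[k_min] - crest_times)), ph$frame_dt_s + 1e-9)
  }
})

test_that("motility signal of a constant map is identically zero", {
  dm <- new_diameter_map(matrix(20, 5, 20), 1:5 * 5, 3.7)
  expect_equal(as.numeric(motility_signal(dm)), rep(0, 20))
})

test_that("a single dip produces one bump of depth / n_nodes", {
  D <- matrix(20, 10, 40)
  D[4, 21] <- 12  # 8 mm dip at one node, one frame
  dm <- new_diameter_map(D, 1:10 * 5, 3.7)
  cs <- motility_signal(dm)
  expect_equal(which.max(cs), 21)
  expect_equal(max(cs), 8 / 10)
  expect_equal(cs[1], 0)
})

test_that("flagged frames contribute zero contraction, not spurious depth", {
  D <- matrix(20, 5, 20)
  fl <- matrix(FALSE, 5, 20)
  D[3, 7] <- 0; fl[3, 7] <- TRUE
  dm <- new_diameter_map(D, 1:5 * 5, 3.7, flagged = fl)
  expect_equal(as.numeric(motility_signal(dm)), rep(0, 20))
})

test_that("a 3 cpm oscillation is recovered from the periodogram", {
  tt <- (0:59) * 3.7
  for (f_cpm in c(2, 3, 4)) {
    cs <- 2 + 1.5 * sin(2 * pi * f_cpm / 60 * tt)
    expect_lt(abs(estimate_frequency_cpm(cs, 3.7) - f_cpm), 0.2)
  }
})

test_that("AUC integration matches closed forms", {
  expect_equal(compute_mri_auc(rep(0, 60), 3.7)$value, 0)
  # 2 mm sustained over 210 s -> 420 mm s (rectangle)
  cs <- rep(2, round(210 / 3.7) + 1)
  expect_equal(compute_mri_auc(cs, 3.7)$value, 2 * (length(cs) - 1) * 3.7)
  # half-sine bump: integral (2/pi) * A * w
  A <- 3; w <- 74
  tt <- (0:59) * 3.7
  cs <- ifelse(tt <= w, A * sin(pi * tt / w), 0)
  expect_lt(abs(compute_mri_auc(cs, 3.7)$value - 2 * A * w / pi) / (2 * A * w / pi),
            0.01)
  expect_error(compute_mri_auc(c(1), 3.7), "2 frames")
})

test_that("diameter maps tidy to long format with units preserved", {
  dm <- new_diameter_map(matrix(c(10, 20, 30, 40), 2, 2), c(0, 5), 3.7)
  td <- tidy(dm)
  expect_equal(nrow(td), 4)
  expect_equal(td$diameter_mm, c(10, 20, 30, 40))
  expect_equal(unique(td$s_mm), c(0, 5))
})
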