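sine_trace <- function(freq_hz, amp = 1, dur_s = 400, fs = 25, base = 10) {
  tt <- seq(0, dur_s, by = 1 / fs)
  new_pressure_traces(tibble::tibble(time_s = tt,
                                     port_01 = base + amp * sin(2 * pi * freq_hz * tt)),
                      fs_hz = fs)
}

mid_amp <- function(trace) {
  x <- trace$data$port_01
  n <- length(x)
  mid <- x[round(n * 0.2):round(n * 0.8)]
  (max(mid) - min(mid)) / 2
}

test_that("the respiration band is suppressed and the contractile band kept", {
  resp <- remove_respiration(sine_trace(0.25))     # ~15 / min breathing
  expect_lt(mid_amp(resp), 0.10)
  slow <- remove_respiration(sine_trace(0.05))     # 3 / min contractions
  expect_gt(mid_amp(slow), 0.90)
  flat <- remove_respiration(sine_trace(0.25, amp = 0))
  expect_equal(flat$data$port_01, rep(10, nrow(flat$data)), tolerance = 1e-8)
  # length and timestamps preserved
  expect_equal(resp$data$time_s, sine_trace(0.25)$data$time_s)
  expect_error(remove_respiration(sine_trace(0.25, dur_s = 10)), "too short")
})

test_that("rolling-percentile baseline zeroes constants and tracks drift", {
  tt <- seq(0, 600, by = 1 / 25)
  flat <- new_pressure_traces(tibble::tibble(time_s = tt, port_01 = 5), fs_hz = 25)
  expect_equal(baseline_correct(flat)$data$port_01, rep(0, length(tt)))

  drift <- 10 * tt / 600
  spikes <- rep(0, length(tt))
  for (s0 in seq(30, 570, by = 60))
    spikes[tt >= s0 & tt < s0 + 6] <- 30
  tr <- new_pressure_traces(tibble::tibble(time_s = tt, port_01 = drift + spikes),
                            fs_hz = 25)
  bc <- baseline_correct(tr)$data$port_01
  between <- tt %% 60 >= 45 & tt %% 60 < 55 & tt > 60 & tt < 540
  expect_lt(max(abs(bc[between])), 1.0)
  # isolated spikes keep their height within 5%
  peak <- max(bc[tt >= 270 & tt < 280])
  expect_lt(abs(peak - 30) / 30, 0.05)
})

test_that("block segmentation is sample-exact and guards its windows", {
  tt <- seq(0, 900, by = 1 / 25)
  tr <- new_pressure_traces(tibble::tibble(time_s = tt, port_01 = rnorm(length(tt))),
                            fs_hz = 25)
  blocks <- segment_blocks(tr, c(0, 600), 210)
  expect_length(blocks, 2)
  expect_equal(nrow(blocks[[1]]$data), 210 * 25 + 1)
  expect_equal(blocks[[2]]$meta$block_start, 600)
  expect_identical(segment_blocks(tr, numeric(0)), list())
  expect_warning(segment_blocks(tr, c(0, 100), 210), "overlap")
  expect_error(segment_blocks(tr, c(0, 800), 210), "2")
})

test_that("port aggregation policies behave and degenerate inputs error", {
  tt <- seq(0, 210, by = 1 / 25)
  tb <- tibble::tibble(time_s = tt, port_01 = 2, port_02 = 4)
  ports <- tibble::tibble(port = 1:2, s_mm = c(10, 60), in_antrum = c(TRUE, TRUE))
  tr <- new_pressure_traces(tb, 25, ports)
  expect_equal(as.numeric(compute_mano_auc(tr, "mean_antral")), 3 * 210)
  expect_equal(as.numeric(compute_mano_auc(tr, "max_activity")), 4 * 210)
  expect_equal(as.numeric(compute_mano_auc(tr, 1L)), 2 * 210)
  # single constant 2 mmHg port over 210 s -> 420 mmHg s
  expect_equal(as.numeric(compute_mano_auc(tr, 1L)), 420)
  none <- new_pressure_traces(tb, 25,
                              tibble::tibble(port = 1:2, s_mm = c(-10, -60),
                                             in_antrum = FALSE))
  expect_error(compute_mano_auc(none), "in-antrum")
  zero <- new_pressure_traces(dplyr::mutate(tb, port_01 = 0, port_02 = 0), 25, ports)
  expect_equal(as.numeric(compute_mano_auc(zero)), 0)
})

test_that("the pipeline AUC tracks the generative integral", {
  blk <- generate_cine(clean_phantom(96), wave_config(occlusion_frac = 0.5),
                       no_resp(), seed = 41)
  mano <- manometry_config(resp_artifact_mmHg = 0, noise_sd_mmHg = 0)
  tr <- generate_pressure(blk$truth$true_wave_params, mano, blk$truth, seed = 41)
  truth <- tr$meta$true_block_auc_mano
  got <- mano_pipeline(tr)$mano_auc
  expect_lt(abs(got - truth) / truth, 0.05)
})

test_that("quiescent traces integrate far below active ones", {
  mano <- manometry_config()
  blk_a <- generate_cine(clean_phantom(96), wave_config(occlusion_frac = 0.5),
                         no_resp(), seed = 42)
  blk_q <- generate_cine(clean_phantom(96), quiet_wave(), no_resp(), seed = 42)
  auc_a <- mano_pipeline(generate_pressure(blk_a$truth$true_wave_params, mano,
                                           blk_a$truth, seed = 1))$mano_auc
  auc_q <- mano_pipeline(generate_pressure(quiet_wave(), mano,
                                           blk_q$truth, seed = 1))$mano_auc
  expect_lt(auc_q, 0.10 * auc_a)
})

test_that("filtering and baseline correction are idempotent to tolerance", {
  blk <- generate_cine(clean_phantom(96), wave_config(occlusion_frac = 0.5),
                       no_resp(), seed = 43)
  tr <- generate_pressure(blk$truth$true_wave_params, manometry_config(),
                          blk$truth, seed = 43)
  once <- baseline_correct(remove_respiration(tr))
  twice <- baseline_correct(remove_respiration(once))
  auc1 <- compute_mano_auc(segment_blocks(once, 0, 210)[[1]])
  auc2 <- compute_mano_auc(segment_blocks(twice, 0, 210)[[1]])
  expect_lt(abs(auc2 - auc1) / auc1, 0.02)
})
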