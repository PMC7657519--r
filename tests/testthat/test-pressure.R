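test_that("quiescent, artifact-free trace is constant at baseline", {
  blk <- generate_cine(clean_phantom(64, 60), quiet_wave(), no_resp(), seed = 1)
  mano <- manometry_config(resp_artifact_mmHg = 0, noise_sd_mmHg = 0)
  tr <- generate_pressure(quiet_wave(), mano, blk$truth, seed = 1)
  for (p in tr$ports$port[tr$ports$in_antrum])
    expect_equal(tr$data[[sprintf("port_%02d", p)]],
                 rep(mano$baseline_mmHg, nrow(tr$data)))
})

test_that("two-regime transduction is continuous and steepens on contact", {
  mano <- manometry_config()
  thr <- mano$occlusion_threshold_mm
  d <- seq(20, 0, by = -0.1)
  p <- transduce_pressure(d, 20, mano)
  expect_equal(transduce_pressure(thr + 1e-9, 20, mano),
               transduce_pressure(thr - 1e-9, 20, mano), tolerance = 1e-6)
  # hydro-only extrapolation under-predicts once the port is in contact
  hydro_only <- mano$baseline_mmHg + mano$hydro_gain_mmHg_per_mm * (20 - d)
  expect_true(all(p[d < thr] > hydro_only[d < thr]))
  # piecewise formula evaluated pointwise
  i <- which(d < thr)[5]
  expect_equal(p[i],
               mano$baseline_mmHg +
                 mano$hydro_gain_mmHg_per_mm * (20 - thr) +
                 mano$contact_gain_mmHg_per_mm * (thr - d[i]))
})

test_that("contact regime raises peak pressure above the hydro prediction", {
  ph <- clean_phantom(64, 60)
  blk <- generate_cine(ph, wave_config(occlusion_frac = 0.85), no_resp(), seed = 2)
  mano <- manometry_config(resp_artifact_mmHg = 0, noise_sd_mmHg = 0)
  tr <- generate_pressure(blk$truth$true_wave_params, mano, blk$truth, seed = 2)
  hydro_only <- manometry_config(resp_artifact_mmHg = 0, noise_sd_mmHg = 0,
                                 contact_gain_mmHg_per_mm = mano$hydro_gain_mmHg_per_mm)
  tr0 <- generate_pressure(blk$truth$true_wave_params, hydro_only, blk$truth, seed = 2)
  pcols <- sprintf("port_%02d", tr$ports$port[tr$ports$in_antrum])
  peak <- max(as.matrix(tr$data[pcols]))
  expect_gt(peak, max(as.matrix(tr0$data[pcols])))
  expect_gt(peak, 35)  # mucosal contact pressures exceed the 15-35 mmHg band
})

test_that("pressure AUC increases strictly with occlusion depth", {
  ph <- clean_phantom(64, 60)
  mano <- manometry_config(resp_artifact_mmHg = 0, noise_sd_mmHg = 0)
  aucs <- vapply(c(0.3, 0.8), function(o) {
    blk <- generate_cine(ph, wave_config(occlusion_frac = o), no_resp(), seed = 3)
    tr <- generate_pressure(blk$truth$true_wave_params, mano, blk$truth, seed = 3)
    pcols <- sprintf("port_%02d", tr$ports$port[tr$ports$in_antrum])
    sum(colSums(as.matrix(tr$data[pcols]) - mano$baseline_mmHg)) / mano$fs_hz
  }, numeric(1))
  expect_gt(aucs[2], aucs[1])
})

test_that("out-of-antrum ports emit baseline plus noise only", {
  blk <- generate_cine(clean_phantom(64, 60), wave_config(occlusion_frac = 0.8),
                       no_resp(), seed = 4)
  mano <- manometry_config(resp_artifact_mmHg = 0, noise_sd_mmHg = 0.3)
  tr <- generate_pressure(blk$truth$true_wave_params, mano, blk$truth, seed = 4)
  outside <- tr$ports$port[!tr$ports$in_antrum]
  expect_gt(length(outside), 0)
  x <- tr$data[[sprintf("port_%02d", outside[1])]]
  expect_lt(max(abs(x - mano$baseline_mmHg)), 5 * 0.3 + 0.5)
})

test_that("trace regeneration is bit-identical for a fixed seed", {
  blk <- generate_cine(clean_phantom(48, 60), wave_config(), no_resp(), seed = 5)
  t1 <- generate_pressure(wave_config(), manometry_config(), blk$truth, seed = 9)
  t2 <- generate_pressure(wave_config(), manometry_config(), blk$truth, seed = 9)
  expect_identical(t1$data, t2$data)
})
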