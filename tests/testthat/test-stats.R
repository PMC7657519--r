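test_that("pearson correlation matches hand-expanded values and contracts", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)
  # hand expansion: cov = 5.5/3, var_x = 5/3, var_y = 8.75/3
  expect_equal(pearson_r(1:4, c(1, 3, 2, 5)), 5.5 / sqrt(5 * 8.75))
  expect_error(pearson_r(1:5, rep(2, 5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "3 complete pairs")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("subject means correlate perfectly for linearly scaled subjects", {
  tbl <- tibble::tibble(subject = rep(1:5, each = 4), visit = 1,
                        mri_auc = rep(1:5, each = 4) * 100 + rep(c(-5, 5, -5, 5), 5),
                        mano_auc = rep(1:5, each = 4) * 150 + rep(c(3, -3, 3, -3), 5))
  sm <- subject_mean_correlation(tbl)
  expect_equal(sm$r, 1)
  expect_equal(nrow(sm$means), 5)
  expect_true(all(is.finite(sm$means$mri_sem)))
  # a single-block subject keeps its mean but loses the SEM
  tbl1 <- dplyr::bind_rows(tbl, tibble::tibble(subject = 6, visit = 1,
                                               mri_auc = 700, mano_auc = 1000))
  sm1 <- subject_mean_correlation(tbl1)
  expect_true(is.na(sm1$means$mri_sem[sm1$means$subject == 6]))
  expect_equal(sm1$means$mri_mean[sm1$means$subject == 6], 700)
})

test_that("shuffling decouples the modalities below the permutation bound", {
  tbl <- simulate_mixed_study(seed = 51)
  set.seed(52)
  r_null <- replicate(200, pearson_r(tbl$mri_auc, sample(tbl$mano_auc)))
  bound <- quantile(abs(r_null), 0.95)
  set.seed(53)
  r_shuf <- pearson_r(tbl$mri_auc, sample(tbl$mano_auc))
  expect_lt(abs(r_shuf), bound + 1e-12)
  expect_gt(pearson_r(tbl$mri_auc, tbl$mano_auc), bound)
})

test_that("low-noise linear truth is recovered with near-zero variance components", {
  tbl <- simulate_mixed_study(sd_subject = 0, sd_visit = 0, sd_slope = 0,
                              sigma = 20, seed = 54)
  f <- fit_mixed(tbl, "linear")
  est <- tidy(f)
  expect_lt(abs(est$estimate[2] - 320) / 320, 0.05)
  vc <- f$varcomp$sd[f$varcomp$term != "Residual "]
  expect_true(all(vc < 0.1 * 320))
})

test_that("duplicating every row leaves the fixed effects unchanged", {
  tbl <- simulate_mixed_study(n_subjects = 8, blocks_per_visit = 6, seed = 55)
  f1 <- fit_mixed(tbl, "linear")
  f2 <- fit_mixed(dplyr::bind_rows(tbl, tbl), "linear")
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 0.02)
})

test_that("spline fit dominates the linear fit on convex-truth data", {
  mf <- coupling_mean_fun(clean_phantom(64))
  tbl <- simulate_mixed_study(mean_fun = mf, seed = 56)
  fl <- fit_mixed(tbl, "linear")
  fs <- fit_mixed(tbl, "natural_spline")
  expect_gt(fs$logLik, fl$logLik)
  expect_equal(fs$fixed_df - fl$fixed_df, 3)
  out <- lrt_nonlinearity(fl, fs)
  expect_gte(out$chi2, 0)
  expect_lt(out$p, 0.05)
})

test_that("the LRT clips at zero and enforces its preconditions", {
  fake <- function(basis, ll, df, n = 100, reml = FALSE)
    structure(list(basis = basis, logLik = ll, fixed_df = df, n = n,
                   REML = reml), class = "stmm_mixed_fit")
  out <- lrt_nonlinearity(fake("linear", -50, 2), fake("natural_spline", -50, 5))
  expect_equal(out$chi2, 0)
  expect_equal(out$p, 1)
  expect_equal(out$df, 3)
  # p decreases as chi2 grows
  out2 <- lrt_nonlinearity(fake("linear", -60, 2), fake("natural_spline", -50, 5))
  expect_lt(out2$p, out$p)
  expect_error(lrt_nonlinearity(fake("natural_spline", -50, 5),
                                fake("linear", -50, 2)), "in that order")
  expect_error(lrt_nonlinearity(fake("linear", -50, 2, reml = TRUE),
                                fake("natural_spline", -45, 5)), "ML fits")
  expect_error(lrt_nonlinearity(fake("linear", -50, 2, n = 50),
                                fake("natural_spline", -45, 5)), "same data")
})

test_that("iid correlation SE follows the Fisher-z closed form", {
  p12 <- se_correlation_iid(12, reps = 4000, seed = 61)
  expect_equal(atanh(p12$se_fisher_z), 1 / 3)
  mc_err <- 3 * p12$se / sqrt(2 * (p12$reps - 1))
  expect_lt(abs(p12$se - p12$se_fisher_z), 0.02 + mc_err)
  big <- se_correlation_iid(10000, reps = 60, seed = 62)
  expect_lt(big$se, 0.02)
})

test_that("the autocorrelated design collapses to iid and inflates with rho", {
  p0 <- se_correlation_kronecker(10, 200, rho_within = 0, reps = 1500, seed = 63)
  expect_lt(abs(p0$se - 1 / sqrt(200 - 10)), 0.006)
  p9 <- se_correlation_kronecker(10, 200, rho_within = 0.9, reps = 1500, seed = 63)
  expect_gt(p9$se, p0$se)
  expect_error(se_correlation_kronecker(10, 200, rho_within = 1.2),
               "positive-definite")
  expect_error(se_correlation_kronecker(10, 200, reps = 1), "replicates")
})

test_that("time-course aggregation flags sparse points and tracks the drink", {
  tbl <- tibble::tibble(subject = rep(1:4, each = 3), visit = 1,
                        time_index = rep(1:3, 4),
                        mri_auc = rep(c(10, 20, 30), 4),
                        mano_auc = rep(c(5, 15, 25), 4))
  tc <- aggregate_timecourse(tbl)
  expect_true(all(tc$sd == 0))
  expect_false(any(tc$flagged))
  cfg <- study_config(n_subjects = 6, blocks_per_subject_visit = 8,
                      drink_event_index = 4, seed = 64)
  tt <- generate_study(cfg, phantom = clean_phantom(64), render = "none")$table
  tc2 <- aggregate_timecourse(tt, "true_mri_auc", "true_mano_auc")
  mri <- dplyr::filter(tc2, .data$modality == "mri")
  expect_gt(mean(mri$mean[mri$time_index >= 4]),
            mean(mri$mean[mri$time_index < 4]) + 1)
})

test_that("non-occlusive post-drink blocks lift MRI above scaled manometry", {
  cfg <- study_config(n_subjects = 8, blocks_per_subject_visit = 8,
                      drink_event_index = 4, n_early_blocks = 2,
                      baseline_active_prob = 0, seed = 65)
  tt <- generate_study(cfg, phantom = clean_phantom(64), render = "none")$table
  tc <- aggregate_timecourse(tt, "true_mri_auc", "true_mano_auc") |>
    dplyr::group_by(.data$modality) |>
    dplyr::mutate(scaled = .data$mean / mean(.data$mean)) |>
    dplyr::ungroup()
  early <- dplyr::filter(tc, .data$time_index == 4)
  expect_gt(early$scaled[early$modality == "mri"],
            early$scaled[early$modality == "mano"])
})
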