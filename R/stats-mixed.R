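#' Mixed-effects conditional-mean model of MRI AUC on manometry AUC
#'
#' Fits the MRI block AUC on a basis of the (standardised) manometry block
#' AUC with random intercepts for subject and for visit-within-subject, and a
#' random subject slope on the linear term. The basis is either linear or a
#' natural cubic spline with `spline_df` degrees of freedom (default 4: three
#' interior knots at quantiles of the predictor, i.e. exactly 3 fixed-effect
#' degrees of freedom more than the linear model, with the random-effects
#' structure held identical so the two fits are nested for a likelihood-ratio
#' test). Maximum likelihood is used by default so log-likelihoods of models
#' with different fixed effects are comparable; set `REML = TRUE` when only
#' variance components are of interest.
#'
#' @param tbl Study table with columns `subject`, `visit`, and the two AUC
#'   columns.
#' @param basis `"linear"` or `"natural_spline"`.
#' @param mri_col,mano_col AUC column names.
#' @param spline_df Degrees of freedom of the natural-spline basis.
#' @param REML Use REML instead of ML.
#' @return An `stmm_mixed_fit`: the `lme4` fit plus basis metadata,
#'   standardisation constants, and convenience accessors via [tidy()] /
#'   [glance()].
#' @export
fit_mixed <- function(tbl, basis = c("linear", "natural_spline"),
                      mri_col = "mri_auc", mano_col = "mano_auc",
                      spline_df = 4, REML = FALSE) {
  basis <- match.arg(basis)
  stopifnot(all(c("subject", "visit", mri_col, mano_col) %in% names(tbl)))
  if (dplyr::n_distinct(tbl$subject) < 2)
    abort("Mixed model needs at least 2 subjects.")
  d <- tibble(y = tbl[[mri_col]],
              subject = factor(tbl$subject),
              sv = interaction(tbl$subject, tbl$visit, drop = TRUE))
  mu <- mean(tbl[[mano_col]]); sdev <- sd(tbl[[mano_col]])
  if (sdev == 0) abort("Manometry AUC is constant; model is unidentified.")
  d$x <- (tbl[[mano_col]] - mu) / sdev
  form <- if (basis == "linear") {
    y ~ x + (1 | subject) + (0 + x | subject) + (1 | sv)
  } else {
    d$B <- splines::ns(d$x, df = spline_df)
    y ~ B + (1 | subject) + (0 + x | subject) + (1 | sv)
  }
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- withCallingHandlers(
    lme4::lmer(form, data = d, REML = REML, control = ctrl),
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w)))
        abort(paste("Mixed model did not converge:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fit = fit,
                 basis = basis, spline_df = if (basis == "linear") NA else spline_df,
                 fixed_df = length(lme4::fixef(fit)),
                 REML = REML, logLik = as.numeric(logLik(fit)),
                 n = nrow(d),
                 center = mu, scale = sdev,
                 varcomp = tibble(term = paste(vc$grp, ifelse(is.na(vc$var1), "", vc$var1)),
                                  sd = vc$sdcor)),
            class = "stmm_mixed_fit")
}

#' @export
print.stmm_mixed_fit <- function(x, ...) {
  cat(sprintf("<stmm_mixed_fit> %s basis, %s, n = %d, logLik = %.1f\n",
              x$basis, if (x$REML) "REML" else "ML", x$n, x$logLik))
  print(x$varcomp)
  invisible(x)
}

#' @describeIn fit_mixed Fixed-effect coefficients as a tibble.
#' @param x An `stmm_mixed_fit`.
#' @param ... Unused.
#' @method tidy stmm_mixed_fit
#' @export
tidy.stmm_mixed_fit <- function(x, ...) {
  fe <- lme4::fixef(x$fit)
  se <- sqrt(diag(as.matrix(stats::vcov(x$fit))))
  tibble(term = names(fe), estimate = as.numeric(fe), std.error = se,
         statistic = as.numeric(fe) / se)
}

#' @describeIn fit_mixed One-row model summary.
#' @method glance stmm_mixed_fit
#' @export
glance.stmm_mixed_fit <- function(x, ...) {
  tibble(basis = x$basis, nobs = x$n, logLik = x$logLik,
         df_fixed = x$fixed_df, REML = x$REML,
         sigma = stats::sigma(x$fit))
}

#' Likelihood-ratio test for a non-linear conditional mean
#'
#' Compares the natural-spline fit against the nested linear fit (same
#' random-effects structure, ML estimation, 3 extra fixed-effect degrees of
#' freedom by default). The statistic is clipped at zero; the p-value comes
#' from the chi-square reference distribution.
#'
#' @param fit_lin Linear-basis `stmm_mixed_fit` (ML).
#' @param fit_spline Natural-spline `stmm_mixed_fit` (ML).
#' @return A tibble with `chi2`, `df`, `p`.
#' @export
lrt_nonlinearity <- function(fit_lin, fit_spline) {
  stopifnot(inherits(fit_lin, "stmm_mixed_fit"),
            inherits(fit_spline, "stmm_mixed_fit"))
  if (fit_lin$basis != "linear" || fit_spline$basis != "natural_spline")
    abort("Expected a linear fit and a natural-spline fit, in that order.")
  if (fit_lin$REML || fit_spline$REML)
    abort("Likelihood-ratio comparison requires ML fits (REML = FALSE).")
  if (fit_lin$n != fit_spline$n)
    abort("Fits were not computed on the same data.")
  df <- fit_spline$fixed_df - fit_lin$fixed_df
  if (df < 1) abort("Spline fit does not nest the linear fit.")
  chi2 <- max(0, 2 * (fit_spline$logLik - fit_lin$logLik))
  tibble(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Simulate a study table from a linear mixed model
#'
#' Parametric generator used for calibration and parameter-recovery checks:
#' manometry AUCs are drawn from a quiescent/active mixture resembling the
#' phantom study, and MRI AUCs follow `mean_fun` of the standardised
#' manometry AUC plus subject intercepts, visit-within-subject intercepts,
#' subject slopes and residual noise.
#'
#' @param n_subjects,n_visits,blocks_per_visit Study layout.
#' @param intercept,slope Fixed effects (response units; slope per SD of the
#'   predictor).
#' @param sd_subject,sd_visit,sd_slope,sigma Random-effect and residual SDs.
#' @param mean_fun Optional function of the standardised predictor replacing
#'   the linear mean `intercept + slope * x` (used for non-linear truth).
#' @param active_prob,active_meanlog,active_sdlog,quiescent_sd Parameters of
#'   the manometry AUC mixture.
#' @param n_extra Extra blocks appended to the last subject's last visit
#'   (to reproduce uneven designs).
#' @param seed Integer seed.
#' @return A tibble with `subject`, `visit`, `block`, `mano_auc`, `mri_auc`.
#' @export
simulate_mixed_study <- function(n_subjects = 15, n_visits = 2,
                                 blocks_per_visit = 14,
                                 intercept = 400, slope = 320,
                                 sd_subject = 120, sd_visit = 60,
                                 sd_slope = 48, sigma = 160,
                                 mean_fun = NULL,
                                 active_prob = 0.7, active_meanlog = log(1500),
                                 active_sdlog = 0.5, quiescent_sd = 40,
                                 n_extra = 1, seed = 1L) {
  set.seed(seed)
  d <- study_layout(study_config(n_subjects = n_subjects, n_visits = n_visits,
                                 blocks_per_subject_visit = blocks_per_visit,
                                 n_total_blocks =
                                   n_subjects * n_visits * blocks_per_visit + n_extra))
  n <- nrow(d)
  act <- runif(n) < active_prob
  mano <- ifelse(act, exp(rnorm(n, active_meanlog, active_sdlog)),
                 abs(rnorm(n, 0, quiescent_sd)))
  x <- as.numeric(scale(mano))
  u <- rnorm(n_subjects, 0, sd_subject)[d$subject]
  vkey <- (d$subject - 1) * n_visits + d$visit
  v <- rnorm(n_subjects * n_visits, 0, sd_visit)[vkey]
  s <- rnorm(n_subjects, 0, sd_slope)[d$subject]
  mu <- if (is.null(mean_fun)) intercept + slope * x else mean_fun(x)
  tibble(subject = d$subject, visit = d$visit, block = d$block,
         time_index = d$time_index,
         mano_auc = mano,
         mri_auc = mu + u + v + s * x + rnorm(n, 0, sigma))
}

#' Non-linear conditional mean implied by the two-regime pressure coupling
#'
#' Maps the analytic (manometry AUC, MRI AUC) coupling curve of the phantom
#' model -- evaluated over a grid of occlusion fractions -- into a mean
#' function of the standardised manometry AUC, rescaled to a given response
#' range. Because the contact regime makes pressure grow faster than diameter
#' loss at high occlusion, MRI AUC is a concave function of manometry AUC;
#' this is the generative analogue of the non-linearity seen in paired data.
#'
#' @param phantom,mano,wave_template Module configurations.
#' @param occ_grid Occlusion fractions spanning quiescence to near-occlusion.
#' @param response_range Range (response units) to which the MRI arm of the
#'   curve is scaled.
#' @return A function mapping the standardised predictor to a mean response;
#'   the underlying curve is attached as attribute `curve`.
#' @export
coupling_mean_fun <- function(phantom = phantom_config(),
                              mano = manometry_config(),
                              wave_template = wave_config(),
                              occ_grid = seq(0, 0.9, by = 0.1),
                              response_range = c(0, 1200)) {
  curve <- purrr::map_dfr(occ_grid, function(o) {
    w <- wave_config(freq_cpm = wave_template$freq_cpm,
                     speed_mm_s = wave_template$speed_mm_s,
                     occlusion_frac = o, width_mm = wave_template$width_mm,
                     active = o > 0)
    a <- true_block_aucs(phantom, w, mano)
    tibble(occlusion = o, mri_auc = a$mri_auc, mano_auc = a$mano_auc)
  })
  # standardise the manometry arm; rescale the MRI arm to the requested range
  xs <- (curve$mano_auc - mean(curve$mano_auc)) / sd(curve$mano_auc)
  ys <- response_range[1] +
    (curve$mri_auc - min(curve$mri_auc)) /
      diff(range(curve$mri_auc)) * diff(response_range)
  f <- function(x) approx(xs, ys, x, rule = 2)$y
  attr(f, "curve") <- curve
  f
}
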