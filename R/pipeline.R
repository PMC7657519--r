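#' Image-side analysis of one acquisition block
#'
#' The full spatio-temporal motility chain on a single cine block: rigid
#' respiratory motion correction, initial lumen contour on the first frame,
#' contour propagation, perpendicular diameter measurement along the axis,
#' reduction to the contraction signal and the per-block motility AUC.
#'
#' @param stack A `cine_stack`. If it was produced by [generate_cine()], the
#'   axis polyline is taken from its metadata; otherwise supply `axis_mm`.
#' @param axis_mm Optional axis polyline (mm, image-centred) for non-phantom
#'   data.
#' @param hint Initial-contour hint (see [initial_contour()]).
#' @param register Run motion correction (disable for already-corrected
#'   stacks).
#' @param node_spacing_mm Centerline node spacing, mm.
#' @return A list: `mri_auc` (mm s), `diameter_map`, `signal` (mm per frame),
#'   `frequency_cpm`, `shifts` (displacement series or `NULL`),
#'   `flagged_frames`.
#' @export
analyze_cine_block <- function(stack, axis_mm = NULL, hint = "auto",
                               register = TRUE, node_spacing_mm = 5) {
  stopifnot(inherits(stack, "cine_stack"))
  if (is.null(axis_mm)) {
    ph <- stack$meta$phantom
    if (is.null(ph)) abort("No axis available: supply `axis_mm`.")
    axis_mm <- ph$axis_polyline
  }
  shifts <- NULL
  if (register) {
    mc <- correct_motion(stack)
    stack <- mc$stack
    shifts <- mc$shifts
  }
  m0 <- initial_contour(stack$data[, , 1], hint)
  masks <- propagate_contours(stack, m0)
  axis <- centerline(axis_mm, spacing_mm = node_spacing_mm)
  dm <- measure_diameters(masks, axis, stack$pixel_mm, stack = stack)
  dm$frame_dt_s <- stack$frame_dt_s
  sig <- motility_signal(dm)
  list(mri_auc = compute_mri_auc(sig, stack$frame_dt_s)$value,
       diameter_map = dm, signal = sig,
       frequency_cpm = estimate_frequency_cpm(sig, stack$frame_dt_s),
       shifts = shifts,
       flagged_frames = attr(masks, "flagged_frames"))
}

#' Measure a whole simulated study
#'
#' Runs the image-side chain (when cine stacks were rendered) and the
#' manometry chain (respiration filter, baseline correction, AUC) on every
#' block of a [generate_study()] result and returns the study table extended
#' with the measured `mri_auc` and `mano_auc`. Blocks without rendered images
#' get a missing `mri_auc`.
#'
#' @param sim Result of [generate_study()] with `render = "traces"` or
#'   `"full"`.
#' @param port_policy Channel aggregation for the manometry AUC.
#' @param register Run motion correction on each block.
#' @return The study tibble with measured `mri_auc` and `mano_auc` columns.
#' @export
analyze_study <- function(sim, port_policy = "mean_antral", register = TRUE) {
  if (is.null(sim$blocks))
    abort("Study was generated with render = \"none\"; nothing to measure.")
  res <- purrr::map(sim$blocks, function(bl) {
    mri <- if (!is.null(bl$stack)) {
      analyze_cine_block(bl$stack, register = register)$mri_auc
    } else NA_real_
    mano <- mano_pipeline(bl$traces, port_policy = port_policy)$mano_auc[1]
    c(mri = mri, mano = mano)
  })
  dplyr::mutate(sim$table,
                mri_auc = vapply(res, `[[`, numeric(1), "mri"),
                mano_auc = vapply(res, `[[`, numeric(1), "mano"))
}

#' Validation report for a measured study table
#'
#' The statistical read-out of a paired study: pooled and per-subject-mean
#' Pearson correlations, linear and natural-spline mixed-effects fits with
#' the non-linearity likelihood-ratio test, and the aggregated time courses.
#'
#' @param tbl Study table with `subject`, `visit`, `time_index`, `mri_auc`,
#'   `mano_auc`.
#' @param spline_df Spline degrees of freedom for the non-linear fit.
#' @return A `validation_report` list: `r_pooled`, `r_subject_mean`,
#'   `subject_means`, `fit_linear`, `fit_spline`, `lrt`, `timecourse`, `n`.
#' @export
validation_report <- function(tbl, spline_df = 4) {
  keep <- stats::complete.cases(tbl$mri_auc, tbl$mano_auc)
  tbl <- tbl[keep, ]
  pooled <- tryCatch(pearson_r(tbl$mri_auc, tbl$mano_auc),
                     error = function(e) NA_real_)
  sm <- tryCatch(subject_mean_correlation(tbl),
                 error = function(e) list(r = NA_real_, means = NULL))
  fits <- tryCatch({
    fl <- fit_mixed(tbl, "linear")
    fs <- fit_mixed(tbl, "natural_spline", spline_df = spline_df)
    list(lin = fl, spl = fs, lrt = lrt_nonlinearity(fl, fs))
  }, error = function(e) list(lin = NULL, spl = NULL, lrt = NULL,
                              error = conditionMessage(e)))
  structure(list(n = nrow(tbl), r_pooled = pooled, r_subject_mean = sm$r,
                 subject_means = sm$means,
                 fit_linear = fits$lin, fit_spline = fits$spl, lrt = fits$lrt,
                 fit_error = fits$error,
                 timecourse = aggregate_timecourse(tbl)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n = %d blocks\n", x$n))
  cat(sprintf("  pooled r        = %.3f\n", x$r_pooled))
  cat(sprintf("  subject-mean r  = %.3f\n", x$r_subject_mean))
  if (!is.null(x$lrt))
    cat(sprintf("  non-linearity LRT: chi2(%d) = %.1f, p = %.3g\n",
                x$lrt$df, x$lrt$chi2, x$lrt$p))
  invisible(x)
}

#' Flatten a validation report for JSON export
#'
#' @param report A `validation_report`.
#' @return A plain nested list of scalars and data frames.
#' @export
report_as_list <- function(report) {
  list(n = report$n, r_pooled = report$r_pooled,
       r_subject_mean = report$r_subject_mean,
       lrt = if (!is.null(report$lrt)) as.list(report$lrt),
       fit_linear = if (!is.null(report$fit_linear))
         list(coef = tidy(report$fit_linear), varcomp = report$fit_linear$varcomp),
       fit_spline = if (!is.null(report$fit_spline))
         list(coef = tidy(report$fit_spline), varcomp = report$fit_spline$varcomp),
       timecourse = report$timecourse)
}

#' One-command phantom validation study
#'
#' Simulates a study, writes it to disk (NIfTI stacks when rendered, traces,
#' truth table, config provenance), measures it, and writes the measured
#' table plus the JSON statistics report. This is the programmatic engine
#' behind the command-line wrapper.
#'
#' @param out_dir Output directory (created if missing).
#' @param cfg A [study_config()].
#' @param phantom,mano,resp,wave_template Module configurations.
#' @param render What to render per block (see [generate_study()]).
#' @param write_stacks Also write each rendered cine block as NIfTI.
#' @return The `validation_report`, invisibly; files under `out_dir`.
#' @export
run_validation_study <- function(out_dir, cfg = study_config(),
                                 phantom = phantom_config(),
                                 mano = manometry_config(),
                                 resp = respiration_config(),
                                 wave_template = wave_config(),
                                 render = "full", write_stacks = FALSE) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    inform(paste("Created output directory", out_dir))
  }
  sim <- generate_study(cfg, phantom, mano, resp, wave_template, render = render)
  write_study_csv(sim$table, file.path(out_dir, "truth_table.csv"))
  write_config_json(sim$configs, file.path(out_dir, "run_config.json"))
  if (!is.null(sim$blocks)) {
    for (b in seq_along(sim$blocks)) {
      bl <- sim$blocks[[b]]
      write_pressure_csv(bl$traces,
                         file.path(out_dir, sprintf("block_%03d_pressure.csv", b)))
      if (write_stacks && !is.null(bl$stack))
        write_cine_nifti(bl$stack,
                         file.path(out_dir, sprintf("block_%03d_cine.nii.gz", b)))
    }
    tbl <- analyze_study(sim)
    write_study_csv(tbl, file.path(out_dir, "measured_table.csv"))
    rep <- validation_report(tbl)
    jsonlite::write_json(report_as_list(rep),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         dataframe = "rows")
    return(invisible(rep))
  }
  invisible(NULL)
}

#' Design-stage power table
#'
#' The two design calculations for a paired-modality validation study: the
#' precision of a per-subject-means correlation, and the precision of the
#' time-resolved between-modality correlation under within-modality
#' autocorrelation.
#'
#' @param n_subjects Subjects in the design.
#' @param n_total Total time-resolved paired observations.
#' @param rho_within Within-modality AR(1) autocorrelation.
#' @param reps_iid,reps_kron Monte-Carlo replicates for each design.
#' @param seed Integer seed.
#' @return A tibble, one row per design, via [tidy()].
#' @export
power_table <- function(n_subjects = 15, n_total = 421, rho_within = 0.5,
                        reps_iid = 10000, reps_kron = 2000, seed = 1L) {
  dplyr::bind_rows(
    tidy(se_correlation_iid(n_subjects, reps = reps_iid, seed = seed)),
    tidy(se_correlation_kronecker(n_subjects, n_total, rho_within,
                                  reps = reps_kron, seed = seed + 1L)))
}
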