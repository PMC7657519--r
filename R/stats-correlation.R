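#' Pearson correlation with explicit degenerate-input contract
#'
#' Product-moment correlation of two equal-length vectors; errors (rather than
#' returning `NA`) on constant input or fewer than 3 pairs, so degenerate
#' study tables fail loudly.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
#' @examples
#' pearson_r(1:4, c(1, 3, 2, 5))
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("Need at least 3 complete pairs.")
  if (var(x) == 0 || var(y) == 0)
    abort("Correlation undefined for constant input.")
  cor(x, y)
}

#' Per-subject mean agreement between modalities
#'
#' Averages each subject's block AUCs (optionally within one visit), computes
#' the Pearson correlation of the per-subject MRI and manometry means, and
#' reports per-subject SEMs. Subjects contributing a single block keep their
#' mean with a missing SEM.
#'
#' @param tbl Study table with columns `subject`, `visit`, and the two AUC
#'   columns.
#' @param mri_col,mano_col Names of the AUC columns.
#' @param visit Optional visit to restrict to (pooled across visits when
#'   `NULL`).
#' @return List: `r` (correlation of the means) and `means`, a tibble with
#'   per-subject `mri_mean`, `mri_sem`, `mano_mean`, `mano_sem`, `n_blocks`.
#' @export
subject_mean_correlation <- function(tbl, mri_col = "mri_auc",
                                     mano_col = "mano_auc", visit = NULL) {
  stopifnot(all(c("subject", mri_col, mano_col) %in% names(tbl)))
  if (!is.null(visit)) tbl <- dplyr::filter(tbl, .data$visit == !!visit)
  sem <- function(v) if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
  means <- tbl |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(mri_mean = mean(.data[[mri_col]]),
                     mri_sem = sem(.data[[mri_col]]),
                     mano_mean = mean(.data[[mano_col]]),
                     mano_sem = sem(.data[[mano_col]]),
                     n_blocks = dplyr::n(), .groups = "drop")
  if (nrow(means) < 3) abort("Need at least 3 subjects.")
  list(r = pearson_r(means$mri_mean, means$mano_mean), means = means)
}

#' Aggregate block AUCs into study time courses
#'
#' Mean, SD and subject count of both modalities at each within-visit time
#' index, pooled over subjects and visits -- the study-level time-course view
#' of motility before and after the drink event. Time points contributed by
#' fewer than 2 subjects are flagged.
#'
#' @inheritParams subject_mean_correlation
#' @param time_col Column holding the within-visit time index.
#' @return A tibble: `time_index`, `modality`, `mean`, `sd`, `n_subjects`,
#'   `flagged`.
#' @export
aggregate_timecourse <- function(tbl, mri_col = "mri_auc",
                                 mano_col = "mano_auc",
                                 time_col = "time_index") {
  stopifnot(all(c("subject", time_col, mri_col, mano_col) %in% names(tbl)))
  long <- tidyr::pivot_longer(
    dplyr::select(tbl, "subject", time_index = dplyr::all_of(time_col),
                  mri = dplyr::all_of(mri_col), mano = dplyr::all_of(mano_col)),
    c("mri", "mano"), names_to = "modality", values_to = "auc")
  long |>
    dplyr::group_by(.data$time_index, .data$modality) |>
    dplyr::summarise(mean = mean(.data$auc), sd = sd(.data$auc),
                     n_subjects = dplyr::n_distinct(.data$subject),
                     .groups = "drop") |>
    dplyr::mutate(flagged = .data$n_subjects < 2)
}
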