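#' Analytic per-block AUCs of the phantom model
#'
#' Evaluates the noise-free wall-motion model directly: the MRI motility AUC
#' from the ground-truth diameter map on the node/frame grid, and the
#' manometry AUC by transducing the analytic diameter series at each in-antrum
#' port on a fine time grid. No images or traces are rendered, so whole-study
#' truth tables are cheap.
#'
#' @param phantom A [phantom_config()].
#' @param wave A [wave_config()].
#' @param mano A [manometry_config()].
#' @param node_spacing_mm Node spacing of the truth diameter map, mm.
#' @param fine_dt_s Time step of the manometry-side integration, seconds.
#' @return Named list: `mri_auc` (mm s), `mano_auc` (mmHg s).
#' @export
true_block_aucs <- function(phantom, wave, mano, node_spacing_mm = 5,
                            fine_dt_s = 0.04) {
  cl <- centerline(phantom$axis_polyline, spacing_mm = node_spacing_mm)
  times <- frame_times(phantom)
  tdm <- outer(cl$s_mm, times, function(s, t) true_diameter(s, t, phantom, wave))
  mri <- diameter_map_auc(tdm, phantom$frame_dt_s)
  L <- attr(cl, "length_mm")
  ports <- port_positions(mano, L)
  tt <- seq(0, max(times), by = fine_dt_s)
  aucs <- vapply(which(ports$in_antrum), function(p) {
    d <- true_diameter(rep(ports$s_mm[p], length(tt)), tt, phantom, wave)
    base_d <- true_diameter(ports$s_mm[p], 0, phantom,
                            wave_config(active = FALSE, occlusion_frac = 0))
    trapz_uniform(transduce_pressure(d, base_d, mano) - mano$baseline_mmHg,
                  fine_dt_s)
  }, numeric(1))
  list(mri_auc = mri, mano_auc = mean(aucs))
}

#' Simulate a multi-subject paired-modality validation study
#'
#' Lays out subjects x visits x blocks according to a [study_config()], draws
#' subject-level contraction amplitudes from a multiplicative log-normal
#' (stable subject characteristics), block-level log-normal jitter, and
#' assigns each block a motility state: quiescent or active baseline blocks
#' before the drink event, transitional non-occlusive blocks immediately
#' after it, and fully developed occlusive blocks later. Ground-truth AUCs
#' for both modalities come from [true_block_aucs()]; cine stacks and
#' manometry traces can optionally be rendered per block.
#'
#' Deterministic given `cfg$seed`: the same configuration reproduces the
#' study bit-for-bit, including all per-block render seeds.
#'
#' @param cfg A [study_config()].
#' @param phantom,mano,resp Module configurations shared by all blocks.
#' @param wave_template Wave settings other than `occlusion_frac` (frequency,
#'   speed, width) shared by all blocks.
#' @param render `"none"` (truth table only), `"traces"` (adds manometry
#'   traces per block), or `"full"` (also renders the cine stacks).
#' @return A list: `table` (the study truth table, one row per block:
#'   subject, visit, block, time index, phase, state, occlusion fraction,
#'   `true_mri_auc`, `true_mano_auc`, block seed) and `blocks` (per-block
#'   list of `stack`/`truth`/`traces`, or `NULL` when `render = "none"`).
#' @export
generate_study <- function(cfg, phantom = phantom_config(),
                           mano = manometry_config(),
                           resp = respiration_config(),
                           wave_template = wave_config(),
                           render = c("none", "traces", "full")) {
  stopifnot(inherits(cfg, "study_config"))
  render <- match.arg(render)
  set.seed(cfg$seed)

  layout <- study_layout(cfg)
  n_blocks <- nrow(layout)
  subj_mult <- exp(rnorm(cfg$n_subjects, 0, cfg$between_subject_sd))
  jitter <- exp(rnorm(n_blocks, 0, cfg$within_subject_sd))
  u_active <- runif(n_blocks)
  block_seed <- sample.int(.Machine$integer.max - 1L, n_blocks)

  occ <- numeric(n_blocks)
  state <- character(n_blocks)
  for (b in seq_len(n_blocks)) {
    if (layout$phase[b] == "baseline") {
      if (u_active[b] < cfg$baseline_active_prob) {
        occ[b] <- cfg$occlusion_active; state[b] <- "active"
      } else {
        occ[b] <- 0; state[b] <- "quiescent"
      }
    } else {
      early <- layout$block[b] - cfg$drink_event_index < cfg$n_early_blocks
      occ[b] <- if (early) cfg$occlusion_early else cfg$occlusion_active
      state[b] <- if (early) "active_nonocclusive" else "active"
    }
    if (occ[b] > 0)
      occ[b] <- min(0.95, occ[b] * subj_mult[layout$subject[b]] * jitter[b])
  }

  # truth AUCs: evaluate once per distinct occlusion level (many blocks share 0)
  uniq <- !duplicated(round(occ, 10))
  auc_lookup <- lapply(which(uniq), function(b) {
    w <- wave_config(freq_cpm = wave_template$freq_cpm,
                     speed_mm_s = wave_template$speed_mm_s,
                     occlusion_frac = occ[b], width_mm = wave_template$width_mm,
                     active = occ[b] > 0)
    true_block_aucs(phantom, w, mano)
  })
  names(auc_lookup) <- as.character(round(occ[uniq], 10))
  mri <- vapply(occ, function(o) auc_lookup[[as.character(round(o, 10))]]$mri_auc,
                numeric(1))
  man <- vapply(occ, function(o) auc_lookup[[as.character(round(o, 10))]]$mano_auc,
                numeric(1))

  tbl <- dplyr::mutate(layout, state = state, occlusion = occ,
                       true_mri_auc = mri, true_mano_auc = man,
                       block_seed = block_seed)
  blocks <- NULL
  if (render != "none") {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      w <- wave_config(freq_cpm = wave_template$freq_cpm,
                       speed_mm_s = wave_template$speed_mm_s,
                       occlusion_frac = occ[b], width_mm = wave_template$width_mm,
                       active = occ[b] > 0)
      out <- if (render == "full") {
        generate_cine(phantom, w, resp, seed = block_seed[b])
      } else {
        times <- frame_times(phantom)
        cl <- centerline(phantom$axis_polyline, spacing_mm = 5)
        tdm <- outer(cl$s_mm, times, function(s, t) true_diameter(s, t, phantom, w))
        list(stack = NULL,
             truth = structure(list(true_diameter_map = tdm, node_s_mm = cl$s_mm,
                                    frame_times_s = times, true_wave_params = w,
                                    displacement_px = NULL,
                                    true_block_auc_mri = mri[b]),
                               class = "ground_truth"))
      }
      out$traces <- generate_pressure(w, mano, out$truth, seed = block_seed[b],
                                      phantom = phantom, resp = resp)
      out
    })
  }
  list(table = tbl, blocks = blocks,
       configs = list(study = cfg, phantom = phantom, mano = mano,
                      resp = resp, wave_template = wave_template))
}

#' Block layout of a study configuration
#'
#' One row per acquisition block with subject, visit, within-visit block
#' index, global time index and phase (baseline vs post-drink). When
#' `n_total_blocks` is set, blocks are spread as evenly as possible with the
#' remainder on the last subject.
#'
#' @param cfg A [study_config()].
#' @return A tibble.
#' @export
study_layout <- function(cfg) {
  rows <- list()
  if (is.null(cfg$n_total_blocks)) {
    per_sv <- rep(cfg$blocks_per_subject_visit, cfg$n_subjects * cfg$n_visits)
  } else {
    nsv <- cfg$n_subjects * cfg$n_visits
    per_sv <- rep(cfg$n_total_blocks %/% nsv, nsv)
    rem <- cfg$n_total_blocks - sum(per_sv)
    if (rem > 0) # remainder goes to the last subject's visits, last visit first
      per_sv[nsv - seq_len(rem) + 1] <- per_sv[nsv - seq_len(rem) + 1] + 1
  }
  i <- 0
  for (s in seq_len(cfg$n_subjects)) for (v in seq_len(cfg$n_visits)) {
    i <- i + 1
    nb <- per_sv[i]
    rows[[i]] <- tibble(subject = s, visit = v, block = seq_len(nb),
                        phase = ifelse(seq_len(nb) < cfg$drink_event_index,
                                       "baseline", "postdrink"))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, time_index = .data$block, .after = "block")
}
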