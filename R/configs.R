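#' Phantom acquisition configuration
#'
#' Describes the simulated dynamic (cine) acquisition of a single coronal-oblique
#' plane through the gastric antrum: a square image grid, in-plane pixel size,
#' and the timing of one acquisition block (by default 60 frames at 3.7 s per
#' frame, i.e. a ~3.5 minute block).
#'
#' @param grid_size Image width/height in pixels.
#' @param pixel_mm In-plane pixel size in mm (isotropic).
#' @param n_frames Number of frames in one acquisition block.
#' @param frame_dt_s Time between consecutive frames of the plane, seconds.
#' @param axis_polyline Two-column matrix (x, y in mm, image-centred
#'   coordinates) tracing the antral axis from the proximal to the distal end.
#'   The default is a gently curved segment about 120 mm long.
#' @param baseline_diameter_mm Length-2 numeric: resting lumen diameter (mm) at
#'   the proximal and distal ends of the axis; interpolated linearly along the
#'   arc length (the antrum tapers towards the pylorus).
#' @param wall_mm Stomach wall thickness in mm.
#' @param intensities Named numeric vector with grey levels `lumen`, `wall`,
#'   `background` (arbitrary units; bright lumen mimics a balanced
#'   steady-state sequence).
#' @param edge_mm Width of the smooth intensity transition at tissue
#'   boundaries, mm (partial-volume blur).
#' @param texture_amp Amplitude of the static smooth background texture that
#'   stands in for surrounding abdominal tissue (0 disables it).
#' @param noise_sd Standard deviation of additive Gaussian image noise.
#'
#' @return An object of class `phantom_config` (a validated list).
#' @export
#' @examples
#' ph <- phantom_config(grid_size = 128)
#' ph$n_frames * ph$frame_dt_s # block duration, seconds
phantom_config <- function(grid_size = 256,
                           pixel_mm = 1.56,
                           n_frames = 60,
                           frame_dt_s = 3.7,
                           axis_polyline = default_antral_axis(),
                           baseline_diameter_mm = c(30, 12),
                           wall_mm = 4,
                           intensities = c(lumen = 0.95, wall = 0.35, background = 0.15),
                           edge_mm = 1.2,
                           texture_amp = 0.06,
                           noise_sd = 0.02) {
  axis_polyline <- as.matrix(axis_polyline)
  if (!is.numeric(axis_polyline) || ncol(axis_polyline) != 2 || nrow(axis_polyline) < 2)
    abort("`axis_polyline` must be a numeric matrix with >= 2 rows and 2 columns (x, y in mm).")
  stopifnot(pixel_mm > 0, grid_size >= 16, n_frames >= 2, frame_dt_s > 0,
            wall_mm > 0, edge_mm > 0, noise_sd >= 0, texture_amp >= 0)
  if (length(baseline_diameter_mm) == 1)
    baseline_diameter_mm <- rep(baseline_diameter_mm, 2)
  if (any(baseline_diameter_mm <= 0))
    abort("`baseline_diameter_mm` must be positive everywhere.")
  if (!all(c("lumen", "wall", "background") %in% names(intensities)))
    abort("`intensities` needs named entries lumen, wall, background.")
  block_s <- n_frames * frame_dt_s
  if (n_frames >= 30 && (block_s < 150 || block_s > 300))
    warn(sprintf("Block duration %.0f s is far from the nominal ~3.5 min block.", block_s))
  structure(list(grid_size = as.integer(grid_size), pixel_mm = pixel_mm,
                 n_frames = as.integer(n_frames), frame_dt_s = frame_dt_s,
                 axis_polyline = axis_polyline,
                 baseline_diameter_mm = baseline_diameter_mm,
                 wall_mm = wall_mm, intensities = intensities, edge_mm = edge_mm,
                 texture_amp = texture_amp, noise_sd = noise_sd),
            class = "phantom_config")
}

#' Default antral axis polyline
#'
#' A gently curved 120 mm segment in image-centred mm coordinates, proximal
#' (wide) end first.
#'
#' @param length_mm Straight-line extent along x, mm.
#' @param bow_mm Maximal perpendicular bowing of the arc, mm.
#' @param n Number of polyline vertices.
#' @return A two-column matrix of (x, y) in mm.
#' @export
default_antral_axis <- function(length_mm = 120, bow_mm = 14, n = 13) {
  t <- seq(0, 1, length.out = n)
  cbind(x = -length_mm / 2 + length_mm * t,
        y = bow_mm * sin(pi * t) - bow_mm / 2)
}

#' Peristaltic wave configuration
#'
#' Parameters of the propagating occlusive contraction wave: a periodic train
#' of Gaussian-shaped lumen constrictions travelling aborally along the antral
#' axis. Defaults follow gastric physiology (about 3 contractions per minute
#' propagating at ~2.5 mm/s).
#'
#' @param freq_cpm Contraction frequency, cycles per minute.
#' @param speed_mm_s Aboral propagation speed, mm/s.
#' @param occlusion_frac Fractional diameter reduction at the wave crest, in
#'   \[0, 1\]; 1 means full luminal occlusion.
#' @param width_mm Gaussian spatial SD of each constriction, mm (FWHM ~12 mm).
#' @param active Logical; `FALSE` gives a quiescent (motionless) antrum
#'   regardless of the other settings.
#' @return A `wave_config` object.
#' @export
wave_config <- function(freq_cpm = 3, speed_mm_s = 2.5, occlusion_frac = 0.5,
                        width_mm = 5, active = TRUE) {
  if (occlusion_frac < 0 || occlusion_frac > 1)
    abort("`occlusion_frac` must lie in [0, 1].")
  if (active && freq_cpm <= 0) abort("`freq_cpm` must be positive when active.")
  stopifnot(speed_mm_s > 0, width_mm > 0)
  structure(list(freq_cpm = freq_cpm, speed_mm_s = speed_mm_s,
                 occlusion_frac = occlusion_frac, width_mm = width_mm,
                 active = isTRUE(active)),
            class = "wave_config")
}

#' Respiratory motion configuration
#'
#' Breathing is modelled as a rigid, whole-frame sinusoidal translation; the
#' period defaults to 4 s (~15 breaths/min), faster than the frame interval,
#' so consecutive frames sample breathing quasi-randomly, as in vivo.
#'
#' @param amplitude_mm Peak displacement, mm (0 disables respiration).
#' @param period_s Breathing period, seconds.
#' @param direction Length-2 vector; normalised internally.
#' @param phase Phase offset, radians.
#' @return A `respiration_config` object.
#' @export
respiration_config <- function(amplitude_mm = 4, period_s = 4,
                               direction = c(0, 1), phase = 0) {
  stopifnot(amplitude_mm >= 0, period_s > 0, length(direction) == 2)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) abort("`direction` must be a non-zero vector.")
  structure(list(amplitude_mm = amplitude_mm, period_s = period_s,
                 direction = direction / nrm, phase = phase),
            class = "respiration_config")
}

#' Perfused-manometry catheter configuration
#'
#' A water-perfused catheter with side-hole recording ports at 5 cm intervals,
#' sampled at 25 Hz. Pressure transduction is two-regime: below full port
#' contact the port sees intrabolus hydrodynamic pressure rising gently with
#' luminal narrowing; once the lumen closes onto the port (diameter below
#' `occlusion_threshold_mm`) it sees mucosal contact pressure, which rises much
#' more steeply. With the default gains the regime switch occurs in the
#' 15--35 mmHg range typical of antral peristalsis.
#'
#' @param n_ports Number of catheter ports.
#' @param port_spacing_mm Axial distance between adjacent ports, mm.
#' @param distal_offset_mm Arc-length position of the most distal port,
#'   measured back from the distal end of the modelled axis, mm.
#' @param fs_hz Sampling rate, Hz.
#' @param baseline_mmHg Resting intraluminal pressure, mmHg.
#' @param occlusion_threshold_mm Lumen diameter (mm) below which the contact
#'   regime applies.
#' @param hydro_gain_mmHg_per_mm Pressure rise per mm of diameter reduction in
#'   the hydrodynamic regime.
#' @param contact_gain_mmHg_per_mm Pressure rise per mm of further narrowing in
#'   the contact regime; must be at least the hydrodynamic gain.
#' @param resp_artifact_mmHg Amplitude of the respiration-band pressure
#'   artifact, mmHg.
#' @param noise_sd_mmHg Additive Gaussian sensor noise, mmHg.
#' @return A `manometry_config` object.
#' @export
manometry_config <- function(n_ports = 16, port_spacing_mm = 50,
                             distal_offset_mm = 10, fs_hz = 25,
                             baseline_mmHg = 5, occlusion_threshold_mm = 6,
                             hydro_gain_mmHg_per_mm = 1.5,
                             contact_gain_mmHg_per_mm = 8,
                             resp_artifact_mmHg = 2, noise_sd_mmHg = 0.5) {
  stopifnot(n_ports >= 1, port_spacing_mm > 0, fs_hz > 0,
            occlusion_threshold_mm > 0, resp_artifact_mmHg >= 0,
            noise_sd_mmHg >= 0)
  if (hydro_gain_mmHg_per_mm < 0 || contact_gain_mmHg_per_mm < hydro_gain_mmHg_per_mm)
    abort("Gains must satisfy contact_gain >= hydro_gain >= 0.")
  structure(list(n_ports = as.integer(n_ports), port_spacing_mm = port_spacing_mm,
                 distal_offset_mm = distal_offset_mm, fs_hz = fs_hz,
                 baseline_mmHg = baseline_mmHg,
                 occlusion_threshold_mm = occlusion_threshold_mm,
                 hydro_gain_mmHg_per_mm = hydro_gain_mmHg_per_mm,
                 contact_gain_mmHg_per_mm = contact_gain_mmHg_per_mm,
                 resp_artifact_mmHg = resp_artifact_mmHg,
                 noise_sd_mmHg = noise_sd_mmHg),
            class = "manometry_config")
}

#' Study-level simulation configuration
#'
#' Lays out a multi-subject, multi-visit validation study of repeated 3.5-min
#' acquisition blocks with a mid-session water-drink event. Each visit starts
#' with fasted baseline blocks (mostly quiescent) and continues with
#' post-drink blocks in which peristalsis is stimulated; the first post-drink
#' blocks are modelled as vigorous but predominantly non-occlusive (free fluid
#' in the lumen), the later ones as occlusive.
#'
#' @param n_subjects Number of participants.
#' @param n_visits Visits per participant.
#' @param blocks_per_subject_visit Acquisition blocks per visit.
#' @param n_total_blocks Optional total block count for the whole study; when
#'   given, blocks are spread as evenly as possible over subject-visits with
#'   the remainder assigned to the last subject (useful to reproduce uneven
#'   real-study designs).
#' @param drink_event_index Index of the first post-drink block within a visit.
#' @param occlusion_active Occlusion fraction of a fully developed post-drink
#'   contraction wave (population mean).
#' @param occlusion_early Occlusion fraction of the transitional, predominantly
#'   non-occlusive blocks immediately after the drink.
#' @param n_early_blocks How many post-drink blocks use `occlusion_early`.
#' @param baseline_active_prob Probability that a pre-drink baseline block
#'   shows (occlusive) phase-like activity rather than quiescence.
#' @param between_subject_sd SD of the log-normal subject-level multiplier on
#'   contraction amplitude (stable subject characteristics).
#' @param within_subject_sd SD of the log-normal block-level amplitude jitter.
#' @param seed Integer seed controlling all randomness in [generate_study()].
#' @return A `study_config` object.
#' @export
study_config <- function(n_subjects = 15, n_visits = 2,
                         blocks_per_subject_visit = 14,
                         n_total_blocks = NULL,
                         drink_event_index = 5,
                         occlusion_active = 0.75,
                         occlusion_early = 0.45,
                         n_early_blocks = 2,
                         baseline_active_prob = 0.25,
                         between_subject_sd = 0.18,
                         within_subject_sd = 0.12,
                         seed = 1L) {
  stopifnot(n_subjects >= 1, n_visits >= 1, blocks_per_subject_visit >= 1,
            drink_event_index >= 1, between_subject_sd >= 0,
            within_subject_sd >= 0, occlusion_active >= 0, occlusion_active <= 1,
            occlusion_early >= 0, occlusion_early <= 1)
  if (!is.null(n_total_blocks) && n_total_blocks < n_subjects * n_visits)
    abort("`n_total_blocks` must allow at least one block per subject-visit.")
  structure(list(n_subjects = as.integer(n_subjects), n_visits = as.integer(n_visits),
                 blocks_per_subject_visit = as.integer(blocks_per_subject_visit),
                 n_total_blocks = if (is.null(n_total_blocks)) NULL else as.integer(n_total_blocks),
                 drink_event_index = as.integer(drink_event_index),
                 occlusion_active = occlusion_active,
                 occlusion_early = occlusion_early,
                 n_early_blocks = as.integer(n_early_blocks),
                 baseline_active_prob = baseline_active_prob,
                 between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %d x %d px @ %.2f mm, %d frames @ %.1f s (block %.0f s)\n",
              x$grid_size, x$grid_size, x$pixel_mm, x$n_frames, x$frame_dt_s,
              x$n_frames * x$frame_dt_s))
  invisible(x)
}

#' @export
print.wave_config <- function(x, ...) {
  cat(sprintf("<wave_config> %s, %.1f cpm @ %.1f mm/s, occlusion %.2f, width %.1f mm\n",
              if (x$active) "active" else "quiescent", x$freq_cpm, x$speed_mm_s,
              x$occlusion_frac, x$width_mm))
  invisible(x)
}

#' @export
print.study_config <- function(x, ...) {
  nb <- x$n_total_blocks %||% (x$n_subjects * x$n_visits * x$blocks_per_subject_visit)
  cat(sprintf("<study_config> %d subjects x %d visits, %d blocks total (seed %d)\n",
              x$n_subjects, x$n_visits, nb, x$seed))
  invisible(x)
}
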