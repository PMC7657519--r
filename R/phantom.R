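#' Peristaltic wave train profile
#'
#' Evaluates the dimensionless occlusion profile g(s, t) in \[0, 1\]: a
#' periodic train of Gaussian-shaped constrictions of spatial SD `width_mm`,
#' spaced one wavelength `speed / freq` apart and travelling aborally
#' (towards increasing arc length) at `speed_mm_s`. Each constriction is
#' truncated at 3 SD and rescaled to unit peak, so contractions are compactly
#' supported and the lumen between them rests exactly at its baseline
#' calibre. The clipped sum never exceeds 1, so `occlusion_frac * g` is the
#' instantaneous fractional diameter reduction.
#'
#' @param s_mm Arc-length positions, mm.
#' @param t_s Time, seconds (scalar or same length as `s_mm`).
#' @param wave A [wave_config()].
#' @return Numeric vector of g values in \[0, 1\].
#' @export
wave_profile <- function(s_mm, t_s, wave) {
  if (!wave$active || wave$occlusion_frac == 0) return(rep(0, length(s_mm)))
  lambda <- wave$speed_mm_s / (wave$freq_cpm / 60)
  u <- (s_mm - wave$speed_mm_s * t_s) %% lambda
  g <- 0
  trunc <- exp(-4.5)  # value at 3 SD
  for (j in -1:1)
    g <- g + pmax(0, exp(-((u + j * lambda)^2) / (2 * wave$width_mm^2)) - trunc) /
      (1 - trunc)
  pmin(g, 1)
}

#' Noise-free lumen diameter of the phantom
#'
#' The analytic ground truth: baseline diameter profile (linear taper from the
#' proximal to the distal end of the axis) modulated by the travelling wave.
#'
#' @inheritParams wave_profile
#' @param phantom A [phantom_config()].
#' @return Diameter in mm (>= 0; 0 only at full occlusion).
#' @export
true_diameter <- function(s_mm, t_s, phantom, wave) {
  L <- polyline_length(phantom$axis_polyline)
  frac <- pmin(1, pmax(0, s_mm / L))
  B <- phantom$baseline_diameter_mm[1] +
    (phantom$baseline_diameter_mm[2] - phantom$baseline_diameter_mm[1]) * frac
  B * (1 - wave$occlusion_frac * wave_profile(s_mm, t_s, wave) * as.numeric(wave$active))
}

polyline_length <- function(polyline) {
  sum(sqrt(rowSums(diff(as.matrix(polyline))^2)))
}

#' Tube coordinate fields (arc length and axial distance) for a phantom
#'
#' For every pixel of a (padded) grid, the arc-length position of the nearest
#' point on the densified axis and the Euclidean distance to it. Computed once
#' per phantom and reused for every frame.
#' @keywords internal
#' @noRd
tube_fields <- function(phantom, pad_px = 0) {
  n <- phantom$grid_size
  idx <- seq(1 - pad_px, n + pad_px)
  mm <- (idx - (n + 1) / 2) * phantom$pixel_mm
  cl <- centerline(phantom$axis_polyline, spacing_mm = 5, dense_step_mm = 0.5)
  dense <- attr(cl, "dense")
  np <- length(idx)
  S <- matrix(0, np, np); Dst <- matrix(0, np, np)
  py <- rep(mm, each = np)  # column-major: column j has y = mm[j]
  px <- rep(mm, np)
  chunk <- max(1L, floor(2e6 / nrow(dense)))
  for (start in seq(1, np * np, by = chunk)) {
    ii <- start:min(start + chunk - 1, np * np)
    d2 <- outer(px[ii]^2 + py[ii]^2, rep(1, nrow(dense))) -
      2 * (outer(px[ii], dense[, "x"]) + outer(py[ii], dense[, "y"])) +
      outer(rep(1, length(ii)), dense[, "x"]^2 + dense[, "y"]^2)
    best <- max.col(-d2, ties.method = "first")
    S[ii] <- dense[best, "s"]
    Dst[ii] <- sqrt(pmax(0, d2[cbind(seq_along(ii), best)]))
  }
  list(S = S, D = Dst, idx = idx, mm = mm, pad_px = pad_px,
       length_mm = attr(cl, "length_mm"))
}

#' Smooth static background texture emulating surrounding tissue
#' @keywords internal
#' @noRd
make_texture <- function(np, amp, sigma_px = 4, seed_offset = 0L) {
  if (amp <= 0) return(matrix(0, np, np))
  raw <- matrix(rnorm(np * np), np, np)
  k <- dnorm(seq(-3 * sigma_px, 3 * sigma_px), sd = sigma_px)
  k <- k / sum(k)
  sm <- apply(raw, 2, function(col) stats::filter(col, k, circular = TRUE))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, k, circular = TRUE)))
  amp * sm / sd(sm)
}

#' Simulate one cine-MRI acquisition block of the antral phantom
#'
#' Renders `n_frames` images of a tapering tubular antrum whose local lumen
#' diameter follows the analytic wave model of [true_diameter()], translates
#' each frame rigidly by the respiratory displacement, and adds smooth
#' background texture plus Gaussian noise. The returned ground truth carries
#' the noise-free diameter map sampled at the centerline nodes, the injected
#' per-frame displacements, and the analytic per-block motility AUC.
#'
#' @param phantom A [phantom_config()].
#' @param wave A [wave_config()].
#' @param resp A [respiration_config()]; use `amplitude_mm = 0` for a
#'   breath-hold-like acquisition.
#' @param seed Integer seed; the block is bit-reproducible given the seed.
#' @param node_spacing_mm Arc-length spacing of the ground-truth diameter
#'   nodes (matching the default analysis centerline).
#' @return A list with elements
#'   \describe{
#'     \item{stack}{a `cine_stack`: frames as an x-y-time array plus geometry
#'       metadata,}
#'     \item{truth}{a `ground_truth` list: `true_diameter_map` (node x frame,
#'       mm), node arc positions, frame times, the wave used, the injected
#'       `displacement_px` per frame, and `true_block_auc_mri` (mm s).}
#'   }
#' @export
#' @examples
#' blk <- generate_cine(phantom_config(grid_size = 96, n_frames = 10),
#'                      wave_config(occlusion_frac = 0.5),
#'                      respiration_config(amplitude_mm = 0), seed = 1)
#' dim(blk$stack$data)
generate_cine <- function(phantom, wave, resp = respiration_config(),
                          seed = 1L, node_spacing_mm = 5) {
  stopifnot(inherits(phantom, "phantom_config"), inherits(wave, "wave_config"),
            inherits(resp, "respiration_config"))
  set.seed(seed)
  n <- phantom$grid_size
  pad <- ceiling(resp$amplitude_mm / phantom$pixel_mm) + 2L
  tf <- tube_fields(phantom, pad_px = pad)
  tex <- make_texture(n + 2L * pad, phantom$texture_amp)
  ints <- phantom$intensities
  times <- frame_times(phantom)
  cl <- centerline(phantom$axis_polyline, spacing_mm = node_spacing_mm)

  # pixel index coordinates into the padded fields
  base_x <- rep(seq_len(n), n) + pad
  base_y <- rep(seq_len(n), each = n) + pad
  data <- array(0, dim = c(n, n, phantom$n_frames))
  disp_px <- matrix(0, phantom$n_frames, 2,
                    dimnames = list(NULL, c("dx_px", "dy_px")))
  for (k in seq_len(phantom$n_frames)) {
    d_mm <- resp$amplitude_mm *
      sin(2 * pi * times[k] / resp$period_s + resp$phase) * resp$direction
    d_px <- d_mm / phantom$pixel_mm
    disp_px[k, ] <- d_px
    xi <- base_x - d_px[1]; yi <- base_y - d_px[2]
    s <- bilinear_sample(tf$S, xi, yi, outside = -1e6)
    d <- bilinear_sample(tf$D, xi, yi, outside = 1e6)
    half <- true_diameter(s, times[k], phantom, wave) / 2
    img <- ints[["background"]] +
      (ints[["wall"]] - ints[["background"]]) *
        ramp01((half + phantom$wall_mm - d) / phantom$edge_mm) +
      (ints[["lumen"]] - ints[["wall"]]) * ramp01((half - d) / phantom$edge_mm)
    img <- img + bilinear_sample(tex, xi, yi, outside = 0)
    if (phantom$noise_sd > 0) img <- img + rnorm(n * n, sd = phantom$noise_sd)
    data[, , k] <- img
  }
  tdm <- outer(cl$s_mm, times,
               function(s, t) true_diameter(s, t, phantom, wave))
  truth <- structure(list(true_diameter_map = tdm, node_s_mm = cl$s_mm,
                          frame_times_s = times, true_wave_params = wave,
                          displacement_px = disp_px,
                          true_block_auc_mri = if (phantom$n_frames >= 10)
                            diameter_map_auc(tdm, phantom$frame_dt_s) else NA_real_),
                     class = "ground_truth")
  stack <- new_cine_stack(data, phantom$pixel_mm, phantom$frame_dt_s,
                          meta = list(seed = seed, phantom = phantom, wave = wave,
                                      respiration = resp))
  list(stack = stack, truth = truth)
}

#' Construct a cine stack object
#'
#' @param data Numeric array `[x, y, t]` (one slice per frame).
#' @param pixel_mm In-plane pixel size, mm.
#' @param frame_dt_s Frame interval, seconds.
#' @param meta Optional metadata list.
#' @return A `cine_stack` object.
#' @export
new_cine_stack <- function(data, pixel_mm, frame_dt_s, meta = list()) {
  stopifnot(length(dim(data)) == 3, pixel_mm > 0, frame_dt_s > 0)
  structure(list(data = data, pixel_mm = pixel_mm, frame_dt_s = frame_dt_s,
                 meta = meta),
            class = "cine_stack")
}

#' @export
print.cine_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cine_stack> %d x %d px, %d frames @ %.1f s, pixel %.2f mm\n",
              d[1], d[2], d[3], x$frame_dt_s, x$pixel_mm))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d nodes x %d frames, MRI AUC %.1f mm s\n",
              nrow(x$true_diameter_map), ncol(x$true_diameter_map),
              x$true_block_auc_mri))
  invisible(x)
}

#' Convert pixel indices to image-centred mm coordinates and back
#' @keywords internal
#' @noRd
px_to_mm <- function(i, n, pixel_mm) (i - (n + 1) / 2) * pixel_mm
mm_to_px <- function(x, n, pixel_mm) x / pixel_mm + (n + 1) / 2
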