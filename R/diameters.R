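#' Measure perpendicular lumen diameters along the centerline
#'
#' For every centerline node and frame, samples the lumen mask along the line
#' perpendicular to the local axis tangent at sub-pixel steps (bilinear mask
#' interpolation) and takes the length of the maximal contiguous run of lumen
#' samples containing -- or, failing that, nearest to -- the node. This is the
#' spatio-temporal motility map: diameter D\[node, frame\] in mm.
#'
#' @param masks List of per-frame lumen masks as produced by
#'   [propagate_contours()] (numeric/logical matrices, 1 = lumen).
#' @param axis A [centerline()] in mm coordinates.
#' @param pixel_mm Pixel size of the masks, mm.
#' @param step_px Sampling step along the perpendicular, pixels.
#' @param halfspan_mm How far to either side of the node to search, mm.
#' @param stack Optional `cine_stack` of the (motion-corrected) intensity
#'   frames the masks were derived from. When given, run endpoints are
#'   re-snapped on the interpolated intensity profile at `threshold`,
#'   recovering the lumen boundary at sub-pixel precision instead of the
#'   pixel-quantised mask edge; the mask still decides which run is the lumen.
#' @param threshold Lumen intensity threshold used for the re-snap (defaults
#'   to the `threshold` attribute of `masks`).
#' @return A `diameter_map` object: matrix `D` (mm, nodes x frames) with node
#'   positions, frame interval and a logical `flagged` matrix marking
#'   node-frames where the perpendicular missed the lumen entirely.
#' @export
measure_diameters <- function(masks, axis, pixel_mm, step_px = 0.25,
                              halfspan_mm = 25, stack = NULL,
                              threshold = attr(masks, "threshold")) {
  stopifnot(inherits(axis, "centerline"), pixel_mm > 0)
  n <- nrow(masks[[1]])
  offs <- seq(-halfspan_mm, halfspan_mm, by = step_px * pixel_mm)
  zero <- which.min(abs(offs))
  n_nodes <- nrow(axis); n_frames <- length(masks)
  use_int <- !is.null(stack) && !is.null(threshold) && is.finite(threshold)
  D <- matrix(0, n_nodes, n_frames)
  flagged <- matrix(FALSE, n_nodes, n_frames)
  # sample coordinates are frame-independent: node position + offset * normal
  xi <- mm_to_px(outer(offs, axis$nx) + rep(axis$x_mm, each = length(offs)), n, pixel_mm)
  yi <- mm_to_px(outer(offs, axis$ny) + rep(axis$y_mm, each = length(offs)), n, pixel_mm)
  run_table <- function(bin) {
    r <- rle(bin)
    ends <- cumsum(r$lengths)
    list(runs = which(r$values), starts = ends - r$lengths + 1, ends = ends,
         lengths = r$lengths)
  }
  pick_run <- function(rt, at) {
    inside <- rt$runs[rt$starts[rt$runs] <= at & rt$ends[rt$runs] >= at]
    if (length(inside)) inside[1] else
      rt$runs[which.min(pmax(rt$starts[rt$runs] - at, at - rt$ends[rt$runs]))]
  }
  for (k in seq_len(n_frames)) {
    v <- bilinear_sample(masks[[k]] * 1, as.vector(xi), as.vector(yi), outside = 0)
    prof <- matrix(v >= 0.5, nrow = length(offs))
    iprof <- if (use_int)
      matrix(bilinear_sample(stack$data[, , k], as.vector(xi), as.vector(yi),
                             outside = -Inf) >= threshold, nrow = length(offs))
    for (i in seq_len(n_nodes)) {
      rt <- run_table(prof[, i])
      if (!length(rt$runs)) { flagged[i, k] <- TRUE; next }
      pick <- pick_run(rt, zero)
      len <- rt$lengths[pick]
      if (use_int) {
        centre <- round((rt$starts[pick] + rt$ends[pick]) / 2)
        it <- run_table(iprof[, i])
        if (length(it$runs)) {
          ipick <- pick_run(it, centre)
          # accept the intensity run only if it agrees with the mask run
          if (it$starts[ipick] <= rt$ends[pick] && it$ends[ipick] >= rt$starts[pick])
            len <- it$lengths[ipick]
        }
      }
      D[i, k] <- len * step_px * pixel_mm
    }
  }
  new_diameter_map(D, axis$s_mm, frame_dt_s = NA_real_, flagged = flagged)
}

#' Construct a diameter map object
#'
#' @param D Matrix of diameters, mm (nodes x frames).
#' @param node_s_mm Node arc-length positions, mm.
#' @param frame_dt_s Frame interval, seconds.
#' @param flagged Optional logical matrix marking unreliable node-frames.
#' @return A `diameter_map`.
#' @export
new_diameter_map <- function(D, node_s_mm, frame_dt_s, flagged = NULL) {
  stopifnot(is.matrix(D), nrow(D) == length(node_s_mm), all(D >= 0 | is.na(D)))
  structure(list(D = D, node_s_mm = node_s_mm, frame_dt_s = frame_dt_s,
                 flagged = flagged %||% matrix(FALSE, nrow(D), ncol(D))),
            class = "diameter_map")
}

#' @export
print.diameter_map <- function(x, ...) {
  cat(sprintf("<diameter_map> %d nodes x %d frames, mean %.1f mm (%d flagged)\n",
              nrow(x$D), ncol(x$D), mean(x$D, na.rm = TRUE), sum(x$flagged)))
  invisible(x)
}

#' @describeIn measure_diameters Long-format view of a diameter map.
#' @param x A `diameter_map`.
#' @param ... Unused.
#' @method tidy diameter_map
#' @export
tidy.diameter_map <- function(x, ...) {
  tibble(node = rep(seq_along(x$node_s_mm), ncol(x$D)),
         s_mm = rep(x$node_s_mm, ncol(x$D)),
         frame = rep(seq_len(ncol(x$D)), each = nrow(x$D)),
         diameter_mm = as.vector(x$D),
         flagged = as.vector(x$flagged))
}

#' Reduce a diameter map to a per-frame contraction signal
#'
#' Per node the resting calibre is taken as the 90th percentile of that
#' node's diameters over the block (robust to noise, and zero contraction for
#' a static tube); the contraction signal is the node-mean of the positive
#' baseline-minus-diameter deficit. Averaging (not summing) over nodes keeps
#' the signal, and the AUC built on it, independent of node density. Flagged
#' or missing node-frames contribute zero contraction and are excluded from
#' the baseline percentile.
#'
#' @param dm A `diameter_map`.
#' @param baseline_prob Percentile used as the per-node resting calibre.
#' @return Numeric vector c(t), mm, one value per frame; the per-node
#'   baselines are attached as attribute `baseline_mm`.
#' @export
motility_signal <- function(dm, baseline_prob = 0.9) {
  stopifnot(inherits(dm, "diameter_map"))
  if (ncol(dm$D) < 10) abort("Need at least 10 frames for a motility signal.")
  D <- dm$D
  D[dm$flagged] <- NA
  base <- apply(D, 1, function(row) {
    if (all(is.na(row))) NA_real_ else quantile(row, baseline_prob, na.rm = TRUE, names = FALSE)
  })
  if (all(is.na(base)) || all(base == 0, na.rm = TRUE))
    warn("Degenerate diameter map: all-zero or fully flagged.")
  deficit <- base - D
  deficit[deficit < 0 | is.na(deficit)] <- 0
  structure(colMeans(deficit), baseline_mm = base)
}

#' Per-block MRI motility AUC
#'
#' Trapezoidal integral of the contraction signal over the acquisition block;
#' the imaging outcome, in mm x s.
#'
#' @param c_t Contraction signal from [motility_signal()], mm per frame.
#' @param frame_dt_s Uniform frame interval, seconds.
#' @param block_id Optional identifier carried into the result.
#' @return A `motility_auc` object (value in mm s).
#' @export
compute_mri_auc <- function(c_t, frame_dt_s, block_id = NA) {
  if (length(c_t) < 2) abort("Need at least 2 frames to integrate.")
  stopifnot(frame_dt_s > 0)
  structure(list(value = trapz_uniform(as.numeric(c_t), frame_dt_s),
                 block_id = block_id, n_frames = length(c_t),
                 baseline = "per-node 90th percentile"),
            class = "motility_auc")
}

#' @export
print.motility_auc <- function(x, ...) {
  cat(sprintf("<motility_auc> %.1f mm s over %d frames (baseline: %s)\n",
              x$value, x$n_frames, x$baseline))
  invisible(x)
}

#' Motility AUC straight from a diameter matrix
#'
#' Convenience composition of [motility_signal()] and [compute_mri_auc()];
#' also the definition used for the analytic ground-truth AUC.
#'
#' @param D Diameter matrix (nodes x frames), mm.
#' @param frame_dt_s Frame interval, seconds.
#' @return AUC value in mm s.
#' @export
diameter_map_auc <- function(D, frame_dt_s) {
  dm <- new_diameter_map(D, seq_len(nrow(D)), frame_dt_s)
  compute_mri_auc(motility_signal(dm), frame_dt_s)$value
}

#' Dominant contraction frequency of a motility signal
#'
#' Periodogram peak of the detrended, Hann-windowed, zero-padded contraction
#' signal, refined by quadratic interpolation around the peak bin.
#'
#' @param c_t Contraction signal, one sample per frame.
#' @param frame_dt_s Frame interval, seconds.
#' @param pad_factor Zero-padding factor for frequency resolution.
#' @return Estimated frequency in cycles per minute.
#' @export
estimate_frequency_cpm <- function(c_t, frame_dt_s, pad_factor = 8) {
  x <- as.numeric(c_t) - mean(c_t)
  n <- length(x)
  if (n < 10) abort("Need at least 10 frames to estimate a frequency.")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xz <- c(x * w, rep(0, (pad_factor - 1) * n))
  nz <- length(xz)
  P <- Mod(fft(xz))[seq_len(floor(nz / 2))]^2
  fr <- (seq_len(floor(nz / 2)) - 1) / (nz * frame_dt_s)
  P[1] <- 0  # DC
  k <- which.max(P)
  if (k > 1 && k < length(P)) {
    a <- P[k - 1]; b <- P[k]; cc <- P[k + 1]
    denom <- a - 2 * b + cc
    delta <- if (denom != 0) 0.5 * (a - cc) / denom else 0
  } else delta <- 0
  (fr[k] + delta / (nz * frame_dt_s)) * 60
}
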