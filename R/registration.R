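#' Estimate the rigid translation between two frames
#'
#' Sub-pixel translation estimate by spectral cross-correlation: both images
#' are demeaned, Hann-windowed, cross-correlated via the FFT, and the integer
#' peak is refined by separable quadratic interpolation. A deliberate rigid
#' simplification of deformable abdominal registration: the phantom's
#' respiratory model is a whole-frame translation, and rigid recovery of it is
#' fully verifiable.
#'
#' Sign convention: applying the returned shift to `frame` (with
#' [shift_image()]) aligns it to `reference`.
#'
#' @param frame,reference Numeric matrices of equal size.
#' @return Length-2 numeric (dx, dy) in pixels, with attributes `confidence`
#'   (normalised correlation peak) and `low_confidence` (logical).
#' @export
#' @examples
#' img <- outer(dnorm(1:64, 30, 6), dnorm(1:64, 36, 8))
#' sh <- estimate_shift(shift_image(img, c(3, -2)), img)
#' round(sh, 1)
estimate_shift <- function(frame, reference) {
  if (!all(dim(frame) == dim(reference)))
    abort("`frame` and `reference` must have identical dimensions.")
  if (sd(frame) == 0 || sd(reference) == 0) {
    warn("Constant image: correlation undefined, returning zero shift.")
    return(structure(c(0, 0), confidence = 0, low_confidence = TRUE))
  }
  n1 <- nrow(frame); n2 <- ncol(frame)
  w <- outer(0.5 - 0.5 * cos(2 * pi * seq(0, n1 - 1) / (n1 - 1)),
             0.5 - 0.5 * cos(2 * pi * seq(0, n2 - 1) / (n2 - 1)))
  a <- (frame - mean(frame)) * w
  b <- (reference - mean(reference)) * w
  cc <- Re(fft(fft(b) * Conj(fft(a)), inverse = TRUE)) / length(a)
  k <- arrayInd(which.max(cc), dim(cc))
  conf <- max(cc) / sqrt(sum(a^2) * sum(b^2))
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  refine <- function(vals) {
    d <- vals[1] - 2 * vals[2] + vals[3]
    if (d == 0) 0 else 0.5 * (vals[1] - vals[3]) / d
  }
  ix <- c((k[1] - 2) %% n1 + 1, k[1], k[1] %% n1 + 1)
  iy <- c((k[2] - 2) %% n2 + 1, k[2], k[2] %% n2 + 1)
  dx <- wrap(k[1], n1) + refine(cc[cbind(ix, k[2])])
  dy <- wrap(k[2], n2) + refine(cc[cbind(k[1], iy)])
  # null scale of the peak for two independent noise fields of this size
  null_conf <- sqrt(2 * log(n1 * n2) / (n1 * n2))
  structure(c(dx, dy), confidence = conf,
            low_confidence = conf < 2 * null_conf)
}

#' Translate an image by a sub-pixel shift
#'
#' Returns the image resampled so that its content moves by `v` pixels.
#' Because the shift is uniform, resampling reduces to a separable 4-tap
#' cubic (Catmull-Rom spline) convolution, which preserves edges much better
#' than bilinear interpolation; samples falling outside the original support
#' use replicated edge values.
#'
#' @param img Numeric matrix.
#' @param v Length-2 shift (dx, dy), pixels.
#' @return Matrix of the same size.
#' @export
shift_image <- function(img, v) {
  cubic_w <- function(f) {
    # Catmull-Rom weights for neighbours at offsets -1, 0, 1, 2
    c(-0.5 * f + f^2 - 0.5 * f^3,
      1 - 2.5 * f^2 + 1.5 * f^3,
      0.5 * f + 2 * f^2 - 1.5 * f^3,
      -0.5 * f^2 + 0.5 * f^3)
  }
  shift_rows <- function(m, s) {
    if (abs(s) < 1e-12) return(m)
    n <- nrow(m)
    i0 <- floor(s); f <- s - i0
    w <- cubic_w(f)
    idx <- function(k) pmin(pmax(seq_len(n) - i0 + k, 1), n)
    w[1] * m[idx(1), , drop = FALSE] + w[2] * m[idx(0), , drop = FALSE] +
      w[3] * m[idx(-1), , drop = FALSE] + w[4] * m[idx(-2), , drop = FALSE]
  }
  t(shift_rows(t(shift_rows(img, v[1])), v[2]))
}

#' Tile-consensus translation estimate
#'
#' Runs [estimate_shift()] on overlapping square tiles and takes the
#' component-wise median of the tile estimates. Locally moving structure --
#' such as a contraction wave marching along the organ -- biases only the
#' tiles it crosses, and the static-majority consensus suppresses that bias;
#' this is the estimator [correct_motion()] uses per frame.
#'
#' @inheritParams estimate_shift
#' @param tile Tile side, pixels (capped at the image size).
#' @param stride Tile stride; defaults to half-overlapping tiles.
#' @return Length-2 shift (dx, dy) with a `confidence` attribute (median tile
#'   confidence) and `n_tiles` used.
#' @export
tile_consensus_shift <- function(frame, reference, tile = 48, stride = tile / 2) {
  tile <- min(tile, nrow(frame), ncol(frame))
  xs <- unique(c(seq(1, nrow(frame) - tile + 1, by = stride)))
  ys <- unique(c(seq(1, ncol(frame) - tile + 1, by = stride)))
  est <- list()
  for (ix in xs) for (iy in ys) {
    fr <- frame[ix:(ix + tile - 1), iy:(iy + tile - 1)]
    rf <- reference[ix:(ix + tile - 1), iy:(iy + tile - 1)]
    if (sd(fr) < 1e-10 || sd(rf) < 1e-10) next
    v <- suppressWarnings(estimate_shift(fr, rf))
    # drop noise-level tiles and wrap-around outliers
    if (!attr(v, "low_confidence") && max(abs(v)) < tile / 3)
      est[[length(est) + 1]] <- c(v, attr(v, "confidence"))
  }
  if (!length(est)) {
    v <- estimate_shift(frame, reference)
    return(structure(c(v[1], v[2]), confidence = attr(v, "confidence"),
                     n_tiles = 0L))
  }
  m <- do.call(rbind, est)
  structure(c(median(m[, 1]), median(m[, 2])),
            confidence = median(m[, 3]), n_tiles = nrow(m))
}

#' Respiratory motion correction of a cine stack
#'
#' Estimates the translation of every frame relative to the temporal-middle
#' frame, then re-references the series to the frame closest to the median
#' estimated displacement: with the frame interval close to the breathing
#' period, the middle frame can sit at an extreme breathing excursion, and
#' aligning the whole block to that excursion would displace every frame
#' (and the contraction wave) from the phantom's resting geometry. Each frame
#' is resampled onto the median-position reference. Shifts come from the
#' tile-consensus estimator so that the propagating contraction does not drag
#' the respiratory estimate. Frame count and geometry metadata are preserved.
#'
#' @param stack A `cine_stack` with at least 2 frames.
#' @param method `"tiles"` (consensus, default) or `"global"` (single
#'   whole-frame correlation).
#' @return A list: `stack` (motion-corrected `cine_stack`) and `shifts`, a
#'   `displacement_series` tibble (`frame`, `dx_px`, `dy_px`, `confidence`)
#'   whose reference-frame row is exactly (0, 0).
#' @export
correct_motion <- function(stack, method = c("tiles", "global")) {
  stopifnot(inherits(stack, "cine_stack"))
  method <- match.arg(method)
  nt <- dim(stack$data)[3]
  if (nt < 2) abort("Motion correction needs at least 2 frames.")
  ref_idx <- floor((nt + 1) / 2)
  ref <- stack$data[, , ref_idx]
  out <- stack$data
  shifts <- matrix(0, nt, 2)
  confs <- numeric(nt)
  est_fun <- if (method == "tiles") tile_consensus_shift else estimate_shift
  for (k in seq_len(nt)) {
    if (k == ref_idx) { confs[k] <- 1; next }
    # windowed correlation shrinks each estimate slightly towards zero, so
    # iterate: re-estimate on the partially shifted frame until convergence
    v_tot <- c(0, 0); conf <- 0
    frame <- stack$data[, , k]
    for (it in 1:6) {
      cur <- if (max(abs(v_tot)) > 1e-9) shift_image(frame, v_tot) else frame
      v <- suppressWarnings(est_fun(cur, ref))
      v_tot <- v_tot + as.numeric(v)
      conf <- attr(v, "confidence")
      if (max(abs(as.numeric(v))) < 0.01) break
    }
    shifts[k, ] <- v_tot
    confs[k] <- conf
  }
  # re-reference to the frame nearest the median displacement (shifts are
  # translations, so re-referencing is exact arithmetic, no re-estimation)
  med <- c(median(shifts[, 1]), median(shifts[, 2]))
  ref_idx <- which.min((shifts[, 1] - med[1])^2 + (shifts[, 2] - med[2])^2)
  shifts <- sweep(shifts, 2, shifts[ref_idx, ])
  for (k in seq_len(nt))
    if (max(abs(shifts[k, ])) > 1e-9)
      out[, , k] <- shift_image(stack$data[, , k], shifts[k, ])
  ds <- tibble(frame = seq_len(nt), dx_px = shifts[, 1], dy_px = shifts[, 2],
               confidence = confs)
  ds <- structure(ds, class = c("displacement_series", class(ds)),
                  reference_frame = ref_idx)
  corrected <- new_cine_stack(out, stack$pixel_mm, stack$frame_dt_s,
                              meta = c(stack$meta, list(motion_corrected = TRUE,
                                                        reference_frame = ref_idx)))
  list(stack = corrected, shifts = ds)
}
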