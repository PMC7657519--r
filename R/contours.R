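#' Rasterize a polygon to a pixel mask (even-odd rule)
#' @keywords internal
#' @noRd
polygon_mask <- function(poly, n1, n2) {
  px <- rep(seq_len(n1), n2)
  py <- rep(seq_len(n2), each = n1)
  m <- nrow(poly)
  inside <- rep(FALSE, n1 * n2)
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, n1, n2)
}

#' Initial lumen contour on a single frame
#'
#' Seeds the contour-propagation stage, mirroring the manual first-frame
#' delineation of the semi-automated workflow. The hint is either a polygon
#' (pixel coordinates) that is rasterized and intersected with bright lumen
#' pixels, or an intensity threshold (auto mode for phantoms). The result is
#' restricted to the largest connected component and hole-filled.
#'
#' @param frame Numeric image matrix.
#' @param hint Two-column polygon matrix in pixel coordinates, or a single
#'   intensity threshold, or `"auto"` (Otsu threshold).
#' @return A logical lumen mask with attribute `threshold`.
#' @export
initial_contour <- function(frame, hint = "auto") {
  if (is.matrix(hint)) {
    if (nrow(hint) < 3) abort("A polygon hint needs at least 3 vertices.")
    poly <- polygon_mask(hint, nrow(frame), ncol(frame))
    if (!any(poly)) abort("Initial contour is empty.")
    rng <- range(frame[poly])
    thr <- if (diff(rng) < 1e-8) rng[1] else
      EBImage::otsu((frame - rng[1]) / diff(rng)) * diff(rng) + rng[1]
    mask <- poly & (frame >= thr)
  } else {
    thr <- if (identical(hint, "auto")) {
      rng <- range(frame)
      EBImage::otsu((frame - rng[1]) / diff(rng)) * diff(rng) + rng[1]
    } else as.numeric(hint)
    mask <- frame >= thr
  }
  if (!any(mask)) abort("Initial contour is empty.")
  lab <- EBImage::bwlabel(mask * 1)
  keep <- which.max(tabulate(lab[lab > 0]))
  mask <- EBImage::fillHull((lab == keep) * 1) > 0
  structure(mask, threshold = thr)
}

#' Propagate a lumen contour through a motion-corrected stack
#'
#' Frame-to-frame tracking: the translation of an image region around the
#' current mask is estimated against the next frame, the mask is carried over
#' by that shift, and then re-snapped to the image by thresholding within a
#' morphological band (dilation) of the propagated boundary. Each mask is
#' reduced to its largest connected component and hole-filled. If a frame
#' loses the lumen (empty snap, or the tracked region no longer looks like
#' lumen), the previous mask is carried forward and the frame is flagged.
#'
#' @param stack A motion-corrected `cine_stack`.
#' @param m0 Initial mask from [initial_contour()] (for frame 1).
#' @param band_px Radius (pixels) of the search band around the propagated
#'   mask; must cover the per-frame advance of the contraction wave.
#' @param threshold Lumen intensity threshold; by default re-estimated from
#'   `m0` as the midpoint between the lumen and its immediate surround.
#' @return List of logical masks (one per frame) with attribute
#'   `flagged_frames` (integer indices where propagation fell back).
#' @export
propagate_contours <- function(stack, m0, band_px = 9, threshold = NULL) {
  stopifnot(inherits(stack, "cine_stack"))
  nt <- dim(stack$data)[3]
  img1 <- stack$data[, , 1]
  if (is.null(threshold)) {
    surround <- (EBImage::dilate(m0 * 1, EBImage::makeBrush(9, "disc")) > 0) & !m0
    threshold <- (median(img1[m0]) + median(img1[surround])) / 2
  }
  brush <- EBImage::makeBrush(2 * band_px + 1, "disc")
  masks <- vector("list", nt)
  masks[[1]] <- m0
  flagged <- integer(0)
  for (k in seq_len(nt)[-1]) {
    prev <- masks[[k - 1]]
    # track the region around the current mask between consecutive frames
    bb <- which(prev, arr.ind = TRUE)
    pad <- 12L
    rx <- max(1, min(bb[, 1]) - pad):min(nrow(prev), max(bb[, 1]) + pad)
    ry <- max(1, min(bb[, 2]) - pad):min(ncol(prev), max(bb[, 2]) + pad)
    v <- estimate_shift(stack$data[rx, ry, k], stack$data[rx, ry, k - 1])
    moved <- if (max(abs(v)) > 0.25) shift_image(prev * 1, -c(v[1], v[2])) > 0.5 else prev
    if (!any(moved)) moved <- prev
    img <- stack$data[, , k]
    looks_like_lumen <- mean(img[moved]) >= threshold * 0.8
    band <- EBImage::dilate(moved * 1, brush) > 0
    cand <- band & (img >= threshold)
    ok <- FALSE
    if (any(cand) && looks_like_lumen) {
      lab <- EBImage::bwlabel(cand * 1)
      overlap <- tabulate(lab[moved & lab > 0])
      if (length(overlap) && max(overlap) > 0) {
        # an occluding contraction can pinch the lumen into separate pools:
        # keep every component that genuinely overlaps the propagated mask
        keep <- which(overlap >= max(3, 0.02 * sum(moved)))
        if (!length(keep)) keep <- which.max(overlap)
        mask <- EBImage::fillHull(matrix(as.integer(lab %in% keep),
                                         nrow(lab))) > 0
        ok <- TRUE
      }
    }
    if (!ok) {
      masks[[k]] <- prev
      flagged <- c(flagged, k)
    } else masks[[k]] <- mask
  }
  structure(masks, flagged_frames = flagged, threshold = threshold)
}
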