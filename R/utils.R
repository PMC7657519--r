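#' Bilinear sampling of a matrix at fractional indices
#'
#' @param m Numeric matrix.
#' @param xi,yi Fractional row/column indices (1-based), same length.
#' @param outside Value returned for samples outside the matrix.
#' @return Numeric vector of sampled values.
#' @keywords internal
#' @noRd
bilinear_sample <- function(m, xi, yi, outside = 0) {
  nx <- nrow(m); ny <- ncol(m)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 <= nx - 1 & y0 <= ny - 1
  # clamp exact upper edge into the last cell
  hit <- xi >= 1 & yi >= 1 & xi <= nx & yi <= ny & !ok
  x0[hit] <- pmin(x0[hit], nx - 1); y0[hit] <- pmin(y0[hit], ny - 1)
  fx[hit] <- xi[hit] - x0[hit]; fy[hit] <- yi[hit] - y0[hit]
  ok <- ok | hit
  out <- rep(outside, length(xi))
  if (any(ok)) {
    i00 <- cbind(x0[ok], y0[ok]); i10 <- cbind(x0[ok] + 1, y0[ok])
    i01 <- cbind(x0[ok], y0[ok] + 1); i11 <- cbind(x0[ok] + 1, y0[ok] + 1)
    out[ok] <- m[i00] * (1 - fx[ok]) * (1 - fy[ok]) + m[i10] * fx[ok] * (1 - fy[ok]) +
      m[i01] * (1 - fx[ok]) * fy[ok] + m[i11] * fx[ok] * fy[ok]
  }
  out
}

#' Trapezoidal integral on a uniform grid
#' @keywords internal
#' @noRd
trapz_uniform <- function(y, dx) {
  n <- length(y)
  if (n < 2) abort("Need at least 2 samples to integrate.")
  dx * (sum(y) - (y[1] + y[n]) / 2)
}

#' Frame acquisition times of a phantom block
#' @keywords internal
#' @noRd
frame_times <- function(phantom) (seq_len(phantom$n_frames) - 1) * phantom$frame_dt_s

ramp01 <- function(u) pmin(1, pmax(0, u + 0.5))
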