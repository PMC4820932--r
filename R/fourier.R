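# Small Fourier toolbox shared by the simulator and the refinement loop.

# Signed integer frequencies for an even-length FFT grid, in cycles/box.
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k >= n / 2] <- k[k >= n / 2] - n
  k
}

#' Sub-pixel image translation (Fourier shift)
#'
#' Translates a square image by `(dx, dy)` pixels using the Fourier shift
#' theorem; exact for periodic images and the identity for zero shift.
#' `dx` moves content along the first array dimension (image x, the
#' direction perpendicular to the tilt axis), `dy` along the second.
#'
#' @param img square numeric matrix.
#' @param dx,dy shift in pixels (may be fractional).
#' @return shifted matrix.
#' @export
shift_image <- function(img, dx, dy) {
  if (dx == 0 && dy == 0) return(img)
  n <- nrow(img)
  k <- fft_freqs(n)
  px <- exp(-2i * pi * k * dx / n)
  py <- exp(-2i * pi * k * dy / n)
  Re(fft(fft(img) * outer(px, py), inverse = TRUE)) / n^2
}

# Gaussian low-pass with half-maximum at spatial frequency 1/cutoff_A.
lowpass_image <- function(img, pixel_size, cutoff_A) {
  if (!is.finite(cutoff_A) || cutoff_A <= 0) return(img)
  n <- nrow(img)
  f <- fft_freqs(n) / (n * pixel_size)
  f2 <- outer(f^2, f^2, "+")
  H <- exp(-log(2) * f2 * cutoff_A^2)
  Re(fft(fft(img) * H, inverse = TRUE)) / n^2
}

# Gaussian low-pass of a 3D grid, half-maximum at 1/cutoff_A. Runs as a
# separable real-space convolution (zero padding at the grid edge): the
# Fourier response exp(-ln2 f^2 c^2) corresponds to a real-space sigma of
# c * sqrt(ln2/2) / pi, and the convolution is far cheaper than a 3D FFT at
# the box sizes the refinement loop uses.
lowpass_volume <- function(grid, pixel_size, cutoff_A) {
  if (!is.finite(cutoff_A) || cutoff_A <= 0) return(grid)
  n <- dim(grid)[1]
  sigma_px <- cutoff_A * sqrt(log(2) / 2) / pi / pixel_size
  gaussian_blur3_cpp(grid, n, max(sigma_px, 0.3))
}

# Ramp (R-weighting) filter along image x, the direction perpendicular to
# the vertical tilt axis; compensates the 1/|r| over-sampling of low
# frequencies in single-axis back-projection.
ramp_filter_image <- function(img) {
  n <- nrow(img)
  w <- abs(fft_freqs(n)) / (n / 2)
  Re(fft(fft(img) * matrix(w, n, n), inverse = TRUE)) / n^2
}

# Locate the translation of `img` relative to `ref` by the Fourier
# cross-correlation peak within a +/- max_shift search window, with 3-point
# parabolic sub-pixel refinement per axis. Ties broken toward the smaller
# shift magnitude; a peak on the search boundary is flagged.
cross_correlation_shift <- function(ref, img, max_shift) {
  n <- nrow(ref)
  cc <- Re(fft(fft(img) * Conj(fft(ref)), inverse = TRUE)) / n^2
  k <- fft_freqs(n)  # shift value for each cc index
  sel <- which(abs(k) <= max_shift)
  sub <- cc[sel, sel, drop = FALSE]
  mx <- max(sub)
  cand <- which(sub >= mx - 1e-12 * abs(mx), arr.ind = TRUE)
  ksel <- k[sel]
  mag <- ksel[cand[, 1]]^2 + ksel[cand[, 2]]^2
  best <- cand[which.min(mag), ]
  sx <- ksel[best[1]]; sy <- ksel[best[2]]
  on_boundary <- max(abs(c(sx, sy))) >= max_shift

  # parabolic refinement on the full wrapped correlation surface
  refine <- function(center, axis) {
    idx <- function(s) ((s %% n) + n) %% n + 1L
    if (axis == 1L) {
      c0 <- cc[idx(center), idx(sy)]
      cm <- cc[idx(center - 1), idx(sy)]
      cp <- cc[idx(center + 1), idx(sy)]
    } else {
      c0 <- cc[idx(sx), idx(center)]
      cm <- cc[idx(sx), idx(center - 1)]
      cp <- cc[idx(sx), idx(center + 1)]
    }
    den <- cm - 2 * c0 + cp
    if (abs(den) < 1e-300) return(0)
    delta <- 0.5 * (cm - cp) / den
    max(min(delta, 0.5), -0.5)
  }
  dx <- sx + if (!on_boundary) refine(sx, 1L) else 0
  dy <- sy + if (!on_boundary) refine(sy, 2L) else 0
  list(shift = c(dx, dy), peak = mx, on_boundary = on_boundary)
}

# Binary dilation of a logical array by `px` single-voxel steps
# (6/4-neighbourhood per step, applied px times).
dilate_mask <- function(mask, px = 1L) {
  d <- dim(mask)
  nd <- length(d)
  for (rep in seq_len(px)) {
    out <- mask
    for (ax in seq_len(nd)) {
      lo <- mask; hi <- mask
      idx_to <- lapply(d, seq_len)
      idx_lo_to <- idx_to; idx_lo_from <- idx_to
      idx_lo_to[[ax]] <- seq_len(d[ax] - 1L)
      idx_lo_from[[ax]] <- 2:d[ax]
      lo[] <- FALSE; hi[] <- FALSE
      lo <- do.call(`[<-`, c(list(lo), idx_lo_to,
                             list(do.call(`[`, c(list(mask), idx_lo_from,
                                                 list(drop = FALSE))))))
      idx_hi_to <- idx_to; idx_hi_from <- idx_to
      idx_hi_to[[ax]] <- 2:d[ax]
      idx_hi_from[[ax]] <- seq_len(d[ax] - 1L)
      hi <- do.call(`[<-`, c(list(hi), idx_hi_to,
                             list(do.call(`[`, c(list(mask), idx_hi_from,
                                                 list(drop = FALSE))))))
      out <- out | lo | hi
    }
    mask <- out
  }
  mask
}
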