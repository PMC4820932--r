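# Fourier shell correlation and the 0.5-threshold resolution criterion.

#' Fourier shell correlation between two volumes
#'
#' Per-shell normalized cross-correlation of the Fourier coefficients of two
#' half-set reconstructions, shell width one Fourier voxel, shells up to
#' Nyquist.
#'
#' @param vol_a,vol_b [density_volume()] objects of equal shape and pixel
#'   size.
#' @return An object of class `fsc_curve` with `shell_freqs` (1/Angstrom,
#'   strictly increasing) and `correlations` (in `[-1, 1]`).
#' @export
compute_fsc <- function(vol_a, vol_b) {
  stopifnot(inherits(vol_a, "density_volume"),
            inherits(vol_b, "density_volume"))
  if (!identical(dim(vol_a$grid), dim(vol_b$grid)))
    stop("volume shapes differ")
  if (vol_a$pixel_size != vol_b$pixel_size)
    stop("pixel sizes differ")
  n <- dim(vol_a$grid)[1]
  fa <- fft(vol_a$grid)
  fb <- fft(vol_b$grid)
  k <- fft_freqs(n)
  r <- sqrt(outer(outer(k^2, k^2, "+"), k^2, "+"))
  shell <- as.integer(round(r))
  keep <- shell >= 1L & shell <= n %/% 2L
  sh <- shell[keep]
  cross <- Re(fa * Conj(fb))[keep]
  pa <- (Mod(fa)^2)[keep]
  pb <- (Mod(fb)^2)[keep]
  sums <- rowsum(cbind(cross, pa, pb), sh)
  shells <- as.integer(rownames(sums))
  den <- sqrt(sums[, 2] * sums[, 3])
  corr <- ifelse(den > 0, sums[, 1] / den, 0)
  structure(list(shell_freqs = shells / (n * vol_a$pixel_size),
                 correlations = as.numeric(corr)),
            class = "fsc_curve")
}

#' Resolution at an FSC threshold
#'
#' Finds the first frequency at which the FSC curve falls to the threshold
#' (default 0.5), linearly interpolated between shells; if the curve never
#' crosses, returns Nyquist (twice the sampling implied by the last shell)
#' with `crossed = FALSE`.
#'
#' @param fsc an `fsc_curve` from [compute_fsc()].
#' @param threshold FSC threshold (default 0.5).
#' @return list with `resolution_A`, `freq` (1/Angstrom) and `crossed`.
#' @export
resolution_at_threshold <- function(fsc, threshold = 0.5) {
  f <- fsc$shell_freqs
  c_ <- fsc$correlations
  if (length(f) == 0) stop("empty FSC curve")
  i <- which(c_ <= threshold)
  if (length(i) == 0)
    return(list(resolution_A = 1 / max(f), freq = max(f), crossed = FALSE))
  i <- i[1]
  if (i == 1) {
    # crossing before the first shell: interpolate from (0, 1)
    f0 <- 0; c0 <- 1
  } else {
    f0 <- f[i - 1]; c0 <- c_[i - 1]
  }
  fc <- if (c0 == c_[i]) f[i] else f0 + (c0 - threshold) / (c0 - c_[i]) *
    (f[i] - f0)
  list(resolution_A = 1 / fc, freq = fc, crossed = TRUE)
}

#' Half-set FSC of an aligned tilt series
#'
#' Splits the aligned images into odd- and even-indexed halves, reconstructs
#' each, and returns their FSC curve together with the 0.5-crossing
#' resolution.
#'
#' @param tilt a [tilt_series()].
#' @param shifts per-image shifts from refinement (or NULL for none).
#' @param weighting back-projection weighting.
#' @param threshold FSC threshold for the reported resolution.
#' @return list with `fsc`, `resolution` (from [resolution_at_threshold()]),
#'   `odd` and `even` half-map [density_volume()]s.
#' @export
halfset_fsc <- function(tilt, shifts = NULL, weighting = "ramp",
                        threshold = 0.5) {
  nimg <- dim(tilt$images)[3]
  odd <- reconstruct_volume(tilt, shifts, weighting,
                            subset = seq(1, nimg, by = 2))
  even <- reconstruct_volume(tilt, shifts, weighting,
                             subset = seq(2, nimg, by = 2))
  fsc <- compute_fsc(odd, even)
  list(fsc = fsc, resolution = resolution_at_threshold(fsc, threshold),
       odd = odd, even = even)
}
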