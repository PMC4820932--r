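# Single-axis projection geometry. The tilt axis is the image vertical (y);
# the beam runs along z at zero tilt; rotation mixes x and z with bilinear
# interpolation, values outside the grid treated as zero. project_volume and
# back_project are exact matrix adjoints (same interpolation weights).

#' Project a volume along a tilted beam
#'
#' Computes line integrals of the density along the beam direction after
#' rotating the sampling rays about the vertical (y) tilt axis. A linear
#' operator; at 0 degrees the image equals the plain z-axis sum of the grid.
#'
#' @param volume a [density_volume()].
#' @param angle_deg tilt angle in degrees, within +/- 90.
#' @return n x n numeric matrix (image x = array x, image y = array y).
#' @export
project_volume <- function(volume, angle_deg) {
  stopifnot(inherits(volume, "density_volume"))
  if (abs(angle_deg) > 90) stop("tilt angle must be within +/- 90 degrees")
  project_vol_cpp(volume$grid, dim(volume$grid)[1], angle_deg)
}

#' Back-project a tilt series into a volume
#'
#' Un-shifts each image by its current shift estimate, optionally applies the
#' ramp (R-weighting) filter, then smears it through the volume along its
#' beam direction and sums. With `weighting = "none"` and zero shifts this is
#' the exact adjoint of [project_volume()].
#'
#' @param tilt a [tilt_series()].
#' @param shifts n_images x 2 matrix of (dx, dy) pixel shifts to remove from
#'   each image (zeros for the raw initial model).
#' @param weighting `"none"` (plain adjoint sum) or `"ramp"` (R-weighted).
#' @param normalize divide the sum by the number of images (off for the pure
#'   adjoint).
#' @return a [density_volume()]; attribute `weighting` records the variant.
#' @export
back_project <- function(tilt, shifts = NULL,
                         weighting = c("none", "ramp"), normalize = FALSE) {
  stopifnot(inherits(tilt, "tilt_series"))
  weighting <- match.arg(weighting)
  n <- dim(tilt$images)[1]
  nimg <- dim(tilt$images)[3]
  if (is.null(shifts)) shifts <- matrix(0, nimg, 2)
  shifts <- as.matrix(shifts)
  if (nrow(shifts) != nimg || ncol(shifts) != 2)
    stop("shifts must be an n_images x 2 matrix")
  w <- if (normalize) 1 / nimg else 1
  stack <- tilt$images
  k <- fft_freqs(n)
  rampW <- if (weighting == "ramp") matrix(abs(k) / (n / 2), n, n) else NULL
  for (i in seq_len(nimg)) {
    sh <- any(shifts[i, ] != 0)
    if (!sh && weighting != "ramp") next
    FF <- fft(stack[, , i])
    if (sh)
      FF <- FF * outer(exp(2i * pi * k * shifts[i, 1] / n),
                       exp(2i * pi * k * shifts[i, 2] / n))
    if (!is.null(rampW)) FF <- FF * rampW
    stack[, , i] <- Re(fft(FF, inverse = TRUE)) / n^2
  }
  vol <- back_project_stack_cpp(stack, n, tilt$angles, w)
  out <- density_volume(vol, tilt$pixel_size)
  attr(out, "weighting") <- weighting
  out
}

# Reconstruction used inside the refinement loop: normalized, ramp-weighted
# by default. `subset` selects images (e.g. odd/even half-sets).
reconstruct_volume <- function(tilt, shifts = NULL,
                               weighting = c("ramp", "none"),
                               subset = NULL) {
  weighting <- match.arg(weighting)
  nimg <- dim(tilt$images)[3]
  if (is.null(shifts)) shifts <- matrix(0, nimg, 2)
  if (!is.null(subset)) {
    tilt <- tilt_series(tilt$images[, , subset, drop = FALSE],
                        tilt$angles[subset], tilt$pixel_size,
                        tilt$true_shifts[subset, , drop = FALSE],
                        tilt$noise_seed)
    shifts <- shifts[subset, , drop = FALSE]
  }
  back_project(tilt, shifts, weighting = weighting, normalize = TRUE)
}
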