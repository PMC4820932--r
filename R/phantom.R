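# Phantom rendering and tilt-series simulation.
#
# Densities are in arbitrary units: the DNA tube renders at 1, gold spheres
# at 5 (hard spheres; the 5:1 contrast stands in for the unstated
# stain/gold ratio). Gold is additive on top of the DNA tube; the PEG shell
# is not modelled.

# Resample a polyline (m x 3) to roughly uniform spacing (last point kept).
resample_polyline <- function(pts, spacing) {
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L == 0) return(pts[1, , drop = FALSE])
  ss <- unique(c(seq(0, L, by = spacing), L))
  out <- sapply(1:3, function(k) approx(s, pts[, k], xout = ss)$y)
  matrix(out, ncol = 3)
}

# Stamp a ball of radius r_px (pixels) centred at cv (0-based voxel coords)
# into logical array `mask` (union semantics). Returns the updated mask.
stamp_ball <- function(mask, cv, r_px) {
  n <- dim(mask)[1]
  rng <- lapply(1:3, function(k) {
    lo <- max(1L, floor(cv[k] - r_px) + 1L)
    hi <- min(n, ceiling(cv[k] + r_px) + 1L)
    lo:hi
  })
  ax <- (rng[[1]] - 1 - cv[1])^2
  ay <- (rng[[2]] - 1 - cv[2])^2
  az <- (rng[[3]] - 1 - cv[3])^2
  ball <- outer(outer(ax, ay, "+"), az, "+") <= r_px^2
  mask[rng[[1]], rng[[2]], rng[[3]]] <-
    mask[rng[[1]], rng[[2]], rng[[3]]] | ball
  mask
}

# Stamp a soft (Gaussian-profile) blob with half-maximum at radius r_px
# into a numeric array with max-union semantics, so overlapping stamps
# along a polyline keep the full value on the centerline ridge.
stamp_soft_ball <- function(grid, cv, r_px, value) {
  n <- dim(grid)[1]
  reach <- 2.4 * r_px
  rng <- lapply(1:3, function(k) {
    lo <- max(1L, floor(cv[k] - reach) + 1L)
    hi <- min(n, ceiling(cv[k] + reach) + 1L)
    lo:hi
  })
  ax <- (rng[[1]] - 1 - cv[1])^2
  ay <- (rng[[2]] - 1 - cv[2])^2
  az <- (rng[[3]] - 1 - cv[3])^2
  r2 <- outer(outer(ax, ay, "+"), az, "+")
  blob <- value * exp(-log(2) * r2 / r_px^2)
  blob[blob < 0.02 * value] <- 0
  grid[rng[[1]], rng[[2]], rng[[3]]] <-
    pmax(grid[rng[[1]], rng[[2]], rng[[3]]], blob)
  grid
}

#' Render a DNA-nanogold phantom into a density volume
#'
#' Renders the conjugate centred in a cubic box: the DNA as a soft-edged
#' tube (Gaussian radial profile, density `dna_density` on the centerline,
#' half-maximum at `dna_tube_width / 2`), the two gold particles as hard
#' spheres of uniform density `gold_density`, additive where they overlap
#' the tube. The attribute `integral` holds the total integrated density in
#' density-units x Angstrom^3.
#'
#' @param phantom a [conjugate_phantom()].
#' @param box_px box edge in pixels (even).
#' @param pixel_size Angstrom per pixel (default 0.94, the acquisition scale).
#' @param dna_density,gold_density rendered densities (defaults 1 and 5).
#' @return a [density_volume()].
#' @export
render_phantom <- function(phantom, box_px, pixel_size = 0.94,
                           dna_density = 1, gold_density = 5) {
  stopifnot(inherits(phantom, "conjugate_phantom"))
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  n <- as.integer(box_px)
  if (n %% 2 != 0) stop("box_px must be even")
  ch <- phantom$chain
  r_gold <- phantom$gold_diameters / 2
  w2 <- phantom$dna_tube_width / 2

  pts_lo <- rbind(sweep(ch$centers, 2, rep(w2, 1)),
                  phantom$gold_centers - r_gold)
  pts_hi <- rbind(sweep(ch$centers, 2, rep(-w2, 1)),
                  phantom$gold_centers + r_gold)
  bmin <- apply(pts_lo, 2, min)
  bmax <- apply(pts_hi, 2, max)
  mid <- (bmin + bmax) / 2
  half_ext <- (bmax - bmin) / 2
  limit <- (n / 2 - 1.5) * pixel_size
  if (any(half_ext > limit)) {
    k <- which.max(half_ext)
    stop(sprintf(
      "phantom extent %.1f A along axis %d exceeds the %.1f A half-box",
      half_ext[k], k, limit))
  }
  # Angstrom -> 0-based voxel coordinate, phantom centred at voxel n/2
  to_vox <- function(p) sweep(p, 2, mid) / pixel_size +
    matrix(n / 2, nrow(p), 3)

  # DNA tube with a Gaussian radial profile: full density on the
  # centerline, half-maximum at the nominal tube radius -- as in stained
  # maps, where the density ridge follows the duplex axis
  grid <- array(0, c(n, n, n))
  if (dna_density > 0) {
    line <- resample_polyline(ch$centers, pixel_size / 2)
    linev <- to_vox(line)
    r_tube <- w2 / pixel_size
    for (i in seq_len(nrow(linev)))
      grid <- stamp_soft_ball(grid, linev[i, ], r_tube, dna_density)
  }

  gv <- to_vox(phantom$gold_centers)
  for (j in 1:2) {
    gm <- stamp_ball(array(FALSE, c(n, n, n)), gv[j, ],
                     r_gold[j] / pixel_size)
    grid[gm] <- grid[gm] + gold_density
  }
  vol <- density_volume(grid, pixel_size)
  attr(vol, "integral") <- sum(grid) * pixel_size^3
  attr(vol, "center_A") <- mid
  vol
}

# Split a conjugate volume into DNA-like and gold-like parts by the density
# midpoint (gold renders well above the DNA tube level).
split_gold_dna <- function(grid, gold_frac = 0.5) {
  thr <- gold_frac * max(grid)
  gold <- grid
  gold[grid < thr] <- 0
  list(dna = grid - gold, gold = gold, threshold = thr)
}

#' Simulate a single-axis tilt series
#'
#' Projects the volume at each tilt angle (same projection operator as the
#' reconstruction), applies a uniform random sub-pixel translation in
#' `[-max_shift_px, max_shift_px]^2` per image, and adds white Gaussian
#' noise scaled so the DNA-region SNR (the metrology definition: gold area
#' excluded) hits `target_snr` per image. With `target_snr = Inf` and
#' `max_shift_px = 0` the images equal the plain projections exactly.
#'
#' @param volume a [density_volume()] (non-empty).
#' @param angle_min,angle_max,step tilt range and increment in degrees
#'   (defaults -60, +60, 1.5: 81 images).
#' @param target_snr DNA-region SNR per image (default 0.31, the observed
#'   average; `Inf` disables noise).
#' @param max_shift_px maximum random translation per image, pixels.
#' @param seed integer seed for shifts and noise.
#' @return a [tilt_series()] with `true_shifts` recorded.
#' @export
simulate_tilt_series <- function(volume, angle_min = -60, angle_max = 60,
                                 step = 1.5, target_snr = 0.31,
                                 max_shift_px = 0, seed = 1) {
  stopifnot(inherits(volume, "density_volume"))
  if (step <= 0) stop("step must be > 0")
  if (!(target_snr > 0)) stop("target_snr must be > 0")
  g <- volume$grid
  if (all(g == 0)) stop("degenerate all-zero volume")
  n <- dim(g)[1]
  angles <- seq(angle_min, angle_max, by = step)
  nimg <- length(angles)
  noisy <- is.finite(target_snr)
  set.seed(derive_seed(seed, 2L))
  shifts <- matrix(runif(2 * nimg, -max_shift_px, max_shift_px), nimg, 2)
  if (max_shift_px == 0) shifts[] <- 0

  projs <- project_stack_cpp(g, n, angles)
  sigmas <- rep(NA_real_, nimg)
  if (noisy) {
    # first pass: per-image noise level from the DNA-region signal (gold
    # shadow excluded). At orientations where the gold projections eclipse
    # the whole DNA the mask is empty; those images inherit the median
    # noise level of the others.
    parts <- split_gold_dna(g)
    pds <- project_stack_cpp(parts$dna, n, angles)
    pgs <- project_stack_cpp(parts$gold, n, angles)
    for (i in seq_len(nimg)) {
      proj <- projs[, , i]
      pd <- pds[, , i]
      pg <- pgs[, , i]
      sig_mask <- pd > 0.02 * max(pd) & pg <= 0.02 * max(pg)
      bg_mask <- !dilate_mask(proj > 1e-9 * max(proj), 3L)
      if (any(sig_mask) && any(bg_mask)) {
        signal <- mean(proj[sig_mask]) - mean(proj[bg_mask])
        sigmas[i] <- signal / target_snr
      }
    }
    if (all(is.na(sigmas)))
      stop("cannot calibrate noise: empty DNA or background region")
    sigmas[is.na(sigmas)] <- median(sigmas, na.rm = TRUE)
  }
  images <- array(0, c(n, n, nimg))
  for (i in seq_len(nimg)) {
    img <- projs[, , i]
    if (any(shifts[i, ] != 0))
      img <- shift_image(img, shifts[i, 1], shifts[i, 2])
    if (noisy) img <- img + matrix(rnorm(n * n, 0, sigmas[i]), n, n)
    images[, , i] <- img
  }
  tilt_series(images, angles, volume$pixel_size, true_shifts = shifts,
              noise_seed = derive_seed(seed, 2L))
}
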