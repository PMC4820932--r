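#' @useDynLib ipetdna, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif cor sd integrate approx median prcomp
#'   dist setNames
#' @importFrom utils head tail write.csv read.csv packageVersion
NULL

# Boltzmann constant in kcal mol^-1 K^-1
.kB <- 1.9872e-3

#' Worm-like-chain parameters
#'
#' Bundles the parameters of the discrete worm-like chain (WLC) used
#' throughout: number of base pairs, persistence length, rise per base pair
#' and temperature. The canonical B-DNA values are the defaults: persistence
#' length 500 A (50 nm) and rise 3.4 A.
#'
#' @param n_bp integer, number of base pairs (>= 3).
#' @param l_p persistence length in Angstrom (> 0).
#' @param d rise per base pair in Angstrom (> 0).
#' @param temperature temperature in Kelvin (> 0).
#' @return An object of class `wlc_params`.
#' @export
#' @examples
#' p <- wlc_params(84)
#' p$l_p  # 500 A
wlc_params <- function(n_bp, l_p = 500, d = 3.4, temperature = 298) {
  n_bp <- as.integer(n_bp)
  if (is.na(n_bp) || n_bp < 3L) stop("n_bp must be an integer >= 3")
  if (!is.finite(l_p) || l_p <= 0) stop("l_p must be > 0")
  if (!is.finite(d) || d <= 0) stop("d must be > 0")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  structure(list(n_bp = n_bp, l_p = l_p, d = d,
                 temperature = temperature, k_B = .kB),
            class = "wlc_params")
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("WLC parameters: %d bp, l_p = %g A, rise = %g A, T = %g K\n",
              x$n_bp, x$l_p, x$d, x$temperature))
  invisible(x)
}

#' dsDNA chain conformation
#'
#' An ordered list of base-pair centres C_i (Angstrom) together with the
#' unit step axes (one per base-pair step, so `nrow(axes) == nrow(centers) - 1`)
#' and the nominal rise.
#'
#' @param centers numeric n x 3 matrix of base-pair centres, Angstrom.
#' @param axes numeric (n-1) x 3 matrix of unit step vectors.
#' @param rise rise per base pair in Angstrom.
#' @return An object of class `chain_conformation`.
#' @export
chain_conformation <- function(centers, axes, rise) {
  centers <- as.matrix(centers)
  axes <- as.matrix(axes)
  if (ncol(centers) != 3 || ncol(axes) != 3)
    stop("centers and axes must have 3 columns")
  if (nrow(axes) != nrow(centers) - 1L)
    stop("need exactly one step axis per consecutive pair of centers")
  nrm <- sqrt(rowSums(axes^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("step axes must be unit vectors")
  structure(list(centers = centers, axes = axes, rise = rise),
            class = "chain_conformation")
}

#' @export
print.chain_conformation <- function(x, ...) {
  ee <- sqrt(sum((x$centers[nrow(x$centers), ] - x$centers[1, ])^2))
  cat(sprintf("dsDNA conformation: %d bp, rise %.3g A, end-to-end %.1f A\n",
              nrow(x$centers), x$rise, ee))
  invisible(x)
}

#' Contour length of a chain conformation
#'
#' Sum of distances between consecutive base-pair centres, Angstrom.
#' @param chain a [chain_conformation()].
#' @return length in Angstrom.
#' @export
chain_length <- function(chain) {
  d <- diff(chain$centers)
  sum(sqrt(rowSums(d^2)))
}

#' End-to-end distance of a chain conformation
#' @param chain a [chain_conformation()].
#' @return distance in Angstrom.
#' @export
end_to_end <- function(chain) {
  sqrt(sum((chain$centers[nrow(chain$centers), ] - chain$centers[1, ])^2))
}

#' DNA-nanogold conjugate phantom
#'
#' A chain conformation plus two gold spheres tethered at the DNA ends. Each
#' gold centre is placed at the corresponding chain end, offset outward along
#' the terminal step axis by one gold radius, mirroring a sphere bonded to the
#' DNA terminus.
#'
#' @param chain a [chain_conformation()].
#' @param gold_diameters numeric length-2, sphere diameters in Angstrom
#'   (default `c(63, 63)`, the ~5 nm nanogold of the imaged conjugates).
#' @param dna_tube_width width of the DNA density tube in Angstrom
#'   (default 20, the ~2 nm width of B-DNA).
#' @return An object of class `conjugate_phantom`.
#' @export
conjugate_phantom <- function(chain, gold_diameters = c(63, 63),
                              dna_tube_width = 20) {
  stopifnot(inherits(chain, "chain_conformation"))
  gold_diameters <- as.numeric(gold_diameters)
  if (length(gold_diameters) != 2 || any(gold_diameters <= 0))
    stop("gold_diameters must be two positive lengths")
  n <- nrow(chain$centers)
  r <- gold_diameters / 2
  g1 <- chain$centers[1, ] - chain$axes[1, ] * r[1]
  g2 <- chain$centers[n, ] + chain$axes[n - 1L, ] * r[2]
  structure(list(chain = chain,
                 gold_centers = rbind(g1, g2),
                 gold_diameters = gold_diameters,
                 dna_tube_width = dna_tube_width),
            class = "conjugate_phantom")
}

#' Cubic 3D density volume
#'
#' Carrier of phantoms and reconstructions: a cubic grid of densities with a
#' pixel size in Angstrom. Edge length must be even (the volume centre is the
#' voxel coordinate N/2, 0-based).
#'
#' @param grid cubic 3D numeric array.
#' @param pixel_size voxel edge in Angstrom (> 0).
#' @param origin 3-vector offset of voxel (0,0,0) in Angstrom.
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(grid, pixel_size, origin = c(0, 0, 0)) {
  d <- dim(grid)
  if (length(d) != 3 || length(unique(d)) != 1)
    stop("grid must be a cubic 3D array")
  if (d[1] %% 2 != 0) stop("grid edge length must be even")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(grid = grid, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  n <- dim(x$grid)[1]
  cat(sprintf("density volume: %d^3 voxels at %.3g A/px (%.1f A box)\n",
              n, x$pixel_size, n * x$pixel_size))
  invisible(x)
}

#' Tilt series of projection images
#'
#' @param images 3D array (n_px x n_px x n_images) of square projection
#'   images, ordered as `angles`.
#' @param angles tilt angles in degrees, strictly increasing.
#' @param pixel_size Angstrom per pixel.
#' @param true_shifts optional n_images x 2 matrix of ground-truth (dx, dy)
#'   pixel offsets applied to each image (synthetic data only).
#' @param noise_seed integer seed used for the noise, or NA.
#' @return An object of class `tilt_series`.
#' @export
tilt_series <- function(images, angles, pixel_size, true_shifts = NULL,
                        noise_seed = NA_integer_) {
  d <- dim(images)
  if (length(d) != 3 || d[1] != d[2]) stop("images must be square, stacked")
  if (d[3] != length(angles)) stop("one image per angle required")
  if (anyDuplicated(angles)) stop("angles must be distinct")
  if (is.unsorted(angles)) {
    # store in strictly increasing angle order regardless of input order
    o <- order(angles)
    images <- images[, , o, drop = FALSE]
    angles <- angles[o]
    if (!is.null(true_shifts)) true_shifts <- true_shifts[o, , drop = FALSE]
  }
  if (is.null(true_shifts)) true_shifts <- matrix(0, d[3], 2)
  structure(list(images = images, angles = angles, pixel_size = pixel_size,
                 true_shifts = true_shifts, noise_seed = noise_seed),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  cat(sprintf(
    "tilt series: %d images of %d^2 px at %.3g A/px, %g to %g deg\n",
    dim(x$images)[3], dim(x$images)[1], x$pixel_size,
    min(x$angles), max(x$angles)))
  invisible(x)
}

#' Detected gold particle
#'
#' @param center particle centre (2- or 3-vector), Angstrom.
#' @param diameter_long extent along the longest direction, Angstrom.
#' @param diameter_perp extent perpendicular to it, Angstrom.
#' @return An object of class `gold_particle`; `diameter_geometric` is the
#'   geometric mean `sqrt(diameter_long * diameter_perp)`.
#' @export
gold_particle <- function(center, diameter_long, diameter_perp) {
  if (diameter_long <= 0 || diameter_perp <= 0)
    stop("diameters must be positive")
  structure(list(center = as.numeric(center),
                 diameter_long = diameter_long,
                 diameter_perp = diameter_perp,
                 diameter_geometric = sqrt(diameter_long * diameter_perp)),
            class = "gold_particle")
}

#' Pair of linked gold particles
#'
#' @param a,b [gold_particle()] objects.
#' @return An object of class `particle_pair` with the centre-to-centre
#'   `distance` in Angstrom.
#' @export
particle_pair <- function(a, b) {
  stopifnot(inherits(a, "gold_particle"), inherits(b, "gold_particle"))
  dist <- sqrt(sum((a$center - b$center)^2))
  if (dist <= 0) stop("coincident particle centers")
  structure(list(a = a, b = b, distance = dist), class = "particle_pair")
}

#' Per-joint bend angles of a conformation
#'
#' Holds the two bend-angle constructions of a base-pair cylinder model:
#' `theta` (angle formed by the centres of three consecutive cylinders,
#' deviation from collinearity; `n_cyl - 2` values) and `phi` (angle between
#' the axes of two consecutive cylinders; `n_cyl - 1` values), together with
#' the WLC parameters that convert them to energy.
#'
#' @param theta,phi numeric vectors of angles in radians, each in `[0, pi]`.
#' @param params a [wlc_params()].
#' @return An object of class `bend_angle_set`.
#' @export
bend_angle_set <- function(theta, phi, params) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(theta < -1e-12 | theta > pi + 1e-12) ||
      any(phi < -1e-12 | phi > pi + 1e-12))
    stop("angles must lie in [0, pi]")
  structure(list(theta = pmin(pmax(theta, 0), pi),
                 phi = pmin(pmax(phi, 0), pi),
                 params = params),
            class = "bend_angle_set")
}
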