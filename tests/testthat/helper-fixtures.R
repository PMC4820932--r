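# Shared fixtures, all generated in code.

# Uniform ball of radius r_px voxels centred in an n^3 grid (0-based centre
# at n/2), value `value`. The edge is anti-aliased over one voxel so the
# phantom is band-limited enough for interpolation-level comparisons.
make_ball_volume <- function(n, r_px, value = 1, pixel_size = 1,
                             sharp = FALSE) {
  x <- (0:(n - 1)) - n / 2
  r <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
  g <- if (sharp) as.numeric(r <= r_px) else pmin(pmax(r_px + 0.5 - r, 0), 1)
  density_volume(array(g * value, c(n, n, n)), pixel_size)
}

# Gaussian-smoothed (band-limited) ball.
smooth_ball_volume <- function(n, r_px, sigma = 1.5, pixel_size = 1) {
  vol <- make_ball_volume(n, r_px, pixel_size = pixel_size)
  density_volume(ipetdna:::gaussian_blur3_cpp(vol$grid, n, sigma),
                 pixel_size)
}

# Small conjugate phantom that fits a modest box: n_bp base pairs of
# straight DNA plus two 63 A gold spheres.
small_conjugate_volume <- function(n_bp = 30, box = 128, pixel = 2.2,
                                   gold = c(63, 63), dna_density = 1,
                                   gold_density = 5) {
  ch <- build_straight_bdna(n_bp)
  ph <- conjugate_phantom(ch, gold_diameters = gold)
  render_phantom(ph, box, pixel, dna_density = dna_density,
                 gold_density = gold_density)
}

# A chain whose centres lie on a circular arc of radius R (Angstrom) in the
# xy plane, spaced `rise` apart.
make_arc_chain <- function(R, arc_angle, rise = 3.4) {
  n <- max(3L, floor(R * arc_angle / rise) + 1L)
  phi <- (seq_len(n) - 1) * rise / R
  centers <- cbind(R * sin(phi), R * (1 - cos(phi)), 0)
  d <- diff(centers)
  axes <- d / sqrt(rowSums(d^2))
  chain_conformation(centers, axes, rise)
}

# Independent oracle for the sampler moment <theta^2> under
# sin(theta) exp(-alpha theta^2 / 2) on [0, pi] (numerical quadrature).
oracle_theta_sq <- function(alpha) {
  f <- function(th) sin(th) * exp(-alpha * th^2 / 2)
  z <- integrate(f, 0, pi, rel.tol = 1e-12)$value
  integrate(function(th) th^2 * f(th), 0, pi, rel.tol = 1e-12)$value / z
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
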