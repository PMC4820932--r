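# ipet_reconstruction: projection operators, adjointness, masks, FSC,
# SNR, particle masks and the refinement fixed point. The full noisy
# shift-recovery property runs in test-acceptance.R at the stated scale.

test_that("projection at zero tilt is the axis sum", {
  set.seed(1)
  n <- 32
  vol <- density_volume(array(rnorm(n^3), c(n, n, n)), 1)
  # apply/sum accumulates in extended precision; agreement is at the
  # double rounding level
  expect_equal(project_volume(vol, 0), apply(vol$grid, c(1, 2), sum),
               tolerance = 1e-12)
})

test_that("ball projections are rotation-invariant and match chord lengths", {
  n <- 128; r <- 32
  # band-limited ball: rotation differences are pure interpolation error,
  # which scales as (voxel/feature size)^2 -- hence the finer grid here
  volb <- smooth_ball_volume(n, r, sigma = 7)
  p0 <- project_volume(volb, 0)
  p30 <- project_volume(volb, 30)
  expect_lt(sqrt(mean((p30 - p0)^2)) / sqrt(mean(p0^2)), 1e-3)

  # sharp ball: central profile vs analytic chord length 2 sqrt(r^2 - rho^2)
  vol <- make_ball_volume(n, 20, sharp = TRUE)
  ps <- project_volume(vol, 0)
  rho <- (0:(n - 1)) - n / 2
  inner <- abs(rho) < 0.8 * 20
  chord <- 2 * sqrt(pmax(20^2 - rho^2, 0))
  prof <- ps[, n / 2 + 1]
  expect_lt(sqrt(mean((prof[inner] - chord[inner])^2)) /
              sqrt(mean(chord[inner]^2)), 0.03)
})

test_that("projection is linear", {
  set.seed(2)
  n <- 24
  a <- array(rnorm(n^3), c(n, n, n))
  b <- array(rnorm(n^3), c(n, n, n))
  pab <- project_volume(density_volume(a + b, 1), 17)
  pa <- project_volume(density_volume(a, 1), 17)
  pb <- project_volume(density_volume(b, 1), 17)
  expect_equal(pab, pa + pb, tolerance = 1e-12)
})

test_that("back-projection of a single 0-degree image fills the beam line", {
  set.seed(3)
  n <- 16
  img <- matrix(rnorm(n^2), n, n)
  bp <- back_project(tilt_series(array(img, c(n, n, 1)), 0, 1))
  for (z in c(1, 5, n))
    expect_identical(bp$grid[, , z], img)
})

test_that("project/back_project satisfy the adjoint identity", {
  set.seed(4)
  n <- 32
  v <- array(rnorm(n^3), c(n, n, n))
  vol <- density_volume(v, 1)
  for (ang in c(-57.3, 0, 12.5, 60)) {
    img <- matrix(rnorm(n^2), n, n)
    lhs <- sum(project_volume(vol, ang) * img)
    rhs <- sum(v * back_project(
      tilt_series(array(img, c(n, n, 1)), ang, 1))$grid)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-4)
  }
})

test_that("back_project validates shift dimensions", {
  n <- 16
  ts <- tilt_series(array(0, c(n, n, 3)) + 1, c(-10, 0, 10), 1)
  expect_error(back_project(ts, matrix(0, 2, 2)), "shifts")
})

test_that("many-view noiseless reconstruction recovers a ball", {
  n <- 64
  vol <- smooth_ball_volume(n, 15, sigma = 1.5)
  # 81 views over the full angular range
  tilt <- simulate_tilt_series(vol, -90 + 1e-9, 90, 2.25, target_snr = Inf)
  rec <- reconstruct_volume(tilt, weighting = "ramp")
  expect_gt(cor(as.numeric(rec$grid), as.numeric(vol$grid)), 0.9)
  # the +-60-degree missing wedge degrades but does not destroy fidelity
  tiltw <- simulate_tilt_series(vol, -60, 60, 1.5, target_snr = Inf)
  recw <- reconstruct_volume(tiltw, weighting = "ramp")
  expect_gt(cor(as.numeric(recw$grid), as.numeric(vol$grid)), 0.75)
  # unweighted back-projection also correlates, more loosely
  bp <- back_project(tilt, normalize = TRUE)
  expect_gt(cor(as.numeric(bp$grid), as.numeric(vol$grid)), 0.7)
})

test_that("Gaussian-boundary mask has the stated profile", {
  m <- make_gaussian_mask(64, 20, 4)
  expect_equal(m[33, 33], 1)          # centre (0-based 32 = 64/2)
  expect_true(all(m >= 0 & m <= 1))
  # value one sigma beyond the radius: exp(-1/2)
  expect_equal(m[33 + 24, 33], exp(-0.5), tolerance = 1e-6)
  # exact circular symmetry: transpose and reflection about the centre
  # pixel (the centre is the 0-based n/2 voxel, index 33) leave it unchanged
  expect_identical(m, t(m))
  expect_identical(m[2:64, ], m[64:2, ])
  expect_error(make_gaussian_mask(64, 30, 4), "size_px / 2")
})

test_that("refinement is a fixed point on clean aligned data", {
  vol <- small_conjugate_volume(n_bp = 10, box = 64, pixel = 4)
  tilt <- simulate_tilt_series(vol, -60, 60, 6, target_snr = Inf,
                               max_shift_px = 0)
  ref <- ipet_refine(tilt, n_iterations = 3)
  expect_lt(max(abs(ref$state$shifts)), 0.1)
})

test_that("image order does not affect the reconstruction", {
  vol <- small_conjugate_volume(n_bp = 10, box = 64, pixel = 4)
  tilt <- simulate_tilt_series(vol, -60, 60, 10, target_snr = Inf)
  nimg <- length(tilt$angles)
  set.seed(5)
  perm <- sample(nimg)
  tilt_perm <- tilt_series(tilt$images[, , perm], tilt$angles[perm],
                           tilt$pixel_size)
  r1 <- reconstruct_volume(tilt)
  r2 <- reconstruct_volume(tilt_perm)
  expect_equal(r2$grid, r1$grid, tolerance = 1e-12)
})

test_that("FSC is 1 for identical and scaled volumes, ~0 for noise", {
  set.seed(6)
  n <- 32
  vol <- make_ball_volume(n, 10)
  fsc_self <- compute_fsc(vol, vol)
  expect_true(all(abs(fsc_self$correlations - 1) < 1e-9))
  expect_true(all(diff(fsc_self$shell_freqs) > 0))

  vol2 <- density_volume(2 * vol$grid, 1)
  expect_true(all(abs(compute_fsc(vol, vol2)$correlations - 1) < 1e-9))

  noise <- density_volume(array(rnorm(n^3), c(n, n, n)), 1)
  fsc_n <- compute_fsc(vol, noise)
  expect_true(all(abs(fsc_n$correlations[-(1:3)]) < 0.1))

  bad <- make_ball_volume(16, 5)
  expect_error(compute_fsc(vol, bad), "shapes")
})

test_that("resolution threshold crossing is interpolated", {
  fsc <- structure(list(shell_freqs = c(0.01, 0.02, 0.03),
                        correlations = c(1.0, 0.5, 0.0)),
                   class = "fsc_curve")
  r <- resolution_at_threshold(fsc)
  expect_equal(r$resolution_A, 50)
  expect_true(r$crossed)

  fsc2 <- structure(list(shell_freqs = c(0.01, 0.02, 0.03),
                         correlations = c(1.0, 0.75, 0.25)),
                    class = "fsc_curve")
  expect_equal(resolution_at_threshold(fsc2)$resolution_A, 40)

  fsc3 <- structure(list(shell_freqs = c(0.01, 0.02, 0.03),
                         correlations = c(1, 1, 1)),
                    class = "fsc_curve")
  r3 <- resolution_at_threshold(fsc3)
  expect_false(r3$crossed)
  expect_equal(r3$resolution_A, 1 / 0.03)  # Nyquist of the curve
})

test_that("half-set FSC of a clean aligned series is high to half-Nyquist", {
  vol <- small_conjugate_volume(n_bp = 50, box = 96, pixel = 4)
  volb <- density_volume(
    ipetdna:::gaussian_blur3_cpp(vol$grid, 96, 1.2), 4)
  tilt <- simulate_tilt_series(volb, -60, 60, 1.5, target_snr = Inf)
  hs <- halfset_fsc(tilt)
  half_ny <- max(hs$fsc$shell_freqs) / 2
  expect_true(all(hs$fsc$correlations[hs$fsc$shell_freqs <= half_ny] > 0.9))
})

test_that("SNR follows its defining formula", {
  set.seed(7)
  n <- 64
  img <- matrix(rnorm(n^2), n, n)
  mask <- make_gaussian_mask(n, 10, 2) >= 1
  # signal region statistically identical to background: SNR ~ 0
  expect_lt(abs(compute_snr(img, mask)), 0.1)

  # inside = bg mean + k * bg sd exactly => SNR = k
  bg <- !ipetdna:::dilate_mask(mask, 3L)
  img2 <- img
  img2[mask] <- mean(img[bg]) + 2.5 * sd(img[bg])
  expect_equal(compute_snr(img2, mask), 2.5, tolerance = 1e-9)

  expect_error(compute_snr(img, mask & FALSE), "empty signal")
  expect_error(compute_snr(img, array(TRUE, dim(img))), "background")
})

test_that("particle mask volume follows the 3x-mass rule", {
  n <- 64; px <- 2
  # ball of exactly the target volume
  r <- 12
  vol <- make_ball_volume(n, r, pixel_size = px, sharp = TRUE)
  n_ball <- sum(vol$grid > 0)
  mw <- n_ball * px^3 / (3 * 1.21)
  mask <- generate_particle_mask(vol, mw, lowpass_A = 8)
  expect_equal(sum(mask), n_ball)
  # recovered within a one/two-voxel shell of the true ball
  ball <- vol$grid > 0
  expect_true(all(mask[!ipetdna:::dilate_mask(ball, 2L)] == FALSE))
  core <- !ipetdna:::dilate_mask(!ball, 2L)
  expect_true(all(mask[core]))

  # monotone: doubling the mass doubles the mask volume
  m2 <- generate_particle_mask(vol, 2 * mw, lowpass_A = 8)
  expect_rel_equal(sum(m2), 2 * n_ball, 0.01)

  # the 52-kDa dsDNA mask volume: 3 x 52000 x 1.21 A^3 within 2%
  # (bigger ball so the 3x-mass volume sits inside the density gradient)
  vol2 <- make_ball_volume(n, 22, pixel_size = px, sharp = TRUE)
  mass_mask <- generate_particle_mask(vol2, 52000, lowpass_A = 8)
  expect_rel_equal(sum(mass_mask) * px^3, 3 * 52000 * 1.21, 0.02)

  expect_error(generate_particle_mask(vol, 1e9), "not attainable")
  expect_error(generate_particle_mask(vol, -5), "molecular_weight")
})
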