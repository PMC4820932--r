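# synthetic_conjugates: straight B-DNA model, WLC sampler, phantom
# rendering, tilt-series simulation.

test_that("straight B-DNA model has the canonical geometry", {
  ch <- build_straight_bdna(84)
  expect_equal(end_to_end(ch), 83 * 3.4)           # 282.2 A, ~30 nm
  expect_equal(chain_length(ch), 282.2)
  expect_equal(nrow(ch$axes), 83)
  # all step axes identical
  expect_equal(max(abs(sweep(ch$axes, 2, ch$axes[1, ]))), 0)

  ch3 <- build_straight_bdna(3)
  expect_equal(ch3$centers[, 1], c(0, 3.4, 6.8))
  expect_equal(ch3$axes[1, ], ch3$axes[2, ])

  # downstream bend angles of the straight chain are all zero
  ang <- chain_bend_angles(ch, wlc_params(84))
  expect_equal(max(ang$theta), 0)
  expect_equal(max(ang$phi), 0)
  expect_length(ang$phi, 82)
  expect_length(ang$theta, 81)

  expect_error(build_straight_bdna(2), "n_bp")
  expect_error(wlc_params(84, l_p = -1), "l_p")
})

test_that("WLC sampler reproduces the exact angular moment at three stiffnesses", {
  # <theta^2> against numerical quadrature of sin(theta) exp(-a theta^2/2)
  for (lp_over_d in c(50, 147, 500)) {
    p <- wlc_params(84, l_p = lp_over_d * 3.4, d = 3.4)
    ens <- sample_wlc_ensemble(p, 1e4, seed = 42)
    expect_rel_equal(mean(ens$angles^2), oracle_theta_sq(lp_over_d), 0.02)
    # small-angle identity 2 d / l_p holds to the same tolerance
    expect_rel_equal(mean(ens$angles^2), 2 / lp_over_d, 0.02)
  }
})

test_that("stiff limit collapses to the straight chain", {
  p <- wlc_params(84, l_p = 1e9)
  ch <- sample_wlc_chain(p, seed = 1)
  expect_lt(max(attr(ch, "joint_angles")), 1e-3)
  expect_rel_equal(end_to_end(ch), 282.2, 1e-5)
})

test_that("end-to-end distance matches the closed-form oracles", {
  cases <- list(c(n_bp = 84, l_p = 500), c(n_bp = 84, l_p = 147 * 3.4),
                c(n_bp = 42, l_p = 500))
  for (cs in cases) {
    p <- wlc_params(cs["n_bp"], l_p = cs["l_p"])
    ens <- sample_wlc_ensemble(p, 1e4, seed = 9)
    r2 <- mean(ens$end_to_end^2)
    se <- sd(ens$end_to_end^2) / sqrt(length(ens$end_to_end))
    # exact discrete freely-rotating closed form: within sampling error
    expect_lt(abs(r2 - wlc_r2_closed_form(p, "discrete")), 4 * se)
    # continuous Kratky-Porod form agrees to discretization accuracy
    expect_rel_equal(sqrt(r2), sqrt(wlc_r2_closed_form(p, "continuous")),
                     0.02)
  }
  # headline number: RMS end-to-end of the 84-bp 50-nm chain is ~258 A
  p <- wlc_params(84)
  ens <- sample_wlc_ensemble(p, 1e4, seed = 9)
  expect_rel_equal(sqrt(mean(ens$end_to_end^2)), 258, 0.02)
})

test_that("sampling is reproducible and chain invariants hold", {
  p <- wlc_params(84)
  ch1 <- sample_wlc_chain(p, seed = 7)
  ch2 <- sample_wlc_chain(p, seed = 7)
  expect_identical(ch1$centers, ch2$centers)
  ch3 <- sample_wlc_chain(p, seed = 8)
  expect_false(identical(ch1$centers, ch3$centers))
  # consecutive spacing equals the rise; axes unit-norm
  expect_lt(max(abs(sqrt(rowSums(diff(ch1$centers)^2)) - 3.4)), 1e-6)
  expect_lt(max(abs(sqrt(rowSums(ch1$axes^2)) - 1)), 1e-9)
  # the stored joint angles equal the realized step-axis angles
  phi <- phi_angles(fit_cylinders(ch1))
  expect_equal(phi, attr(ch1, "joint_angles"), tolerance = 1e-9)
})

test_that("rendered phantom has the constructed gold geometry", {
  vol <- small_conjugate_volume(n_bp = 30, box = 128, pixel = 2.2)
  golds <- locate_gold_in_volume(vol)
  d <- sqrt(sum((golds[[1]]$center - golds[[2]]$center)^2))
  # centre-to-centre = chain length + 2 gold radii, within one pixel
  expect_lt(abs(d - (29 * 3.4 + 63)), vol$pixel_size)
  expect_identical(vol$grid,
                   small_conjugate_volume(n_bp = 30, box = 128,
                                          pixel = 2.2)$grid)
})

test_that("gold-only phantom integral matches the analytic sphere volume", {
  ch <- build_straight_bdna(10)
  ph <- conjugate_phantom(ch)
  vol <- render_phantom(ph, 192, 0.94, dna_density = 0)
  analytic <- 2 * 5 * (4 / 3) * pi * 31.5^3
  expect_rel_equal(attr(vol, "integral"), analytic, 0.01)
})

test_that("oversized phantoms are rejected with the offending extent", {
  ch <- build_straight_bdna(84)
  ph <- conjugate_phantom(ch)
  expect_error(render_phantom(ph, 64, 0.94), "extent")
})

test_that("tilt simulation covers the acquisition geometry", {
  vol <- small_conjugate_volume(n_bp = 10, box = 64, pixel = 4)
  tilt <- simulate_tilt_series(vol, -60, 60, 1.5, target_snr = Inf)
  expect_equal(dim(tilt$images)[3], 81)  # the ~80-micrograph acquisition
  expect_equal(tilt$angles[1], -60)
  expect_equal(tail(tilt$angles, 1), 60)
})

test_that("noiseless unshifted simulation equals plain projection exactly", {
  vol <- small_conjugate_volume(n_bp = 10, box = 64, pixel = 4)
  tilt <- simulate_tilt_series(vol, -30, 30, 15, target_snr = Inf,
                               max_shift_px = 0)
  for (i in seq_along(tilt$angles))
    expect_identical(tilt$images[, , i],
                     project_volume(vol, tilt$angles[i]))
  expect_equal(tilt$true_shifts, matrix(0, 5, 2))
})

test_that("tilt simulation is seed-deterministic and hits the target SNR", {
  vol <- small_conjugate_volume(n_bp = 50, box = 128, pixel = 3)
  t1 <- simulate_tilt_series(vol, -60, 60, 15, target_snr = 0.31,
                             max_shift_px = 4, seed = 5)
  t2 <- simulate_tilt_series(vol, -60, 60, 15, target_snr = 0.31,
                             max_shift_px = 4, seed = 5)
  expect_identical(t1$images, t2$images)
  expect_identical(t1$true_shifts, t2$true_shifts)
  expect_false(identical(
    t1$images,
    simulate_tilt_series(vol, -60, 60, 15, target_snr = 0.31,
                         max_shift_px = 4, seed = 6)$images))

  # round trip: measured DNA-region SNR of the 0-degree image ~ target
  i0 <- which(t1$angles == 0)
  parts <- ipetdna:::split_gold_dna(vol$grid)
  proj <- project_volume(vol, 0)
  pd <- ipetdna:::project_vol_cpp(parts$dna, 128, 0)
  pg <- ipetdna:::project_vol_cpp(parts$gold, 128, 0)
  dna_mask <- pd > 0.02 * max(pd) & pg <= 0.02 * max(pg)
  # un-shift the simulated image so the mask is aligned with it
  img <- shift_image(t1$images[, , i0], -t1$true_shifts[i0, 1],
                     -t1$true_shifts[i0, 2])
  snr <- compute_snr(img, dna_mask, exclude = pg > 0.02 * max(pg))
  expect_rel_equal(snr, 0.31, 0.10)
})

test_that("degenerate simulation inputs error", {
  vol <- density_volume(array(0, c(16, 16, 16)), 1)
  expect_error(simulate_tilt_series(vol), "degenerate")
  v2 <- make_ball_volume(16, 4)
  expect_error(simulate_tilt_series(v2, step = 0), "step")
  expect_error(simulate_tilt_series(v2, target_snr = -1), "target_snr")
})
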