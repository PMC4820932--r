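# bending_energy: cylinder fitting, the two bend-angle constructions, the
# harmonic WLC energy, windowed energies, Monte-Carlo ensemble statistics
# and persistence-length recovery.

kBT298 <- 1.9872e-3 * 298  # 0.5922 kcal/mol

make_cylinders <- function(centers) {
  d <- diff(centers)
  structure(list(centers = centers, axes = d / sqrt(rowSums(d^2)),
                 length = 3.4, width = 20),
            class = "cylinder_set")
}

test_that("cylinder fitting follows the base-pair steps", {
  ch <- build_straight_bdna(84)
  cyl <- fit_cylinders(ch)
  expect_equal(nrow(cyl$centers), 83)
  expect_equal(max(abs(sweep(cyl$axes, 2, cyl$axes[1, ]))), 0)

  ch3 <- chain_conformation(rbind(c(0, 0, 0), c(3.4, 0, 0), c(3.4, 3.4, 0)),
                            rbind(c(1, 0, 0), c(0, 1, 0)), 3.4)
  cyl3 <- fit_cylinders(ch3)
  expect_equal(cyl3$axes, rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(cyl3$centers, rbind(c(1.7, 0, 0), c(3.4, 1.7, 0)))

  wch <- sample_wlc_chain(wlc_params(84), seed = 2)
  expect_equal(fit_cylinders(wch)$axes, wch$axes, tolerance = 1e-9)

  bad <- chain_conformation(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                            rbind(c(1, 0, 0), c(1, 0, 0)), 1)
  expect_error(fit_cylinders(bad), "coincident")
})

test_that("theta angles measure deviation from collinearity", {
  straight <- make_cylinders(cbind((0:9) * 3.4, 0, 0))
  expect_equal(max(theta_angles(straight)), 0)

  right <- make_cylinders(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(theta_angles(right), pi / 2)

  # centres on a circle of radius R at spacing s: theta = s / R
  R <- 100; s <- 3.4
  phi <- (0:40) * s / R
  circ <- make_cylinders(cbind(R * sin(phi), R * (1 - cos(phi)), 0))
  th <- theta_angles(circ)
  expect_true(all(abs(th - s / R) / (s / R) < 0.02))
})

test_that("phi angles measure the axis-to-axis bend", {
  straight <- fit_cylinders(build_straight_bdna(20))
  expect_equal(max(phi_angles(straight)), 0)

  right <- make_cylinders(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(phi_angles(right), c(pi / 2))

  # pooled over sampled chains, <phi^2> = 2 d / l_p
  p <- wlc_params(84)
  phis <- unlist(lapply(1:1000, function(k) {
    phi_angles(fit_cylinders(sample_wlc_chain(p, seed = k)))
  }))
  expect_rel_equal(mean(phis^2), 2 * 3.4 / 500, 0.02)
})

test_that("harmonic WLC energy has the right scale and form", {
  p <- wlc_params(84)
  # straight chain: exactly zero (the structure-no.-0 control)
  en0 <- bending_energy(chain_bend_angles(build_straight_bdna(84), p))
  expect_identical(en0$E_theta, 0)
  expect_identical(en0$E_phi, 0)

  # one joint at phi = sqrt(2 d / l_p): energy = k_B T (equipartition mean)
  one <- bend_angle_set(numeric(0), sqrt(2 * 3.4 / 500), p)
  expect_equal(bending_energy(one)$E_phi, kBT298, tolerance = 1e-6)
  expect_equal(bending_energy(one)$E_phi, 0.5922, tolerance = 1e-3)

  # quadratic form: doubling all angles quadruples the energy
  ang <- chain_bend_angles(sample_wlc_chain(p, seed = 3), p)
  ang2 <- bend_angle_set(2 * ang$theta, 2 * ang$phi, p)
  expect_equal(bending_energy(ang2)$E_phi, 4 * bending_energy(ang)$E_phi,
               tolerance = 1e-12)
  expect_equal(bending_energy(ang2)$E_theta,
               4 * bending_energy(ang)$E_theta, tolerance = 1e-12)
})

test_that("energies are invariant under rigid motion", {
  p <- wlc_params(84)
  ch <- sample_wlc_chain(p, seed = 11)
  # random rotation (QR of a random matrix) plus translation
  set.seed(4)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  ch2 <- chain_conformation(ch$centers %*% t(Q) +
                              matrix(c(10, -20, 5), nrow(ch$centers), 3,
                                     byrow = TRUE),
                            ch$axes %*% t(Q), ch$rise)
  e1 <- bending_energy(chain_bend_angles(ch, p))
  e2 <- bending_energy(chain_bend_angles(ch2, p))
  expect_equal(e2$E_theta, e1$E_theta, tolerance = 1e-9)
  expect_equal(e2$E_phi, e1$E_phi, tolerance = 1e-9)
})

test_that("theta- and phi-energies agree for gently bent smooth chains", {
  # uniform-curvature arc, max joint angle << 10 degrees
  ch <- make_arc_chain(R = 300, arc_angle = 0.9)
  p <- wlc_params(nrow(ch$centers))
  en <- bending_energy(chain_bend_angles(ch, p))
  expect_rel_equal(en$E_theta, en$E_phi, 0.15)
})

test_that("windowed energy keeps exactly the interior joints", {
  p <- wlc_params(84)
  ang <- chain_bend_angles(sample_wlc_chain(p, seed = 5), p)
  full <- subchain_energy(ang, 1, 84)
  expect_equal(full$E_phi, bending_energy(ang)$E_phi)
  expect_equal(full$E_theta, bending_energy(ang)$E_theta)

  # central 42 bp of 84: 40 phi joints, 39 theta joints
  ctr <- subchain_energy(ang, 22, 63)
  expect_length(ctr$per_joint_phi, 40)
  expect_length(ctr$per_joint_theta, 39)

  # uniform curvature: energy ratio = joint-count ratio exactly
  arc <- make_arc_chain(R = 500, arc_angle = 0.56)
  pa <- wlc_params(nrow(arc$centers))
  aang <- chain_bend_angles(arc, pa)
  n_bp <- nrow(arc$centers)
  sub <- subchain_energy(aang, 22, 63)
  expect_rel_equal(sub$E_phi / bending_energy(aang)$E_phi,
                   40 / length(aang$phi), 1e-6)

  # ensemble: central-window mean energy scales with the joint count
  ens <- sample_wlc_ensemble(p, 4000, seed = 6)
  coef <- p$k_B * p$temperature * p$l_p / (2 * p$d)
  full_mean <- mean(coef * rowSums(ens$angles^2))
  # phi joint j of a sampled chain corresponds to ensemble angle column j
  ctr_mean <- mean(coef * rowSums(ens$angles[, 22:61]^2))
  expect_rel_equal(ctr_mean / full_mean, 40 / 82, 0.03)

  expect_error(subchain_energy(ang, 10, 11), "at least 3")
  expect_error(subchain_energy(ang, 0, 42), "start_bp")
})

test_that("Monte-Carlo mean energy reproduces equipartition", {
  p <- wlc_params(84)
  res <- wlc_mean_energy_mc(p, 1e4, seed = 1)
  expect_equal(res$analytic, 82 * kBT298)
  # the ~50 kcal/mol room-temperature WLC prediction (analytic 48.6)
  expect_rel_equal(res$mean, 48.56, 0.03)

  # single joint: mean ~ k_B T
  res3 <- wlc_mean_energy_mc(wlc_params(3), 1e4, seed = 2)
  expect_rel_equal(res3$mean, kBT298, 0.05)

  # energy is exactly linear in temperature (sampling density is T-free)
  hot <- wlc_mean_energy_mc(wlc_params(84, temperature = 596), 2000,
                            seed = 3)
  cold <- wlc_mean_energy_mc(wlc_params(84, temperature = 298), 2000,
                             seed = 3)
  expect_equal(hot$mean, 2 * cold$mean, tolerance = 1e-12)
  expect_error(wlc_mean_energy_mc(p, 50), "n_chains")
})

test_that("persistence length is recovered from angle samples", {
  for (lp in c(500, 147)) {
    p <- wlc_params(84, l_p = lp)
    ens <- sample_wlc_ensemble(p, 1250, seed = 13)  # > 1e5 joint samples
    lp_hat <- estimate_persistence_length(as.numeric(ens$angles), d = 3.4)
    expect_rel_equal(lp_hat, lp, 0.03)
  }
  expect_warning(out <- estimate_persistence_length(rep(0, 200), 3.4),
                 "infinite")
  expect_identical(out, Inf)
  expect_error(estimate_persistence_length(rep(0.1, 10), 3.4), "100")
})
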