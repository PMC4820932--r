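# Worm-like-chain bending angles and energy.
#
# Convention (fixed so energy totals are reproducible): an n_bp chain gives
# n_bp - 1 base-pair-step cylinders, hence n_bp - 2 phi angles (between
# consecutive cylinder axes) and n_bp - 3 theta angles (from three
# consecutive cylinder centres). Both angles are deviations from
# collinearity: a straight chain scores exactly zero energy. Each joint
# contributes the harmonic WLC term (k_B T l_p / (2 d)) * angle^2, applied
# at all angle magnitudes.

#' Fit base-pair-step cylinders to a chain
#'
#' Cylinder i spans base pairs i and i+1: centre at the midpoint of C_i and
#' C_{i+1}, axis the unit vector from C_i to C_{i+1}, fixed length equal to
#' the rise and width 20 A.
#'
#' @param chain a [chain_conformation()] with >= 3 centres.
#' @return An object of class `cylinder_set` with `centers`
#'   ((n-1) x 3), `axes` ((n-1) x 3), `length` and `width`.
#' @export
fit_cylinders <- function(chain) {
  stopifnot(inherits(chain, "chain_conformation"))
  C <- chain$centers
  if (nrow(C) < 3) stop("need at least 3 base-pair centers")
  d <- diff(C)
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-9)) stop("coincident consecutive base-pair centers")
  structure(list(centers = (C[-nrow(C), ] + C[-1, ]) / 2,
                 axes = d / len,
                 length = chain$rise, width = 20),
            class = "cylinder_set")
}

#' Theta bend angles (three consecutive cylinder centres)
#'
#' `theta_i` is the angle between the vector from centre i-1 to centre i and
#' the vector from centre i to centre i+1 -- the deviation from
#' collinearity, zero for a straight chain.
#'
#' @param cylinders a `cylinder_set` from [fit_cylinders()] (>= 3 cylinders).
#' @return numeric vector of `n_cyl - 2` angles, radians in `[0, pi]`.
#' @export
theta_angles <- function(cylinders) {
  stopifnot(inherits(cylinders, "cylinder_set"))
  C <- cylinders$centers
  if (nrow(C) < 3) stop("need at least 3 cylinders")
  v <- diff(C)
  u <- v / sqrt(rowSums(v^2))
  dotp <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
  acos(pmin(pmax(dotp, -1), 1))
}

#' Phi bend angles (consecutive cylinder axes)
#'
#' `phi_i = acos(axis_i . axis_{i+1})`, clamped to `[0, pi]`.
#'
#' @param cylinders a `cylinder_set` (>= 2 cylinders).
#' @return numeric vector of `n_cyl - 1` angles, radians.
#' @export
phi_angles <- function(cylinders) {
  stopifnot(inherits(cylinders, "cylinder_set"))
  A <- cylinders$axes
  if (nrow(A) < 2) stop("need at least 2 cylinders")
  dotp <- rowSums(A[-nrow(A), , drop = FALSE] * A[-1, , drop = FALSE])
  acos(pmin(pmax(dotp, -1), 1))
}

#' Bend angles of a chain conformation
#'
#' Convenience wrapper: fits cylinders and returns both angle constructions
#' as a [bend_angle_set()].
#'
#' @param chain a [chain_conformation()].
#' @param params a [wlc_params()] (used for energy conversion).
#' @return a [bend_angle_set()].
#' @export
chain_bend_angles <- function(chain, params) {
  cyl <- fit_cylinders(chain)
  bend_angle_set(theta_angles(cyl), phi_angles(cyl), params)
}

#' Worm-like-chain bending energy
#'
#' Per joint `E_j = (k_B T l_p / (2 d)) * angle_j^2`, summed separately over
#' the theta and phi angle lists. Zero for the straight chain.
#'
#' @param angles a [bend_angle_set()].
#' @return An object of class `energy_report` with `E_theta`, `E_phi`
#'   (kcal/mol) and the per-joint terms.
#' @export
bending_energy <- function(angles) {
  stopifnot(inherits(angles, "bend_angle_set"))
  p <- angles$params
  coef <- p$k_B * p$temperature * p$l_p / (2 * p$d)
  pj_t <- coef * angles$theta^2
  pj_p <- coef * angles$phi^2
  structure(list(E_theta = sum(pj_t), E_phi = sum(pj_p),
                 per_joint_theta = pj_t, per_joint_phi = pj_p),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("bending energy: E_theta = %.2f, E_phi = %.2f kcal/mol\n",
              x$E_theta, x$E_phi))
  invisible(x)
}

#' Bending energy of a base-pair window
#'
#' Restricts the energy to joints all of whose contributing cylinders span
#' base pairs inside `[start_bp, end_bp]` (1-based, inclusive). The default
#' central window of an 84-bp chain, bp 22-63, keeps 40 phi joints and 39
#' theta joints out of 82/81, discounting the end fluctuations.
#'
#' @param angles a [bend_angle_set()].
#' @param start_bp,end_bp window limits (window of >= 3 bp).
#' @return an `energy_report` for the window.
#' @export
subchain_energy <- function(angles, start_bp = 22, end_bp = 63) {
  stopifnot(inherits(angles, "bend_angle_set"))
  n_bp <- angles$params$n_bp
  if (start_bp < 1 || end_bp > n_bp || start_bp >= end_bp)
    stop("require 1 <= start_bp < end_bp <= n_bp")
  if (end_bp - start_bp + 1 < 3) stop("window must span at least 3 bp")
  # cylinder i spans bp i, i+1; keep cylinders start_bp .. end_bp - 1
  # phi_j uses cylinders j, j+1   -> j in start_bp .. end_bp - 2
  # theta_j uses cylinders j..j+2 -> j in start_bp .. end_bp - 3
  phi_keep <- seq_len(length(angles$phi)) >= start_bp &
    seq_len(length(angles$phi)) <= end_bp - 2
  th_keep <- seq_len(length(angles$theta)) >= start_bp &
    seq_len(length(angles$theta)) <= end_bp - 3
  sub <- bend_angle_set(angles$theta[th_keep], angles$phi[phi_keep],
                        angles$params)
  bending_energy(sub)
}

#' Monte-Carlo mean WLC bending energy
#'
#' Samples `n_chains` discrete WLC conformations, sums the phi-based
#' harmonic joint energies per chain, and returns the ensemble mean and
#' standard deviation. By equipartition the mean approaches
#' `(n_bp - 2) * k_B * T` -- for 84 bp at 298 K, 82 x 0.592 = 48.6
#' kcal/mol, the ~50 kcal/mol room-temperature WLC prediction.
#'
#' @param params a [wlc_params()].
#' @param n_chains number of sampled chains (>= 100, default 1e4).
#' @param seed integer seed.
#' @return list with `mean`, `sd` (kcal/mol), `n_chains` and the `analytic`
#'   equipartition value.
#' @export
wlc_mean_energy_mc <- function(params, n_chains = 1e4, seed = 1) {
  stopifnot(inherits(params, "wlc_params"))
  if (n_chains < 100) stop("n_chains must be >= 100")
  ens <- sample_wlc_ensemble(params, n_chains, seed)
  coef <- params$k_B * params$temperature * params$l_p / (2 * params$d)
  E <- coef * rowSums(ens$angles^2)
  list(mean = mean(E), sd = sd(E), n_chains = n_chains,
       analytic = (params$n_bp - 2) * params$k_B * params$temperature)
}

#' Persistence length from bend-angle samples
#'
#' Inverts the sampler moment identity `<phi^2> = 2 d / l_p`:
#' `l_p_hat = 2 d / mean(phi^2)`. All-zero angles signal infinite stiffness
#' (returns `Inf` with a warning).
#'
#' @param phi_samples bend angles in radians (>= 100 samples).
#' @param d rise per base pair, Angstrom.
#' @param temperature Kelvin; not used by the moment identity, kept for
#'   interface symmetry with the energy functions.
#' @return estimated persistence length, Angstrom.
#' @export
estimate_persistence_length <- function(phi_samples, d, temperature = 298) {
  if (length(phi_samples) < 100) stop("need at least 100 angle samples")
  msq <- mean(phi_samples^2)
  if (msq == 0) {
    warning("zero mean-square angle: infinite stiffness")
    return(Inf)
  }
  2 * d / msq
}
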