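# Discrete worm-like-chain generation.
#
# Joint convention: an n_bp chain has n_bp - 1 step axes and n_bp - 2 bend
# joints. Each joint's polar bend angle is drawn from the Boltzmann density
# of the harmonic bending potential on the sphere,
#   p(theta) ~ sin(theta) * exp(-(l_p / (2 d)) * theta^2),   theta in [0, pi],
# and the azimuth uniformly on [0, 2 pi). In the stiff limit this gives
# <theta^2> -> 2 d / l_p, the moment identity used for persistence-length
# recovery.

# Draw n angles from sin(theta) * exp(-alpha * theta^2 / 2) on [0, pi] by
# rejection from the Rayleigh envelope theta * exp(-alpha * theta^2 / 2)
# (valid since sin(theta) <= theta). Exact, vectorised.
sample_bend_angles <- function(n, alpha) {
  out <- numeric(0)
  sigma <- 1 / sqrt(alpha)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 64L)
    th <- sigma * sqrt(-2 * log(runif(m)))
    keep <- th <= pi & runif(m) <= sin(th) / th
    out <- c(out, th[keep])
  }
  out[seq_len(n)]
}

# Derive a child seed (< 2^31) from a root seed and a counter.
derive_seed <- function(root, k) {
  as.integer((abs(as.numeric(root)) * 1009 + 104729 * k) %% 2147483647)
}

#' Straight B-form DNA model chain
#'
#' Builds the canonical straight B-DNA chain: collinear base-pair centres
#' spaced by the rise along +x (the in-image-plane direction, perpendicular
#' to both the beam and the tilt axis), identical step axes, and a stored helical
#' twist phase for rendering. An 84-bp chain is ~2 nm wide and ~30 nm long
#' (end-to-end 83 x 3.4 = 282.2 A).
#'
#' @param n_bp number of base pairs (>= 3).
#' @param rise rise per base pair, Angstrom (default 3.4).
#' @param twist_deg helical twist per step, degrees (default 36).
#' @param width nominal duplex width, Angstrom (default 20).
#' @return A [chain_conformation()] with attributes `twist_deg` and `width`.
#' @export
#' @examples
#' ch <- build_straight_bdna(84)
#' end_to_end(ch)  # 282.2
build_straight_bdna <- function(n_bp, rise = 3.4, twist_deg = 36, width = 20) {
  n_bp <- as.integer(n_bp)
  if (is.na(n_bp) || n_bp < 3L) stop("n_bp must be an integer >= 3")
  centers <- cbind((seq_len(n_bp) - 1) * rise, 0, 0)
  axes <- matrix(rep(c(1, 0, 0), each = n_bp - 1L), ncol = 3)
  ch <- chain_conformation(centers, axes, rise)
  attr(ch, "twist_deg") <- twist_deg
  attr(ch, "width") <- width
  ch
}

#' Sample one worm-like-chain conformation
#'
#' Draws a single discrete WLC conformation: every interior joint bends by a
#' polar angle from the exact `sin(theta)`-weighted Boltzmann density (see
#' [wlc_params()] for the stiffness parameters) with a uniform azimuth, and
#' the local frame is propagated along the chain. Reproducible for a fixed
#' seed.
#'
#' @param params a [wlc_params()].
#' @param seed integer seed.
#' @return A [chain_conformation()]. The drawn joint angles are stored in
#'   attribute `joint_angles` (length `n_bp - 2`).
#' @export
sample_wlc_chain <- function(params, seed) {
  stopifnot(inherits(params, "wlc_params"))
  set.seed(derive_seed(seed, 0L))
  n <- params$n_bp
  alpha <- params$l_p / params$d
  n_joint <- n - 2L
  theta <- sample_bend_angles(n_joint, alpha)
  phi_az <- runif(n_joint, 0, 2 * pi)

  centers <- matrix(0, n, 3)
  axes <- matrix(0, n - 1L, 3)
  t_vec <- c(1, 0, 0); u_vec <- c(0, 1, 0); w_vec <- c(0, 0, 1)
  axes[1, ] <- t_vec
  centers[2, ] <- centers[1, ] + params$d * t_vec
  for (j in seq_len(n_joint)) {
    t_new <- cos(theta[j]) * t_vec +
      sin(theta[j]) * (cos(phi_az[j]) * u_vec + sin(phi_az[j]) * w_vec)
    t_new <- t_new / sqrt(sum(t_new^2))
    # transport the frame: project the old normal off the new tangent
    u_vec <- u_vec - sum(u_vec * t_new) * t_new
    u_vec <- u_vec / sqrt(sum(u_vec^2))
    w_vec <- c(t_new[2] * u_vec[3] - t_new[3] * u_vec[2],
               t_new[3] * u_vec[1] - t_new[1] * u_vec[3],
               t_new[1] * u_vec[2] - t_new[2] * u_vec[1])
    t_vec <- t_new
    axes[j + 1L, ] <- t_vec
    centers[j + 2L, ] <- centers[j + 1L, ] + params$d * t_vec
  }
  ch <- chain_conformation(centers, axes, params$d)
  attr(ch, "joint_angles") <- theta
  ch
}

#' Sample a worm-like-chain ensemble (vectorised)
#'
#' Draws `n_chains` conformations simultaneously and returns the quantities
#' ensemble statistics need: every joint angle and every end-to-end distance.
#' Statistically identical to repeated [sample_wlc_chain()] but orders of
#' magnitude faster for Monte-Carlo work.
#'
#' @param params a [wlc_params()].
#' @param n_chains number of chains.
#' @param seed integer seed.
#' @return list with `angles` (`n_chains x (n_bp - 2)` matrix, radians) and
#'   `end_to_end` (vector of end-to-end centre distances, Angstrom).
#' @export
sample_wlc_ensemble <- function(params, n_chains, seed) {
  stopifnot(inherits(params, "wlc_params"))
  set.seed(derive_seed(seed, 1L))
  n <- params$n_bp
  alpha <- params$l_p / params$d
  n_joint <- n - 2L
  theta <- matrix(sample_bend_angles(n_chains * n_joint, alpha),
                  n_chains, n_joint)
  phi_az <- matrix(runif(n_chains * n_joint, 0, 2 * pi), n_chains, n_joint)

  tm <- matrix(rep(c(1, 0, 0), each = n_chains), n_chains, 3)
  um <- matrix(rep(c(0, 1, 0), each = n_chains), n_chains, 3)
  pos <- params$d * tm  # after the first step
  for (j in seq_len(n_joint)) {
    wj <- cbind(tm[, 2] * um[, 3] - tm[, 3] * um[, 2],
                tm[, 3] * um[, 1] - tm[, 1] * um[, 3],
                tm[, 1] * um[, 2] - tm[, 2] * um[, 1])
    ct <- cos(theta[, j]); st <- sin(theta[, j])
    ca <- cos(phi_az[, j]); sa <- sin(phi_az[, j])
    tn <- ct * tm + st * (ca * um + sa * wj)
    tn <- tn / sqrt(rowSums(tn^2))
    um <- um - rowSums(um * tn) * tn
    um <- um / sqrt(rowSums(um^2))
    tm <- tn
    pos <- pos + params$d * tm
  }
  list(angles = theta, end_to_end = sqrt(rowSums(pos^2)))
}

#' Closed-form mean-squared end-to-end distance
#'
#' Two oracles for the chain sampler. `"continuous"` is the Kratky-Porod
#' result `<R^2> = 2 l_p L (1 - (l_p/L)(1 - exp(-L/l_p)))` with contour
#' `L = (n_bp - 1) d`. `"discrete"` is the exact freely-rotating-chain sum
#' `<R^2> = d^2 sum_{i,j} c^|i-j|` with `c = <cos theta>` computed by
#' numerical integration of the sampling density, which matches the discrete
#' generator without small-angle approximation.
#'
#' @param params a [wlc_params()].
#' @param model `"continuous"` or `"discrete"`.
#' @return mean-squared end-to-end distance, Angstrom^2.
#' @export
wlc_r2_closed_form <- function(params, model = c("continuous", "discrete")) {
  model <- match.arg(model)
  n_step <- params$n_bp - 1L
  if (model == "continuous") {
    L <- n_step * params$d
    lp <- params$l_p
    return(2 * lp * L * (1 - (lp / L) * (1 - exp(-L / lp))))
  }
  alpha <- params$l_p / params$d
  f <- function(th) sin(th) * exp(-alpha * th^2 / 2)
  z <- integrate(f, 0, pi, rel.tol = 1e-10)$value
  cbar <- integrate(function(th) cos(th) * f(th), 0, pi,
                    rel.tol = 1e-10)$value / z
  k <- n_step
  # sum_{i,j=1..k} c^|i-j| = k + 2 * sum_{m=1}^{k-1} (k - m) c^m
  m <- seq_len(k - 1L)
  params$d^2 * (k + 2 * sum((k - m) * cbar^m))
}
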