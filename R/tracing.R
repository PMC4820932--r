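# Conformation tracing: locate the two gold particles in a 3D map, trace
# the inter-gold centerline as a minimum-cost path through the density, fit
# a smooth piecewise-polynomial (Bezier-equivalent) curve, and place
# base-pair frames along it.

#' Locate the two gold particles in a density volume
#'
#' Thresholds the map at `gold_frac` of its maximum, labels connected
#' components (26-connectivity) and measures the two strongest blobs:
#' centroid, extent along the longest principal axis and the two
#' perpendicular extents, and their 3D geometric-mean diameter (cube root of
#' the product).
#'
#' @param volume a [density_volume()].
#' @param gold_frac gold threshold as a fraction of the map maximum
#'   (default 0.5; gold renders far above DNA density).
#' @param min_vox minimum blob size in voxels.
#' @return list of two objects of class `gold_particle3d`, each with
#'   `center` (Angstrom), `diameters` (3 extents) and `diameter_geometric`.
#'   Errors if the number of qualifying blobs is not exactly two.
#' @export
locate_gold_in_volume <- function(volume, gold_frac = 0.5, min_vox = 27L) {
  stopifnot(inherits(volume, "density_volume"))
  g <- volume$grid
  px <- volume$pixel_size
  bw <- g >= gold_frac * max(g)
  labels <- label_components_cpp(bw, dim(g))
  counts <- tabulate(labels[labels > 0])
  keep <- which(counts >= min_vox)
  if (length(keep) != 2)
    stop(sprintf("expected exactly 2 gold blobs above threshold, found %d",
                 length(keep)))
  keep <- keep[order(counts[keep], decreasing = TRUE)]
  out <- lapply(keep, function(lab) {
    idx <- which(labels == lab, arr.ind = TRUE)
    coords <- (idx - 1) * px
    center <- colMeans(coords)
    pr <- prcomp(coords, center = TRUE)
    extents <- apply(pr$x, 2, function(s) diff(range(s))) + px
    structure(list(center = center,
                   diameters = as.numeric(extents),
                   diameter_geometric = prod(extents)^(1 / 3)),
              class = "gold_particle3d")
  })
  out
}

#' @export
print.gold_particle3d <- function(x, ...) {
  cat(sprintf("gold particle: centre (%.1f, %.1f, %.1f) A, geom. diameter %.1f A\n",
              x$center[1], x$center[2], x$center[3], x$diameter_geometric))
  invisible(x)
}

#' Trace the DNA centerline between two gold particles
#'
#' Minimum-cost path over supra-threshold voxels (cost per step proportional
#' to 1/(density + eps), eps = 1% of the map maximum; 26-connectivity) from
#' one gold centre to the other, then resampled to roughly one point per
#' `resample_A` Angstrom. The returned centerline's endpoints are placed at
#' the two gold centres.
#'
#' @param volume a [density_volume()].
#' @param gold_a,gold_b `gold_particle3d` objects (or 3-vectors, Angstrom).
#' @param density_threshold voxels below this density are not traversable.
#' @param resample_A spacing of the returned control points (default 10 A).
#' @return An object of class `centerline` with `control_points` (m x 3,
#'   Angstrom) and `arc_length`.
#' @export
trace_centerline <- function(volume, gold_a, gold_b, density_threshold,
                             resample_A = 10) {
  stopifnot(inherits(volume, "density_volume"))
  g <- volume$grid
  px <- volume$pixel_size
  n <- dim(g)
  ca <- if (is.list(gold_a)) gold_a$center else as.numeric(gold_a)
  cb <- if (is.list(gold_b)) gold_b$center else as.numeric(gold_b)
  bw <- g >= density_threshold
  if (!any(bw)) stop("no voxels above density_threshold; reduce the threshold")
  vox <- which(bw)
  coords <- arrayInd(vox, n)
  node_of <- array(0L, n)
  node_of[vox] <- seq_along(vox)

  eps <- 0.01 * max(g)
  inv_d <- 1 / (g[vox] + eps)

  # half-neighbourhood offsets (13 of the 26)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[1:13, , drop = FALSE]
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    nb <- sweep(coords, 2, -o)  # coords + o
    ok <- nb[, 1] >= 1 & nb[, 1] <= n[1] &
          nb[, 2] >= 1 & nb[, 2] <= n[2] &
          nb[, 3] >= 1 & nb[, 3] <= n[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + n[1] * (nb[ok, 2] - 1L + n[2] * (nb[ok, 3] - 1L))
    nbid <- node_of[nb_lin]
    sel <- nbid > 0L
    if (!any(sel)) next
    a_id <- which(ok)[sel]
    b_id <- nbid[sel]
    step_len <- sqrt(sum(o^2)) * px
    from <- c(from, a_id)
    to <- c(to, b_id)
    wt <- c(wt, 0.5 * (inv_d[a_id] + inv_d[b_id]) * step_len)
  }
  gph <- igraph::make_graph(rbind(from, to), n = length(vox),
                            directed = FALSE)

  nearest_node <- function(p) {
    pv <- p / px + 1  # Angstrom -> 1-based voxel
    which.min(colSums((t(coords) - pv)^2))
  }
  s <- nearest_node(ca)
  t_ <- nearest_node(cb)
  sp <- suppressWarnings(
    igraph::shortest_paths(gph, from = s, to = t_, weights = wt,
                           output = "vpath"))
  path <- as.integer(sp$vpath[[1]])
  if (length(path) < 2)
    stop("no connected supra-threshold path between the gold particles; ",
         "reduce density_threshold")
  pts <- (coords[path, , drop = FALSE] - 1) * px
  # moving-average smoothing of the voxel path: the 26-connected walk
  # zig-zags at the voxel scale, which would inflate the arc length
  if (nrow(pts) >= 7) {
    sm <- pts
    for (k in 1:3) sm <- (rbind(sm[1, ], sm[-nrow(sm), ]) + sm +
                            rbind(sm[-1, ], sm[nrow(sm), ])) / 3
    pts <- sm
  }
  pts <- rbind(ca, pts, cb)
  pts <- resample_polyline(pts, resample_A)
  pts[1, ] <- ca
  pts[nrow(pts), ] <- cb
  arc <- sum(sqrt(rowSums(diff(pts)^2)))
  structure(list(control_points = pts, arc_length = arc),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d points, arc length %.1f A\n",
              nrow(x$control_points), x$arc_length))
  invisible(x)
}

#' Trim a centerline near its endpoints
#'
#' Removes `trim_a` / `trim_b` Angstrom of arc length from the two ends
#' (e.g. one gold radius each, leaving the DNA portion between the gold
#' surfaces), returning the trimmed point matrix.
#'
#' @param centerline a `centerline` (or m x 3 point matrix).
#' @param trim_a,trim_b arc length to drop at each end, Angstrom.
#' @return m x 3 matrix of points.
#' @export
trim_centerline <- function(centerline, trim_a, trim_b) {
  pts <- if (inherits(centerline, "centerline"))
    centerline$control_points else as.matrix(centerline)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (trim_a + trim_b >= L) stop("trim exceeds the arc length")
  interp_at <- function(si) sapply(1:3, function(k) approx(s, pts[, k],
                                                           xout = si)$y)
  out <- rbind(interp_at(trim_a),
               pts[s > trim_a & s < L - trim_b, , drop = FALSE],
               interp_at(L - trim_b))
  out
}

#' Fit a smooth curve through centerline points
#'
#' Least-squares piecewise-polynomial (B-spline) fit of degree 2 or 3 --
#' equivalently a chain of quadratic or cubic Bezier segments with
#' C^(degree-1) >= C^1 joins. The number of segments grows until the maximum
#' residual distance of any control point to the curve is within
#' `fit_tolerance`.
#'
#' @param centerline a `centerline` or an m x 3 point matrix (m >= 3).
#' @param degree polynomial degree, 2 or 3 (default 3).
#' @param fit_tolerance maximum residual in Angstrom (default 3).
#' @param max_segments segment-count cap before giving up.
#' @return An object of class `smooth_curve` with `total_length`,
#'   `fit_residual`, `n_segments` and `degree`; evaluate with
#'   [curve_points()].
#' @export
fit_smooth_curve <- function(centerline, degree = 3, fit_tolerance = 3,
                             max_segments = 32) {
  pts <- if (inherits(centerline, "centerline"))
    centerline$control_points else as.matrix(centerline)
  if (nrow(pts) < 3) stop("need at least 3 points")
  if (!degree %in% c(2, 3)) stop("degree must be 2 or 3")
  seg <- sqrt(rowSums(diff(pts)^2))
  tt <- c(0, cumsum(seg))
  tt <- tt / tt[length(tt)]

  fit_one <- function(nseg) {
    df <- degree + nseg - 1L
    if (df + 1L > nrow(pts)) return(NULL)
    basis <- splines::bs(tt, df = df, degree = degree, intercept = FALSE)
    X <- cbind(1, basis)
    qrX <- qr(X)
    beta <- qr.coef(qrX, pts)
    resid <- pts - X %*% beta
    list(beta = beta, basis_attrs = attributes(basis),
         max_resid = max(sqrt(rowSums(resid^2))), nseg = nseg)
  }
  best <- NULL
  for (nseg in seq_len(max_segments)) {
    f <- fit_one(nseg)
    if (is.null(f)) break
    best <- f
    if (f$max_resid <= fit_tolerance) break
  }
  if (is.null(best)) stop("too few points for the requested degree")
  if (best$max_resid > fit_tolerance)
    stop(sprintf(
      "fit tolerance %.3g A unattainable at %d segments (achieved %.3g A)",
      fit_tolerance, best$nseg, best$max_resid))
  curve <- structure(list(beta = best$beta,
                          basis_attrs = best$basis_attrs,
                          degree = degree,
                          n_segments = best$nseg,
                          fit_residual = best$max_resid,
                          total_length = NA_real_),
                     class = "smooth_curve")
  dense <- curve_points(curve, seq(0, 1, length.out = 2048))
  curve$total_length <- sum(sqrt(rowSums(diff(dense)^2)))
  curve
}

#' Evaluate a smooth curve
#'
#' @param curve a `smooth_curve` from [fit_smooth_curve()].
#' @param t parameter values in `[0, 1]`.
#' @return length(t) x 3 matrix of points, Angstrom.
#' @export
curve_points <- function(curve, t) {
  at <- curve$basis_attrs
  basis <- splines::bs(t, knots = at$knots,
                       Boundary.knots = at$Boundary.knots,
                       degree = at$degree, intercept = FALSE)
  cbind(1, basis) %*% curve$beta
}

#' @export
print.smooth_curve <- function(x, ...) {
  cat(sprintf(
    "smooth curve: degree %d, %d segments, length %.1f A, residual %.2g A\n",
    x$degree, x$n_segments, x$total_length, x$fit_residual))
  invisible(x)
}

#' Curvature profile of a smooth curve
#'
#' Discrete curvature (turning angle over arc length) at interior points of
#' an arc-length-uniform resampling; used to verify constant-curvature fits.
#'
#' @param curve a `smooth_curve`.
#' @param n_samples number of resampled points.
#' @return numeric vector of curvature values (1/Angstrom).
#' @export
curve_curvature <- function(curve, n_samples = 200) {
  dense <- curve_points(curve, seq(0, 1, length.out = 4096))
  pts <- resample_polyline(dense, curve$total_length / n_samples)
  v <- diff(pts)
  len <- sqrt(rowSums(v^2))
  u <- v / len
  dotp <- pmin(pmax(rowSums(u[-nrow(u), ] * u[-1, ]), -1), 1)
  ang <- acos(dotp)
  ang / ((len[-length(len)] + len[-1]) / 2)
}

#' Place base-pair frames along a smooth curve
#'
#' Distributes `n_bp` base-pair centres equally in arc length along the
#' curve, with step axes given by the normalized centre differences and
#' rotation-minimizing (parallel-transport) normals carrying the helical
#' twist phase; twist is decoupled from bending. If the curve length deviates
#' from `(n_bp - 1) * rise` by more than 25% a warning is issued and the
#' spacing is rescaled to the curve.
#'
#' @param curve a `smooth_curve`.
#' @param n_bp number of base pairs.
#' @param rise nominal rise per base pair, Angstrom.
#' @param twist_deg helical twist per step, degrees.
#' @return a [chain_conformation()]; attribute `frames` holds the
#'   transported normal at each step and `twist_deg` the phase increment.
#' @export
frames_along_curve <- function(curve, n_bp, rise = 3.4, twist_deg = 36) {
  stopifnot(inherits(curve, "smooth_curve"))
  n_bp <- as.integer(n_bp)
  if (n_bp < 3) stop("n_bp must be >= 3")
  target <- (n_bp - 1L) * rise
  L <- curve$total_length
  if (abs(L - target) / target > 0.25)
    warning(sprintf(
      "curve length %.1f A deviates >25%% from (n_bp-1)*rise = %.1f A; %s",
      L, target, "proceeding by arc-length rescaling"))
  tgrid <- seq(0, 1, length.out = 8192)
  dense <- curve_points(curve, tgrid)
  s <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  s_i <- seq(0, s[length(s)], length.out = n_bp)
  t_i <- approx(s, tgrid, xout = s_i, ties = "ordered")$y
  centers <- curve_points(curve, t_i)
  d <- diff(centers)
  axes <- d / sqrt(rowSums(d^2))

  # rotation-minimizing normals by projection transport
  normals <- matrix(0, nrow(axes), 3)
  t1 <- axes[1, ]
  ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * t1) * t1
  normals[1, ] <- u / sqrt(sum(u^2))
  if (nrow(axes) > 1) for (i in 2:nrow(axes)) {
    u <- normals[i - 1, ] - sum(normals[i - 1, ] * axes[i, ]) * axes[i, ]
    normals[i, ] <- u / sqrt(sum(u^2))
  }
  ch <- chain_conformation(centers, axes,
                           rise = s[length(s)] / (n_bp - 1L))
  attr(ch, "frames") <- normals
  attr(ch, "twist_deg") <- twist_deg
  ch
}
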