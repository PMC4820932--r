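# 2D image metrology: gold detection, geometric-mean diameters,
# centre-to-centre distances, the Pearson linking statistic, histogram peak
# statistics and the pi/4 isotropic-projection correction.

# Otsu threshold (maximal between-class variance) over a fixed-bin histogram.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(
    as.integer((x - rng[1]) / diff(rng) * n_bins) + 1L, 1L), n_bins),
    nbins = n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * diff(rng) / n_bins
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[n_bins]
  between <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Longest-direction (max Feret) extent and the perpendicular extent of a
# pixel-coordinate cloud, in pixels (+1 for the pixel footprint).
feret_extents <- function(coords) {
  if (nrow(coords) >= 3) {
    hull <- coords[grDevices::chull(coords[, 1], coords[, 2]), , drop = FALSE]
  } else hull <- coords
  dmat <- as.matrix(dist(hull))
  ij <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  u <- hull[ij[2], ] - hull[ij[1], ]
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(c(long = 1, perp = 1))
  u <- u / nu
  v <- c(-u[2], u[1])
  pv <- hull %*% v
  c(long = max(dmat) + 1, perp = max(pv) - min(pv) + 1)
}

#' Detect gold particles in a 2D image
#'
#' Otsu threshold, connected components (8-connectivity), size filter, then
#' per component the sub-pixel centroid, the extent along its longest
#' direction, the perpendicular extent, and their geometric mean -- the
#' two-perpendicular-direction diameter measurement used for nanoparticle
#' histograms.
#'
#' @param image numeric matrix.
#' @param pixel_size Angstrom per pixel.
#' @param min_px minimum component size in pixels (default 20).
#' @return list of [gold_particle()] (possibly empty), centres in Angstrom.
#' @export
detect_gold_particles <- function(image, pixel_size, min_px = 20L) {
  if (length(image) == 0) stop("empty image")
  thr <- otsu_threshold(image)
  bw <- image > thr
  labels <- label_components_cpp(bw, dim(image))
  counts <- tabulate(labels[labels > 0])
  keep <- which(counts > min_px)
  out <- list()
  for (lab in keep) {
    idx <- which(labels == lab, arr.ind = TRUE)
    centroid <- colMeans(idx)
    ext <- feret_extents(idx)
    out[[length(out) + 1L]] <- gold_particle(
      center = (centroid - 1) * pixel_size,
      diameter_long = ext["long"] * pixel_size,
      diameter_perp = ext["perp"] * pixel_size)
  }
  out
}

#' Pearson linking statistic of particle pairs
#'
#' Pearson correlation between the x coordinates of the two particles of
#' each pair across many pairs (`r_xx`), and likewise for y (`r_yy`).
#' Values near 1 indicate that the two particles of a pair are physically
#' linked rather than randomly placed.
#'
#' @param pairs list of [particle_pair()] (>= 3).
#' @return list with `r_xx` and `r_yy`.
#' @export
pearson_linking <- function(pairs) {
  if (length(pairs) < 3) stop("need at least 3 pairs")
  ax <- vapply(pairs, function(p) p$a$center[1], 0)
  ay <- vapply(pairs, function(p) p$a$center[2], 0)
  bx <- vapply(pairs, function(p) p$b$center[1], 0)
  by <- vapply(pairs, function(p) p$b$center[2], 0)
  if (sd(ax) == 0 || sd(bx) == 0 || sd(ay) == 0 || sd(by) == 0)
    stop("degenerate coordinates: zero variance, correlation undefined")
  list(r_xx = cor(ax, bx), r_yy = cor(ay, by))
}

#' Modal-bin statistic of a histogram
#'
#' Fixed-width bins centred on `min(values) + k * bin_width` (so a reported
#' peak reads `centre +/- bin_width/2`, the half-bin notation of peak
#' populations); returns the modal bin centre and the fraction of samples in
#' it, ties broken toward the lower bin.
#'
#' @param values numeric vector (>= 1 value).
#' @param bin_width bin width in the units of `values` (> 0).
#' @return An object of class `peak_statistic` with `bin_width`,
#'   `peak_center`, `peak_fraction`.
#' @export
histogram_peak <- function(values, bin_width) {
  if (length(values) < 1) stop("need at least one value")
  if (bin_width <= 0) stop("bin_width must be > 0")
  v0 <- min(values)
  idx <- floor((values - v0) / bin_width + 0.5)
  counts <- table(idx)
  modal <- as.integer(names(counts)[which.max(counts)])
  structure(list(bin_width = bin_width,
                 peak_center = v0 + modal * bin_width,
                 peak_fraction = max(counts) / length(values)),
            class = "peak_statistic")
}

#' @export
print.peak_statistic <- function(x, ...) {
  cat(sprintf("peak %.4g +/- %.3g (%.1f%% of samples)\n",
              x$peak_center, x$bin_width / 2, 100 * x$peak_fraction))
  invisible(x)
}

#' Projected length of an isotropically oriented rod
#'
#' A rod of 3D length L viewed in projection appears shorter; under an
#' isotropic orientation distribution the mean in-plane projected length is
#' `(pi/4) * L` (the mean of sin(theta) over the sphere). Returns the closed
#' form and a Monte-Carlo confirmation from uniformly random orientations.
#'
#' @param length_3d rod length (> 0), any unit.
#' @param n_samples Monte-Carlo orientations (default 1e6).
#' @param seed integer seed.
#' @return list with `analytic_mean` and `mc_mean`, same unit as
#'   `length_3d`.
#' @export
projected_length_stats <- function(length_3d, n_samples = 1e6, seed = 1) {
  if (length_3d <= 0) stop("length_3d must be > 0")
  set.seed(derive_seed(seed, 3L))
  z <- runif(n_samples, -1, 1)  # cos(polar angle), uniform on the sphere
  list(analytic_mean = pi / 4 * length_3d,
       mc_mean = length_3d * mean(sqrt(1 - z^2)))
}

#' Relative shortening of an observed length
#'
#' `100 * (reference - observed) / reference`, in percent.
#'
#' @param reference reference length (> 0).
#' @param observed observed length, same unit.
#' @return percent shortening (negative if `observed` exceeds `reference`).
#' @export
relative_shortening <- function(reference, observed) {
  if (reference <= 0) stop("reference must be > 0")
  100 * (reference - observed) / reference
}
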