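# Pipeline orchestration: configuration, seed fan-out, the
# simulate -> reconstruct -> measure -> trace -> energy chain, and the run
# manifest with per-file checksums.

#' Pipeline configuration
#'
#' All tunables of a full simulated IPET run. Defaults follow the imaging
#' geometry of the acquisition being emulated: tilt -60..+60 degrees at 1.5
#' degree increments (81 images), 0.94 A/pixel, 512-pixel boxes, DNA-region
#' SNR 0.31. All randomness flows from `seed` via per-stage substreams.
#'
#' @param seed root integer seed.
#' @param tilt_min,tilt_max,tilt_step tilt range and increment, degrees.
#' @param pixel_size Angstrom per pixel.
#' @param box_px box edge, pixels (even).
#' @param snr_target per-image DNA-region SNR (Inf disables noise).
#' @param max_shift_px maximum random per-image shift, pixels.
#' @param n_iterations refinement iterations.
#' @param n_conformations number of conjugates to simulate and process.
#' @param wlc a [wlc_params()] for the DNA.
#' @param gold_diameters two gold sphere diameters, Angstrom.
#' @param dna_tube_width DNA tube width, Angstrom.
#' @param mass_da particle mass for SNR/particle masks, Dalton.
#' @param trace_threshold_frac centerline trace threshold as a fraction of
#'   the map maximum.
#' @param output_dir output directory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            tilt_min = -60, tilt_max = 60, tilt_step = 1.5,
                            pixel_size = 0.94, box_px = 512,
                            snr_target = 0.31, max_shift_px = 15,
                            n_iterations = 10, n_conformations = 1,
                            wlc = wlc_params(84),
                            gold_diameters = c(63, 63),
                            dna_tube_width = 20,
                            mass_da = 52000,
                            trace_threshold_frac = 0.1,
                            output_dir = tempfile("ipet_run_")) {
  if (tilt_step <= 0) stop("tilt_step must be > 0")
  if (tilt_max <= tilt_min) stop("tilt_max must exceed tilt_min")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (box_px %% 2 != 0 || box_px < 16) stop("box_px must be even and >= 16")
  if (!(snr_target > 0)) stop("snr_target must be > 0")
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (n_conformations < 1) stop("n_conformations must be >= 1")
  stopifnot(inherits(wlc, "wlc_params"))
  structure(list(seed = as.integer(seed), tilt_min = tilt_min,
                 tilt_max = tilt_max, tilt_step = tilt_step,
                 pixel_size = pixel_size, box_px = as.integer(box_px),
                 snr_target = snr_target, max_shift_px = max_shift_px,
                 n_iterations = as.integer(n_iterations),
                 n_conformations = as.integer(n_conformations),
                 wlc = wlc, gold_diameters = gold_diameters,
                 dna_tube_width = dna_tube_width, mass_da = mass_da,
                 trace_threshold_frac = trace_threshold_frac,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (key = value text)
#'
#' Lossless round trip: numeric fields serialize at full precision.
#'
#' @param config a [pipeline_config()] (write).
#' @param path file path.
#' @return `write_config` the path invisibly; `read_config` a
#'   [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  num <- function(x) paste(formatC(x, format = "g", digits = 17),
                           collapse = ",")
  flat <- c(
    seed = num(config$seed), tilt_min = num(config$tilt_min),
    tilt_max = num(config$tilt_max), tilt_step = num(config$tilt_step),
    pixel_size = num(config$pixel_size), box_px = num(config$box_px),
    snr_target = num(config$snr_target),
    max_shift_px = num(config$max_shift_px),
    n_iterations = num(config$n_iterations),
    n_conformations = num(config$n_conformations),
    wlc_n_bp = num(config$wlc$n_bp), wlc_l_p = num(config$wlc$l_p),
    wlc_d = num(config$wlc$d), wlc_temperature = num(config$wlc$temperature),
    gold_diameters = num(config$gold_diameters),
    dna_tube_width = num(config$dna_tube_width),
    mass_da = num(config$mass_da),
    trace_threshold_frac = num(config$trace_threshold_frac),
    output_dir = config$output_dir)
  writeLines(paste(names(flat), flat, sep = " = "), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  nums <- function(k) as.numeric(strsplit(vals[[k]], ",")[[1]])
  pipeline_config(
    seed = nums("seed"), tilt_min = nums("tilt_min"),
    tilt_max = nums("tilt_max"), tilt_step = nums("tilt_step"),
    pixel_size = nums("pixel_size"), box_px = nums("box_px"),
    snr_target = nums("snr_target"), max_shift_px = nums("max_shift_px"),
    n_iterations = nums("n_iterations"),
    n_conformations = nums("n_conformations"),
    wlc = wlc_params(nums("wlc_n_bp"), nums("wlc_l_p"), nums("wlc_d"),
                     nums("wlc_temperature")),
    gold_diameters = nums("gold_diameters"),
    dna_tube_width = nums("dna_tube_width"), mass_da = nums("mass_da"),
    trace_threshold_frac = nums("trace_threshold_frac"),
    output_dir = vals[["output_dir"]])
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full simulated IPET pipeline
#'
#' For each of `n_conformations`: sample a WLC DNA conformation, build and
#' render the DNA-nanogold phantom, simulate the tilt series, run the IPET
#' refinement, compute the half-set FSC resolution, locate the gold
#' particles in the final map, trace and fit the inter-gold centerline,
#' place base-pair frames and compute the bending energies. Every stage
#' writes its standard-format outputs under `config$output_dir`; the
#' returned manifest records files, checksums and summary numbers, and an
#' identical configuration reproduces identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.txt` and `summary.csv` in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, sprintf(...))
  files <- character(0)
  rows <- list()

  for (k in seq_len(config$n_conformations)) {
    seed_k <- derive_seed(config$seed, 100L + k)
    chain <- run_stage("simulate",
                       sample_wlc_chain(config$wlc, seed_k))
    phantom <- run_stage("simulate",
                         conjugate_phantom(chain, config$gold_diameters,
                                           config$dna_tube_width))
    vol <- run_stage("simulate",
                     render_phantom(phantom, config$box_px,
                                    config$pixel_size))
    tilt <- run_stage("simulate",
                      simulate_tilt_series(vol, config$tilt_min,
                                           config$tilt_max,
                                           config$tilt_step,
                                           config$snr_target,
                                           config$max_shift_px,
                                           seed = seed_k))
    files <- c(files,
               run_stage("simulate", {
                 write_chain_csv(chain, out("chain_true_%02d.csv", k))
                 write_mrc(tilt, out("tilt_%02d.mrc", k))
                 write_tlt(tilt$angles, out("tilt_%02d.tlt", k))
                 out(c("chain_true_%02d.csv", "tilt_%02d.mrc",
                       "tilt_%02d.tlt"), k)
               }))

    refined <- run_stage("reconstruct",
                         ipet_refine(tilt, config$n_iterations,
                                     mass_da = config$mass_da))
    fscres <- run_stage("reconstruct",
                        halfset_fsc(tilt, refined$state$shifts))
    files <- c(files, run_stage("reconstruct", {
      write_mrc(refined$volume, out("map_%02d.mrc", k))
      write_fsc_csv(fscres$fsc, out("fsc_%02d.csv", k))
      out(c("map_%02d.mrc", "fsc_%02d.csv"), k)
    }))

    golds <- run_stage("measure",
                       locate_gold_in_volume(refined$volume))
    gold_dist <- sqrt(sum((golds[[1]]$center - golds[[2]]$center)^2))

    # noisy maps can break connectivity at the nominal threshold; back
    # off by halving (up to 3 times) before giving up
    cl <- run_stage("trace", {
      res <- NULL
      for (frac in config$trace_threshold_frac / c(1, 2, 4, 8)) {
        res <- tryCatch(
          trace_centerline(refined$volume, golds[[1]], golds[[2]],
                           frac * max(refined$volume$grid)),
          error = function(e) NULL)
        if (!is.null(res)) break
      }
      if (is.null(res))
        stop("no connected path at any trace threshold tried")
      res
    })
    dna_pts <- run_stage("trace",
                         trim_centerline(cl, golds[[1]]$diameter_geometric / 2,
                                         golds[[2]]$diameter_geometric / 2))
    curve <- run_stage("trace",
                       fit_smooth_curve(dna_pts, fit_tolerance = max(
                         3, config$pixel_size)))
    fitted <- run_stage("trace",
                        frames_along_curve(curve, config$wlc$n_bp,
                                           config$wlc$d))
    files <- c(files, run_stage("trace", {
      write_chain_csv(fitted, out("chain_fit_%02d.csv", k))
      write_pdb_centers(fitted, out("chain_fit_%02d.pdb", k))
      out(c("chain_fit_%02d.csv", "chain_fit_%02d.pdb"), k)
    }))

    ang <- run_stage("energy", chain_bend_angles(fitted, config$wlc))
    en <- run_stage("energy", bending_energy(ang))
    rows[[k]] <- data.frame(
      id = k, n_bp = config$wlc$n_bp,
      E_theta = en$E_theta, E_phi = en$E_phi,
      mean_theta_deg = mean(ang$theta) * 180 / pi,
      mean_phi_deg = mean(ang$phi) * 180 / pi,
      length_3d_A = curve$total_length,
      gold_distance_A = gold_dist,
      resolution_A = fscres$resolution$resolution_A,
      snr_final = tail(refined$state$snr_history, 1))
  }

  summary_df <- do.call(rbind, rows)
  write.csv(summary_df, out("summary.csv"), row.names = FALSE)
  write_config(config, out("config.txt"))
  files <- c(files, out("summary.csv"))

  checksums <- tools::md5sum(files)
  manifest_lines <- c(
    sprintf("ipetdna_version = %s",
            as.character(utils::packageVersion("ipetdna"))),
    sprintf("seed = %d", config$seed),
    sprintf("n_conformations = %d", config$n_conformations),
    sprintf("%s  %s", checksums, basename(names(checksums))))
  writeLines(manifest_lines, out("manifest.txt"))
  manifest <- list(version = as.character(utils::packageVersion("ipetdna")),
                   config = config, files = files, checksums = checksums,
                   summary = summary_df)
  invisible(manifest)
}
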