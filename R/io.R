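# Standard-format I/O: MRC (mode 2, 32-bit float, little-endian, MRC2014
# header), plain-text .tlt angle files, chain CSV and pseudo-atom PDB.
# No MRC reader exists in the installed R stack, so the format is
# implemented here; round-trip and truncation behaviour are under test.

write_mrc_data <- function(data, pixel_size, path) {
  d <- dim(data)
  if (length(d) == 2) d <- c(d, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2)                      # mode 2: float32
  wi(c(0, 0, 0))             # nxstart
  wi(d)                      # mx my mz
  wf(d * pixel_size)         # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1, 2, 3))             # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))
  wi(c(1, 0))                # ispg, nsymbt
  wi(rep(0L, 25))            # extra
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(as.numeric(data)))
  wi(0)                      # nlabl
  writeBin(raw(800), con)    # labels
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

read_mrc_data <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", k, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (length(mode) == 0 || length(d) < 3) stop("truncated MRC header")
  if (mode != 2) stop(sprintf("unsupported MRC mode %d (only mode 2)", mode))
  ri(3)                   # nxstart
  m <- ri(3)              # mx my mz
  cella <- rf(3)
  seek(con, 1024)
  ndat <- prod(d)
  vals <- rf(ndat)
  if (length(vals) < ndat)
    stop(sprintf("truncated MRC data: expected %d values, got %d",
                 ndat, length(vals)))
  pixel <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] else 1
  list(data = array(vals, d), pixel_size = pixel, dims = d)
}

#' Write a density volume or tilt series as MRC
#'
#' Mode-2 (32-bit float) MRC with the pixel size in the header. Tilt series
#' are written as an image stack (nz = number of images); write the angle
#' list alongside with [write_tlt()].
#'
#' @param x a [density_volume()] or [tilt_series()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_mrc <- function(x, path) {
  if (inherits(x, "density_volume")) {
    write_mrc_data(x$grid, x$pixel_size, path)
  } else if (inherits(x, "tilt_series")) {
    write_mrc_data(x$images, x$pixel_size, path)
  } else stop("x must be a density_volume or tilt_series")
  invisible(path)
}

#' Read an MRC volume
#'
#' @param path MRC file (mode 2).
#' @return a [density_volume()].
#' @export
read_mrc_volume <- function(path) {
  m <- read_mrc_data(path)
  density_volume(m$data, m$pixel_size)
}

#' Read an MRC image stack plus angle file as a tilt series
#'
#' @param path MRC stack (mode 2).
#' @param angles_path plain-text .tlt file, one angle (degrees) per line.
#' @return a [tilt_series()].
#' @export
read_mrc_stack <- function(path, angles_path) {
  m <- read_mrc_data(path)
  tilt_series(m$data, read_tlt(angles_path), m$pixel_size)
}

#' Write / read a .tlt tilt-angle file
#'
#' One angle in degrees per line, the common tomography convention.
#'
#' @param angles numeric vector of angles (write) .
#' @param path file path.
#' @return `write_tlt` the path invisibly; `read_tlt` the numeric vector.
#' @export
write_tlt <- function(angles, path) {
  writeLines(formatC(angles, format = "f", digits = 3), path)
  invisible(path)
}

#' @rdname write_tlt
#' @export
read_tlt <- function(path) as.numeric(readLines(path))

#' Write / read a chain conformation as CSV
#'
#' Columns `index, x, y, z, axis_x, axis_y, axis_z` (axes on the first
#' n-1 rows; NA on the last).
#'
#' @param chain a [chain_conformation()] (write).
#' @param path file path.
#' @return `write_chain_csv` the path invisibly; `read_chain_csv` a
#'   [chain_conformation()].
#' @export
write_chain_csv <- function(chain, path) {
  n <- nrow(chain$centers)
  df <- data.frame(index = seq_len(n),
                   x = chain$centers[, 1], y = chain$centers[, 2],
                   z = chain$centers[, 3],
                   axis_x = c(chain$axes[, 1], NA),
                   axis_y = c(chain$axes[, 2], NA),
                   axis_z = c(chain$axes[, 3], NA))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chain_csv
#' @param rise rise stored on the read chain (default: median centre
#'   spacing).
#' @export
read_chain_csv <- function(path, rise = NULL) {
  df <- read.csv(path)
  centers <- as.matrix(df[, c("x", "y", "z")])
  axes <- as.matrix(df[-nrow(df), c("axis_x", "axis_y", "axis_z")])
  if (is.null(rise))
    rise <- median(sqrt(rowSums(diff(centers)^2)))
  chain_conformation(centers, axes, rise)
}

#' Write base-pair centres as a pseudo-atom PDB
#'
#' One CA pseudo-atom per base-pair centre, for visualization in molecular
#' graphics programs.
#'
#' @param chain a [chain_conformation()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_pdb_centers <- function(chain, path) {
  n <- nrow(chain$centers)
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d  CA  DNA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, i, chain$centers[i, 1], chain$centers[i, 2],
            chain$centers[i, 3])
  }, "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write an FSC curve as CSV
#'
#' Two columns: spatial frequency (1/Angstrom) and correlation.
#'
#' @param fsc an `fsc_curve`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fsc_csv <- function(fsc, path) {
  write.csv(data.frame(freq_invA = fsc$shell_freqs,
                       correlation = fsc$correlations),
            path, row.names = FALSE)
  invisible(path)
}

#' The two 84-base conjugate DNA sequences
#'
#' Returns the two complementary 84-base strands (5'-thiol-modified in the
#' conjugates) packaged with the package as a FASTA fixture.
#'
#' @return named character vector of two sequences.
#' @export
dna84_sequences <- function() {
  path <- system.file("extdata", "dna84_sequences.fasta",
                      package = "ipetdna", mustWork = TRUE)
  lines <- readLines(path)
  headers <- grep("^>", lines)
  ends <- c(headers[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(headers), function(i) {
    paste(lines[(headers[i] + 1L):ends[i]], collapse = "")
  }, "")
  names(seqs) <- sub("^>\\s*", "", lines[headers])
  seqs
}
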