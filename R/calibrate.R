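#' White/black reference pair
#'
#' Bundles the two reference cubes used for reflectance calibration: a white
#' standard (maximum reflectance under the acquisition conditions) and a
#' black/dark frame (lens capped, lights off). Both must share the shape and
#' wavelength grid of the raw cubes they calibrate.
#'
#' @param white,black raw [hypercube]s.
#' @return An object of class `reference_pair`.
#' @export
reference_pair <- function(white, black) {
  stopifnot(inherits(white, "hypercube"), inherits(black, "hypercube"))
  if (!identical(dim(white$data), dim(black$data)))
    stop("white and black reference cubes must share shape")
  if (!isTRUE(all.equal(white$wavelengths, black$wavelengths)))
    stop("white and black reference cubes must share the wavelength grid")
  structure(list(white = white, black = black), class = "reference_pair")
}

#' Reflectance calibration of a raw hypercube
#'
#' Converts raw intensities to relative reflectance per pixel and band:
#' `I = (I0 - B) / (W - B)`, with `I0` the raw cube, `W` the white reference
#' and `B` the black (dark-current) reference. Where the denominator
#' `W - B` is not larger than `eps` the reflectance is set to 0 and the
#' voxel is flagged in the degenerate-denominator mask. Values are *not*
#' clipped; voxels outside the plausible [0, 1.5] reflectance range are
#' merely counted in the attached QC summary.
#'
#' @param raw raw [hypercube].
#' @param refs a [reference_pair] matching `raw` in shape and wavelengths.
#' @param eps nonnegative threshold on the raw-intensity scale below which
#'   the denominator is treated as degenerate.
#' @return A reflectance [hypercube] with an extra element `qc`: a list with
#'   `degenerate` (logical array, TRUE where `W - B <= eps`),
#'   `n_degenerate`, `n_below_0` and `n_above_1.5`.
#' @examples
#' wl <- c(500, 600)
#' raw <- hypercube(array(0.6, c(2, 2, 2)), wl)
#' refs <- reference_pair(hypercube(array(1, c(2, 2, 2)), wl),
#'                        hypercube(array(0.2, c(2, 2, 2)), wl))
#' calibrate_reflectance(raw, refs)$data[1, 1, 1]  # (0.6-0.2)/(1-0.2) = 0.5
#' @export
calibrate_reflectance <- function(raw, refs, eps = 1e-8) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_pair"))
  if (eps < 0) stop("`eps` must be nonnegative")
  if (!identical(dim(raw$data), dim(refs$white$data)))
    stop("raw cube and reference cubes differ in shape")
  if (!isTRUE(all.equal(raw$wavelengths, refs$white$wavelengths)))
    stop("raw cube and reference cubes differ in wavelength grid")

  denom <- refs$white$data - refs$black$data
  degen <- denom <= eps
  refl <- (raw$data - refs$black$data) / denom
  refl[degen] <- 0
  out <- hypercube(refl, raw$wavelengths, "reflectance")
  out$qc <- list(degenerate = degen,
                 n_degenerate = sum(degen),
                 n_below_0 = sum(refl < 0),
                 n_above_1.5 = sum(refl > 1.5))
  out
}

#' Write the calibration QC summary as JSON
#'
#' @param cube a calibrated [hypercube] carrying a `qc` element.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"), !is.null(cube$qc))
  qc <- cube$qc[c("n_degenerate", "n_below_0", "n_above_1.5")]
  qc$n_voxels <- length(cube$data)
  jsonlite::write_json(qc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Crop the spectral axis of a hypercube
#'
#' Retains exactly the bands whose wavelength lies in the closed interval
#' `[lo, hi]`. Sensors are typically noisy at the edges of their sensitivity
#' range, so analyses restrict to an interior window (e.g. 500-900 nm for a
#' 380-1030 nm VIS-NIR camera).
#'
#' @param cube a [hypercube].
#' @param lo,hi interval bounds in nm, `lo < hi`.
#' @return The cropped [hypercube].
#' @export
crop_spectral <- function(cube, lo, hi) {
  stopifnot(inherits(cube, "hypercube"))
  if (!(lo < hi)) stop("`lo` must be smaller than `hi`")
  keep <- cube$wavelengths >= lo & cube$wavelengths <= hi
  if (!any(keep))
    stop("no bands fall inside [", lo, ", ", hi, "] nm")
  hypercube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
            cube$kind)
}

#' Extract non-overlapping square ROIs at random positions
#'
#' Draws `n` pairwise non-overlapping `side x side` windows from a cube by
#' seeded rejection sampling (uniformly random upper-left corners; proposals
#' overlapping an accepted ROI are discarded, up to `10 * n` proposals).
#' Overlapping windows would duplicate texture statistics across "samples",
#' so overlap is disallowed.
#'
#' @param cube a [hypercube].
#' @param side window side in pixels, at most `min(rows, cols)`.
#' @param n number of ROIs requested.
#' @param seed integer seed; the same seed reproduces the same origins.
#' @return List of `n` [roi] objects.
#' @export
extract_rois <- function(cube, side, n, seed) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  side <- as.integer(side)
  if (side < 1L || side > min(d[1L], d[2L]))
    stop("`side` must be between 1 and min(rows, cols) = ", min(d[1:2]))
  max_r <- d[1L] - side + 1L
  max_c <- d[2L] - side + 1L
  origins <- with_seed(seed, {
    acc <- matrix(integer(0), ncol = 2L)
    proposals <- 0L
    while (nrow(acc) < n && proposals < 10L * n) {
      proposals <- proposals + 1L
      cand <- c(sample.int(max_r, 1L), sample.int(max_c, 1L))
      if (nrow(acc) == 0L ||
          !any(abs(acc[, 1L] - cand[1L]) < side &
               abs(acc[, 2L] - cand[2L]) < side)) {
        acc <- rbind(acc, cand)
      }
    }
    acc
  })
  if (nrow(origins) < n)
    stop("could not place ", n, " non-overlapping ", side, "x", side,
         " ROIs; maximum achieved was ", nrow(origins))
  lapply(seq_len(n), function(i) roi(cube, origins[i, ], side))
}

#' Mean reflectance spectrum of an ROI
#'
#' Averages all `side^2` pixel spectra of a reflectance ROI into one value
#' per band; this mean spectrum is the sample's spectral representation.
#'
#' @param x an [roi] with a reflectance cube.
#' @return Numeric vector of length `bands`, named by wavelength.
#' @export
mean_spectrum <- function(x) {
  stopifnot(inherits(x, "roi"))
  if (x$cube$kind != "reflectance")
    stop("mean_spectrum expects a reflectance ROI; calibrate first")
  d <- dim(x$cube$data)
  if (prod(d[1:2]) == 0L) stop("empty ROI")
  s <- colMeans(matrix(x$cube$data, nrow = d[1L] * d[2L], ncol = d[3L]))
  names(s) <- format(x$cube$wavelengths, trim = TRUE)
  s
}
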