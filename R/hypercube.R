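#' Hyperspectral cube
#'
#' A `hypercube` is the package's in-memory container for one hyperspectral
#' image: a `lines x samples x bands` numeric array together with the
#' per-band wavelengths in nanometres and free-form acquisition metadata.
#' Pixel values are either raw sensor counts (before calibration) or
#' reflectance in `[0, 1.2]` (after [calibrate()]).
#'
#' @param data numeric 3-D array, `lines x samples x bands`.
#' @param wavelengths numeric vector of band-centre wavelengths (nm),
#'   strictly increasing, one per band.
#' @param meta named list of acquisition tags (e.g. `interleave`,
#'   `calibrated`). Optional.
#' @return An object of class `hypercube`.
#' @examples
#' cube <- hypercube(array(0.5, c(4, 4, 3)), c(500, 600, 700))
#' dim(cube$data)
#' @export
hypercube <- function(data, wavelengths, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (lines x samples x bands)")
  wavelengths <- as.numeric(wavelengths)
  if (dim(data)[3L] != length(wavelengths))
    stop(sprintf("bands (%d) != length(wavelengths) (%d)",
                 dim(data)[3L], length(wavelengths)))
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(data = data, wavelengths = wavelengths, meta = meta),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d lines x %d samples x %d bands (%.1f-%.1f nm)%s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              if (isTRUE(x$meta$calibrated)) " [reflectance]" else ""))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Index of the band nearest a target wavelength
#'
#' @param cube a [hypercube()] (or a numeric wavelength vector).
#' @param wavelength target wavelength in nm.
#' @param max_gap maximum tolerated distance in nm; `Inf` disables the check.
#' @return integer band index.
#' @export
band_nearest <- function(cube, wavelength, max_gap = Inf) {
  wl <- if (inherits(cube, "hypercube")) cube$wavelengths else as.numeric(cube)
  i <- which.min(abs(wl - wavelength))
  if (abs(wl[i] - wavelength) > max_gap)
    stop(sprintf("no band within %g nm of %g nm (nearest: %g nm)",
                 max_gap, wavelength, wl[i]))
  i
}

# pixels-x-bands view of a cube; rows ordered like as.vector(mask)
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}
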