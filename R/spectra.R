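#' Segment the leaf region of interest
#'
#' Threshold segmentation on the band nearest a reference NIR wavelength
#' (default 800 nm), where leaf/background contrast is maximal, followed by
#' a largest-connected-component filter to reject background specks.
#'
#' @param cube calibrated reflectance [hypercube()].
#' @param threshold reflectance threshold; pixels above it are leaf
#'   candidates.
#' @param wavelength segmentation wavelength in nm.
#' @param min_pixels minimum accepted ROI size.
#' @param max_area_frac if the mask covers more than this fraction of the
#'   frame the result is flagged (degenerate threshold) via attribute
#'   `qc_flag`.
#' @return logical matrix (`lines x samples`); leaf pixels are `TRUE`.
#' @export
segment_roi <- function(cube, threshold = 0.35, wavelength = 800,
                        min_pixels = 50, max_area_frac = 0.95) {
  b <- band_nearest(cube, wavelength)
  img <- cube$data[, , b]
  cand <- img > threshold
  if (!any(cand))
    stop("segmentation error: empty mask (no pixel above threshold)")
  lab <- EBImage::bwlabel(cand)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  mask <- lab == keep
  if (sum(mask) < min_pixels)
    stop(sprintf("segmentation error: ROI has %d pixels (< min_pixels = %d)",
                 sum(mask), min_pixels))
  if (sum(mask) > max_area_frac * length(mask))
    attr(mask, "qc_flag") <- "mask_covers_frame"
  mask
}

#' Mean reflectance spectrum over a mask
#'
#' Per-band arithmetic mean over the masked pixels, the ROI spectrum used
#' throughout the pipeline.
#'
#' @param cube a [hypercube()].
#' @param mask logical matrix matching the cube's spatial dimensions.
#' @return numeric reflectance vector, one value per band.
#' @export
mean_spectrum <- function(cube, mask) {
  d <- dim(cube$data)
  if (!all(dim(mask) == d[1:2]))
    stop("mask shape does not match the cube")
  idx <- which(as.vector(mask))
  if (!length(idx)) stop("empty mask")
  colMeans(cube_matrix(cube)[idx, , drop = FALSE])
}

#' Savitzky-Golay deviation noise metric
#'
#' Subtracts a Savitzky-Golay smoothed copy from the raw spectrum and
#' reports the deviation series and its RMS inside an analysis window
#' (default 400-700 nm). Large RMS in 400-500 nm is the signature of
#' acquisition without supplemental blue illumination.
#'
#' @param spectrum reflectance vector.
#' @param wavelengths matching wavelengths (nm).
#' @param window_nm analysis window, nm pair.
#' @param sg_window Savitzky-Golay window length (odd, > `sg_order`).
#' @param sg_order Savitzky-Golay polynomial order.
#' @return list of class `noise_report`: `deviation`, `wavelengths`
#'   (inside the window), `rms`, `window`.
#' @export
sg_deviation <- function(spectrum, wavelengths, window_nm = c(400, 700),
                         sg_window = 11, sg_order = 2) {
  stopifnot(length(spectrum) == length(wavelengths))
  if (sg_window %% 2 != 1 || sg_window <= sg_order)
    stop("sg_window must be odd and greater than sg_order")
  if (window_nm[1] < min(wavelengths) - 1e-9 ||
      window_nm[1] > max(wavelengths) ||
      window_nm[2] > max(wavelengths) + 1e-9)
    stop("analysis window outside the wavelength range")
  smoothed <- signal::sgolayfilt(spectrum, p = sg_order, n = sg_window)
  idx <- which(wavelengths >= window_nm[1] & wavelengths <= window_nm[2])
  dev <- spectrum[idx] - smoothed[idx]
  structure(list(deviation = dev, wavelengths = wavelengths[idx],
                 rms = sqrt(mean(dev^2)), window = window_nm),
            class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("<noise_report> %d bands in %g-%g nm, RMS deviation %.5f\n",
              length(x$deviation), x$window[1], x$window[2], x$rms))
  invisible(x)
}

#' Extract ROI spectra from a dataset of cubes
#'
#' Runs [segment_roi()] and [mean_spectrum()] over every cube of a
#' [generate_dataset()] result (or any list of cubes) and returns the
#' spectra matrix alongside the sample metadata.
#'
#' @param dataset a `leaf_dataset` (with rendered cubes).
#' @param threshold,wavelength,min_pixels passed to [segment_roi()].
#' @return list: `spectra` (leaves x bands), `masks`, plus the dataset's
#'   metadata columns.
#' @export
extract_spectra <- function(dataset, threshold = 0.35, wavelength = 800,
                            min_pixels = 50) {
  stopifnot(inherits(dataset, "leaf_dataset"), !is.null(dataset$cubes))
  masks <- lapply(dataset$cubes, segment_roi, threshold = threshold,
                  wavelength = wavelength, min_pixels = min_pixels)
  spectra <- t(vapply(seq_along(dataset$cubes), function(i)
    mean_spectrum(dataset$cubes[[i]], masks[[i]]),
    numeric(length(dataset$wavelengths))))
  list(spectra = spectra, masks = masks, labels = dataset$labels,
       treatments = dataset$treatments, stages = dataset$stages,
       plant_ids = dataset$plant_ids, replicate_idx = dataset$replicate_idx,
       wavelengths = dataset$wavelengths)
}
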