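#' Build the RIS image stack for one leaf
#'
#' Crops the ROI bounding box of each RIS band image, zeroes background
#' pixels with the mask, and resizes to `out_hw` (bilinear). Channels
#' follow the RIS order, reference image first.
#'
#' @param cube reflectance [hypercube()].
#' @param mask logical leaf mask.
#' @param ris_wavelengths RIS wavelengths in nm, reference first; each must
#'   match a cube band to within half the band spacing.
#' @param out_hw output size `c(H, W)` (default 32x32).
#' @return numeric array `H x W x k`.
#' @export
make_ris_stack <- function(cube, mask, ris_wavelengths,
                           out_hw = c(32L, 32L)) {
  stopifnot(length(ris_wavelengths) >= 1L)
  half_gap <- if (length(cube$wavelengths) > 1L)
    max(diff(cube$wavelengths)) / 2 else Inf
  bands <- vapply(ris_wavelengths, function(wl) {
    i <- which.min(abs(cube$wavelengths - wl))
    if (abs(cube$wavelengths[i] - wl) > half_gap + 1e-9)
      stop(sprintf("RIS wavelength %g nm not present in the cube", wl))
    i
  }, integer(1))
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  sub_mask <- mask[rows[1]:rows[2], cols[1]:cols[2]]
  out <- array(0, c(out_hw[1], out_hw[2], length(bands)))
  for (j in seq_along(bands)) {
    img <- cube$data[rows[1]:rows[2], cols[1]:cols[2], bands[j]]
    img[!sub_mask] <- 0
    out[, , j] <- EBImage::resize(img, w = out_hw[1], h = out_hw[2])
  }
  out
}

#' Build RIS stacks for a set of leaves
#'
#' @param cubes list of reflectance cubes.
#' @param masks matching list of leaf masks.
#' @param ris_wavelengths RIS wavelengths, reference first.
#' @param out_hw stack size `c(H, W)`.
#' @return array `(n, H, W, k)`.
#' @export
build_stacks <- function(cubes, masks, ris_wavelengths, out_hw = c(32L, 32L)) {
  n <- length(cubes)
  out <- array(0, c(n, out_hw[1], out_hw[2], length(ris_wavelengths)))
  for (i in seq_len(n))
    out[i, , , ] <- make_ris_stack(cubes[[i]], masks[[i]], ris_wavelengths,
                                   out_hw)
  out
}

#' Spectroscopy-image combination
#'
#' Standardizes the spectral block and the image-feature block separately
#' (centre/scale fitted on the calibration rows only) and concatenates
#' them, spectral block first, so both blocks enter the classifier on a
#' comparable scale. Zero-variance columns are standardized to 0 and
#' flagged in the `qc` attribute.
#'
#' @param spectral EW reflectance matrix (n x |EW|).
#' @param image CNN feature matrix (n x d_img).
#' @param calib_idx rows used to fit the standardization (default: all).
#' @return matrix `n x (|EW| + d_img)` with attributes `blocks` (column
#'   counts) and `qc`.
#' @export
combine_features <- function(spectral, image, calib_idx = NULL) {
  spectral <- as.matrix(spectral); image <- as.matrix(image)
  stopifnot(nrow(spectral) == nrow(image),
            all(is.finite(spectral)), all(is.finite(image)))
  if (is.null(calib_idx)) calib_idx <- seq_len(nrow(spectral))
  std_block <- function(m) {
    ctr <- colMeans(m[calib_idx, , drop = FALSE])
    scl <- apply(m[calib_idx, , drop = FALSE], 2, stats::sd)
    flat <- which(scl == 0 | !is.finite(scl))
    scl[flat] <- 1
    z <- sweep(sweep(m, 2, ctr), 2, scl, "/")
    z[, flat] <- 0
    list(z = z, flat = flat)
  }
  s <- std_block(spectral); i <- std_block(image)
  out <- cbind(s$z, i$z)
  attr(out, "blocks") <- c(spectral = ncol(spectral), image = ncol(image))
  attr(out, "qc") <- list(zero_variance_spectral = s$flat,
                          zero_variance_image = i$flat)
  out
}

#' Fuse one young/mature sample pair
#'
#' Concatenates the combined feature vectors of the paired young and
#' mature leaf from the same plant and replicate (young block first). The
#' pair must agree on treatment label, plant and replicate.
#'
#' @param young,mature lists with `vector`, `label`, `plant_id`,
#'   `replicate_idx` (and optionally `stage`).
#' @return list of class `fused_sample`: `vector`, `label`, `plant_id`,
#'   `replicate_idx`.
#' @export
fuse_sample <- function(young, mature) {
  if (!identical(young$plant_id, mature$plant_id))
    stop("pairing error: plant_id mismatch")
  if (!identical(young$replicate_idx, mature$replicate_idx))
    stop("pairing error: replicate_idx mismatch")
  if (!identical(as.character(young$label), as.character(mature$label)))
    stop("pairing error: treatment label mismatch")
  structure(list(vector = c(young$vector, mature$vector),
                 label = young$label, plant_id = young$plant_id,
                 replicate_idx = young$replicate_idx),
            class = "fused_sample")
}

#' Fuse young and mature feature tables into one matrix per pair
#'
#' Matches rows by `(plant_id, replicate_idx)` across the two stages,
#' checks label agreement, and concatenates young-block then mature-block.
#'
#' @param young_x,mature_x feature matrices for the two stages.
#' @param young_meta,mature_meta data frames with columns `label`,
#'   `plant_id`, `replicate_idx` aligned to the matrices.
#' @return list: `x` (pairs x (d_young + d_mature)), `labels`, `plant_ids`,
#'   `replicate_idx`.
#' @export
fuse_pairs <- function(young_x, mature_x, young_meta, mature_meta) {
  ky <- paste(young_meta$plant_id, young_meta$replicate_idx, sep = "_")
  km <- paste(mature_meta$plant_id, mature_meta$replicate_idx, sep = "_")
  if (anyDuplicated(ky) || anyDuplicated(km))
    stop("pairing error: duplicated (plant_id, replicate_idx)")
  j <- match(ky, km)
  if (anyNA(j)) stop("pairing error: unmatched young samples")
  if (!all(as.character(young_meta$label) ==
           as.character(mature_meta$label[j])))
    stop("pairing error: treatment label mismatch within a pair")
  list(x = cbind(as.matrix(young_x), as.matrix(mature_x)[j, , drop = FALSE]),
       labels = young_meta$label, plant_ids = young_meta$plant_id,
       replicate_idx = young_meta$replicate_idx)
}
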