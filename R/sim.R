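#' Simulation parameters for synthetic leaf cubes
#'
#' Defines the spectral and spatial model of the bundled leaf-cube
#' simulator. The noiseless leaf spectrum is a sum of smooth components:
#' a low visible baseline, a Gaussian green peak near 560 nm whose height
#' grows with drought-stress level, a logistic red edge near 730 nm whose
#' position blue-shifts with stress, and a high NIR plateau. Young and
#' mature leaves differ by a fixed smooth perturbation plus stage-specific
#' effect gains, so the two stages carry partially distinct stress signals.
#'
#' @param n_bands number of spectral bands (default 272).
#' @param wl_range wavelength range in nm, `c(min, max)` (default 400-1000).
#' @param green_peak_center centre of the green reflectance peak, nm.
#' @param green_peak_amp peak amplitude at stress level 0 (reflectance).
#' @param green_peak_sigma Gaussian width of the green peak, nm.
#' @param green_peak_gain_per_level additive peak-height gain per stress
#'   level (>= 0); stress raises the 560 nm reflectance.
#' @param rededge_center red-edge inflection wavelength at level 0, nm.
#' @param rededge_scale logistic scale of the red edge, nm.
#' @param rededge_blueshift_per_level blue shift of the red edge per stress
#'   level, nm (>= 0).
#' @param nir_level NIR plateau reflectance in `[0, 1]`.
#' @param baseline visible baseline reflectance.
#' @param stage_offset amplitude of the smooth spectral perturbation added
#'   to mature leaves (reflectance units).
#' @param stage_gains named list with `young` and `mature` entries, each a
#'   named vector `c(green=, rededge=)` of multipliers applied to the two
#'   per-level stress effects. Lets the two stages respond to stress in
#'   different spectral regions.
#' @param sample_jitter named list of per-leaf biological variability
#'   standard deviations: `green_amp` (reflectance), `rededge_nm` (nm),
#'   `baseline` (reflectance), `scale` (multiplicative). Applied by
#'   [generate_dataset()], never by [base_spectrum()].
#' @param pixel_noise_sd i.i.d. Gaussian pixel noise sd (reflectance).
#' @param blue_noise_sd extra high-frequency noise sd applied only to bands
#'   below 500 nm when `blue_light = FALSE`, emulating the absence of
#'   supplemental blue illumination.
#' @param blue_light logical; simulate acquisition with supplemental blue
#'   lights (TRUE suppresses the 400-500 nm noise).
#' @param background_reflectance flat reflectance of non-leaf pixels.
#' @param leaf_shape full ellipse axes of the leaf footprint, pixels.
#' @param frame_size frame size `c(lines, samples)`, pixels.
#' @param seed integer seed used by dataset-level generation.
#' @return A validated list of class `sim_params`.
#' @seealso [base_spectrum()], [render_cube()], [generate_dataset()]
#' @export
sim_params <- function(n_bands = 272L,
                       wl_range = c(400, 1000),
                       green_peak_center = 560,
                       green_peak_amp = 0.10,
                       green_peak_sigma = 30,
                       green_peak_gain_per_level = 0.03,
                       rededge_center = 730,
                       rededge_scale = 12,
                       rededge_blueshift_per_level = 8,
                       nir_level = 0.55,
                       baseline = 0.05,
                       stage_offset = 0.02,
                       stage_gains = list(
                         young  = c(green = 1.3, rededge = 0.7),
                         mature = c(green = 0.7, rededge = 1.3)),
                       sample_jitter = list(
                         green_amp = 0.015, rededge_nm = 4,
                         baseline = 0.01, scale = 0.03),
                       pixel_noise_sd = 0.01,
                       blue_noise_sd = 0.03,
                       blue_light = TRUE,
                       background_reflectance = 0.03,
                       leaf_shape = c(40, 24),
                       frame_size = c(64, 64),
                       seed = 1L) {
  p <- list(n_bands = as.integer(n_bands), wl_range = as.numeric(wl_range),
            green_peak_center = green_peak_center,
            green_peak_amp = green_peak_amp,
            green_peak_sigma = green_peak_sigma,
            green_peak_gain_per_level = green_peak_gain_per_level,
            rededge_center = rededge_center, rededge_scale = rededge_scale,
            rededge_blueshift_per_level = rededge_blueshift_per_level,
            nir_level = nir_level, baseline = baseline,
            stage_offset = stage_offset, stage_gains = stage_gains,
            sample_jitter = sample_jitter,
            pixel_noise_sd = pixel_noise_sd, blue_noise_sd = blue_noise_sd,
            blue_light = isTRUE(blue_light),
            background_reflectance = background_reflectance,
            leaf_shape = as.numeric(leaf_shape),
            frame_size = as.integer(frame_size), seed = as.integer(seed))
  stopifnot(p$n_bands >= 2L, p$wl_range[2] > p$wl_range[1],
            p$green_peak_gain_per_level >= 0,
            p$rededge_blueshift_per_level >= 0,
            p$nir_level >= 0, p$nir_level <= 1,
            p$pixel_noise_sd >= 0, p$blue_noise_sd >= 0,
            all(p$leaf_shape > 0), all(p$frame_size > 0))
  p$wavelengths <- seq(p$wl_range[1], p$wl_range[2], length.out = p$n_bands)
  class(p) <- "sim_params"
  p
}

#' Wavelength grid of a parameter set
#' @param params a [sim_params()] object.
#' @return numeric vector of band-centre wavelengths (nm).
#' @export
sim_wavelengths <- function(params) params$wavelengths

# shared spectral kernel; all stress/stage/jitter effects enter through the
# component parameters so the functional form is identical everywhere
spectrum_components <- function(wl, baseline, green_amp, green_center,
                                green_sigma, rededge_pos, rededge_scale,
                                nir_level, stage, stage_offset, scale = 1) {
  r <- baseline +
    green_amp * exp(-0.5 * ((wl - green_center) / green_sigma)^2) +
    (nir_level - baseline) * stats::plogis((wl - rededge_pos) / rededge_scale)
  if (stage == "mature")
    r <- r + stage_offset * sin(2 * pi * (wl - min(wl)) / diff(range(wl)))
  pmin(pmax(r * scale, 0), 1.2)
}

#' Noiseless leaf reflectance spectrum at a given stress level
#'
#' Deterministic spectral model: the reflectance at the green peak is
#' non-decreasing in stress level and the red-edge inflection moves to
#' shorter wavelengths as stress increases, matching the qualitative
#' behaviour of drought-stressed tomato canopies.
#'
#' @param level drought-stress level: 0 (well-watered), 1 (reduced),
#'   2 (deficient).
#' @param stage `"young"` or `"mature"`.
#' @param params a [sim_params()] object.
#' @return numeric reflectance vector over `sim_wavelengths(params)`.
#' @examples
#' p <- sim_params(n_bands = 60)
#' s0 <- base_spectrum(0, "young", p)
#' s2 <- base_spectrum(2, "young", p)
#' s2[band_nearest(p$wavelengths, 560)] > s0[band_nearest(p$wavelengths, 560)]
#' @export
base_spectrum <- function(level, stage = c("young", "mature"), params = sim_params()) {
  stage <- match.arg(stage)
  if (length(level) != 1L || !level %in% 0:2)
    stop("`level` must be 0, 1 or 2")
  g <- params$stage_gains[[stage]]
  spectrum_components(
    wl           = params$wavelengths,
    baseline     = params$baseline,
    green_amp    = params$green_peak_amp +
                   level * params$green_peak_gain_per_level * g[["green"]],
    green_center = params$green_peak_center,
    green_sigma  = params$green_peak_sigma,
    rededge_pos  = params$rededge_center -
                   level * params$rededge_blueshift_per_level * g[["rededge"]],
    rededge_scale = params$rededge_scale,
    nir_level    = params$nir_level,
    stage        = stage,
    stage_offset = params$stage_offset)
}

#' Red-edge position of a spectrum
#'
#' Wavelength of the maximal first finite-difference derivative inside a
#' window (default 680-780 nm), the conventional red-edge position.
#'
#' @param spectrum reflectance vector.
#' @param wavelengths matching wavelengths (nm).
#' @param window search window in nm.
#' @return wavelength (nm) of the steepest reflectance rise.
#' @export
rededge_position <- function(spectrum, wavelengths, window = c(680, 780)) {
  d <- diff(spectrum) / diff(wavelengths)
  mid <- (wavelengths[-1] + wavelengths[-length(wavelengths)]) / 2
  in_w <- mid >= window[1] & mid <= window[2]
  if (!any(in_w)) stop("red-edge window outside wavelength range")
  mid[in_w][which.max(d[in_w])]
}

leaf_mask <- function(params) {
  h <- params$frame_size[1]; w <- params$frame_size[2]
  a <- params$leaf_shape[1] / 2; b <- params$leaf_shape[2] / 2
  if (params$leaf_shape[1] >= w || params$leaf_shape[2] >= h)
    stop("leaf ellipse exceeds the frame")
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xy <- expand.grid(row = seq_len(h), col = seq_len(w))
  m <- ((xy$col - cx) / a)^2 + ((xy$row - cy) / b)^2 <= 1
  matrix(m, h, w)
}

#' Render one synthetic leaf cube from a spectrum
#'
#' Pixels inside an elliptical leaf footprint carry `spectrum` plus i.i.d.
#' Gaussian noise (`pixel_noise_sd`; plus `blue_noise_sd` below 500 nm when
#' `blue_light = FALSE`); background pixels carry a flat low reflectance.
#' The noise stream is arranged so that toggling `blue_light` with the same
#' seed leaves the common pixel noise identical.
#'
#' @param spectrum reflectance vector over `sim_wavelengths(params)`.
#' @param params a [sim_params()] object.
#' @param rng_seed integer seed; same seed gives a bit-identical cube.
#' @param blue_light overrides `params$blue_light` when given.
#' @return list with `cube` (a [hypercube()], reflectance) and `mask`
#'   (logical ground-truth leaf footprint).
#' @export
render_cube <- function(spectrum, params, rng_seed = params$seed,
                        blue_light = params$blue_light) {
  stopifnot(length(spectrum) == params$n_bands)
  mask <- leaf_mask(params)
  h <- params$frame_size[1]; w <- params$frame_size[2]; nb <- params$n_bands
  mat <- matrix(params$background_reflectance, h * w, nb)
  idx <- which(as.vector(mask))
  set.seed(as.integer(rng_seed))
  noise <- matrix(stats::rnorm(length(idx) * nb, sd = params$pixel_noise_sd),
                  length(idx), nb)
  if (!isTRUE(blue_light) && params$blue_noise_sd > 0) {
    blue <- which(params$wavelengths < 500)
    if (length(blue))
      noise[, blue] <- noise[, blue] +
        matrix(stats::rnorm(length(idx) * length(blue),
                            sd = params$blue_noise_sd), length(idx))
  }
  mat[idx, ] <- rep(spectrum, each = length(idx)) + noise
  mat <- pmin(pmax(mat, 0), 1.2)
  cube <- hypercube(array(mat, c(h, w, nb)), params$wavelengths,
                    meta = list(calibrated = TRUE, synthetic = TRUE,
                                blue_light = isTRUE(blue_light)))
  list(cube = cube, mask = mask)
}

#' Synthetic white and dark reference frames
#'
#' One row per spatial column (push-broom convention: references are
#' averaged over scan lines), one column per band. The white frame sits
#' near the sensor's full scale with a small spatial ripple; the dark frame
#' carries a small offset.
#'
#' @param params a [sim_params()] object.
#' @param full_scale sensor full-scale counts.
#' @param white_level white-board level as a fraction of full scale.
#' @param ripple relative amplitude of the spatial ripple (0 gives
#'   spatially constant frames).
#' @param dark_offset dark-frame counts.
#' @return a [reference_pair()].
#' @export
make_reference_frames <- function(params, full_scale = 4095,
                                  white_level = 0.9, ripple = 0.02,
                                  dark_offset = 40) {
  ns <- params$frame_size[2]; nb <- params$n_bands
  col_rip <- 1 + ripple * sin(2 * pi * seq_len(ns) / ns)
  band_rip <- 1 + (ripple / 2) * cos(2 * pi * seq_len(nb) / nb)
  white <- full_scale * white_level * outer(col_rip, band_rip)
  dark <- dark_offset * outer(rep(1, ns), 1 + (ripple / 4) * band_rip)
  reference_pair(white, dark)
}

#' Frame a reflectance cube as raw sensor counts
#'
#' Inverse of [calibrate()]: `raw = dark + r * (white - dark)`, broadcasting
#' the per-column references along scan lines. Calibrating the result
#' recovers `r` exactly.
#'
#' @param cube reflectance [hypercube()].
#' @param refs a [reference_pair()].
#' @return raw-count [hypercube()].
#' @export
synthesize_raw <- function(cube, refs) {
  d <- dim(cube$data)
  raw <- array(0, d)
  for (b in seq_len(d[3]))
    raw[, , b] <- matrix(refs$dark[, b], d[1], d[2], byrow = TRUE) +
      cube$data[, , b] *
      matrix(refs$white[, b] - refs$dark[, b], d[1], d[2], byrow = TRUE)
  hypercube(raw, cube$wavelengths, meta = list(calibrated = FALSE))
}

#' Generate a labelled synthetic young/mature leaf dataset
#'
#' Emulates the study design: per-treatment leaf counts per stage, each
#' plant contributing up to three replicate leaves, and every
#' `(plant_id, replicate)` present in both stages (total young/mature
#' pairing). Per-leaf biological variability (`params$sample_jitter`) is
#' drawn once per leaf; pixel noise is drawn per cube.
#'
#' @param design integer vector of per-treatment leaf counts per stage,
#'   e.g. `c(108, 105, 102)`.
#' @param params a [sim_params()] object.
#' @param seed integer seed; the full dataset is reproducible from it.
#' @param render if `FALSE`, skip cube rendering and return spectra only
#'   (`spectra` holds the per-leaf jittered noiseless spectrum).
#' @return list of class `leaf_dataset`: `cubes`, `truth_masks`,
#'   `spectra` (leaves x bands, noiseless per-leaf spectra), `labels`
#'   (0/1/2), `treatments` (factor), `stages`, `plant_ids`,
#'   `replicate_idx`, `wavelengths`, `params`.
#' @examples
#' ds <- generate_dataset(c(2, 2, 2), sim_params(n_bands = 24,
#'   frame_size = c(16, 16), leaf_shape = c(10, 6)), seed = 1)
#' length(ds$cubes)  # 12 = 6 pairs
#' @export
generate_dataset <- function(design = c(108, 105, 102),
                             params = sim_params(), seed = params$seed,
                             render = TRUE) {
  stopifnot(length(design) == 3L, all(design >= 1))
  set.seed(as.integer(seed))
  stages <- c("young", "mature")
  treatments <- c("well", "reduced", "deficient")
  # per-class plant/replicate layout, shared by both stages (pairing total)
  plant0 <- 0L
  meta <- do.call(rbind, lapply(1:3, function(ci) {
    n <- design[ci]
    reps <- if (n %% 3L == 0L) 3L else 1L
    pl <- plant0 + rep(seq_len(ceiling(n / reps)), each = reps)[seq_len(n)]
    plant0 <<- max(pl)
    data.frame(label = ci - 1L, plant_id = pl,
               replicate_idx = stats::ave(pl, pl, FUN = seq_along))
  }))
  n_pairs <- nrow(meta)
  rows <- meta[rep(seq_len(n_pairs), times = 2L), ]
  rows$stage <- rep(stages, each = n_pairs)
  rows$treatment <- factor(treatments[rows$label + 1L], levels = treatments)
  n <- nrow(rows)
  # per-leaf jitter and cube seeds, drawn under the dataset seed
  jit <- params$sample_jitter
  j_amp <- stats::rnorm(n, 0, jit$green_amp)
  j_re <- stats::rnorm(n, 0, jit$rededge_nm)
  j_base <- stats::rnorm(n, 0, jit$baseline)
  j_scale <- exp(stats::rnorm(n, 0, jit$scale))
  cube_seeds <- sample.int(.Machine$integer.max - 1L, n)

  spectra <- matrix(0, n, params$n_bands)
  for (i in seq_len(n)) {
    g <- params$stage_gains[[rows$stage[i]]]
    lev <- rows$label[i]
    spectra[i, ] <- spectrum_components(
      wl = params$wavelengths,
      baseline = params$baseline + j_base[i],
      green_amp = params$green_peak_amp + j_amp[i] +
        lev * params$green_peak_gain_per_level * g[["green"]],
      green_center = params$green_peak_center,
      green_sigma = params$green_peak_sigma,
      rededge_pos = params$rededge_center + j_re[i] -
        lev * params$rededge_blueshift_per_level * g[["rededge"]],
      rededge_scale = params$rededge_scale,
      nir_level = params$nir_level,
      stage = rows$stage[i], stage_offset = params$stage_offset,
      scale = j_scale[i])
  }
  cubes <- NULL; masks <- NULL
  if (render) {
    rendered <- lapply(seq_len(n), function(i)
      render_cube(spectra[i, ], params, rng_seed = cube_seeds[i]))
    cubes <- lapply(rendered, `[[`, "cube")
    masks <- lapply(rendered, `[[`, "mask")
  }
  structure(list(cubes = cubes, truth_masks = masks, spectra = spectra,
                 labels = rows$label, treatments = rows$treatment,
                 stages = rows$stage, plant_ids = rows$plant_id,
                 replicate_idx = rows$replicate_idx,
                 wavelengths = params$wavelengths, params = params,
                 seed = as.integer(seed)),
            class = "leaf_dataset")
}

#' @export
print.leaf_dataset <- function(x, ...) {
  cat(sprintf("<leaf_dataset> %d leaves (%d pairs), %d bands%s\n",
              length(x$labels), sum(x$stages == "young"),
              length(x$wavelengths),
              if (is.null(x$cubes)) " [spectra only]" else ""))
  print(table(stage = x$stages, treatment = x$treatments))
  invisible(x)
}

#' Synthetic band-selection benchmark dataset
#'
#' A spectra-like matrix with a handful of informative bands among pure
#' noise, used to exercise wavelength selection. Each informative band
#' carries a distinct cyclic pattern of class means (separation `effect`
#' in units of the noise sd), so every informative band contributes
#' complementary class information.
#'
#' @param n_per_class samples per class (3 classes).
#' @param n_bands total number of bands.
#' @param informative indices of the informative bands.
#' @param effect class-mean separation per informative band.
#' @param noise_sd Gaussian noise sd.
#' @param seed integer seed.
#' @return list with `x` (matrix), `y` (factor), `informative`.
#' @export
make_band_dataset <- function(n_per_class = 50, n_bands = 100,
                              informative = c(10, 30, 50, 70, 90),
                              effect = 1.0, noise_sd = 1.0, seed = 1L) {
  stopifnot(all(informative >= 1), all(informative <= n_bands))
  set.seed(as.integer(seed))
  n <- 3L * n_per_class
  y <- factor(rep(0:2, each = n_per_class))
  x <- matrix(stats::rnorm(n * n_bands, sd = noise_sd), n, n_bands)
  patterns <- list(c(0, 1, 2), c(2, 0, 1), c(1, 2, 0), c(0, 2, 1), c(2, 1, 0))
  for (j in seq_along(informative)) {
    pat <- patterns[[(j - 1L) %% length(patterns) + 1L]]
    x[, informative[j]] <- x[, informative[j]] +
      effect * pat[as.integer(y)]
  }
  list(x = x, y = y, informative = sort(informative))
}
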