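test_that("base spectrum responds to stress as drought physiology dictates", {
  p <- tiny_params()
  b560 <- band_nearest(p$wavelengths, 560)
  for (stage in c("young", "mature")) {
    specs <- lapply(0:2, base_spectrum, stage = stage, params = p)
    peak <- vapply(specs, `[[`, numeric(1), b560)
    expect_true(all(diff(peak) > 0))      # 560 nm reflectance rises with stress
    re <- vapply(specs, rededge_position, numeric(1),
                 wavelengths = p$wavelengths)
    expect_true(all(diff(re) <= 0))       # red edge blue-shifts with stress
  }
  expect_error(base_spectrum(3, "young", p), "level")
})

test_that("zero effect gains collapse all stress levels onto one spectrum", {
  p <- tiny_params(green_peak_gain_per_level = 0,
                   rededge_blueshift_per_level = 0)
  s <- lapply(0:2, base_spectrum, stage = "young", params = p)
  expect_identical(s[[1]], s[[2]])
  expect_identical(s[[2]], s[[3]])
})

test_that("red-edge blue shift matches the configured per-level distance", {
  # equal stage gains so the shift is exactly level * configured nm
  p <- sim_params(n_bands = 272, frame_size = c(24, 24),
                  leaf_shape = c(14, 8),
                  rededge_blueshift_per_level = 8,
                  stage_gains = list(young = c(green = 1, rededge = 1),
                                     mature = c(green = 1, rededge = 1)))
  spacing <- diff(p$wavelengths)[1]
  r0 <- rededge_position(base_spectrum(0, "young", p), p$wavelengths)
  r2 <- rededge_position(base_spectrum(2, "young", p), p$wavelengths)
  expect_lt(abs((r0 - r2) - 2 * 8), spacing)
})

test_that("rendered cubes carry the spectrum exactly when noiseless", {
  p <- tiny_params(pixel_noise_sd = 0)
  s <- base_spectrum(1, "young", p)
  rc <- render_cube(s, p, rng_seed = 3)
  pix <- which(as.vector(rc$mask))
  m <- matrix(rc$cube$data, prod(p$frame_size), p$n_bands)
  for (i in pix[c(1, length(pix) %/% 2, length(pix))])
    expect_equal(m[i, ], s, tolerance = 0)
  # background stays low in the NIR
  bg <- m[-pix, band_nearest(p$wavelengths, 900)]
  expect_true(all(bg < 0.05))
})

test_that("in-mask mean recovers the spectrum within the standard error", {
  p <- tiny_params(pixel_noise_sd = 0.02)
  s <- base_spectrum(2, "mature", p)
  rc <- render_cube(s, p, rng_seed = 9)
  n_pix <- sum(rc$mask)
  mu <- mean_spectrum(rc$cube, rc$mask)
  expect_true(all(abs(mu - s) <= 3 * p$pixel_noise_sd / sqrt(n_pix) + 1e-12))
})

test_that("rendering is bit-identical under the same seed", {
  p <- tiny_params()
  s <- base_spectrum(0, "young", p)
  expect_identical(render_cube(s, p, rng_seed = 5),
                   render_cube(s, p, rng_seed = 5))
  expect_false(identical(render_cube(s, p, rng_seed = 5)$cube$data,
                         render_cube(s, p, rng_seed = 6)$cube$data))
})

test_that("oversized leaf ellipse is rejected", {
  p <- tiny_params()
  p$leaf_shape <- c(40, 8)
  expect_error(render_cube(base_spectrum(0, "young", p), p, 1), "ellipse")
})

test_that("reference frames invert the calibration identity", {
  p <- tiny_params()
  refs <- make_reference_frames(p)
  expect_true(all(refs$white > refs$dark))
  s <- base_spectrum(1, "young", p)
  rc <- render_cube(s, p, rng_seed = 2)
  raw <- synthesize_raw(rc$cube, refs)
  cal <- calibrate(raw, refs)
  expect_equal(cal$data, rc$cube$data, tolerance = 1e-12)
  # ripple 0 -> spatially constant frames
  flat <- make_reference_frames(p, ripple = 0)
  expect_equal(max(apply(flat$white, 2, stats::sd)), 0)
  # degenerate white = dark rejected
  expect_error(reference_pair(matrix(1, 2, 2), matrix(1, 2, 2)),
               "white <= dark")
})

test_that("dataset generation honours the study design and pairing", {
  p <- sim_params(n_bands = 24, frame_size = c(16, 16), leaf_shape = c(10, 6))
  ds <- generate_dataset(c(108, 105, 102), p, seed = 4)
  expect_length(ds$cubes, 630)
  expect_equal(as.vector(table(ds$treatments[ds$stages == "young"])),
               c(108, 105, 102))
  # pairing totality: every (plant, replicate) once per stage
  ky <- paste(ds$plant_ids, ds$replicate_idx)[ds$stages == "young"]
  km <- paste(ds$plant_ids, ds$replicate_idx)[ds$stages == "mature"]
  expect_false(anyDuplicated(ky) > 0)
  expect_setequal(ky, km)

  ds2 <- generate_dataset(c(2, 2, 2), p, seed = 4)
  expect_length(ds2$cubes, 12)
  expect_equal(sum(ds2$stages == "young"), 6)

  # reproducibility of the full dataset
  ds3 <- generate_dataset(c(2, 2, 2), p, seed = 4)
  expect_identical(ds2$spectra, ds3$spectra)
  expect_identical(ds2$cubes[[5]]$data, ds3$cubes[[5]]$data)
})

test_that("class-mean noiseless spectra are strictly ordered at 560 nm", {
  p <- tiny_params()
  ds <- generate_dataset(c(4, 4, 4), p, seed = 7, render = FALSE)
  b560 <- band_nearest(p$wavelengths, 560)
  for (stage in c("young", "mature")) {
    base <- vapply(0:2, function(l)
      base_spectrum(l, stage, p)[b560], numeric(1))
    expect_true(all(diff(base) > 0))
  }
})
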