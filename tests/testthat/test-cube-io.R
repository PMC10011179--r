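make_cube <- function(seed = 1, bands = 7, hw = c(6, 5)) {
  set.seed(seed)
  hypercube(array(runif(prod(hw) * bands), c(hw, bands)),
            seq(400, 1000, length.out = bands))
}

test_that("ENVI write/read round-trips exactly at the chosen dtype", {
  cube <- make_cube()
  tf <- file.path(tempdir(), "rt_f64")
  write_envi(cube, tf, data_type = 5)
  back <- read_envi(tf)
  expect_identical(back$data, cube$data)
  expect_identical(back$wavelengths, cube$wavelengths)
  # float32: one write/read quantizes, a second round trip is bit-exact
  tf4 <- file.path(tempdir(), "rt_f32")
  write_envi(cube, tf4, data_type = 4)
  once <- read_envi(tf4)
  write_envi(once, tf4, data_type = 4)
  expect_identical(read_envi(tf4)$data, once$data)
  expect_equal(once$data, cube$data, tolerance = 1e-6)
})

test_that("all interleaves load to the same logical array", {
  cube <- make_cube(seed = 2)
  arrs <- lapply(c("bil", "bip", "bsq"), function(il) {
    tf <- file.path(tempdir(), paste0("il_", il))
    write_envi(cube, tf, interleave = il, data_type = 5)
    read_envi(tf)$data
  })
  expect_identical(arrs[[1]], arrs[[2]])
  expect_identical(arrs[[2]], arrs[[3]])
  expect_identical(arrs[[1]], cube$data)
})

test_that("header inconsistencies raise format errors naming the field", {
  cube <- make_cube(seed = 3)
  tf <- file.path(tempdir(), "badhdr")
  write_envi(cube, tf, data_type = 5)
  hdr <- readLines(paste0(tf, ".hdr"))
  # wavelength count mismatch
  writeLines(sub("^bands = 7", "bands = 8", hdr), paste0(tf, ".hdr"))
  expect_error(read_envi(tf), "wavelength")
  # missing wavelength list
  writeLines(hdr[!grepl("^wavelength =", hdr)], paste0(tf, ".hdr"))
  expect_error(read_envi(tf), "'wavelength' missing")
})

test_that("calibration matches the elementwise correction formula", {
  set.seed(42)
  d <- c(5, 4, 6)
  dark <- matrix(runif(d[2] * d[3], 10, 20), d[2], d[3])
  white <- dark + matrix(runif(d[2] * d[3], 100, 200), d[2], d[3])
  refl <- array(runif(prod(d)), d)           # ground truth in [0, 1]
  raw_arr <- array(0, d)
  for (b in seq_len(d[3])) for (j in seq_len(d[2]))
    raw_arr[, j, b] <- dark[j, b] + refl[, j, b] * (white[j, b] - dark[j, b])
  raw <- hypercube(raw_arr, seq_len(d[3]))
  cal <- calibrate(raw, reference_pair(white, dark))
  # independent recomputation, straight from the formula
  expected <- array(0, d)
  for (b in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1]))
    expected[i, j, b] <- (raw_arr[i, j, b] - dark[j, b]) /
      (white[j, b] - dark[j, b])
  expect_lt(max(abs(cal$data - expected)), 1e-7)
})

test_that("calibration identities hold exactly", {
  d <- c(3, 4, 2)
  dark <- matrix(1, d[2], d[3]); white <- matrix(9, d[2], d[3])
  refs <- reference_pair(white, dark)
  wl <- c(500, 600)
  expect_equal(calibrate(hypercube(array(9, d), wl), refs)$data,
               array(1, d))
  expect_equal(calibrate(hypercube(array(1, d), wl), refs)$data,
               array(0, d))
  expect_equal(calibrate(hypercube(array(5, d), wl), refs)$data[1, 1, 1],
               0.5)
})

test_that("calibration is affine-invariant and monotone in the raw counts", {
  set.seed(5)
  d <- c(4, 3, 5)
  dark <- matrix(runif(15, 5, 10), 3, 5)
  white <- dark + matrix(runif(15, 50, 80), 3, 5)
  raw <- array(runif(prod(d), 10, 60), d)
  wl <- seq_len(d[3])
  c1 <- calibrate(hypercube(raw, wl), reference_pair(white, dark))
  c2 <- calibrate(hypercube(raw * 7, wl), reference_pair(white * 7, dark * 7))
  expect_equal(c1$data, c2$data, tolerance = 1e-12)
  c3 <- calibrate(hypercube(raw + 1, wl), reference_pair(white, dark))
  expect_true(all(c3$data >= c1$data))
})

test_that("white = dark at any pixel-band aborts with its coordinate", {
  white <- matrix(c(10, 10, 10, 5), 2, 2)
  dark <- matrix(5, 2, 2)
  refs <- structure(list(white = white, dark = dark),
                    class = "reference_pair")   # bypass constructor check
  raw <- hypercube(array(7, c(2, 2, 2)), c(500, 600))
  expect_error(calibrate(raw, refs), "sample 2, band 2")
})
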