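test_that("band-image correlation reproduces hand-computed values", {
  # cube whose two bands are x=(0,1,2,3), y=(1,0,3,2) over a 4-pixel mask
  arr <- array(0, c(2, 2, 3))
  arr[, , 1] <- matrix(c(0, 1, 2, 3), 2, 2)
  arr[, , 2] <- matrix(c(1, 0, 3, 2), 2, 2)
  arr[, , 3] <- -matrix(c(0, 1, 2, 3), 2, 2)     # negation about the mean
  cube <- hypercube(arr, c(500, 600, 700))
  mask <- matrix(TRUE, 2, 2)
  cm <- image_correlation(cube, mask, 1:3)
  expect_equal(diag(cm$r), rep(1, 3))
  expect_equal(cm$r[1, 2], 0.6)                  # covariance arithmetic
  expect_equal(cm$r[1, 3], -1)
  expect_equal(cm$r, t(cm$r), tolerance = 1e-12)
})

test_that("zero-variance band images are flagged and zeroed", {
  arr <- array(0, c(2, 2, 2))
  arr[, , 1] <- matrix(1:4, 2, 2)
  arr[, , 2] <- 0.5                              # flat image
  cube <- hypercube(arr, c(500, 600))
  cm <- image_correlation(cube, matrix(TRUE, 2, 2), 1:2)
  expect_equal(cm$r[1, 2], 0)
  expect_equal(cm$qc$zero_variance, 2L)
})

test_that("container scan matches hand simulation on fixed matrices", {
  # all admissible: identity correlations over 6 EWs, reference = 2
  r0 <- diag(6)
  gc0 <- greedy_container(r0, 2)
  expect_equal(gc0$member_idx, c(1, 3, 4, 5))    # first four in scan order
  # none admissible
  r1 <- matrix(0.9, 6, 6); diag(r1) <- 1
  expect_length(greedy_container(r1, 3)$member_idx, 0)
  # mixed 6x6: indices 1 and 4 pass against the reference (2), but 4
  # fails against 1 once 1 is inside
  r2 <- diag(6)
  r2[1, 2] <- r2[2, 1] <- 0.1
  r2[4, 2] <- r2[2, 4] <- 0.2
  r2[4, 1] <- r2[1, 4] <- 0.8
  r2[3, 2] <- r2[2, 3] <- 0.9
  r2[5, 2] <- r2[2, 5] <- 0.25
  r2[5, 1] <- r2[1, 5] <- 0.05
  r2[6, 2] <- r2[2, 6] <- 0.9
  gc2 <- greedy_container(r2, 2)
  expect_equal(sort(gc2$member_idx), sort(oracle_container(r2, 2)))
  expect_equal(gc2$member_idx, oracle_container(r2, 2))
  expect_false(4 %in% gc2$member_idx)
  # randomized 8x8 suites against the oracle
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(runif(64, -1, 1), 8); m <- (m + t(m)) / 2; diag(m) <- 1
    ref <- sample(8, 1)
    got <- greedy_container(m, ref)
    expect_equal(got$member_idx, oracle_container(m, ref))
    # admitted members pairwise weakly correlated
    mem <- c(ref, got$member_idx)
    off <- abs(m[mem, mem])[upper.tri(diag(length(mem)))]
    expect_true(all(off <= 0.3 + 1e-12))
  }
})

test_that("container output depends only on the matrix and scan order", {
  set.seed(4)
  m <- matrix(runif(36, -0.5, 0.5), 6); m <- (m + t(m)) / 2; diag(m) <- 1
  plain <- greedy_container(m, 2)
  labelled <- greedy_container(
    structure(list(r = m, wavelengths = c(501, 577, 613, 680, 733, 801)),
              class = "corr_matrix"), 2)
  expect_equal(plain$member_idx, labelled$member_idx)
})

test_that("superposition search maximizes accuracy with ties to smaller k", {
  accs <- c(0.8, 0.9, 0.9)
  got <- superposition_search(c(5, 2, 9), function(k) accs[k])
  expect_equal(got$k_selected, 2)
  expect_equal(got$indices, c(5, 2))
  expect_equal(got$accuracies, accs)
  one <- superposition_search(7, function(k) 0.5)
  expect_equal(one$k_selected, 1)
  expect_error(superposition_search(c(1, 2), function(k)
    if (k == 2) stop("boom") else 0.5), "k = 2")
})

test_that("superposition search finds signal carried by a later channel", {
  # channel 2 carries the only class signal; spectra are pure noise
  hits <- 0
  for (seed in 1:5) {
    set.seed(seed)
    y <- factor(rep(0:2, each = 8))
    n <- length(y)
    stacks <- array(rnorm(n * 16 * 16 * 3, sd = 0.05), c(n, 16, 16, 3))
    for (i in seq_len(n))
      stacks[i, , , 2] <- stacks[i, , , 2] + as.integer(y[i]) * 0.4
    spectra <- matrix(rnorm(n * 4), n, 4)
    ev <- ris_superposition_evaluator(stacks, spectra, y,
                                      lenet_config(input_hw = c(16, 16)),
                                      epochs = 15, folds = 3, seed = seed)
    got <- superposition_search(1:3, ev)
    hits <- hits + (got$k_selected >= 2)
  }
  expect_gte(hits, 4)
})
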