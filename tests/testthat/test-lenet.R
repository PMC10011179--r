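test_that("training loss decreases to a fit on a trivially separable fixture", {
  px <- painted_stacks(n_per_class = 10, channels = 1, seed = 2)
  net <- train_lenet(px$stacks, px$y,
                     lenet_config(input_hw = c(16, 16)), epochs = 50,
                     seed = 3)
  expect_lt(net$loss[50], net$loss[1])
  # monitored run: transient upticks stay within optimizer tolerance
  expect_true(all(diff(net$loss) <= 0.05))
  expect_equal(mean(predict(net, px$stacks) == px$y), 1.0)
})

test_that("training is bit-deterministic given the seed", {
  px <- painted_stacks(n_per_class = 5, seed = 4)
  cfg <- lenet_config(input_hw = c(16, 16))
  n1 <- train_lenet(px$stacks, px$y, cfg, epochs = 5, seed = 11)
  n2 <- train_lenet(px$stacks, px$y, cfg, epochs = 5, seed = 11)
  expect_identical(n1$params, n2$params)
  n3 <- train_lenet(px$stacks, px$y, cfg, epochs = 5, seed = 12)
  expect_false(identical(n1$params, n3$params))
})

test_that("feature tap returns the 84-unit pre-activation block", {
  px <- painted_stacks(n_per_class = 4, channels = 2, seed = 5)
  net <- train_lenet(px$stacks, px$y,
                     lenet_config(input_hw = c(16, 16), in_channels = 2),
                     epochs = 3, seed = 1)
  f <- extract_features(net, px$stacks)
  expect_equal(dim(f), c(12, 84))
  expect_true(all(is.finite(f)))
  # identical stacks give identical features
  twice <- px$stacks[c(1, 1), , , , drop = FALSE]
  f2 <- extract_features(net, twice)
  expect_identical(f2[1, ], f2[2, ])
  # geometry mismatch is an error
  expect_error(extract_features(net, px$stacks[, 1:8, , , drop = FALSE]),
               "does not match")
})

test_that("an all-zero stack propagates to the tapped layer's bias", {
  cfg <- lenet_config(input_hw = c(16, 16), in_channels = 1)
  px <- painted_stacks(n_per_class = 2, seed = 6)
  net <- train_lenet(px$stacks, px$y, cfg, epochs = 1, seed = 1)
  # zero out all biases upstream of the tap; set a recognizable fc2 bias
  net$params$b1[] <- 0; net$params$b2[] <- 0; net$params$b3[] <- 0
  net$params$b4 <- seq_len(84) / 100
  zero <- array(0, c(1, 16, 16, 1))
  expect_equal(as.vector(extract_features(net, zero)), seq_len(84) / 100)
})

test_that("DenseNet-1D forward pass has the contracted shape and softmax rows", {
  set.seed(8)
  x <- matrix(rnorm(9 * 30), 9)
  y <- factor(rep(0:2, 3))
  dn <- train_densenet1d_net(x, y, densenet1d_config(), epochs = 2, seed = 2)
  p <- predict(dn, x, type = "prob")
  expect_equal(dim(p), c(9, 3))
  expect_equal(rowSums(p), rep(1, 9), tolerance = 1e-12)
  # dense-block channel arithmetic: layer l input = init + (l-1) * growth
  cfg <- dn$cfg
  for (l in seq_len(cfg$layers_in_block))
    expect_equal(nrow(dn$params[[paste0("W", l)]]),
                 cfg$kernel * (cfg$init_channels + (l - 1) * cfg$growth_rate))
  # determinism
  dn2 <- train_densenet1d_net(x, y, densenet1d_config(), epochs = 2, seed = 2)
  expect_identical(dn$params, dn2$params)
})

test_that("analytic gradients match finite differences for both networks", {
  # LeNet on a small config
  cfg <- hsidrought:::lenet_config(input_hw = c(16, 16), in_channels = 2,
                                   conv_maps = c(3, 4), fc = c(10, 7))
  set.seed(2)
  x <- array(rnorm(4 * 16 * 16 * 2), c(4, 16, 16, 2)); y <- c(1, 2, 3, 1)
  idx1 <- hsidrought:::make_im2col_idx2d(16, 16, 2, 5)
  p1d <- hsidrought:::lenet_dims(cfg)$pool1
  idx2 <- hsidrought:::make_im2col_idx2d(p1d[1], p1d[2], 3, 5)
  params <- hsidrought:::lenet_init(cfg, 1)
  loss_of <- function(pp) {
    fw <- hsidrought:::lenet_forward(pp, cfg, x, idx1, idx2)
    hsidrought:::softmax_ce(fw$z5, y)$loss
  }
  fw <- hsidrought:::lenet_forward(params, cfg, x, idx1, idx2, keep = TRUE)
  ce <- hsidrought:::softmax_ce(fw$z5, y)
  g <- hsidrought:::lenet_backward(params, cfg, fw, ce$dlogits, idx1, idx2)
  h <- 1e-5
  for (nm in names(params)) for (r in 1:2) {
    i <- sample(length(params[[nm]]), 1)
    pe <- params
    pe[[nm]][i] <- pe[[nm]][i] + h; up <- loss_of(pe)
    pe[[nm]][i] <- pe[[nm]][i] - 2 * h; dn <- loss_of(pe)
    num <- (up - dn) / (2 * h)
    expect_lt(abs(g[[nm]][i] - num), 1e-4 * max(1, abs(num)))
  }
  # DenseNet-1D
  dcfg <- densenet1d_config(layers_in_block = 3, growth_rate = 4,
                            init_channels = 5)
  xL <- matrix(rnorm(5 * 15), 5); yd <- c(1, 2, 3, 2, 1)
  dpar <- hsidrought:::densenet1d_init(dcfg, 15, 1)
  didx <- hsidrought:::densenet1d_idx(dcfg, 15)
  dloss <- function(pp) {
    fw <- hsidrought:::densenet1d_forward(pp, dcfg, xL, didx)
    hsidrought:::softmax_ce(fw$logits, yd)$loss
  }
  fwd <- hsidrought:::densenet1d_forward(dpar, dcfg, xL, didx, keep = TRUE)
  ced <- hsidrought:::softmax_ce(fwd$logits, yd)
  gd <- hsidrought:::densenet1d_backward(dpar, dcfg, xL, fwd, ced$dlogits)
  for (nm in names(dpar)) for (r in 1:2) {
    i <- sample(length(dpar[[nm]]), 1)
    pe <- dpar
    pe[[nm]][i] <- pe[[nm]][i] + h; up <- dloss(pe)
    pe[[nm]][i] <- pe[[nm]][i] - 2 * h; dn <- dloss(pe)
    num <- (up - dn) / (2 * h)
    expect_lt(abs(gd[[nm]][i] - num), 1e-4 * max(1, abs(num)))
  }
})
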