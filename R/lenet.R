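#' LeNet-5 configuration
#'
#' The classical LeNet-5 layout used as the image-feature extractor: two
#' 5x5 convolution layers (6 then 16 maps), two 2x2 average-pooling
#' layers, two fully connected layers (120 and 84 units) and a 3-class
#' output layer. Features are tapped before the activation: by default the
#' 84-unit second fully connected layer's pre-activation output
#' (`"fc2_preactivation"`); `"output_preactivation"` taps the 3-unit
#' output logits instead.
#'
#' @param input_hw input image size `c(H, W)`; both spatial reductions
#'   (conv 5x5 then 2x2 pool, twice) must land on integer sizes.
#' @param in_channels number of image channels (the RIS stack depth).
#' @param conv_maps feature maps of the two convolution layers.
#' @param kernel convolution kernel size.
#' @param fc widths of the two fully connected layers.
#' @param n_classes number of output classes.
#' @param feature_tap `"fc2_preactivation"` (84-d) or
#'   `"output_preactivation"`.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @return list of class `lenet_config`.
#' @export
lenet_config <- function(input_hw = c(32L, 32L), in_channels = 1L,
                         conv_maps = c(6L, 16L), kernel = 5L,
                         fc = c(120L, 84L), n_classes = 3L,
                         feature_tap = c("fc2_preactivation",
                                         "output_preactivation"),
                         lr = 5e-3, batch_size = 16L) {
  feature_tap <- match.arg(feature_tap)
  structure(list(input_hw = as.integer(input_hw),
                 in_channels = as.integer(in_channels),
                 conv_maps = as.integer(conv_maps), kernel = as.integer(kernel),
                 fc = as.integer(fc), n_classes = as.integer(n_classes),
                 feature_tap = feature_tap, lr = lr,
                 batch_size = as.integer(batch_size)),
            class = "lenet_config")
}

lenet_dims <- function(cfg) {
  k <- cfg$kernel
  h1 <- cfg$input_hw - (k - 1L)
  if (any(h1 < 2L) || any(h1 %% 2L != 0L))
    stop("input_hw incompatible with conv/pool geometry (first stage)")
  p1 <- h1 %/% 2L
  h2 <- p1 - (k - 1L)
  if (any(h2 < 2L) || any(h2 %% 2L != 0L))
    stop("input_hw incompatible with conv/pool geometry (second stage)")
  p2 <- h2 %/% 2L
  list(conv1 = h1, pool1 = p1, conv2 = h2, pool2 = p2,
       flat = prod(p2) * cfg$conv_maps[2])
}

lenet_init <- function(cfg, seed) {
  d <- lenet_dims(cfg)
  k2 <- cfg$kernel^2
  with_preserved_rng(seed, {
    params <- list(
      W1 = he_init(k2 * cfg$in_channels, cfg$conv_maps[1],
                   k2 * cfg$in_channels),
      b1 = numeric(cfg$conv_maps[1]),
      W2 = he_init(k2 * cfg$conv_maps[1], cfg$conv_maps[2],
                   k2 * cfg$conv_maps[1]),
      b2 = numeric(cfg$conv_maps[2]),
      W3 = he_init(d$flat, cfg$fc[1], d$flat),
      b3 = numeric(cfg$fc[1]),
      W4 = he_init(cfg$fc[1], cfg$fc[2], cfg$fc[1]),
      b4 = numeric(cfg$fc[2]),
      W5 = he_init(cfg$fc[2], cfg$n_classes, cfg$fc[2]),
      b5 = numeric(cfg$n_classes))
  })
  params
}

# full forward pass; caches kept only when training
lenet_forward <- function(params, cfg, x, idx1, idx2, keep = FALSE) {
  n <- dim(x)[1]
  d <- lenet_dims(cfg)
  c1 <- conv2d_forward(x, params$W1, params$b1, idx1)
  a1 <- relu(c1$out)
  p1 <- avgpool2(a1)
  c2 <- conv2d_forward(p1, params$W2, params$b2, idx2)
  a2 <- relu(c2$out)
  p2 <- avgpool2(a2)
  flat <- matrix(aperm(p2, c(2, 3, 4, 1)), nrow = prod(dim(p2)[2:4]), ncol = n)
  flat <- t(flat)
  z3 <- sweep(flat %*% params$W3, 2, params$b3, "+"); a3 <- relu(z3)
  z4 <- sweep(a3 %*% params$W4, 2, params$b4, "+"); a4 <- relu(z4)
  z5 <- sweep(a4 %*% params$W5, 2, params$b5, "+")
  out <- list(z4 = z4, z5 = z5)
  if (keep)
    out <- c(out, list(x = x, c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2,
                       p2 = p2, flat = flat, z3 = z3, a3 = a3, a4 = a4))
  out
}

lenet_backward <- function(params, cfg, fw, dz5, idx1, idx2) {
  g <- list()
  g$W5 <- crossprod(fw$a4, dz5); g$b5 <- colSums(dz5)
  da4 <- dz5 %*% t(params$W5)
  dz4 <- da4 * (fw$z4 > 0)
  g$W4 <- crossprod(fw$a3, dz4); g$b4 <- colSums(dz4)
  da3 <- dz4 %*% t(params$W4)
  dz3 <- da3 * (fw$z3 > 0)
  g$W3 <- crossprod(fw$flat, dz3); g$b3 <- colSums(dz3)
  dflat <- dz3 %*% t(params$W3)
  dp2 <- aperm(array(t(dflat), c(dim(fw$p2)[2:4], nrow(dflat))), c(4, 1, 2, 3))
  da2 <- avgpool2_backward(dp2)
  dz2 <- da2 * (fw$c2$out > 0)
  in2 <- c(dim(fw$p1)[2:3], dim(fw$p1)[4])
  b2 <- conv2d_backward(dz2, fw$c2$cols, params$W2, idx2, in2)
  g$W2 <- b2$dW; g$b2 <- b2$db
  da1 <- avgpool2_backward(b2$dx)
  dz1 <- da1 * (fw$c1$out > 0)
  b1 <- conv2d_backward(dz1, fw$c1$cols, params$W1, idx1,
                        c(cfg$input_hw, cfg$in_channels))
  g$W1 <- b1$dW; g$b1 <- b1$db
  g
}

#' Train a LeNet-5 image-feature extractor
#'
#' Trains the network as a 3-class drought-stress classifier on
#' calibration image stacks with Adam and softmax cross-entropy, then
#' freezes it for feature extraction. Deterministic given `seed`.
#'
#' @param stacks image array `(n, H, W, C)` as built by
#'   [make_ris_stack()]/[build_stacks()].
#' @param labels class labels (coerced to factor; >= 2 classes required).
#' @param cfg a [lenet_config()]; `input_hw`/`in_channels` must match
#'   `stacks`.
#' @param epochs training epochs.
#' @param seed integer seed (weight init and batch shuffling).
#' @return object of class `lenet`: parameters, config, class `levels`,
#'   per-epoch mean `loss` trace.
#' @export
train_lenet <- function(stacks, labels, cfg = lenet_config(), epochs = 50L,
                        seed = 1L) {
  y <- as.factor(labels)
  if (nlevels(y) < 2L) stop("need at least 2 classes to train")
  stopifnot(length(dim(stacks)) == 4L, dim(stacks)[1] == length(y))
  cfg$input_hw <- dim(stacks)[2:3]
  cfg$in_channels <- dim(stacks)[4]
  cfg$n_classes <- max(cfg$n_classes, nlevels(y))
  yi <- as.integer(y)
  n <- dim(stacks)[1]
  idx1 <- make_im2col_idx2d(cfg$input_hw[1], cfg$input_hw[2],
                            cfg$in_channels, cfg$kernel)
  dpool1 <- lenet_dims(cfg)$pool1
  idx2 <- make_im2col_idx2d(dpool1[1], dpool1[2], cfg$conv_maps[1],
                            cfg$kernel)
  params <- lenet_init(cfg, seed)
  state <- adam_init(params)
  loss_trace <- numeric(epochs)
  with_preserved_rng(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        fw <- lenet_forward(params, cfg, stacks[bi, , , , drop = FALSE],
                            idx1, idx2, keep = TRUE)
        ce <- softmax_ce(fw$z5, yi[bi])
        if (!is.finite(ce$loss)) stop("training error: non-finite loss")
        losses <- c(losses, ce$loss)
        g <- lenet_backward(params, cfg, fw, ce$dlogits, idx1, idx2)
        upd <- adam_step(params, g, state, lr = cfg$lr)
        params <- upd$params; state <- upd$state
      }
      loss_trace[ep] <- mean(losses)
    }
  })
  structure(list(params = params, cfg = cfg, levels = levels(y),
                 loss = loss_trace, idx1 = idx1, idx2 = idx2, seed = seed),
            class = "lenet")
}

#' Extract CNN image features from stacks
#'
#' Pre-activation outputs of the tapped layer of a trained LeNet-5
#' (default: the 84-unit second fully connected layer), i.e. the image
#' features taken "without the activation function".
#'
#' @param extractor a trained [train_lenet()] model.
#' @param stacks image array `(n, H, W, C)` matching the training geometry.
#' @return numeric matrix `n x 84` (or `n x n_classes` under the output
#'   tap).
#' @export
extract_features <- function(extractor, stacks) {
  stopifnot(inherits(extractor, "lenet"))
  cfg <- extractor$cfg
  if (!all(dim(stacks)[2:3] == cfg$input_hw) ||
      dim(stacks)[4] != cfg$in_channels)
    stop(sprintf("stack shape %s does not match extractor input %s x %d",
                 paste(dim(stacks)[-1], collapse = "x"),
                 paste(cfg$input_hw, collapse = "x"), cfg$in_channels))
  fw <- lenet_forward(extractor$params, cfg, stacks, extractor$idx1,
                      extractor$idx2)
  if (cfg$feature_tap == "fc2_preactivation") fw$z4 else fw$z5
}

#' Save / load a trained LeNet-5 extractor
#'
#' Writes the weights as one binary artifact (RDS) with a JSON sidecar
#' (`<path>.json`) describing the architecture and training seed.
#'
#' @param extractor a trained [train_lenet()] model.
#' @param path artifact path (sidecar gets `.json` appended).
#' @return `path` (save) or the restored `lenet` object (load).
#' @export
save_lenet <- function(extractor, path) {
  stopifnot(inherits(extractor, "lenet"))
  saveRDS(extractor, path)
  jsonlite::write_json(
    list(input_hw = extractor$cfg$input_hw,
         in_channels = extractor$cfg$in_channels,
         conv_maps = extractor$cfg$conv_maps, fc = extractor$cfg$fc,
         n_classes = extractor$cfg$n_classes,
         feature_tap = extractor$cfg$feature_tap,
         levels = extractor$levels, seed = extractor$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_lenet
#' @export
load_lenet <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "lenet")) stop("not a saved LeNet extractor")
  obj
}

#' @export
predict.lenet <- function(object, stacks, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  fw <- lenet_forward(object$params, object$cfg, stacks, object$idx1,
                      object$idx2)
  p <- softmax_rows(fw$z5[, seq_along(object$levels), drop = FALSE])
  colnames(p) <- object$levels
  if (type == "prob") p
  else factor(object$levels[max.col(p, ties.method = "first")],
              levels = object$levels)
}
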