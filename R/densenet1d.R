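#' One-dimensional DenseNet configuration
#'
#' A compact densely connected convolutional classifier for 1-D feature
#' vectors (spectra, spectroscopy-image combinations, fused vectors). A
#' stem convolution lifts the input signal to `init_channels`; a single
#' dense block follows, in which layer l receives the concatenation of the
#' stem output and all previous layer outputs (input channels
#' `init_channels + (l-1) * growth_rate`) and contributes `growth_rate`
#' new channels. Global average pooling and a linear layer produce the
#' class logits.
#'
#' @param layers_in_block convolution layers inside the dense block.
#' @param growth_rate channels added by each dense layer.
#' @param kernel convolution kernel size (odd; same padding).
#' @param init_channels channels produced by the stem convolution.
#' @param n_classes output classes.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs default training epochs.
#' @return list of class `densenet1d_config`.
#' @export
densenet1d_config <- function(layers_in_block = 4L, growth_rate = 12L,
                              kernel = 3L, init_channels = 16L,
                              n_classes = 3L, lr = 1e-2, batch_size = 16L,
                              epochs = 100L) {
  stopifnot(kernel %% 2L == 1L, layers_in_block >= 1L, growth_rate >= 1L)
  structure(list(layers_in_block = as.integer(layers_in_block),
                 growth_rate = as.integer(growth_rate),
                 kernel = as.integer(kernel),
                 init_channels = as.integer(init_channels),
                 n_classes = as.integer(n_classes), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs)),
            class = "densenet1d_config")
}

densenet1d_init <- function(cfg, L, seed) {
  k <- cfg$kernel
  with_preserved_rng(seed, {
    params <- list(Ws = he_init(k, cfg$init_channels, k),
                   bs = numeric(cfg$init_channels))
    for (l in seq_len(cfg$layers_in_block)) {
      cin <- cfg$init_channels + (l - 1L) * cfg$growth_rate
      params[[paste0("W", l)]] <- he_init(k * cin, cfg$growth_rate, k * cin)
      params[[paste0("b", l)]] <- numeric(cfg$growth_rate)
    }
    ctot <- cfg$init_channels + cfg$layers_in_block * cfg$growth_rate
    params$Wd <- he_init(ctot, cfg$n_classes, ctot)
    params$bd <- numeric(cfg$n_classes)
  })
  params
}

# index tables depend only on the signal length; built once per model
densenet1d_idx <- function(cfg, L) {
  layers <- lapply(seq_len(cfg$layers_in_block), function(l)
    make_im2col_idx1d(L, cfg$init_channels + (l - 1L) * cfg$growth_rate,
                      cfg$kernel))
  list(stem = make_im2col_idx1d(L, 1L, cfg$kernel), layers = layers)
}

densenet1d_forward <- function(params, cfg, x, idx, keep = FALSE) {
  # x: (N, L) matrix -> (N, L, 1) signal
  n <- nrow(x); L <- ncol(x)
  xs <- array(x, c(n, L, 1L))
  stem <- conv1d_forward(xs, params$Ws, params$bs, idx$stem)
  cat_x <- stem$out
  caches <- list(stem = stem, idx_s = idx$stem, layers = list())
  for (l in seq_len(cfg$layers_in_block)) {
    cin <- dim(cat_x)[3]
    idx_l <- idx$layers[[l]]
    h <- relu(cat_x)
    cv <- conv1d_forward(h, params[[paste0("W", l)]],
                         params[[paste0("b", l)]], idx_l)
    caches$layers[[l]] <- list(idx = idx_l, cols = cv$cols, pre = cat_x,
                               z = cv$out)
    cat_x <- array(c(cat_x, cv$out), c(n, L, cin + cfg$growth_rate))
  }
  h_out <- relu(cat_x)
  gap <- apply(h_out, c(1, 3), mean)                 # (N, C_tot)
  logits <- sweep(gap %*% params$Wd, 2, params$bd, "+")
  out <- list(logits = logits, gap = gap, cat_final = cat_x)
  if (keep) out$caches <- caches
  out
}

densenet1d_backward <- function(params, cfg, x, fw, dlogits) {
  n <- nrow(x); L <- ncol(x)
  g <- list()
  g$Wd <- crossprod(fw$gap, dlogits); g$bd <- colSums(dlogits)
  dgap <- dlogits %*% t(params$Wd)                   # (N, C_tot)
  ctot <- ncol(dgap)
  dh <- aperm(array(t(dgap) / L, c(ctot, n, L)), c(2, 3, 1))
  dcat <- dh * (fw$cat_final > 0)
  for (l in rev(seq_len(cfg$layers_in_block))) {
    cache <- fw$caches$layers[[l]]
    cin <- dim(cache$pre)[3]
    dz <- dcat[, , cin + seq_len(cfg$growth_rate), drop = FALSE]
    bk <- conv1d_backward(dz, cache$cols, params[[paste0("W", l)]],
                          cache$idx, c(L, cin))
    g[[paste0("W", l)]] <- bk$dW; g[[paste0("b", l)]] <- bk$db
    dcat <- dcat[, , seq_len(cin), drop = FALSE] +
      bk$dx * (cache$pre > 0)
  }
  bs <- conv1d_backward(dcat, fw$caches$stem$cols, params$Ws,
                        fw$caches$idx_s, c(L, 1L))
  g$Ws <- bs$dW; g$bs <- bs$db
  g
}

#' Train the 1-D DenseNet classifier
#'
#' @param x feature matrix (samples x length); each row is treated as a
#'   1-D signal.
#' @param labels class labels (coerced to factor).
#' @param cfg a [densenet1d_config()].
#' @param epochs training epochs (default from `cfg`).
#' @param seed integer seed; training is deterministic given it.
#' @return object of class `densenet1d` with `params`, `cfg`, `levels`,
#'   per-epoch `loss` trace and the input `length`.
#' @export
train_densenet1d_net <- function(x, labels, cfg = densenet1d_config(),
                                 epochs = cfg$epochs, seed = 1L) {
  y <- as.factor(labels)
  if (nlevels(y) < 2L) stop("need at least 2 classes to train")
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), ncol(x) >= cfg$kernel)
  cfg$n_classes <- max(cfg$n_classes, nlevels(y))
  yi <- as.integer(y)
  n <- nrow(x)
  params <- densenet1d_init(cfg, ncol(x), seed)
  idx <- densenet1d_idx(cfg, ncol(x))
  state <- adam_init(params)
  loss_trace <- numeric(epochs)
  with_preserved_rng(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        fw <- densenet1d_forward(params, cfg, x[bi, , drop = FALSE], idx,
                                 keep = TRUE)
        ce <- softmax_ce(fw$logits, yi[bi])
        if (!is.finite(ce$loss)) stop("training error: non-finite loss")
        losses <- c(losses, ce$loss)
        g <- densenet1d_backward(params, cfg, x[bi, , drop = FALSE], fw,
                                 ce$dlogits)
        upd <- adam_step(params, g, state, lr = cfg$lr)
        params <- upd$params; state <- upd$state
      }
      loss_trace[ep] <- mean(losses)
    }
  })
  structure(list(params = params, cfg = cfg, levels = levels(y),
                 loss = loss_trace, length = ncol(x), seed = seed),
            class = "densenet1d")
}

#' @export
predict.densenet1d <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != object$length)
    stop(sprintf("input length %d does not match model length %d",
                 ncol(x), object$length))
  fw <- densenet1d_forward(object$params, object$cfg, x,
                           densenet1d_idx(object$cfg, ncol(x)))
  p <- softmax_rows(fw$logits[, seq_along(object$levels), drop = FALSE])
  colnames(p) <- object$levels
  if (type == "prob") p
  else factor(object$levels[max.col(p, ties.method = "first")],
              levels = object$levels)
}
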