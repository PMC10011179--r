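# Minimal vectorized neural-network primitives (im2col convolutions,
# average pooling, dense layers, softmax cross-entropy, Adam). Shared by
# the LeNet-5 image-feature extractor and the 1-D DenseNet classifier.
# All forward passes are pure matrix algebra; backward passes return
# gradients in the same shapes as the parameters.

# linear-index patch table for a valid 2-D convolution over (H, W, C);
# patch columns are ordered (di, dj, c), di fastest
make_im2col_idx2d <- function(H, W, C, k) {
  oh <- H - k + 1L; ow <- W - k + 1L
  base <- as.vector(outer(seq_len(oh), (seq_len(ow) - 1L) * H, "+"))
  off <- as.vector(outer(outer(0:(k - 1L), (0:(k - 1L)) * H, "+"),
                         (0:(C - 1L)) * H * W, "+"))
  idx <- outer(base, off, "+")
  attr(idx, "out_hw") <- c(oh, ow)
  idx
}

# batch im2col: x (N, H, W, C) -> (N*P, K), p fastest within sample
im2col2d <- function(x, idx) {
  n <- dim(x)[1]; P <- nrow(idx); K <- ncol(idx)
  xm <- matrix(x, n, prod(dim(x)[-1]))        # (N, H*W*C)
  a <- array(xm[, as.vector(idx)], c(n, P, K))
  matrix(aperm(a, c(2, 1, 3)), n * P, K)
}

col2im2d <- function(dcol, idx, H, W, C, n) {
  P <- nrow(idx); K <- ncol(idx)
  iv <- as.vector(idx)
  # (N*P, K) -> (N, P*K), then sum columns sharing a target pixel
  dm <- matrix(aperm(array(dcol, c(P, n, K)), c(2, 1, 3)), n, P * K)
  acc <- rowsum(t(dm), iv)                    # (#unique targets, N)
  dx <- matrix(0, H * W * C, n)
  dx[as.integer(rownames(acc)), ] <- acc
  aperm(array(dx, c(H, W, C, n)), c(4, 1, 2, 3))
}

conv2d_forward <- function(x, Wm, b, idx) {
  n <- dim(x)[1]
  ohw <- attr(idx, "out_hw")
  cols <- im2col2d(x, idx)
  z <- sweep(cols %*% Wm, 2, b, "+")
  a <- array(z, c(ohw[1], ohw[2], n, ncol(Wm)))
  list(out = aperm(a, c(3, 1, 2, 4)), cols = cols)
}

conv2d_backward <- function(dout, cols, Wm, idx, in_dim) {
  # dout (N, oh, ow, F) -> rows matching cols
  n <- dim(dout)[1]
  dz <- matrix(aperm(dout, c(2, 3, 1, 4)),
               nrow = prod(dim(dout)[1:3]), ncol = dim(dout)[4])
  list(dW = crossprod(cols, dz), db = colSums(dz),
       dx = col2im2d(dz %*% t(Wm), idx, in_dim[1], in_dim[2], in_dim[3], n))
}

avgpool2 <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[2], 2L); o2 <- seq(1L, d[3], 2L)
  (x[, o1, o2, , drop = FALSE] + x[, o1 + 1L, o2, , drop = FALSE] +
   x[, o1, o2 + 1L, , drop = FALSE] + x[, o1 + 1L, o2 + 1L, , drop = FALSE]) / 4
}

avgpool2_backward <- function(dp) {
  d <- dim(dp)
  dp[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), ,
     drop = FALSE] / 4
}

relu <- function(x) { x[x < 0] <- 0; x }

softmax_rows <- function(z) {
  z <- exp(z - apply(z, 1, max))
  z / rowSums(z)
}

# cross-entropy loss and logit gradient; y integer classes 1..C
softmax_ce <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  eps <- 1e-12
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], eps)))
  g <- p
  g[cbind(seq_len(n), y)] <- g[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = g / n)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# 1-D analogues (same-padded convolution over (L, C) signals)
make_im2col_idx1d <- function(L, C, k) {
  pad <- (k - 1L) %/% 2L
  Lp <- L + 2L * pad
  base <- seq_len(L)                      # output position p covers p..p+k-1 in padded signal
  off <- as.vector(outer(0:(k - 1L), (0:(C - 1L)) * Lp, "+"))
  idx <- outer(base, off, "+")
  attr(idx, "pad") <- pad
  attr(idx, "Lp") <- Lp
  idx
}

im2col1d <- function(x, idx) {
  # x (N, L, C)
  n <- dim(x)[1]; L <- dim(x)[2]; C <- dim(x)[3]
  pad <- attr(idx, "pad"); Lp <- attr(idx, "Lp")
  P <- nrow(idx); K <- ncol(idx)
  xp <- array(0, c(n, Lp, C))
  xp[, pad + seq_len(L), ] <- x
  xm <- matrix(xp, n, Lp * C)
  a <- array(xm[, as.vector(idx)], c(n, P, K))
  matrix(aperm(a, c(2, 1, 3)), n * P, K)
}

col2im1d <- function(dcol, idx, L, C, n) {
  pad <- attr(idx, "pad"); Lp <- attr(idx, "Lp")
  P <- nrow(idx); K <- ncol(idx)
  iv <- as.vector(idx)
  dm <- matrix(aperm(array(dcol, c(P, n, K)), c(2, 1, 3)), n, P * K)
  acc <- rowsum(t(dm), iv)
  dxp <- matrix(0, Lp * C, n)
  dxp[as.integer(rownames(acc)), ] <- acc
  dxp <- array(dxp, c(Lp, C, n))
  aperm(dxp[pad + seq_len(L), , , drop = FALSE], c(3, 1, 2))
}

conv1d_forward <- function(x, Wm, b, idx) {
  n <- dim(x)[1]; L <- nrow(idx)
  cols <- im2col1d(x, idx)
  z <- sweep(cols %*% Wm, 2, b, "+")
  list(out = aperm(array(z, c(L, n, ncol(Wm))), c(2, 1, 3)), cols = cols)
}

conv1d_backward <- function(dout, cols, Wm, idx, in_dim) {
  n <- dim(dout)[1]
  dz <- matrix(aperm(dout, c(2, 1, 3)),
               nrow = prod(dim(dout)[1:2]), ncol = dim(dout)[3])
  list(dW = crossprod(cols, dz), db = colSums(dz),
       dx = col2im1d(dz %*% t(Wm), idx, in_dim[1], in_dim[2], n))
}

he_init <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
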