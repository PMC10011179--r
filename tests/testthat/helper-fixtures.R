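# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain double loops / direct formulas, independent of the package's
# vectorized implementations.

tiny_params <- function(...) {
  sim_params(n_bands = 40, frame_size = c(24, 24), leaf_shape = c(14, 8),
             ...)
}

# brute-force ReliefF: explicit neighbour enumeration, Manhattan distance on
# min-max scaled features, every sample an anchor
oracle_relieff <- function(x, y, k) {
  x <- as.matrix(x); y <- as.factor(y)
  n <- nrow(x); p <- ncol(x)
  for (j in seq_len(p)) {
    r <- range(x[, j]); span <- r[2] - r[1]
    x[, j] <- if (span == 0) 0 else (x[, j] - r[1]) / span
  }
  prior <- table(y) / n
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- sapply(seq_len(n), function(j) sum(abs(x[i, ] - x[j, ])))
    ord <- order(d)[order(d) != i]
    for (f in seq_len(p)) {
      hits <- ord[y[ord] == y[i]][1:k]
      w[f] <- w[f] - mean(abs(x[hits, f] - x[i, f])) / n
      for (cl in setdiff(levels(y), as.character(y[i]))) {
        miss <- ord[y[ord] == cl][1:k]
        coef <- prior[[cl]] / (1 - prior[[as.character(y[i])]])
        w[f] <- w[f] + coef * mean(abs(x[miss, f] - x[i, f])) / n
      }
    }
  }
  w
}

# direct per-class precision/recall/F1 from a confusion matrix (percent)
oracle_metrics <- function(conf) {
  k <- nrow(conf)
  prec <- rec <- f1 <- numeric(k)
  for (c in seq_len(k)) {
    tp <- conf[c, c]
    pred_c <- sum(conf[, c]); true_c <- sum(conf[c, ])
    prec[c] <- if (pred_c > 0) 100 * tp / pred_c else NA_real_
    rec[c] <- if (true_c > 0) 100 * tp / true_c else NA_real_
    f1[c] <- if (!is.na(prec[c]) && !is.na(rec[c]) && prec[c] + rec[c] > 0)
      2 * prec[c] * rec[c] / (prec[c] + rec[c]) else NA_real_
  }
  list(precision = prec, recall = rec, f1 = f1,
       accuracy = 100 * sum(diag(conf)) / sum(conf))
}

# hand simulation of the container scan, written independently
oracle_container <- function(r, ref, thr = 0.3, maxm = 4) {
  inside <- ref
  admitted <- c()
  for (j in seq_len(nrow(r))) {
    if (j == ref) next
    if (length(admitted) >= maxm) break
    ok <- TRUE
    for (m in inside) if (abs(r[j, m]) > thr) ok <- FALSE
    if (ok) { inside <- c(inside, j); admitted <- c(admitted, j) }
  }
  if (length(admitted))
    admitted <- admitted[order(abs(r[admitted, ref]), admitted)]
  admitted
}

# painted image stacks whose intensity encodes the class
painted_stacks <- function(n_per_class = 10, hw = c(16, 16), channels = 1,
                           gain = 0.3, noise = 0.02, seed = 1) {
  set.seed(seed)
  y <- factor(rep(0:2, each = n_per_class))
  n <- length(y)
  stacks <- array(stats::rnorm(n * prod(hw) * channels, sd = noise),
                  c(n, hw[1], hw[2], channels))
  for (i in seq_len(n))
    stacks[i, , , ] <- stacks[i, , , ] + as.integer(y[i]) * gain
  list(stacks = stacks, y = y)
}
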