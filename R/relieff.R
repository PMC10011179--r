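#' Multi-class ReliefF feature weights
#'
#' Kononenko's ReliefF with every sample used as an anchor: for each
#' anchor, the k nearest same-class hits and the k nearest misses of every
#' other class (Manhattan distance on min-max scaled features) update the
#' weights; miss contributions are weighted by the class prior relative to
#' the anchor's complement. The effective wavelength whose reflectance
#' image gets the highest weight serves as the reference image of the RIS.
#'
#' @param x feature matrix (samples x features), e.g. EW spectra.
#' @param y class labels (coerced to factor).
#' @param k_neighbors neighbours per class (default 10); must be at most
#'   the smallest class size minus one.
#' @param scale min-max scale features before weighting (default TRUE).
#'   Constant features contribute zero (guarded division).
#' @return numeric weight vector, one per feature.
#' @export
relieff_weights <- function(x, y, k_neighbors = 10L, scale = TRUE) {
  x <- as.matrix(x); y <- as.factor(y)
  n <- nrow(x); p <- ncol(x)
  k <- as.integer(k_neighbors)
  cls_n <- table(y)
  if (k < 1L) stop("k_neighbors must be >= 1")
  if (k > min(cls_n) - 1L)
    stop(sprintf(
      "k_neighbors = %d exceeds smallest class size minus one (%d)",
      k, min(cls_n) - 1L))
  if (scale) {
    rng <- apply(x, 2, range)
    span <- rng[2, ] - rng[1, ]
    span[span == 0] <- 1            # constant feature -> diffs are 0 anyway
    x <- sweep(sweep(x, 2, rng[1, ]), 2, span, "/")
  }
  prior <- as.numeric(cls_n) / n
  names(prior) <- names(cls_n)
  d <- as.matrix(stats::dist(x, method = "manhattan"))
  w <- numeric(p)
  for (i in seq_len(n)) {
    ci <- as.character(y[i])
    ord <- order(d[i, ])
    ord <- ord[ord != i]
    hits <- ord[y[ord] == y[i]][seq_len(k)]
    w <- w - colMeans(abs(sweep(x[hits, , drop = FALSE], 2, x[i, ]))) / n
    for (cl in setdiff(levels(y), ci)) {
      miss <- ord[y[ord] == cl][seq_len(k)]
      coef <- prior[[cl]] / (1 - prior[[ci]])
      w <- w + coef *
        colMeans(abs(sweep(x[miss, , drop = FALSE], 2, x[i, ]))) / n
    }
  }
  w
}
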