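#' Pearson correlation between the band images of selected wavelengths
#'
#' Correlates the vectorized in-mask pixel values of each pair of
#' effective-wavelength band images of one sample cube. A zero-variance
#' band image has undefined correlation; it is recorded as 0 and flagged in
#' the `qc` attribute.
#'
#' @param cube reflectance [hypercube()].
#' @param mask logical leaf mask (>= 2 pixels).
#' @param ew_indices band indices of the effective wavelengths.
#' @return list of class `corr_matrix`: `r` (symmetric, unit diagonal) and
#'   `wavelengths`.
#' @export
image_correlation <- function(cube, mask, ew_indices) {
  idx <- which(as.vector(mask))
  if (length(idx) < 2L) stop("mask must contain at least 2 pixels")
  m <- cube_matrix(cube)[idx, ew_indices, drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  flat <- sds == 0
  r <- suppressWarnings(stats::cor(m))
  if (any(flat)) {
    r[flat, ] <- 0; r[, flat] <- 0
  }
  diag(r) <- 1
  structure(list(r = r, wavelengths = cube$wavelengths[ew_indices],
                 qc = list(zero_variance = which(flat))),
            class = "corr_matrix")
}

#' Average band-image correlation over several samples
#'
#' Element-wise mean of per-sample [image_correlation()] matrices; more
#' stable than the single-sample protocol, which remains available by
#' passing one cube.
#'
#' @param cubes list of reflectance cubes.
#' @param masks matching list of leaf masks.
#' @param ew_indices band indices of the effective wavelengths.
#' @return a `corr_matrix`.
#' @export
image_correlation_avg <- function(cubes, masks, ew_indices) {
  rs <- lapply(seq_along(cubes), function(i)
    image_correlation(cubes[[i]], masks[[i]], ew_indices)$r)
  r <- Reduce(`+`, rs) / length(rs)
  diag(r) <- 1
  structure(list(r = r,
                 wavelengths = cubes[[1]]$wavelengths[ew_indices],
                 qc = list(n_samples = length(cubes))),
            class = "corr_matrix")
}

#' Greedy weak-correlation container scan
#'
#' Starting from the ReliefF reference image, scans the remaining
#' effective wavelengths in ascending index order and admits a band image
#' into the container iff its absolute correlation with EVERY image
#' already in the container is at most `threshold`. The scan stops after
#' `max_members` admissions (or exhaustion); admitted members are then
#' ranked by their absolute correlation with the reference, ascending.
#' Ties are broken by the smaller index.
#'
#' @param corr a `corr_matrix` (or plain correlation matrix).
#' @param reference_idx row/column index of the reference image.
#' @param threshold admission threshold on `|r|` (default 0.3, i.e. r in
#'   `[-0.3, +0.3]`).
#' @param max_members maximum admitted members beside the reference.
#' @return list of class `ris_candidates`: `reference_idx`, `member_idx`
#'   (correlation-ranked), `candidate_order` (reference first), and the
#'   `threshold`.
#' @export
greedy_container <- function(corr, reference_idx, threshold = 0.3,
                             max_members = 4L) {
  r <- if (inherits(corr, "corr_matrix")) corr$r else as.matrix(corr)
  p <- nrow(r)
  if (reference_idx < 1L || reference_idx > p)
    stop("reference_idx out of range")
  container <- reference_idx
  members <- integer(0)
  for (j in setdiff(seq_len(p), reference_idx)) {
    if (length(members) >= max_members) break
    if (all(abs(r[j, container]) <= threshold)) {
      container <- c(container, j)
      members <- c(members, j)
    }
  }
  if (length(members)) {
    key <- abs(r[members, reference_idx])
    members <- members[order(key, members)]
  }
  wl <- if (inherits(corr, "corr_matrix")) corr$wavelengths else NULL
  structure(list(reference_idx = reference_idx, member_idx = members,
                 candidate_order = c(reference_idx, members),
                 reference_wl = wl[reference_idx],
                 member_wls = wl[members], threshold = threshold),
            class = "ris_candidates")
}

#' Superposition search over stacked reflectance images
#'
#' Stacks the candidate band images one by one in correlation-rank order
#' (reference first) and returns the stack depth `k` whose
#' spectroscopy-image evaluation accuracy is maximal; ties go to the
#' smaller `k`.
#'
#' @param candidate_order candidate indices, reference first.
#' @param evaluator function of `k` returning the evaluation accuracy of
#'   the first `k` candidates (see [ris_superposition_evaluator()]).
#' @return list of class `ris`: `reference_idx`, `member_idx` (selected
#'   members after the reference), `k_selected`, `accuracies` (one per
#'   candidate depth).
#' @export
superposition_search <- function(candidate_order, evaluator) {
  stopifnot(length(candidate_order) >= 1L)
  accs <- vapply(seq_along(candidate_order), function(k) {
    a <- tryCatch(evaluator(k), error = function(e)
      stop(sprintf("superposition evaluator failed at k = %d: %s",
                   k, conditionMessage(e)), call. = FALSE))
    as.numeric(a)
  }, numeric(1))
  k_sel <- which.max(accs)            # which.max takes the first maximum
  structure(list(reference_idx = candidate_order[1],
                 member_idx = candidate_order[seq_len(k_sel)][-1],
                 indices = candidate_order[seq_len(k_sel)],
                 k_selected = k_sel, accuracies = accs),
            class = "ris")
}

#' Default superposition evaluator: LeNet-5 features + EW spectra + SVM CV
#'
#' Builds the evaluator used by the RIS superposition search: for depth
#' `k`, a LeNet-5 is trained on the first `k` image channels, its
#' pre-activation features are combined with the EW spectra
#' (per-block standardization, spectral block first), and the combination
#' is scored by SVM cross-validation accuracy.
#'
#' @param stacks image stack array `(n, H, W, K_max)`, channels already in
#'   candidate order.
#' @param ew_spectra matrix of EW reflectance values (n x |EW|).
#' @param y class labels.
#' @param lenet_cfg a [lenet_config()] (its `in_channels` is overridden
#'   per depth).
#' @param epochs LeNet training epochs per depth.
#' @param folds,seed SVM cross-validation settings.
#' @return function of `k` returning an accuracy in `[0, 1]`.
#' @export
ris_superposition_evaluator <- function(stacks, ew_spectra, y,
                                        lenet_cfg = lenet_config(),
                                        epochs = 20L, folds = 5L,
                                        seed = 1L) {
  force(stacks); force(ew_spectra); force(y)
  function(k) {
    sub <- stacks[, , , seq_len(k), drop = FALSE]
    cfg <- lenet_cfg
    cfg$in_channels <- k
    cfg$input_hw <- dim(stacks)[2:3]
    net <- train_lenet(sub, y, cfg, epochs = epochs, seed = seed)
    feats <- extract_features(net, sub)
    comb <- combine_features(ew_spectra, feats)
    cv_fitness(comb, y, folds = folds, seed = seed)
  }
}

#' @export
print.ris <- function(x, ...) {
  cat(sprintf("<ris> k = %d (reference idx %d%s)\n", x$k_selected,
              x$reference_idx,
              if (length(x$member_idx))
                paste0(" + members ", paste(x$member_idx, collapse = ", "))
              else ""))
  invisible(x)
}
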