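#' Stratified 7:3 calibration/prediction split
#'
#' Partitions samples into calibration and prediction sets, stratified by
#' class with largest-remainder rounding of the per-class quotas (this is
#' the allocation that turns 315 pairs of 108/105/102 into 220/95). With
#' `groups`, whole groups (e.g. plants) are allocated instead of single
#' samples, so no group straddles the split; groups must be class-pure.
#'
#' @param labels class labels (coerced to factor).
#' @param ratio calibration fraction (default 0.7).
#' @param seed integer seed for the within-class shuffle.
#' @param groups optional group ids (e.g. `plant_ids`) for grouped
#'   splitting.
#' @return list of class `split_spec` with integer index vectors
#'   `calibration` and `prediction`, plus `ratio` and `seed`.
#' @export
split_dataset <- function(labels, ratio = 0.7, seed = 1L, groups = NULL) {
  y <- as.factor(labels)
  if (any(table(y) < 2L))
    stop("every class needs at least 2 samples to split")
  units <- if (is.null(groups)) seq_along(y) else unique(groups)
  if (!is.null(groups)) {
    ug <- vapply(units, function(g) {
      cls <- unique(as.character(y[groups == g]))
      if (length(cls) > 1L) stop("groups must be class-pure")
      cls
    }, character(1))
    uy <- factor(ug, levels = levels(y))
  } else uy <- y
  counts <- table(uy)
  quota <- ratio * as.numeric(counts)
  n_cal <- floor(quota)
  rem <- round(sum(quota)) - sum(n_cal)
  if (rem > 0) {
    take <- order(quota - floor(quota), decreasing = TRUE)[seq_len(rem)]
    n_cal[take] <- n_cal[take] + 1L
  }
  n_cal <- pmin(pmax(n_cal, 1L), as.numeric(counts) - 1L)
  cal_units <- integer(0)
  with_preserved_rng(seed, {
    for (ci in seq_along(levels(uy))) {
      u <- units[uy == levels(uy)[ci]]
      cal_units <- c(cal_units, sample(u)[seq_len(n_cal[ci])])
    }
  })
  if (is.null(groups)) {
    cal <- sort(cal_units)
  } else {
    cal <- which(groups %in% cal_units)
  }
  structure(list(calibration = cal,
                 prediction = setdiff(seq_along(y), cal),
                 ratio = ratio, seed = as.integer(seed),
                 grouped = !is.null(groups)),
            class = "split_spec")
}

# shared standardization wrapper so SVM sees comparable scales
fit_standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(ctr = ctr, scl = scl)
}
apply_standardizer <- function(x, st)
  sweep(sweep(x, 2, st$ctr), 2, st$scl, "/")

#' Train a drought-stress classifier
#'
#' Uniform wrappers returning a `ds_model` that exposes class predictions
#' and per-class scores for ROC analysis. `train_svm` fits an RBF-kernel
#' SVM (C = 1 by default, probability scores, per-feature standardization
#' fitted on the calibration set); `train_rf` fits a 500-tree random
#' forest with sqrt(d) features per split; `train_densenet1d` fits the 1-D
#' DenseNet of [densenet1d_config()]. All are deterministic given `seed`.
#'
#' @param x calibration feature matrix.
#' @param y calibration labels (coerced to factor; >= 2 classes).
#' @param cost,kernel,gamma SVM parameters (`gamma = NULL` uses the e1071
#'   default `1/d`).
#' @param seed integer seed.
#' @return object of class `ds_model`.
#' @export
train_svm <- function(x, y, cost = 1, kernel = "radial", gamma = NULL,
                      seed = 1L) {
  x <- as.matrix(x); y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("degenerate single-class input")
  st <- fit_standardizer(x)
  xs <- apply_standardizer(x, st)
  fit <- with_preserved_rng(seed, {
    args <- list(x = xs, y = y, kernel = kernel, cost = cost,
                 scale = FALSE, probability = TRUE, fitted = FALSE)
    if (!is.null(gamma)) args$gamma <- gamma
    do.call(e1071::svm, args)
  })
  structure(list(kind = "svm", fit = fit, std = st, levels = levels(y)),
            class = "ds_model")
}

#' @rdname train_svm
#' @param ntree,mtry random-forest parameters (`mtry = NULL` uses
#'   `floor(sqrt(d))`).
#' @export
train_rf <- function(x, y, ntree = 500L, mtry = NULL, seed = 1L) {
  x <- as.matrix(x); y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("degenerate single-class input")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- with_preserved_rng(seed,
    randomForest::randomForest(x, y, ntree = ntree, mtry = mtry))
  structure(list(kind = "rf", fit = fit, levels = levels(y)),
            class = "ds_model")
}

#' @rdname train_svm
#' @param cfg a [densenet1d_config()].
#' @param epochs DenseNet training epochs.
#' @export
train_densenet1d <- function(x, y, cfg = densenet1d_config(),
                             epochs = cfg$epochs, seed = 1L) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("degenerate single-class input")
  st <- fit_standardizer(as.matrix(x))
  xs <- apply_standardizer(as.matrix(x), st)
  fit <- train_densenet1d_net(xs, y, cfg, epochs = epochs, seed = seed)
  structure(list(kind = "densenet", fit = fit, std = st,
                 levels = levels(y)),
            class = "ds_model")
}

#' @export
predict.ds_model <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (object$kind == "svm") {
    xs <- apply_standardizer(x, object$std)
    if (type == "class") return(stats::predict(object$fit, xs))
    p <- attr(stats::predict(object$fit, xs, probability = TRUE),
              "probabilities")
    return(p[, object$levels, drop = FALSE])
  }
  if (object$kind == "rf") {
    if (type == "class") return(stats::predict(object$fit, x))
    return(stats::predict(object$fit, x, type = "prob")[, object$levels,
                                                        drop = FALSE])
  }
  xs <- apply_standardizer(x, object$std)
  stats::predict(object$fit, xs, type = type)
}

#' Per-class metrics from a confusion matrix
#'
#' Rows are true classes, columns predicted classes. Precision, recall and
#' F1 are reported in percent; a class never predicted has undefined
#' precision (NA, flagged), a class absent from the truth has undefined
#' recall.
#'
#' @param confusion square counts matrix (true x predicted).
#' @return list with `precision`, `recall`, `f1` (percent, per class),
#'   `accuracy` (percent) and `flags`.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  tp <- diag(confusion)
  rowS <- rowSums(confusion); colS <- colSums(confusion)
  precision <- ifelse(colS > 0, tp / colS, NA_real_) * 100
  recall <- ifelse(rowS > 0, tp / rowS, NA_real_) * 100
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  flags <- character(0)
  if (anyNA(precision)) flags <- c(flags, "class_never_predicted")
  if (anyNA(recall)) flags <- c(flags, "class_absent_from_truth")
  list(precision = precision, recall = recall, f1 = f1,
       accuracy = 100 * sum(tp) / sum(confusion), flags = flags)
}

roc_points <- function(truth_bin, score) {
  r <- pROC::roc(response = factor(as.integer(truth_bin), levels = 0:1),
                 predictor = score, quiet = TRUE,
                 direction = "<", levels = c("0", "1"))
  list(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities),
       auc = as.numeric(r$auc))
}

#' Evaluate a classifier on calibration and prediction sets
#'
#' Computes the full model report: calibration and prediction accuracies
#' (ACC_C, ACC_P, percent), the prediction-set confusion matrix (rows =
#' true class), per-class precision/recall/F1, and one-vs-rest ROC curves
#' with AUC per class.
#'
#' @param model a `ds_model` (or any object whose `predict` yields classes
#'   and, with `type = "prob"`, per-class scores).
#' @param calib,pred lists with elements `x` (features) and `y` (labels).
#' @return list of class `model_report`.
#' @export
evaluate <- function(model, calib, pred) {
  lv <- model$levels
  yc <- factor(as.character(calib$y), levels = lv)
  yp <- factor(as.character(pred$y), levels = lv)
  pc <- factor(as.character(stats::predict(model, calib$x)), levels = lv)
  pp <- factor(as.character(stats::predict(model, pred$x)), levels = lv)
  confusion <- table(true = yp, predicted = pp)
  m <- metrics_from_confusion(confusion)
  scores <- stats::predict(model, pred$x, type = "prob")
  roc <- lapply(lv, function(cl) {
    if (!any(yp == cl) || all(yp == cl))
      return(list(fpr = NA_real_, tpr = NA_real_, auc = NA_real_))
    roc_points(yp == cl, scores[, cl])
  })
  names(roc) <- lv
  structure(list(acc_c = 100 * mean(pc == yc), acc_p = m$accuracy,
                 precision = stats::setNames(m$precision, lv),
                 recall = stats::setNames(m$recall, lv),
                 f1 = stats::setNames(m$f1, lv),
                 confusion = unclass(confusion), roc = roc,
                 n_calib = length(yc), n_pred = length(yp),
                 flags = m$flags),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> ACC_C = %.2f%%, ACC_P = %.2f%% (n = %d/%d)\n",
              x$acc_c, x$acc_p, x$n_calib, x$n_pred))
  tab <- rbind(precision = x$precision, recall = x$recall, f1 = x$f1)
  print(round(tab, 2))
  invisible(x)
}

#' Serialize / restore a model report
#'
#' Lossless JSON round trip of a [evaluate()] report.
#'
#' @param report a `model_report`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return `report_to_json`: the path or JSON string;
#'   `report_from_json`: the restored `model_report`.
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- unclass(report)
  obj$confusion <- list(counts = as.vector(obj$confusion),
                        classes = rownames(report$confusion))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  path
}

#' @rdname report_to_json
#' @param json a path or JSON string produced by `report_to_json`.
#' @export
report_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  cls <- obj$confusion$classes
  k <- length(cls)
  conf <- matrix(obj$confusion$counts, k, k, dimnames = list(cls, cls))
  names(dimnames(conf)) <- c("true", "predicted")
  obj$confusion <- conf
  for (f in c("precision", "recall", "f1"))
    obj[[f]] <- stats::setNames(as.numeric(obj[[f]]), cls)
  obj$roc <- lapply(obj$roc, function(r)
    list(fpr = as.numeric(r$fpr), tpr = as.numeric(r$tpr),
         auc = as.numeric(r$auc)))
  obj$flags <- as.character(obj$flags)
  structure(obj, class = "model_report")
}
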