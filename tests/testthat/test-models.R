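test_that("stratified split reproduces the published 7:3 arithmetic", {
  # 315 pairs of 108/105/102 -> 220 calibration / 95 prediction
  y_pairs <- rep(c("well", "reduced", "deficient"), c(108, 105, 102))
  sp <- split_dataset(y_pairs, ratio = 0.7, seed = 1)
  expect_length(sp$calibration, 220)
  expect_length(sp$prediction, 95)
  # 630 leaves -> 441/189, within one per class of the 7:3 quota
  y_leaves <- rep(y_pairs, 2)
  sp2 <- split_dataset(y_leaves, ratio = 0.7, seed = 1)
  expect_equal(length(sp2$calibration), 441)
  per_class <- table(y_leaves[sp2$calibration])
  quota <- 0.7 * table(y_leaves)
  expect_true(all(abs(per_class - quota[names(per_class)]) <= 1))
  # different seeds give different partitions of identical sizes
  sp3 <- split_dataset(y_pairs, ratio = 0.7, seed = 2)
  expect_length(sp3$calibration, 220)
  expect_false(identical(sp$calibration, sp3$calibration))
  expect_error(split_dataset(c("a", "b", "b")), "at least 2")
})

test_that("grouped splitting keeps plants intact", {
  y <- rep(c("well", "reduced", "deficient"), each = 12)
  plants <- rep(1:12, each = 3)
  sp <- split_dataset(y, seed = 3, groups = plants)
  straddle <- intersect(plants[sp$calibration], plants[sp$prediction])
  expect_length(straddle, 0)
})

test_that("classifiers fit separable toy data and expose scores", {
  set.seed(1)
  y <- factor(rep(0:1, each = 20))
  x <- cbind(rnorm(40, mean = 8 * as.integer(y)), rnorm(40))
  m <- train_svm(x, y, seed = 1)
  expect_equal(mean(predict(m, x) == y), 1.0)
  p <- predict(m, x, type = "prob")
  expect_equal(colnames(p), levels(y))
  expect_error(train_svm(x, factor(rep(0, 40), levels = c(0, 1))),
               "single-class")
})

test_that("a one-tree stump forest reproduces the brute-force best split", {
  set.seed(2)
  x <- matrix(runif(60), 30, 2)
  y <- factor(as.integer(x[, 1] > 0.55))
  # brute-force best stump on feature 1
  thr <- sort(x[, 1])
  errs <- sapply(thr, function(t) sum((x[, 1] > t) != (y == 1)))
  best_thr <- thr[which.min(errs)]
  m <- with(list(), randomForest::randomForest(
    x, y, ntree = 1, mtry = 2, maxnodes = 2, replace = FALSE,
    sampsize = 30))
  pred <- predict(m, x)
  expect_equal(as.character(pred), as.character(as.integer(x[, 1] > best_thr)))
  # the packaged wrapper trains and predicts coherently
  mr <- train_rf(x, y, ntree = 50, seed = 5)
  expect_gte(mean(predict(mr, x) == y), 0.97)
})

test_that("evaluate matches hand-computed metrics on a worked confusion case", {
  # confusion [[2,0],[1,1]]: precision0 = 66.67, recall0 = 100, F1 = 80
  m <- metrics_from_confusion(matrix(c(2, 1, 0, 1), 2, 2))
  expect_equal(m$precision[1], 200 / 3, tolerance = 1e-12)
  expect_equal(m$recall[1], 100)
  expect_equal(m$f1[1], 80, tolerance = 1e-12)
})

test_that("metrics match the exhaustive oracle on small confusion matrices", {
  # exhaustive over entries <= 2, plus a random sample with entries <= 5
  grid2 <- as.matrix(expand.grid(rep(list(0:2), 9)))
  grid2 <- grid2[rowSums(grid2) > 0, ]
  set.seed(7)
  grid5 <- matrix(sample(0:5, 9 * 2000, replace = TRUE), ncol = 9)
  grid5 <- grid5[rowSums(grid5) > 0, ]
  for (grid in list(grid2, grid5)) {
    # vectorized oracle, straight from the definitions
    tp <- grid[, c(1, 5, 9)]
    rowS <- cbind(grid[, 1] + grid[, 4] + grid[, 7],
                  grid[, 2] + grid[, 5] + grid[, 8],
                  grid[, 3] + grid[, 6] + grid[, 9])
    colS <- cbind(grid[, 1] + grid[, 2] + grid[, 3],
                  grid[, 4] + grid[, 5] + grid[, 6],
                  grid[, 7] + grid[, 8] + grid[, 9])
    prec_o <- ifelse(colS > 0, 100 * tp / colS, NA)
    rec_o <- ifelse(rowS > 0, 100 * tp / rowS, NA)
    f1_o <- ifelse(!is.na(prec_o) & !is.na(rec_o) & (prec_o + rec_o) > 0,
                   2 * prec_o * rec_o / (prec_o + rec_o), NA)
    got <- vapply(seq_len(nrow(grid)), function(i) {
      m <- metrics_from_confusion(matrix(grid[i, ], 3, 3))
      c(m$precision, m$recall, m$f1)
    }, numeric(9))
    expect_equal(t(got)[, 1:3], unname(prec_o))
    expect_equal(t(got)[, 4:6], unname(rec_o))
    expect_equal(t(got)[, 7:9], unname(f1_o))
    # F1 harmonic-mean identity wherever defined
    h <- 2 * prec_o * rec_o / (prec_o + rec_o)
    idx <- !is.na(f1_o)
    expect_equal(t(got)[, 7:9][idx], unname(h[idx]))
  }
})

test_that("evaluate produces a complete, serializable report", {
  set.seed(3)
  y <- factor(rep(0:2, each = 15))
  x <- cbind(as.integer(y) + rnorm(45, sd = 0.2), rnorm(45))
  sp <- split_dataset(y, seed = 1)
  m <- train_svm(x[sp$calibration, ], y[sp$calibration], seed = 1)
  rep1 <- evaluate(m, list(x = x[sp$calibration, ], y = y[sp$calibration]),
                   list(x = x[sp$prediction, ], y = y[sp$prediction]))
  expect_equal(sum(rep1$confusion), rep1$n_pred)
  expect_equal(unname(rowSums(rep1$confusion)),
               as.vector(table(y[sp$prediction])))
  expect_true(all(rep1$roc[[1]]$fpr >= 0 & rep1$roc[[1]]$fpr <= 1))
  # perfect predictor: all metrics 100, diagonal confusion
  perfect <- structure(list(kind = "svm", levels = levels(y)),
                       class = c("perfect_model"))
  predict.perfect_model <<- function(object, x, type = "class", ...) {
    lab <- factor(round(pmin(pmax(x[, 1], 0), 2)), levels = 0:2)
    if (type == "prob") {
      p <- matrix(0.001, nrow(x), 3, dimnames = list(NULL, 0:2))
      p[cbind(seq_len(nrow(x)), as.integer(lab))] <- 0.998
      p
    } else lab
  }
  on.exit(rm("predict.perfect_model", envir = .GlobalEnv), add = TRUE)
  xq <- cbind(as.integer(y) - 1L + 0.001, 0)
  repp <- evaluate(perfect, list(x = xq, y = y), list(x = xq, y = y))
  expect_equal(repp$acc_c, 100)
  expect_equal(repp$acc_p, 100)
  expect_equal(unname(repp$precision), rep(100, 3))
  expect_equal(unname(repp$f1), rep(100, 3))
  expect_equal(sum(diag(repp$confusion)), sum(repp$confusion))
  # JSON round trip is lossless
  back <- report_from_json(report_to_json(rep1))
  expect_equal(back$acc_c, rep1$acc_c)
  expect_equal(back$precision, rep1$precision)
  expect_equal(unname(back$confusion), unname(rep1$confusion))
  expect_equal(back$roc$`0`$auc, rep1$roc$`0`$auc)
})

test_that("random scores give chance-level AUC", {
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    truth <- rep(c(TRUE, FALSE), each = 50)
    r <- pROC::roc(response = factor(as.integer(truth), levels = 0:1),
                   predictor = runif(100), quiet = TRUE, direction = "<",
                   levels = c("0", "1"))
    as.numeric(r$auc)
  }, numeric(1))
  expect_lt(max(abs(aucs - 0.5)), 0.2)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("DenseNet wrapper trains, predicts and evaluates", {
  set.seed(4)
  y <- factor(rep(0:2, each = 15))
  x <- matrix(rnorm(45 * 24), 45)
  for (b in c(5, 12, 19)) x[, b] <- x[, b] + 2 * as.integer(y)
  m <- train_densenet1d(x, y, epochs = 80, seed = 2)
  expect_gte(mean(predict(m, x) == y), 0.9)
  p <- predict(m, x, type = "prob")
  expect_equal(rowSums(p), rep(1, 45), tolerance = 1e-12)
})
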