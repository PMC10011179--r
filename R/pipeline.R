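#' Configuration of a full synthetic drought-stress experiment
#'
#' Bundles every stage's settings for [run_experiment()]. All stochastic
#' stages derive their seeds deterministically from the global `seed`, so
#' a config reruns to an identical summary table.
#'
#' @param design per-treatment leaf counts per stage.
#' @param params a [sim_params()].
#' @param ga a [ga_config()] for effective-wavelength selection.
#' @param ris_threshold correlation-container admission threshold on |r|.
#' @param ris_max_members container capacity beside the reference image.
#' @param single_sample_corr use one calibration sample for the band-image
#'   correlation matrix (the published protocol) instead of averaging over
#'   all calibration samples.
#' @param lenet a [lenet_config()].
#' @param lenet_epochs final feature-extractor training epochs.
#' @param superposition_epochs LeNet epochs inside the RIS superposition
#'   search.
#' @param densenet a [densenet1d_config()].
#' @param densenet_epochs DenseNet training epochs.
#' @param models classifiers to fit: subset of `"svm"`, `"rf"`,
#'   `"densenet"`.
#' @param feature_sets feature strategies to evaluate, in ladder order:
#'   subset of `"full_spectra"`, `"ew_spectra"`, `"combo"`, `"fused"`.
#' @param split_ratio calibration fraction of the 7:3 split.
#' @param stack_hw RIS image-stack size.
#' @param seg_threshold,seg_wavelength,seg_min_pixels segmentation
#'   settings (see [segment_roi()]).
#' @param cv_folds folds of the evaluator cross-validations.
#' @param seed global experiment seed.
#' @param out_dir optional directory for per-stage artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(design = c(12, 12, 12),
                       params = sim_params(),
                       ga = ga_config(pop_size = 20L, generations = 15L,
                                      stall_limit = 2L, cv_folds = 3L),
                       ris_threshold = 0.3, ris_max_members = 4L,
                       single_sample_corr = FALSE,
                       lenet = lenet_config(),
                       lenet_epochs = 30L, superposition_epochs = 10L,
                       densenet = densenet1d_config(),
                       densenet_epochs = 40L,
                       models = c("svm", "rf", "densenet"),
                       feature_sets = c("full_spectra", "ew_spectra",
                                        "combo", "fused"),
                       split_ratio = 0.7,
                       stack_hw = c(32L, 32L),
                       seg_threshold = 0.35, seg_wavelength = 800,
                       seg_min_pixels = 20L,
                       cv_folds = 3L,
                       seed = 1L, out_dir = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

strategy_ladder <- c("full_spectra", "ew_spectra", "combo", "fused")

fit_one <- function(model, xc, yc, xp, yp, cfg, seed) {
  m <- switch(model,
              svm = train_svm(xc, yc, seed = seed),
              rf = train_rf(xc, yc, seed = seed),
              densenet = train_densenet1d(xc, yc, cfg$densenet,
                                          epochs = cfg$densenet_epochs,
                                          seed = seed),
              stop(sprintf("unknown model '%s'", model)))
  evaluate(m, list(x = xc, y = yc), list(x = xp, y = yp))
}

#' Run the end-to-end synthetic drought-stress experiment
#'
#' Simulates a labelled young/mature leaf dataset, frames it as raw counts
#' and calibrates it back with white/dark references, segments leaves and
#' extracts mean spectra, selects effective wavelengths per stage with the
#' GA restart protocol, determines the reflectance image set (ReliefF
#' reference, correlation container, superposition search), extracts
#' LeNet-5 image features, forms spectroscopy-image combinations, fuses
#' young/mature pairs, and trains/evaluates the requested classifiers on
#' each feature strategy under a shared pair-level 7:3 split.
#'
#' @param cfg a [run_config()].
#' @return list of class `experiment_result`: `summary` (data frame:
#'   feature_set, stage, model, acc_c, acc_p), `reports` (named
#'   `model_report` list), `ews`, `ris`, `split`, `config`.
#' @export
run_experiment <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  seeds <- list(sim = cfg$seed, split = cfg$seed + 1L,
                ga = cfg$seed + 2L, lenet = cfg$seed + 3L,
                model = cfg$seed + 4L, eval = cfg$seed + 5L)
  stage_names <- c("young", "mature")

  ds <- generate_dataset(cfg$design, cfg$params, seed = seeds$sim)
  refs <- make_reference_frames(cfg$params)
  ds$cubes <- lapply(ds$cubes, function(cb)
    calibrate(synthesize_raw(cb, refs), refs))
  ex <- extract_spectra(ds, threshold = cfg$seg_threshold,
                        wavelength = cfg$seg_wavelength,
                        min_pixels = cfg$seg_min_pixels)

  n_pairs <- sum(ds$stages == "young")
  pair_labels <- ds$labels[seq_len(n_pairs)]
  split <- split_dataset(pair_labels, ratio = cfg$split_ratio,
                         seed = seeds$split)
  cal_pairs <- split$calibration; pred_pairs <- split$prediction

  stage_data <- list()
  ews <- list(); ris_sel <- list()
  for (si in seq_along(stage_names)) {
    st <- stage_names[si]
    rows <- which(ds$stages == st)          # pair i <-> rows[i]
    sp <- ex$spectra[rows, , drop = FALSE]
    y <- factor(ds$labels[rows])
    cubes <- ds$cubes[rows]; masks <- ex$masks[rows]

    ga_cfg <- cfg$ga
    ew <- ew_protocol(sp[cal_pairs, , drop = FALSE], y[cal_pairs],
                      ga_cfg, seed = seeds$ga + si,
                      wavelengths = ds$wavelengths)
    ew_sp <- sp[, ew$indices, drop = FALSE]

    w <- relieff_weights(ew_sp[cal_pairs, , drop = FALSE], y[cal_pairs],
                         k_neighbors = min(10L,
                           min(table(y[cal_pairs])) - 1L))
    ref_idx <- which.max(w)
    corr <- if (cfg$single_sample_corr)
      image_correlation(cubes[[cal_pairs[1]]], masks[[cal_pairs[1]]],
                        ew$indices)
    else image_correlation_avg(cubes[cal_pairs], masks[cal_pairs],
                               ew$indices)
    cand <- greedy_container(corr, ref_idx,
                             threshold = cfg$ris_threshold,
                             max_members = cfg$ris_max_members)
    cand_wl <- ds$wavelengths[ew$indices][cand$candidate_order]
    stacks <- build_stacks(cubes, masks, cand_wl, out_hw = cfg$stack_hw)
    evaluator <- ris_superposition_evaluator(
      stacks[cal_pairs, , , , drop = FALSE],
      ew_sp[cal_pairs, , drop = FALSE], y[cal_pairs],
      lenet_cfg = cfg$lenet, epochs = cfg$superposition_epochs,
      folds = cfg$cv_folds, seed = seeds$lenet + si)
    ris <- superposition_search(cand$candidate_order, evaluator)
    ris$wavelengths_nm <- cand_wl[seq_len(ris$k_selected)]

    k_stacks <- stacks[, , , seq_len(ris$k_selected), drop = FALSE]
    net <- train_lenet(k_stacks[cal_pairs, , , , drop = FALSE],
                       y[cal_pairs], cfg$lenet,
                       epochs = cfg$lenet_epochs,
                       seed = seeds$lenet + 10L + si)
    feats <- extract_features(net, k_stacks)
    combo <- combine_features(ew_sp, feats, calib_idx = cal_pairs)

    ews[[st]] <- ew; ris_sel[[st]] <- ris
    stage_data[[st]] <- list(full_spectra = sp, ew_spectra = ew_sp,
                             combo = combo, y = y, corr = corr)
  }

  meta_of <- function(st) {
    rows <- which(ds$stages == st)
    data.frame(label = ds$labels[rows], plant_id = ds$plant_ids[rows],
               replicate_idx = ds$replicate_idx[rows])
  }
  fused <- fuse_pairs(stage_data$young$combo, stage_data$mature$combo,
                      meta_of("young"), meta_of("mature"))
  fused_x <- fused$x
  fused_y <- stage_data$young$y

  reports <- list(); rows <- list()
  for (fs in cfg$feature_sets) {
    if (fs == "fused") {
      tabs <- list(fused = list(x = fused_x, y = fused_y))
    } else {
      tabs <- lapply(stage_data, function(sd)
        list(x = sd[[fs]], y = sd$y))
    }
    for (st in names(tabs)) {
      xc <- tabs[[st]]$x[cal_pairs, , drop = FALSE]
      xp <- tabs[[st]]$x[pred_pairs, , drop = FALSE]
      yc <- tabs[[st]]$y[cal_pairs]; yp <- tabs[[st]]$y[pred_pairs]
      for (mo in cfg$models) {
        rpt <- fit_one(mo, xc, yc, xp, yp, cfg, seed = seeds$model)
        attr(rpt, "split_seed") <- split$seed
        key <- paste(fs, st, mo, sep = ".")
        reports[[key]] <- rpt
        rows[[key]] <- data.frame(feature_set = fs, stage = st,
                                  model = mo, acc_c = rpt$acc_c,
                                  acc_p = rpt$acc_p,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  res <- structure(list(summary = summary, reports = reports, ews = ews,
                        ris = ris_sel,
                        corr = lapply(stage_data, `[[`, "corr"),
                        split = split, config = cfg),
                   class = "experiment_result")
  if (!is.null(cfg$out_dir)) write_experiment(res, cfg$out_dir)
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(transform(x$summary, acc_c = round(acc_c, 2),
                  acc_p = round(acc_p, 2)))
  invisible(x)
}

write_experiment <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  for (st in names(res$ews)) {
    ew <- res$ews[[st]]
    jsonlite::write_json(
      list(indices = ew$indices, wavelengths_nm = ew$wavelengths_nm,
           fitness = ew$fitness, n_runs = ew$n_runs, trace = ew$trace),
      file.path(dir, sprintf("ews_%s.json", st)), digits = NA,
      auto_unbox = TRUE)
    ris <- res$ris[[st]]
    jsonlite::write_json(
      list(k_selected = ris$k_selected,
           wavelengths_nm = ris$wavelengths_nm,
           accuracies = ris$accuracies),
      file.path(dir, sprintf("ris_%s.json", st)), digits = NA,
      auto_unbox = TRUE)
  }
  for (st in names(res$corr)) {
    cm <- res$corr[[st]]
    r <- round(cm$r, 6)
    dimnames(r) <- list(sprintf("%.1f", cm$wavelengths),
                        sprintf("%.1f", cm$wavelengths))
    utils::write.csv(r, file.path(dir, sprintf("corr_%s.csv", st)))
    png_path <- file.path(dir, sprintf("corr_%s.png", st))
    grDevices::png(png_path, width = 480, height = 480)
    graphics::image(seq_len(nrow(r)), seq_len(ncol(r)), cm$r,
                    zlim = c(-1, 1), xlab = "EW index", ylab = "EW index",
                    main = sprintf("Band-image correlation (%s)", st),
                    col = grDevices::hcl.colors(64, "Blue-Red"))
    grDevices::dev.off()
  }
  for (key in names(res$reports)) {
    rpt <- res$reports[[key]]
    report_to_json(rpt, file.path(dir, sprintf("report_%s.json", key)))
    utils::write.csv(rpt$confusion,
                     file.path(dir, sprintf("confusion_%s.csv", key)))
    roc_tab <- do.call(rbind, lapply(names(rpt$roc), function(cl)
      data.frame(class = cl, fpr = rpt$roc[[cl]]$fpr,
                 tpr = rpt$roc[[cl]]$tpr, auc = rpt$roc[[cl]]$auc)))
    utils::write.csv(roc_tab, file.path(dir, sprintf("roc_%s.csv", key)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Compare feature strategies of one experiment
#'
#' Tabulates ACC_C/ACC_P per feature strategy for a given model (and
#' stage), ordered along the strategy ladder full spectra -> EW spectra ->
#' spectroscopy-image combination -> subsample fusion, with deltas between
#' consecutive strategies. Reports must share the same split seed to be
#' comparable.
#'
#' @param reports named list of `model_report`s (names are feature-set
#'   labels), e.g. a filtered `experiment_result$reports`.
#' @return data frame: `feature_set`, `acc_c`, `acc_p`, `delta_acc_c`,
#'   `delta_acc_p`.
#' @export
compare_feature_sets <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 reports to compare")
  seeds <- lapply(reports, attr, "split_seed")
  if (length(unique(unlist(lapply(seeds, function(s)
    if (is.null(s)) NA_integer_ else s)))) > 1L)
    stop("comparability error: reports use different split seeds")
  nm <- names(reports)
  ord <- order(match(nm, strategy_ladder, nomatch = length(strategy_ladder) + 1L))
  nm <- nm[ord]; reports <- reports[ord]
  acc_c <- vapply(reports, `[[`, numeric(1), "acc_c")
  acc_p <- vapply(reports, `[[`, numeric(1), "acc_p")
  data.frame(feature_set = nm, acc_c = acc_c, acc_p = acc_p,
             delta_acc_c = c(NA, diff(acc_c)),
             delta_acc_p = c(NA, diff(acc_p)),
             row.names = NULL, stringsAsFactors = FALSE)
}
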