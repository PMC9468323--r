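#' Stratified k-fold split
#'
#' Partitions subjects into `k` disjoint, exhaustive test folds with class
#' proportions preserved to within one subject per fold: within each
#' class, indices are shuffled (seeded) and dealt round-robin across
#' folds.
#'
#' @param labels class labels, one per subject; every class must have at
#'   least `k` members.
#' @param k number of folds (default 10).
#' @param seed integer seed for the shuffle.
#' @return object of class `"fold_split"`: list with `k`, `seed`, and
#'   `folds`, a list of k integer vectors of test indices.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("infeasible stratification: class(es) ",
         paste(names(counts)[counts < k], collapse = ", "),
         " have fewer than k = ", k, " members")
  folds <- vector("list", k)
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold_of <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], idx[fold_of == f])
    }
  })
  structure(list(k = as.integer(k), seed = seed,
                 folds = lapply(folds, sort)),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat("Stratified", x$k, "fold split of",
      length(unlist(x$folds)), "subjects (seed", x$seed, ")\n")
  invisible(x)
}

## Extract per-subject component time courses for one CV fold.
## Group maps (and therefore the decomposition) are estimated from
## training subjects only and applied unchanged to test subjects.
.fold_timecourses <- function(cohort, train_idx, level, n_components,
                              keep, atlas_labels, fold_seed,
                              icasso_runs = 0L) {
  if (level == "truth") {
    return(list(tcs = cohort$timecourses, group_maps = NULL))
  }
  if (level == "roi") {
    tcs <- lapply(cohort$voxels, roi_mean_timecourses,
                  atlas_labels = atlas_labels)
    return(list(tcs = tcs, group_maps = NULL))
  }
  red <- two_stage_pca(cohort$voxels[train_idx],
                       n_group_components = n_components)
  group_maps <- if (icasso_runs >= 2L) {
    rep <- icasso_stability(red$group_reduced, n_components,
                            n_runs = icasso_runs, seed = fold_seed)
    rep$consensus_maps
  } else {
    infomax_ica(red$group_reduced, n_components,
                seed = fold_seed)$sources
  }
  tcs <- lapply(cohort$voxels, function(v) {
    sc <- back_reconstruct(group_maps, v)
    if (!is.null(keep)) sc <- select_components(sc, keep = keep)
    sc$timecourses
  })
  list(tcs = tcs, group_maps = group_maps)
}

#' Cross-validated classification experiment on a cohort
#'
#' Runs the full evaluation protocol on a synthetic (or loaded) cohort:
#' stratified k-fold cross-validation in which, for every fold, the group
#' decomposition is fitted on the training subjects only (two-stage PCA +
#' Infomax, optionally ICASSO consensus), all subjects are
#' back-reconstructed against the training-fold group maps, connectivity
#' features are built, the classifier is trained on the training fold, and
#' the held-out fold is scored.  Metrics are reported per fold and as
#' mean +/- sd across folds, together with the pooled confusion matrix
#' over all held-out predictions.
#'
#' @param cohort a [make_cohort()] object (or a compatible list with
#'   `voxels`, `timecourses`, `labels`).
#' @param mode `"dynamic"` (windowed features + LSTM) or `"static"`
#'   (whole-course features + SVM or RF).
#' @param level `"ica"` (group ICA + dual regression), `"roi"` (atlas
#'   means; requires `atlas_labels`), or `"truth"` (ground-truth
#'   generator time courses, for calibration studies).
#' @param classifier `"lstm"`, `"svm"`, or `"rf"`; defaults to `"lstm"`
#'   for dynamic mode and `"svm"` for static.
#' @param k number of CV folds (default 10).
#' @param width,step sliding-window parameters (defaults 50 and 1 TR).
#' @param n_components group ICA dimension; defaults to the cohort's
#'   number of latent components.
#' @param keep optional component keep-list applied after
#'   back-reconstruction.
#' @param icasso_runs if >= 2, use ICASSO consensus maps per fold instead
#'   of a single Infomax run (default 0 = single run).
#' @param atlas_labels per-voxel region labels for `level = "roi"`.
#' @param positive positive-class label for sensitivity/specificity/AUC;
#'   defaults to the second factor level.
#' @param lstm_args list of extra arguments for [train_lstm()].
#' @param seed integer seed driving the fold split, per-fold ICA
#'   initialisation, and classifier training.
#' @param verbose print fold progress.
#' @return object of class `"experiment_report"`: `per_fold` (data.frame
#'   of per-fold metrics), `mean`, `sd`, `pooled` (metrics of the pooled
#'   predictions, plus `kappa`, `jaccard`, and binary `auc`),
#'   `confusion`, `predictions`, and the configuration.
#' @export
run_experiment <- function(cohort, mode = c("dynamic", "static"),
                           level = c("ica", "roi", "truth"),
                           classifier = NULL, k = 10L,
                           width = 50L, step = 1L,
                           n_components = NULL, keep = NULL,
                           icasso_runs = 0L, atlas_labels = NULL,
                           positive = NULL, lstm_args = list(),
                           seed = 1L, verbose = FALSE) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  if (is.null(classifier))
    classifier <- if (mode == "dynamic") "lstm" else "svm"
  classifier <- match.arg(classifier, c("lstm", "svm", "rf"))
  if (mode == "dynamic" && classifier != "lstm")
    stop("dynamic features are sequences; use the LSTM classifier")
  if (mode == "static" && classifier == "lstm")
    stop("static features are vectors; use the SVM or RF classifier")
  if (level == "roi" && is.null(atlas_labels))
    stop("level = 'roi' requires `atlas_labels`")

  labels <- as.factor(cohort$labels$group)
  n <- length(labels)
  if (is.null(n_components))
    n_components <- if (!is.null(cohort$maps)) nrow(cohort$maps) else
      stop("`n_components` is required when the cohort has no map count")
  if (is.null(positive)) positive <- levels(labels)[2L]

  split <- stratified_kfold(labels, k = k, seed = seed)
  pred_all <- factor(rep(NA_character_, n), levels = levels(labels))
  prob_pos <- rep(NA_real_, n)
  fold_rows <- vector("list", k)

  for (f in seq_len(k)) {
    test_idx <- split$folds[[f]]
    train_idx <- setdiff(seq_len(n), test_idx)
    fold_seed <- seed + 1000L * f
    if (verbose) message("fold ", f, "/", k)

    ft <- .fold_timecourses(cohort, train_idx, level, n_components, keep,
                            atlas_labels, fold_seed,
                            icasso_runs = icasso_runs)
    tcs <- ft$tcs

    if (mode == "dynamic") {
      plan <- plan_windows(nrow(tcs[[1L]]), width = width, step = step)
      feats <- lapply(tcs, dfc_sequence, plan = plan)
      lstm_call <- c(list(sequences = feats[train_idx],
                          labels = labels[train_idx],
                          seed = fold_seed + 1L),
                     lstm_args)
      model <- do.call(train_lstm, lstm_call)
      pred <- predict(model, feats[test_idx], type = "class")
      prob <- predict(model, feats[test_idx], type = "prob")
    } else {
      feats <- t(vapply(tcs, static_fc,
                        numeric(ncol(tcs[[1L]]) *
                                  (ncol(tcs[[1L]]) - 1L) / 2L)))
      model <- if (classifier == "svm")
        train_svm_baseline(feats[train_idx, , drop = FALSE],
                           labels[train_idx], seed = fold_seed + 1L)
      else
        train_rf_baseline(feats[train_idx, , drop = FALSE],
                          labels[train_idx], seed = fold_seed + 1L)
      pred <- predict(model, feats[test_idx, , drop = FALSE],
                      type = "class")
      prob <- predict(model, feats[test_idx, , drop = FALSE],
                      type = "prob")
    }

    pred_all[test_idx] <- pred
    if (positive %in% colnames(prob))
      prob_pos[test_idx] <- prob[, positive]
    mets <- suppressWarnings(
      binary_metrics(confusion_counts(labels[test_idx], pred, positive)))
    fold_rows[[f]] <- data.frame(fold = f, n_test = length(test_idx),
                                 t(mets))
  }

  per_fold <- do.call(rbind, fold_rows)
  metric_cols <- setdiff(names(per_fold), c("fold", "n_test"))
  mean_row <- vapply(per_fold[metric_cols], mean, 0, na.rm = TRUE)
  sd_row <- vapply(per_fold[metric_cols], stats::sd, 0, na.rm = TRUE)

  conf <- multiclass_confusion(labels, pred_all)
  pooled <- suppressWarnings(
    binary_metrics(confusion_counts(labels, pred_all, positive)))
  pooled <- c(pooled, kappa = cohen_kappa(conf),
              jaccard = jaccard_score(labels, pred_all))
  if (nlevels(labels) == 2L && !anyNA(prob_pos))
    pooled <- c(pooled,
                auc = as.numeric(roc_auc(labels, prob_pos, positive)))

  structure(list(per_fold = per_fold, mean = mean_row, sd = sd_row,
                 pooled = pooled, confusion = conf,
                 predictions = data.frame(cohort$labels,
                                          predicted = pred_all,
                                          prob_positive = prob_pos),
                 positive = positive,
                 config = list(mode = mode, level = level,
                               classifier = classifier, k = k,
                               width = width, step = step,
                               n_components = n_components, keep = keep,
                               icasso_runs = icasso_runs, seed = seed)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Experiment: %s features at the %s level, %s classifier, %d-fold CV\n",
              cfg$mode, cfg$level, toupper(cfg$classifier), cfg$k))
  cat(sprintf("  mean ACC %.3f +/- %.3f | SEN %.3f | SPE %.3f | F1 %.3f (positive = %s)\n",
              x$mean["ACC"], x$sd["ACC"], x$mean["SEN"], x$mean["SPE"],
              x$mean["F1"], x$positive))
  cat(sprintf("  pooled ACC %.3f | kappa %.3f | Jaccard %.3f%s\n",
              x$pooled["ACC"], x$pooled["kappa"], x$pooled["jaccard"],
              if (!is.na(x$pooled["auc"])) sprintf(" | AUC %.3f",
                                                   x$pooled["auc"]) else ""))
  invisible(x)
}

#' Tab-separated summary of one or more experiment reports
#'
#' @param reports named list of `"experiment_report"` objects.
#' @param path optional file to write; when `NULL` the data.frame is just
#'   returned.
#' @return data.frame with one row per report (invisibly when written).
#' @export
summarize_experiments <- function(reports, path = NULL) {
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(method = nm, mode = r$config$mode, level = r$config$level,
               classifier = r$config$classifier,
               ACC = r$mean["ACC"], ACC_sd = r$sd["ACC"],
               SEN = r$mean["SEN"], SPE = r$mean["SPE"],
               F1 = r$mean["F1"], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
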