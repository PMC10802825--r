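# Feature-selected random-forest prediction of spontaneous VT termination
# with stratified k-fold cross-validated diagnostic metrics.

#' Classifier configuration
#'
#' @param n_trees Trees per forest (default 500).
#' @param k_folds Cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment and forest fitting.
#' @param candidate_features Names of the candidate feature columns. The
#'   default is the first-10-CL variability block plus the three AR(1)
#'   stability terms.
#' @param positive_class Label treated as the positive class (default
#'   `"terminating"`: the model predicts spontaneous termination).
#' @param selection `"per_fold"` (default) re-runs feature selection inside
#'   every training fold, keeping the evaluation leakage-free; `"once"` runs
#'   a single selection pass on the full data before cross-validation, a
#'   simpler but optimistically biased protocol.
#' @param group_by_patient If `TRUE`, folds are formed over patients rather
#'   than episodes, so no patient contributes to both a training and a test
#'   fold.
#' @return List of class `vt_classifier_config`.
#' @export
classifier_config <- function(n_trees = 500L, k_folds = 10L, seed = 1L,
                              candidate_features = c("mean_cl10", "sd_cl10",
                                                     "rmssd10", "nn50_10",
                                                     "pnn50_10", "tinn10",
                                                     "ar_phi", "ar_resid_sd",
                                                     "ar_const"),
                              positive_class = "terminating",
                              selection = c("per_fold", "once"),
                              group_by_patient = FALSE) {
  stopifnot(k_folds >= 2L, length(candidate_features) >= 1L, n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees), k_folds = as.integer(k_folds),
                 seed = as.integer(seed),
                 candidate_features = candidate_features,
                 positive_class = positive_class,
                 selection = match.arg(selection),
                 group_by_patient = isTRUE(group_by_patient)),
            class = "vt_classifier_config")
}

# Drop rows with missing candidate features (degenerate AR fits), with a
# message; returns row indices kept.
complete_feature_rows <- function(features, cols) {
  keep <- stats::complete.cases(features[, cols, drop = FALSE])
  if (!all(keep))
    message(sum(!keep), " episode(s) dropped: missing feature values")
  which(keep)
}

#' Importance-based feature selection
#'
#' Fits one random forest on all candidate features and returns those whose
#' impurity (mean decrease in Gini) importance strictly exceeds the mean
#' importance across candidates. Deterministic for a fixed seed.
#'
#' @param features Feature `data.frame`.
#' @param labels Character vector of class labels (two classes, each with at
#'   least 2 episodes).
#' @param cfg A [classifier_config()].
#' @return Character vector of selected feature names (never empty: strict
#'   inequality against the mean always leaves at least one candidate out and
#'   at least one in, except the all-equal-importance corner, where the
#'   single top-ranked feature is returned).
#' @export
select_features <- function(features, labels, cfg = classifier_config()) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need two classes to select features")
  if (min(table(labels)) < 2L) stop("need at least 2 episodes per class")
  keep <- complete_feature_rows(features, cfg$candidate_features)
  x <- features[keep, cfg$candidate_features, drop = FALSE]
  y <- factor(labels[keep])
  fit <- withr::with_seed(cfg$seed,
    randomForest::randomForest(x = x, y = y, ntree = cfg$n_trees))
  imp <- randomForest::importance(fit)[, 1]
  sel <- names(imp)[imp > mean(imp)]
  if (!length(sel)) sel <- names(imp)[which.max(imp)]
  sel
}

#' Diagnostic metrics from a confusion table
#'
#' Standard definitions; any ratio with a zero denominator is reported as
#' `NA` rather than 0.
#'
#' @param tp,fp,tn,fn Non-negative counts (true/false positives/negatives).
#' @return List with `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("at least one count must be positive")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  list(accuracy = ratio(tp + tn, sum(counts)),
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       ppv = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn))
}

# Stratified fold assignment: within each class (or patient group), shuffled
# indices are dealt round-robin over folds.
assign_folds <- function(labels, k, patient = NULL, group_by_patient = FALSE) {
  n <- length(labels)
  fold <- integer(n)
  if (group_by_patient) {
    stopifnot(!is.null(patient))
    pats <- sample(unique(patient))
    pfold <- stats::setNames(rep_len(seq_len(k), length(pats)), pats)
    fold <- unname(pfold[patient])
  } else {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  }
  fold
}

#' Cross-validated evaluation of the termination classifier
#'
#' Stratified k-fold cross-validation. Within each training fold, feature
#' selection (importance greater than the mean; see [select_features()]) is
#' followed by a random-forest fit on the selected features; out-of-fold
#' predicted probabilities are pooled across folds. Classification metrics
#' are computed on the pooled predictions at the 0.5 probability threshold,
#' the AUROC from the pooled probabilities, and the accuracy CI as the
#' normal-approximation binomial interval `accuracy +/- 1.96 sqrt(p(1-p)/n)`.
#' Fully reproducible for a fixed `cfg$seed`.
#'
#' @param features Feature `data.frame` (must contain
#'   `cfg$candidate_features`; `patient_id` is required when
#'   `cfg$group_by_patient`).
#' @param labels Character labels aligned with `features` rows; defaults to
#'   `features$label`.
#' @param cfg A [classifier_config()].
#' @return Object of class `vt_eval`: list with `accuracy`, `accuracy_ci95`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `auroc`,
#'   `selected_features` (union over folds, with per-fold detail), `per_fold`
#'   data frame, and the pooled `predictions` data frame.
#' @export
cross_validate <- function(features, labels = features$label,
                           cfg = classifier_config()) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(features))
  keep <- complete_feature_rows(features, cfg$candidate_features)
  features <- features[keep, , drop = FALSE]
  labels <- labels[keep]
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("need exactly two classes")
  if (!cfg$positive_class %in% classes)
    stop("positive_class '", cfg$positive_class, "' not present in labels")
  if (min(table(labels)) < cfg$k_folds)
    stop("each class needs at least k_folds = ", cfg$k_folds,
         " episodes for stratified folds; use a smaller k")
  n <- nrow(features)
  pos <- cfg$positive_class

  withr::with_seed(cfg$seed, {
    fold <- assign_folds(labels, cfg$k_folds,
                         patient = features$patient_id,
                         group_by_patient = cfg$group_by_patient)
    sel_once <- if (cfg$selection == "once")
      select_features(features, labels, cfg) else NULL
    prob <- rep(NA_real_, n)
    fold_sel <- vector("list", cfg$k_folds)
    for (f in seq_len(cfg$k_folds)) {
      tr <- fold != f
      te <- !tr
      if (!any(te)) next
      sel <- if (cfg$selection == "once") sel_once else
        select_features(features[tr, , drop = FALSE], labels[tr], cfg)
      fold_sel[[f]] <- sel
      rf <- randomForest::randomForest(
        x = features[tr, sel, drop = FALSE], y = factor(labels[tr]),
        ntree = cfg$n_trees)
      prob[te] <- stats::predict(
        rf, features[te, sel, drop = FALSE], type = "prob")[, pos]
    }
  })

  pred_pos <- prob >= 0.5
  truth_pos <- labels == pos
  cm <- confusion_metrics(tp = sum(pred_pos & truth_pos),
                          fp = sum(pred_pos & !truth_pos),
                          tn = sum(!pred_pos & !truth_pos),
                          fn = sum(!pred_pos & truth_pos))
  auroc <- as.numeric(pROC::auc(
    pROC::roc(response = truth_pos, predictor = prob,
              levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
  half <- 1.96 * sqrt(cm$accuracy * (1 - cm$accuracy) / n)
  per_fold <- do.call(rbind, lapply(seq_len(cfg$k_folds), function(f) {
    te <- fold == f
    data.frame(fold = f, n = sum(te),
               accuracy = if (any(te))
                 mean((prob[te] >= 0.5) == truth_pos[te]) else NA_real_,
               selected = paste(fold_sel[[f]], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(accuracy = cm$accuracy,
         accuracy_ci95 = c(low = max(0, cm$accuracy - half),
                           high = min(1, cm$accuracy + half)),
         sensitivity = cm$sensitivity, specificity = cm$specificity,
         ppv = cm$ppv, npv = cm$npv, auroc = auroc,
         selected_features = sort(unique(unlist(fold_sel %||% sel_once))),
         per_fold = per_fold,
         predictions = data.frame(episode_id = features$episode_id %||%
                                    as.character(seq_len(n)),
                                  label = labels, prob = prob, fold = fold,
                                  stringsAsFactors = FALSE),
         config = cfg),
    class = "vt_eval")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vt_eval <- function(x, ...) {
  cat(sprintf(paste0("<vt_eval> accuracy %.3f (95%% CI %.3f-%.3f), ",
                     "sens %.3f, spec %.3f, PPV %.3f, NPV %.3f, AUROC %.3f\n"),
              x$accuracy, x$accuracy_ci95["low"], x$accuracy_ci95["high"],
              x$sensitivity, x$specificity, x$ppv, x$npv, x$auroc))
  cat("selected features:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}
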