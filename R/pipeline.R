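# End-to-end pipeline and figure helpers.

#' Poincare plot of first-10-CL lag pairs
#'
#' Scatter of each cycle length against the next over the first 10 CLs of
#' every eligible episode (9 pairs per episode), coloured by outcome, with
#' the identity line.
#'
#' @param x A `vt_cohort`.
#' @param n First-window length (default 10).
#' @return Invisibly, the data frame of plotted pairs.
#' @export
plot_poincare <- function(x, n = 10L) {
  stopifnot(inherits(x, "vt_cohort"))
  elig <- Filter(function(e) length(e$cl_ms) >= max(n, MIN_ELIGIBLE_BEATS),
                 x$episodes)
  pairs <- do.call(rbind, lapply(elig, function(e) {
    w <- first_segment(e, n)
    data.frame(cl = w[-n], cl_next = w[-1], label = e$label,
               stringsAsFactors = FALSE)
  }))
  cols <- c(terminating = "#1f77b4", sustained = "#d62728",
            unknown = "grey50")
  graphics::plot(pairs$cl, pairs$cl_next, col = cols[pairs$label], pch = 19,
                 cex = 0.6, xlab = "CL (ms)", ylab = "CL + 1 (ms)",
                 main = sprintf("Poincare plot, first %d CLs", n))
  graphics::abline(0, 1, col = "grey40")
  graphics::legend("topleft", legend = names(cols[unique(pairs$label)]),
                   col = cols[unique(pairs$label)], pch = 19, bty = "n")
  invisible(pairs)
}

#' Box plots of selected features by outcome group
#'
#' @param features Feature table from [cohort_features()].
#' @param which_features Feature columns to plot (default: the first-10-CL
#'   SD, TINN and AR coefficient).
#' @return Invisibly, `features`.
#' @export
plot_feature_boxes <- function(features,
                               which_features = c("sd_cl10", "tinn10",
                                                  "ar_phi")) {
  stopifnot(all(which_features %in% names(features)))
  old <- graphics::par(mfrow = c(1, length(which_features)))
  on.exit(graphics::par(old))
  for (f in which_features)
    graphics::boxplot(features[[f]] ~ factor(features$label), xlab = "",
                      ylab = f, col = c("#d62728", "#1f77b4"))
  invisible(features)
}

#' Three-dimensional feature scatter
#'
#' Cloud plot of first-10-CL SD, TINN and AR coefficient coloured by outcome
#' (requires the `lattice` package).
#'
#' @param features Feature table from [cohort_features()].
#' @return The lattice plot object.
#' @export
plot_feature_cloud <- function(features) {
  if (!requireNamespace("lattice", quietly = TRUE))
    stop("plot_feature_cloud requires the 'lattice' package")
  cols <- c(terminating = "#1f77b4", sustained = "#d62728")
  lattice::cloud(sd_cl10 ~ tinn10 * ar_phi, data = features,
                 groups = features$label, pch = 19,
                 par.settings = list(superpose.symbol = list(col = cols)),
                 auto.key = TRUE)
}

#' Write cross-validation metrics as JSON
#'
#' @param eval A `vt_eval` from [cross_validate()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(eval, path) {
  stopifnot(inherits(eval, "vt_eval"))
  jsonlite::write_json(
    list(accuracy = eval$accuracy,
         accuracy_ci95 = as.list(eval$accuracy_ci95),
         sensitivity = eval$sensitivity, specificity = eval$specificity,
         ppv = eval$ppv, npv = eval$npv, auroc = eval$auroc,
         selected_features = as.list(eval$selected_features),
         per_fold = eval$per_fold),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Run the full analysis pipeline on a cohort file
#'
#' Reads the cohort, extracts per-episode features, compares the two outcome
#' groups, cross-validates the termination classifier, and writes
#' `features.csv`, `compare.md`, `metrics.json`, `per_fold.csv` and (when
#' `plots = TRUE`) `poincare.png`, `feature_boxplots.png` and
#' `feature_cloud.png` into `out_dir`.
#'
#' @param cohort_csv Path to a long-format cohort CSV (see [read_cohort()]).
#' @param out_dir Output directory, created if absent.
#' @param seed Integer seed for the classifier.
#' @param k_folds,n_trees,selection,group_by_patient Passed to
#'   [classifier_config()].
#' @param bin_width TINN histogram bin width (ms).
#' @param plots Whether to write figure files.
#' @return Invisibly, a list with `features`, `comparison` and `eval`.
#' @export
run_pipeline <- function(cohort_csv, out_dir, seed = 1L, k_folds = 10L,
                         n_trees = 500L, bin_width = 7.8125,
                         selection = "per_fold", group_by_patient = FALSE,
                         plots = TRUE) {
  ch <- read_cohort(cohort_csv, strict = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  features <- cohort_features(ch, bin_width = bin_width)
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  comparison <- compare_groups(features)
  write_comparison(comparison, file.path(out_dir, "compare.md"))
  cfg <- classifier_config(n_trees = n_trees, k_folds = k_folds, seed = seed,
                           selection = selection,
                           group_by_patient = group_by_patient)
  eval <- cross_validate(features, cfg = cfg)
  write_metrics_json(eval, file.path(out_dir, "metrics.json"))
  utils::write.csv(eval$per_fold, file.path(out_dir, "per_fold.csv"),
                   row.names = FALSE)
  if (plots) {
    grDevices::png(file.path(out_dir, "poincare.png"), 700, 700)
    plot_poincare(ch); grDevices::dev.off()
    grDevices::png(file.path(out_dir, "feature_boxplots.png"), 900, 400)
    plot_feature_boxes(features); grDevices::dev.off()
    if (requireNamespace("lattice", quietly = TRUE)) {
      grDevices::png(file.path(out_dir, "feature_cloud.png"), 700, 700)
      print(plot_feature_cloud(features)); grDevices::dev.off()
    }
  }
  invisible(list(features = features, comparison = comparison, eval = eval))
}
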