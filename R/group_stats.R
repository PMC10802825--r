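# Group-level comparison of per-episode features between spontaneously
# terminating and sustained episodes.

#' Choose between Student's t-test and Mann-Whitney U test
#'
#' Parametric comparison is used only when both groups pass a Shapiro-Wilk
#' normality check at `alpha_norm`; otherwise (including degenerate cases such
#' as constant groups, where the normality test is undefined) the rank-based
#' test is chosen.
#'
#' @param values_a,values_b Numeric vectors, each with at least 3 values.
#' @param alpha_norm Significance level of the normality gate (default 0.05).
#' @return `"t_test"` or `"mann_whitney"`.
#' @export
choose_test <- function(values_a, values_b, alpha_norm = 0.05) {
  if (length(values_a) < 3L || length(values_b) < 3L)
    stop("need at least 3 values per group")
  normal_p <- function(v) {
    tryCatch(stats::shapiro.test(v)$p.value, error = function(cond) 0)
  }
  if (normal_p(values_a) > alpha_norm && normal_p(values_b) > alpha_norm)
    "t_test" else "mann_whitney"
}

#' Compare features between terminating and sustained episodes
#'
#' For every numeric feature column, runs a two-sided Student's t-test or
#' Mann-Whitney U test (chosen per feature by [choose_test()]) between the
#' two label groups, and summarises each group as mean +/- SD (parametric
#' rows) or median (IQR) (rank-based rows). Episodes with a missing value for
#' a feature are excluded from that feature's row. Per-feature p-values are
#' reported unadjusted by default, mirroring per-feature reporting practice;
#' `adjust = "BH"` switches on Benjamini-Hochberg correction.
#'
#' @param features Feature `data.frame` from [cohort_features()], or any
#'   data frame with numeric feature columns.
#' @param labels Character vector of episode labels aligned with `features`
#'   rows; defaults to `features$label`. Exactly the two labels
#'   `"terminating"` and `"sustained"` must both be present.
#' @param alpha_norm Normality-gate level passed to [choose_test()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `data.frame` of class `vt_comparison`: one row per feature with
#'   columns `feature`, `summary_terminating`, `summary_sustained`,
#'   `test_used`, `p_value`.
#' @export
compare_groups <- function(features, labels = features$label,
                           alpha_norm = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(features))
  if (!all(c("terminating", "sustained") %in% labels))
    stop("both 'terminating' and 'sustained' labels must be present")
  num_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  if (!length(num_cols)) stop("no numeric feature columns")
  rows <- lapply(num_cols, function(f) {
    a <- features[[f]][labels == "terminating"]
    b <- features[[f]][labels == "sustained"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    test <- choose_test(a, b, alpha_norm = alpha_norm)
    if (test == "t_test") {
      p <- stats::t.test(a, b, alternative = "two.sided")$p.value
      sa <- sprintf("%.2f ± %.2f", mean(a), stats::sd(a))
      sb <- sprintf("%.2f ± %.2f", mean(b), stats::sd(b))
    } else {
      p <- stats::wilcox.test(a, b, alternative = "two.sided",
                              exact = FALSE)$p.value
      qa <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
      qb <- stats::quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
      sa <- sprintf("%.2f (%.2f-%.2f)", qa[2], qa[1], qa[3])
      sb <- sprintf("%.2f (%.2f-%.2f)", qb[2], qb[1], qb[3])
    }
    data.frame(feature = f, summary_terminating = sa, summary_sustained = sb,
               test_used = test, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("vt_comparison", "data.frame")
  out
}

#' Write a group-comparison report
#'
#' Writes the [compare_groups()] table as CSV or a pipe-delimited Markdown
#' table (chosen from the file extension: `.md`/`.markdown` for Markdown,
#' anything else CSV).
#'
#' @param comparison A `vt_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "vt_comparison"))
  if (grepl("\\.(md|markdown)$", path, ignore.case = TRUE)) {
    header <- c("| Feature | Terminating | Sustained | Test | P-value |",
                "|---|---|---|---|---|")
    body <- sprintf("| %s | %s | %s | %s | %.3g |",
                    comparison$feature, comparison$summary_terminating,
                    comparison$summary_sustained, comparison$test_used,
                    comparison$p_value)
    writeLines(c(header, body), path)
  } else {
    utils::write.csv(comparison, path, row.names = FALSE)
  }
  invisible(path)
}
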