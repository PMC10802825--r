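# Per-episode cycle-length variability and morphology features.
#
# All standard deviations use the sample (n-1) denominator, the usual
# convention for short-window HRV reporting.

#' First-n cycle-length window of an episode
#'
#' @param e A `vt_episode`.
#' @param n Window length (default 10, the analysis window used throughout:
#'   CL1 through CL10, where CL1 is the PVC-coupled interval).
#' @return Numeric vector of the first `n` cycle lengths, in order.
#' @export
first_segment <- function(e, n = 10L) {
  stopifnot(inherits(e, "vt_episode"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  if (length(e$cl_ms) < n)
    stop("episode '", e$episode_id, "' has ", length(e$cl_ms),
         " cycle lengths; cannot take the first ", n)
  e$cl_ms[seq_len(n)]
}

#' Mean, SD and minimum of a cycle-length window
#'
#' @param window Numeric vector of cycle lengths (ms), length >= 2.
#' @return List with `mean`, `sd` (sample, n-1 denominator) and `min`, all ms.
#' @export
basic_stats <- function(window) {
  window <- as.numeric(window)
  if (length(window) < 2L) stop("need at least 2 cycle lengths (sd undefined)")
  list(mean = mean(window), sd = stats::sd(window), min = min(window))
}

#' Successive-difference variability metrics (RMSSD, NN50, pNN50)
#'
#' Over the successive differences `d_i = x[i+1] - x[i]`:
#' RMSSD is `sqrt(mean(d^2))`; NN50 counts differences with `|d| > threshold`;
#' pNN50 is that count as a percentage of the `n - 1` differences.
#'
#' @param window Numeric vector of cycle lengths (ms), length >= 2.
#' @param threshold Absolute-difference threshold in ms (default 50).
#' @return List with `rmssd` (ms), `nn50` (count) and `pnn50` (percent).
#' @export
successive_diff_metrics <- function(window, threshold = 50) {
  window <- as.numeric(window)
  if (length(window) < 2L) stop("need at least 2 cycle lengths")
  d <- diff(window)
  nn50 <- sum(abs(d) > threshold)
  list(rmssd = sqrt(mean(d^2)), nn50 = nn50, pnn50 = 100 * nn50 / length(d))
}

#' Triangular interpolation of the cycle-length histogram (TINN)
#'
#' The window is binned into a histogram with bins of width `bin_width`
#' aligned to 0 ms. With `X` the centre of the modal bin (ties broken towards
#' the lowest bin) and `D(X)` its count, TINN is `M - N` for the bin-edge pair
#' `N < X < M` whose triangle — zero outside `[N, M]`, peaking at `(X, D(X))`,
#' evaluated at bin centres — minimises the summed squared error against the
#' histogram over the occupied span. Candidate edges run over the occupied
#' span only, so `bin_width <= TINN <= range + 2 * bin_width`. Ties in the
#' error are broken towards the narrowest triangle. If all values fall in one
#' bin the search degenerates to a single zero-error triangle of one bin
#' width.
#'
#' The default bin width is the conventional 1/128 s HRV histogram bin.
#' On 10-beat windows the histogram is sparse, so TINN is sensitive to
#' `bin_width`; the parameter is exposed for that reason.
#'
#' @param window Numeric vector of cycle lengths (ms), length >= 2.
#' @param bin_width Histogram bin width in ms (default 7.8125 = 1000/128).
#' @return TINN in ms.
#' @export
tinn <- function(window, bin_width = 7.8125) {
  window <- as.numeric(window)
  if (length(window) < 2L) stop("need at least 2 cycle lengths")
  if (bin_width <= 0) stop("bin_width must be positive")
  k <- floor(window / bin_width)            # bin index of each value
  kmin <- min(k); kmax <- max(k)
  counts <- tabulate(k - kmin + 1L, nbins = kmax - kmin + 1L)
  centers <- (seq.int(kmin, kmax) + 0.5) * bin_width
  peak <- which.max(counts)                 # ties -> lowest bin
  X <- centers[peak]; DX <- counts[peak]
  left_edges <- seq.int(kmin, kmin + peak - 1L) * bin_width      # edges <= left edge of peak
  right_edges <- seq.int(kmin + peak, kmax + 1L) * bin_width     # edges >= right edge of peak
  best_err <- Inf; best_width <- NA_real_
  for (N in left_edges) {
    up <- ifelse(centers >= N & centers <= X, DX * (centers - N) / (X - N), 0)
    for (M in right_edges) {
      tri <- up
      right <- centers > X & centers <= M
      tri[right] <- DX * (M - centers[right]) / (M - X)
      tri[centers > M] <- 0
      err <- sum((counts - tri)^2)
      if (err < best_err - 1e-12 ||
          (abs(err - best_err) <= 1e-12 && (M - N) < best_width)) {
        best_err <- err
        best_width <- M - N
      }
    }
  }
  best_width
}

#' Poincare plot dispersion (SD1, SD2)
#'
#' Over the lag-1 pairs `(x[i], x[i+1])`, SD1 is the sample SD of
#' `(x[i+1] - x[i]) / sqrt(2)` (dispersion perpendicular to the identity
#' line) and SD2 the sample SD of `(x[i+1] + x[i]) / sqrt(2)` (dispersion
#' along it). The rotated-coordinate form is used rather than
#' `sd2^2 = 2 sdnn^2 - sd1^2`, which can go negative on 10-beat windows.
#'
#' @param window Numeric vector of cycle lengths (ms), length >= 3.
#' @return List with `sd1` and `sd2`, both ms and non-negative.
#' @export
poincare <- function(window) {
  window <- as.numeric(window)
  n <- length(window)
  if (n < 3L) stop("need at least 3 cycle lengths (2 lag pairs)")
  x <- window[-n]; y <- window[-1]
  list(sd1 = stats::sd((y - x) / sqrt(2)), sd2 = stats::sd((y + x) / sqrt(2)))
}

#' Initiation-to-shortest cycle-length dynamics
#'
#' Locates the first occurrence of the episode's minimum CL and reports:
#' the time to reach it (cumulative CL sum through the minimum beat,
#' inclusive, in seconds), the percentage of beats elapsed, and the
#' percentage decrease from CL1 to the minimum. Since the minimum can be no
#' larger than CL1, the percentage change is always >= 0.
#'
#' @param e A `vt_episode`.
#' @return List with `time_to_min_s`, `pct_beats_to_min`,
#'   `pct_change_first_to_min`.
#' @export
initiation_to_shortest <- function(e) {
  stopifnot(inherits(e, "vt_episode"))
  cl <- e$cl_ms
  idx <- which.min(cl)                      # first occurrence
  list(time_to_min_s = sum(cl[seq_len(idx)]) / 1000,
       pct_beats_to_min = 100 * idx / length(cl),
       pct_change_first_to_min = 100 * (cl[1] - cl[idx]) / cl[1])
}

#' Whole-episode cycle-length standard deviation
#'
#' Sample SD (n-1 denominator) over the full CL series, the within-episode
#' variability measure reported alongside the first-10-CL metrics.
#'
#' @param e A `vt_episode`.
#' @return SD in ms.
#' @export
episode_sd <- function(e) {
  stopifnot(inherits(e, "vt_episode"))
  if (length(e$cl_ms) < 2L) stop("need at least 2 cycle lengths")
  stats::sd(e$cl_ms)
}

FEATURE_NAMES <- c("mean_cl10", "sd_cl10", "rmssd10", "nn50_10", "pnn50_10",
                   "tinn10", "sd1_10", "sd2_10", "ar_phi", "ar_const",
                   "ar_resid_sd", "first_cl", "min_cl", "min_cl10", "cl10th",
                   "episode_sd", "episode_duration_s", "n_beats",
                   "time_to_min_s", "pct_beats_to_min",
                   "pct_change_first_to_min")

#' Extract the full per-episode feature vector
#'
#' Computes every variability, morphology and AR(1)-stability feature from
#' the first 10 cycle lengths, plus whole-episode descriptors. Episodes whose
#' first-10 window is constant have no defined AR(1) fit; with
#' `on_degenerate = "na"` (default) the three AR features are returned as
#' `NA` so the caller can exclude the episode, with `"error"` the error
#' propagates.
#'
#' @param e A `vt_episode` with at least 11 cycle lengths.
#' @param bin_width TINN histogram bin width in ms.
#' @param on_degenerate How to handle a degenerate (constant-window) AR fit.
#' @return One-row `data.frame` with `episode_id`, `patient_id`, `label` and
#'   the 21 numeric features.
#' @export
extract_features <- function(e, bin_width = 7.8125,
                             on_degenerate = c("na", "error")) {
  stopifnot(inherits(e, "vt_episode"))
  on_degenerate <- match.arg(on_degenerate)
  if (length(e$cl_ms) < MIN_ELIGIBLE_BEATS)
    stop("episode '", e$episode_id, "' has fewer than ", MIN_ELIGIBLE_BEATS,
         " cycle lengths and is not analysis-eligible")
  w <- first_segment(e, 10L)
  bs <- basic_stats(w)
  sdm <- successive_diff_metrics(w)
  pc <- poincare(w)
  its <- initiation_to_shortest(e)
  ar <- tryCatch(fit_ar1(w), error = function(cond) {
    if (on_degenerate == "error") stop(cond)
    message("episode '", e$episode_id, "': degenerate AR(1) fit (",
            conditionMessage(cond), "); AR features set to NA")
    list(phi = NA_real_, c = NA_real_, resid_sd = NA_real_)
  })
  data.frame(
    episode_id = e$episode_id, patient_id = e$patient_id, label = e$label,
    mean_cl10 = bs$mean, sd_cl10 = bs$sd, rmssd10 = sdm$rmssd,
    nn50_10 = sdm$nn50, pnn50_10 = sdm$pnn50,
    tinn10 = tinn(w, bin_width = bin_width),
    sd1_10 = pc$sd1, sd2_10 = pc$sd2,
    ar_phi = ar$phi, ar_const = ar$c, ar_resid_sd = ar$resid_sd,
    first_cl = e$cl_ms[1], min_cl = min(e$cl_ms), min_cl10 = bs$min,
    cl10th = e$cl_ms[10], episode_sd = episode_sd(e),
    episode_duration_s = episode_duration_s(e), n_beats = length(e$cl_ms),
    time_to_min_s = its$time_to_min_s,
    pct_beats_to_min = its$pct_beats_to_min,
    pct_change_first_to_min = its$pct_change_first_to_min,
    stringsAsFactors = FALSE)
}

#' Feature table for a whole cohort
#'
#' Applies [extract_features()] to every analysis-eligible episode (>= 11
#' cycle lengths). Shorter episodes are skipped with a message.
#'
#' @param x A `vt_cohort`.
#' @param bin_width TINN histogram bin width in ms.
#' @return `data.frame`, one row per eligible episode.
#' @export
cohort_features <- function(x, bin_width = 7.8125) {
  stopifnot(inherits(x, "vt_cohort"))
  rows <- list()
  for (e in x$episodes) {
    if (length(e$cl_ms) < MIN_ELIGIBLE_BEATS) {
      message("skipping episode '", e$episode_id, "': fewer than ",
              MIN_ELIGIBLE_BEATS, " cycle lengths")
      next
    }
    rows[[length(rows) + 1L]] <- extract_features(e, bin_width = bin_width)
  }
  if (!length(rows)) stop("no analysis-eligible episodes in cohort")
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
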