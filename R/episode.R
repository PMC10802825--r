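#' @keywords internal
"_PACKAGE"

VT_LABELS <- c("terminating", "sustained", "unknown")

# Minimum number of cycle lengths for an episode to enter the first-10-CL
# analyses ("longer than 10 CLs" read as strictly greater).
MIN_ELIGIBLE_BEATS <- 11L

# Physiological plausibility band for a VT cycle length (ms); values outside
# trigger a warning, not an error, because device exports occasionally carry
# sensing artefacts that the analyst may still wish to inspect.
CL_PLAUSIBLE_MS <- c(100, 1000)

#' Construct a ventricular tachycardia episode
#'
#' An episode is an ordered series of device-measured cycle lengths (CL, in
#' milliseconds). Element 1 of `cl_ms` is CL1, the interval between the
#' initiating premature ventricular contraction (PVC) and the first VT beat;
#' subsequent elements are the device-measured beat-to-beat intervals.
#'
#' @param episode_id Character scalar, unique within a cohort.
#' @param patient_id Character scalar.
#' @param label One of `"terminating"` (episode self-terminated without
#'   therapy), `"sustained"` (required anti-tachycardia pacing or shock), or
#'   `"unknown"`.
#' @param cl_ms Numeric vector of positive cycle lengths in milliseconds,
#'   ordered by beat; `cl_ms[1]` is the PVC-coupled CL1.
#' @param zone_rate_bpm Optional positive scalar: programmed rate of the
#'   slowest therapy zone (device metadata, carried through unused).
#' @param detection_time_s Optional positive scalar: programmed detection
#'   time of the slowest therapy zone (device metadata).
#' @param strict If `TRUE`, require at least 11 CLs (analysis eligibility).
#'
#' @return An object of class `vt_episode`.
#' @examples
#' e <- episode("F1", "P01", "unknown", c(373, 375, 360, 373))
#' episode_duration_s(e)
#' @export
episode <- function(episode_id, patient_id, label, cl_ms,
                    zone_rate_bpm = NA_real_, detection_time_s = NA_real_,
                    strict = FALSE) {
  stopifnot(is.character(episode_id), length(episode_id) == 1L,
            is.character(patient_id), length(patient_id) == 1L)
  label <- match.arg(label, VT_LABELS)
  cl_ms <- as.numeric(cl_ms)
  if (length(cl_ms) == 0L)
    stop("episode '", episode_id, "': cl_ms must contain at least one cycle length")
  if (anyNA(cl_ms) || any(cl_ms <= 0))
    stop("episode '", episode_id, "': all cycle lengths must be positive and non-missing")
  if (any(cl_ms < CL_PLAUSIBLE_MS[1] | cl_ms > CL_PLAUSIBLE_MS[2]))
    warning("episode '", episode_id, "': cycle lengths outside the plausible ",
            CL_PLAUSIBLE_MS[1], "-", CL_PLAUSIBLE_MS[2], " ms range", call. = FALSE)
  if (strict && length(cl_ms) < MIN_ELIGIBLE_BEATS)
    stop("episode '", episode_id, "': only ", length(cl_ms),
         " cycle lengths; analysis-eligible episodes need >= ", MIN_ELIGIBLE_BEATS)
  if (!is.na(zone_rate_bpm) && zone_rate_bpm <= 0)
    stop("zone_rate_bpm must be positive")
  if (!is.na(detection_time_s) && detection_time_s <= 0)
    stop("detection_time_s must be positive")
  structure(
    list(episode_id = episode_id, patient_id = patient_id, label = label,
         cl_ms = cl_ms, zone_rate_bpm = as.numeric(zone_rate_bpm),
         detection_time_s = as.numeric(detection_time_s)),
    class = "vt_episode")
}

#' @export
print.vt_episode <- function(x, ...) {
  cat(sprintf("<vt_episode %s> patient %s, label %s, %d beats, %.3f s\n",
              x$episode_id, x$patient_id, x$label, length(x$cl_ms),
              episode_duration_s(x)))
  invisible(x)
}

#' Episode duration in seconds
#'
#' The total episode duration is the sum of its cycle lengths, converted from
#' milliseconds to seconds.
#'
#' @param e A `vt_episode`.
#' @return Duration in seconds.
#' @export
episode_duration_s <- function(e) {
  stopifnot(inherits(e, "vt_episode"))
  sum(e$cl_ms) / 1000
}

#' Construct a cohort of episodes
#'
#' @param episodes List of `vt_episode` objects with unique `episode_id`s.
#' @param provenance Free-text provenance (source file, or generator seed and
#'   parameter digest).
#' @return An object of class `vt_cohort`.
#' @export
cohort <- function(episodes, provenance = "") {
  stopifnot(is.list(episodes),
            all(vapply(episodes, inherits, logical(1), "vt_episode")))
  ids <- vapply(episodes, `[[`, character(1), "episode_id")
  if (anyDuplicated(ids))
    stop("duplicate episode_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(episodes = episodes, provenance = provenance),
            class = "vt_cohort")
}

#' @export
print.vt_cohort <- function(x, ...) {
  labs <- vapply(x$episodes, `[[`, character(1), "label")
  cat(sprintf("<vt_cohort> %d episodes (%s)\n", length(x$episodes),
              paste(sprintf("%s: %d", names(table(labs)), table(labs)),
                    collapse = ", ")))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.vt_cohort <- function(x) length(x$episodes)

#' Episode labels of a cohort
#' @param x A `vt_cohort`.
#' @return Character vector of labels, one per episode.
#' @export
cohort_labels <- function(x) {
  stopifnot(inherits(x, "vt_cohort"))
  vapply(x$episodes, `[[`, character(1), "label")
}

COHORT_COLUMNS <- c("episode_id", "patient_id", "label", "beat_index", "cl_ms")

#' Read a cohort from long-format CSV
#'
#' The file must have header `episode_id,patient_id,label,beat_index,cl_ms`,
#' one row per beat, with `beat_index` contiguous from 0 within each episode.
#' Row order is irrelevant; beats are reordered by `beat_index`.
#'
#' @param path CSV file path.
#' @param strict If `TRUE` (default), any invariant violation (analysis
#'   eligibility < 11 CLs, non-positive CL, bad label) is an error. If
#'   `FALSE`, episodes with invalid values are dropped with a message; short
#'   episodes are retained (eligibility is enforced again at feature
#'   extraction).
#' @return A `vt_cohort`.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("format error: missing column(s) ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L)
    return(cohort(list(), provenance = path))
  episodes <- list()
  # canonical episode order (by id), so shuffled rows yield the same cohort
  for (id in sort(unique(as.character(df$episode_id)))) {
    rows <- df[df$episode_id == id, , drop = FALSE]
    rows <- rows[order(rows$beat_index), , drop = FALSE]
    if (!identical(as.integer(rows$beat_index), seq_len(nrow(rows)) - 1L))
      stop("format error: beat_index not contiguous from 0 in episode '", id, "'")
    pid <- unique(rows$patient_id)
    lab <- unique(rows$label)
    if (length(pid) != 1L || length(lab) != 1L)
      stop("format error: inconsistent patient_id/label within episode '", id, "'")
    e <- tryCatch(
      episode(as.character(id), as.character(pid), lab, rows$cl_ms,
              strict = strict),
      error = function(cond) cond)
    if (inherits(e, "error")) {
      if (strict) stop("validation error: ", conditionMessage(e))
      message("dropping episode '", id, "': ", conditionMessage(e))
    } else {
      episodes[[length(episodes) + 1L]] <- e
    }
  }
  cohort(episodes, provenance = path)
}

#' Write a cohort to long-format CSV
#'
#' Cycle lengths are serialized with full double precision, so
#' `read_cohort(write_cohort(x, f))` reproduces ids, labels and CL values
#' bit-exactly.
#'
#' @param x A `vt_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "vt_cohort"))
  rows <- lapply(x$episodes, function(e) {
    data.frame(episode_id = e$episode_id, patient_id = e$patient_id,
               label = e$label, beat_index = seq_along(e$cl_ms) - 1L,
               cl_ms = sprintf("%.17g", e$cl_ms),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) df <- as.data.frame(stats::setNames(rep(list(character(0)),
                                                           5), COHORT_COLUMNS))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(cond) cond, warning = function(cond) cond)
  if (!isTRUE(ok)) stop("I/O error writing '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Read an optional episode metadata sidecar
#'
#' JSON object keyed by `episode_id`, each entry optionally carrying
#' `zone_rate_bpm` and `detection_time_s`. Matching episodes in the cohort
#' get the metadata attached; unmatched keys are ignored with a message.
#'
#' @param x A `vt_cohort`.
#' @param path JSON file path.
#' @return The updated `vt_cohort`.
#' @export
attach_metadata <- function(x, path) {
  stopifnot(inherits(x, "vt_cohort"))
  meta <- jsonlite::read_json(path)
  ids <- vapply(x$episodes, `[[`, character(1), "episode_id")
  for (key in names(meta)) {
    i <- match(key, ids)
    if (is.na(i)) { message("metadata key '", key, "' matches no episode"); next }
    m <- meta[[key]]
    if (!is.null(m$zone_rate_bpm)) x$episodes[[i]]$zone_rate_bpm <- as.numeric(m$zone_rate_bpm)
    if (!is.null(m$detection_time_s)) x$episodes[[i]]$detection_time_s <- as.numeric(m$detection_time_s)
  }
  x
}
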