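#' Multi-subject epoched EEG container
#'
#' Constructs and validates an `eeg_epochs` object, the in-memory model of a
#' full multi-subject study: for every (subject, condition) a
#' trials x sensors x timepoints array of potentials in microvolts, on shared
#' sensor and time axes.
#'
#' @param data named list, one element per subject; each element a named list
#'   of conditions holding a 3-d numeric array with dimensions
#'   (trials, sensors, timepoints).
#' @param sensor_names character vector naming the sensor axis.
#' @param times numeric vector of timepoint positions in ms; must be strictly
#'   increasing with a constant step equal to `1000 / sampling_rate`.
#' @param sampling_rate sampling rate in Hz.
#' @return an object of class `eeg_epochs` with fields `subjects`,
#'   `conditions`, `data`, `sensor_names`, `times`, `sampling_rate`.
#' @examples
#' x <- array(rnorm(2 * 4 * 10), c(2, 4, 10))
#' ep <- eeg_epochs(list(s1 = list(A = x, B = x)),
#'                  sensor_names = paste0("E", 1:4),
#'                  times = seq(0, 90, by = 10), sampling_rate = 100)
#' ep
#' @export
eeg_epochs <- function(data, sensor_names, times, sampling_rate) {
  if (!is.list(data) || length(data) == 0 || is.null(names(data)))
    stopf("'data' must be a non-empty named list of subjects")
  subjects <- names(data)
  conds <- names(data[[1]])
  if (is.null(conds) || length(conds) == 0)
    stopf("each subject must hold a named list of condition arrays")
  n_sensors <- length(sensor_names)
  n_times <- length(times)
  if (n_sensors < 2L) stopf("at least 2 sensors are required")
  if (!is.numeric(times) || n_times < 2L)
    stopf("'times' must be a numeric vector of length >= 2")
  steps <- diff(times)
  if (any(steps <= 0)) stopf("'times' must be strictly increasing")
  if (max(steps) - min(steps) > 1e-9)
    stopf("'times' must have a constant step (tolerance 1e-9 ms)")
  if (abs(steps[1] - 1000 / sampling_rate) > 1e-6)
    stopf("'times' step (%g ms) does not match sampling_rate %g Hz",
          steps[1], sampling_rate)
  for (s in subjects) {
    if (!identical(sort(names(data[[s]])), sort(conds)))
      stopf("subject '%s' does not have the same conditions as subject '%s'",
            s, subjects[1])
    for (cn in conds) {
      a <- data[[s]][[cn]]
      if (!is.array(a) || length(dim(a)) != 3L)
        stopf("block (%s, %s) is not a 3-d array", s, cn)
      d <- dim(a)
      if (d[1] < 1L) stopf("block (%s, %s) has no trials", s, cn)
      if (d[2] != n_sensors)
        stopf("block (%s, %s) has %d sensors, expected %d", s, cn, d[2], n_sensors)
      if (d[3] != n_times)
        stopf("block (%s, %s) has %d timepoints, expected %d", s, cn, d[3], n_times)
    }
    # keep condition order aligned across subjects
    data[[s]] <- data[[s]][conds]
  }
  structure(list(subjects = subjects, conditions = conds, data = data,
                 sensor_names = as.character(sensor_names),
                 times = as.numeric(times),
                 sampling_rate = as.numeric(sampling_rate)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  tr <- range(vapply(x$data, function(s) vapply(s, function(a) dim(a)[1], 0L), integer(length(x$conditions))))
  cat(sprintf("<eeg_epochs> %d subjects, %d conditions (%s)\n",
              length(x$subjects), length(x$conditions),
              paste(x$conditions, collapse = ", ")))
  cat(sprintf("  %d sensors, %d timepoints (%g..%g ms @ %g Hz), %s trials/block\n",
              length(x$sensor_names), length(x$times), min(x$times),
              max(x$times), x$sampling_rate,
              if (tr[1] == tr[2]) tr[1] else paste0(tr[1], "-", tr[2])))
  if (isTRUE(attr(x, "average_referenced"))) cat("  average-referenced\n")
  invisible(x)
}

#' Analysis target definition
#'
#' Declarative description of what to analyze: the conditions to keep, the
#' pairwise comparisons between them, the epoch time range and the window
#' length for windowed statistics.
#'
#' @param conditions character vector of condition labels.
#' @param comparisons list of ordered label pairs, e.g.
#'   `list(c("famous", "scrambled"))`.
#' @param time_range numeric `[start_ms, end_ms]`, half-open on the right.
#' @param window_ms window length in ms for windowed analyses.
#' @return object of class `analysis_target`.
#' @export
analysis_target <- function(conditions, comparisons = list(), time_range,
                            window_ms = NULL) {
  conditions <- as.character(conditions)
  comparisons <- lapply(comparisons, as.character)
  for (cmp in comparisons) {
    if (length(cmp) != 2L)
      stopf("each comparison must be an ordered pair of labels")
    missing <- setdiff(cmp, conditions)
    if (length(missing))
      stopf("comparison label(s) %s not in target conditions (%s)",
            paste(missing, collapse = ", "), paste(conditions, collapse = ", "))
  }
  if (length(time_range) != 2L || time_range[1] >= time_range[2])
    stopf("'time_range' must be [start_ms, end_ms] with start < end")
  if (!is.null(window_ms) && window_ms <= 0) stopf("'window_ms' must be > 0")
  structure(list(conditions = conditions, comparisons = comparisons,
                 time_range = as.numeric(time_range),
                 window_ms = if (!is.null(window_ms)) as.numeric(window_ms)),
            class = "analysis_target")
}

#' Read an analysis target from a JSON document
#'
#' Accepts the JSON form
#' `{"conditions": [...], "comparisons": [["A","B"], ...],
#'   "time_range": [0, 600], "window_ms": 5}`.
#'
#' @param path path to a JSON file.
#' @return an [analysis_target()].
#' @export
read_target <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("conditions", "time_range"))
    if (is.null(doc[[f]])) stopf("target document is missing '%s'", f)
  cmp <- doc$comparisons
  if (is.matrix(cmp)) cmp <- lapply(seq_len(nrow(cmp)), function(i) cmp[i, ])
  analysis_target(doc$conditions, cmp %||% list(), doc$time_range,
                  doc$window_ms)
}

#' @export
print.analysis_target <- function(x, ...) {
  cat("<analysis_target>\n  conditions:", paste(x$conditions, collapse = ", "),
      "\n  comparisons:",
      if (length(x$comparisons))
        paste(vapply(x$comparisons, paste, "", collapse = " vs "),
              collapse = "; ") else "(none)",
      "\n  time_range:", paste(x$time_range, collapse = ".."), "ms")
  if (!is.null(x$window_ms)) cat("\n  window_ms:", x$window_ms)
  cat("\n")
  invisible(x)
}

# Map a time (ms) to a 0-based sample offset from times[1], by
# round-half-away-from-zero of (t - times[1]) * rate / 1000. This mapping
# makes adjacent half-open windows partition-exact.
time_to_offset <- function(t, times, sampling_rate) {
  as.integer(round_half_away((t - times[1]) * sampling_rate / 1000))
}

#' Extract an analysis view from an epochs dataset
#'
#' Restricts an [eeg_epochs()] dataset to the conditions and half-open time
#' range `[start_ms, end_ms)` of an [analysis_target()], optionally applying
#' the average reference (subtracting the across-sensor mean from every
#' sample), and attaches the target to the result.
#'
#' @param x an `eeg_epochs` object.
#' @param target an `analysis_target` (or list coercible to one).
#' @param average_reference logical; re-reference every sample to the mean
#'   across sensors (default `TRUE`). Re-referencing removes the arbitrary
#'   recording reference and is assumed by the topographic statistics.
#' @return an `eeg_epochs` view restricted to the requested conditions and
#'   times, with attributes `target` and `average_referenced`.
#' @export
extract_epochs <- function(x, target, average_reference = TRUE) {
  stopifnot(inherits(x, "eeg_epochs"))
  if (!inherits(target, "analysis_target")) {
    target <- analysis_target(target$conditions, target$comparisons %||% list(),
                              target$time_range, target$window_ms)
  }
  missing <- setdiff(target$conditions, x$conditions)
  if (length(missing))
    stopf("condition(s) %s not in dataset (available: %s)",
          paste(missing, collapse = ", "), paste(x$conditions, collapse = ", "))
  lo <- time_to_offset(target$time_range[1], x$times, x$sampling_rate)
  hi <- time_to_offset(target$time_range[2], x$times, x$sampling_rate)
  keep <- seq.int(lo + 1L, hi)
  keep <- keep[keep >= 1L & keep <= length(x$times)]
  if (length(keep) == 0L)
    stopf("time_range [%g, %g) selects no samples", target$time_range[1],
          target$time_range[2])
  data <- lapply(x$data, function(s) {
    lapply(s[target$conditions], function(a) {
      a <- a[, , keep, drop = FALSE]
      if (average_reference) {
        m <- colMeans(aperm(a, c(2L, 1L, 3L)))          # trials x time
        a - aperm(array(m, c(dim(a)[1], dim(a)[3], dim(a)[2])), c(1L, 3L, 2L))
      } else a
    })
  })
  out <- eeg_epochs(data, x$sensor_names, x$times[keep], x$sampling_rate)
  attr(out, "target") <- target
  attr(out, "average_referenced") <- average_reference
  out
}

#' Event-related potentials by averaging trials
#'
#' @param x an `eeg_epochs` object (typically an [extract_epochs()] view).
#' @param level `"subject"` returns, per condition, a
#'   subjects x sensors x timepoints array of trial-averaged responses;
#'   `"group"` returns, per condition, a sensors x timepoints matrix equal to
#'   the unweighted mean of the subject-level ERPs (each subject counts once,
#'   regardless of trial count).
#' @return named list over conditions of arrays/matrices as described.
#' @export
erp <- function(x, level = c("subject", "group")) {
  stopifnot(inherits(x, "eeg_epochs"))
  level <- match.arg(level)
  subj <- lapply(x$conditions, function(cn) {
    a <- array(NA_real_,
               c(length(x$subjects), length(x$sensor_names), length(x$times)),
               dimnames = list(x$subjects, x$sensor_names, NULL))
    for (i in seq_along(x$subjects)) {
      blk <- x$data[[i]][[cn]]
      a[i, , ] <- colMeans(blk)                         # mean over trials
    }
    a
  })
  names(subj) <- x$conditions
  if (level == "subject") return(subj)
  lapply(subj, function(a) {
    m <- apply(a, c(2L, 3L), mean)
    dimnames(m) <- list(x$sensor_names, NULL)
    m
  })
}

#' Tile a time axis into analysis windows
#'
#' Windows are half-open `[start_ms, end_ms)` intervals of nominal length
#' `window_ms`, tiled left-to-right from the first timepoint. Boundaries are
#' mapped to sample indices with the same round-half-away-from-zero rule as
#' [extract_epochs()], so adjacent windows partition the samples exactly
#' (at non-integer samples-per-window rates windows hold floor or ceiling
#' counts, e.g. 5 or 6 samples for 5 ms at 1100 Hz). A trailing remainder
#' shorter than half a window (in samples) is dropped; a longer remainder is
#' kept as a short final window.
#'
#' @param times numeric vector of timepoints in ms (uniform step).
#' @param window_ms nominal window length in ms; must be at least one sample
#'   period.
#' @param sampling_rate sampling rate in Hz; defaults to the rate implied by
#'   `times`.
#' @return data.frame with columns `start_ms`, `end_ms`, `start_idx`,
#'   `end_idx` (inclusive 1-based sample index ranges, disjoint and ordered).
#' @export
time_windows <- function(times, window_ms, sampling_rate = 1000 / diff(times[1:2])) {
  period <- 1000 / sampling_rate
  if (window_ms < period - 1e-9)
    stopf("window_ms (%g) is smaller than the sample period (%g ms)",
          window_ms, period)
  n <- length(times)
  w_nominal <- window_ms * sampling_rate / 1000        # samples per window
  k <- 0L
  out <- list()
  repeat {
    off0 <- time_to_offset(times[1] + k * window_ms, times, sampling_rate)
    off1 <- time_to_offset(times[1] + (k + 1) * window_ms, times, sampling_rate)
    if (off0 >= n) break
    start_idx <- off0 + 1L
    end_idx <- min(off1, n)
    len <- end_idx - start_idx + 1L
    if (off1 > n && len < w_nominal / 2) break          # drop short remainder
    out[[length(out) + 1L]] <- data.frame(
      start_ms = times[1] + k * window_ms,
      end_ms = min(times[1] + (k + 1) * window_ms, times[1] + n * period),
      start_idx = start_idx, end_idx = end_idx)
    k <- k + 1L
  }
  do.call(rbind, out)
}

# Group ERP window-mean topographies for the two conditions of a comparison.
# Returns list(A, B): sensors-length vectors.
window_topographies <- function(group_erp, comparison, win) {
  idx <- seq.int(win$start_idx, win$end_idx)
  list(A = rowMeans(group_erp[[comparison[1]]][, idx, drop = FALSE]),
       B = rowMeans(group_erp[[comparison[2]]][, idx, drop = FALSE]))
}
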