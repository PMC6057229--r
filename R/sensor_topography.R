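#' Distribution of significant sensors
#'
#' Per-sensor paired tests between two conditions in successive analysis
#' windows. For every sensor and window, each subject contributes the mean of
#' its condition ERP over the window samples at that sensor; a two-sided
#' paired t-test across subjects compares the two conditions. The map of
#' mean differences, p-values and significance flags estimates the spatial
#' extent of an effect, and the count of significant sensors per window its
#' temporal dynamics.
#'
#' P-values are uncorrected by default — this analysis is a visualization of
#' spatial extent, in the spirit of uncorrected display thresholds common in
#' neuroimaging — with optional Benjamini-Hochberg correction across sensors
#' within each window (`fdr = TRUE`).
#'
#' @param x an `eeg_epochs` view from [extract_epochs()] containing both
#'   conditions for every subject (>= 2 subjects).
#' @param comparison ordered pair of condition labels `c(cond1, cond2)`;
#'   differences are cond1 - cond2.
#' @param window_ms window length in ms.
#' @param alpha per-sensor significance level.
#' @param fdr logical; Benjamini-Hochberg across sensors within window.
#' @return object of class `sensor_sig_map` with `table` (long data.frame:
#'   window_start, window_end, sensor, diff_uV, p, significant), `counts`
#'   (data.frame: window_start, window_end, sig_count) and metadata.
#' @export
sensor_tests <- function(x, comparison, window_ms, alpha = 0.05, fdr = FALSE) {
  stopifnot(inherits(x, "eeg_epochs"))
  if (length(x$subjects) < 2L)
    stopf("sensor tests need at least 2 subjects, got %d", length(x$subjects))
  missing <- setdiff(comparison, x$conditions)
  if (length(missing))
    stopf("condition(s) %s not in view (available: %s)",
          paste(missing, collapse = ", "), paste(x$conditions, collapse = ", "))
  win <- time_windows(x$times, window_ms, x$sampling_rate)
  sub_erp <- erp(x, "subject")
  n_sensors <- length(x$sensor_names)
  rows <- vector("list", nrow(win))
  for (i in seq_len(nrow(win))) {
    idx <- seq.int(win$start_idx[i], win$end_idx[i])
    # subjects x sensors window means for each condition
    v1 <- rowMeans(sub_erp[[comparison[1]]][, , idx, drop = FALSE], dims = 2L)
    v2 <- rowMeans(sub_erp[[comparison[2]]][, , idx, drop = FALSE], dims = 2L)
    tt <- paired_t_cols(v1 - v2)
    p <- if (fdr) stats::p.adjust(tt$p, "BH") else tt$p
    rows[[i]] <- data.frame(window_start = win$start_ms[i],
                            window_end = win$end_ms[i],
                            sensor = x$sensor_names,
                            diff_uV = unname(tt$mean), p = unname(p),
                            significant = unname(p < alpha))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  counts <- data.frame(window_start = win$start_ms, window_end = win$end_ms,
                       sig_count = vapply(rows, function(r) sum(r$significant), 0L))
  structure(list(analysis_name = "sensor_topography",
                 table = tab, counts = counts,
                 annotation = list(comparison = comparison,
                                   window_ms = window_ms, alpha = alpha,
                                   fdr = fdr,
                                   n_subjects = length(x$subjects))),
            class = c("sensor_sig_map", "topostat_result"))
}

#' Count of significant sensors per window
#'
#' @param map a [sensor_tests()] result.
#' @return data.frame with `window_start`, `window_end`, `sig_count`.
#' @export
significant_channels_count <- function(map) {
  stopifnot(inherits(map, "sensor_sig_map"))
  map$counts
}
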