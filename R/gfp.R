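#' Global field power of a topography
#'
#' GFP is the root mean square of the mean-referenced sensor values,
#' \deqn{GFP = \sqrt{\frac{1}{n}\sum_i (U_i - \bar U)^2},}
#' i.e. the (population) standard deviation of the potentials across the
#' montage. It is reference-free: adding any constant to all sensors leaves
#' it unchanged, and scaling all sensors by \eqn{\lambda \ge 0} scales it by
#' \eqn{\lambda}.
#'
#' @param values numeric vector of per-sensor potentials (µV), length >= 2.
#' @return scalar GFP in µV.
#' @examples
#' gfp(c(1, -1))      # 1
#' gfp(c(2, 0, -2))   # sqrt(8/3)
#' @export
gfp <- function(values) {
  if (length(values) < 2L)
    stopf("GFP needs at least 2 sensors, got %d", length(values))
  sqrt(mean((values - mean(values))^2))
}

#' GFP time series per subject and condition
#'
#' Computes GFP on every subject's condition ERP at every timepoint, plus the
#' group summary (across-subject mean and standard error). The group curve is
#' the mean of individual GFP series, never the GFP of the group-averaged
#' ERP: GFP is non-linear, so the two differ whenever subject topographies
#' differ.
#'
#' @param x an `eeg_epochs` view from [extract_epochs()].
#' @param level `"erp"` (default) computes GFP on subject ERPs; `"trial"`
#'   returns in addition trial-level GFP arrays (exposed for exploration, not
#'   used by the group statistics).
#' @return object of class `gfp_series`: list with `series` (named list over
#'   conditions of subjects x timepoints GFP matrices), `summary`
#'   (long data.frame: condition, time_ms, mean, sem), `times`,
#'   `sampling_rate`, `subjects`.
#' @export
gfp_series <- function(x, level = c("erp", "trial")) {
  stopifnot(inherits(x, "eeg_epochs"))
  level <- match.arg(level)
  sub_erp <- erp(x, "subject")
  gfp_array <- function(a) {
    # a: subjects x sensors x time; GFP = sqrt(E[v^2] - E[v]^2) over sensors
    mu <- colMeans(aperm(a, c(2L, 1L, 3L)))
    ss <- colMeans(aperm(a^2, c(2L, 1L, 3L)))
    m <- sqrt(pmax(ss - mu^2, 0))
    rownames(m) <- x$subjects
    m
  }
  series <- lapply(sub_erp, gfp_array)
  n <- length(x$subjects)
  summary <- do.call(rbind, lapply(names(series), function(cn) {
    g <- series[[cn]]
    data.frame(condition = cn, time_ms = x$times,
               mean = colMeans(g),
               sem = apply(g, 2L, stats::sd) / sqrt(n))
  }))
  rownames(summary) <- NULL
  trial <- NULL
  if (level == "trial") {
    trial <- lapply(x$subjects, function(s) lapply(x$data[[s]], function(a) {
      mu <- colMeans(aperm(a, c(2L, 1L, 3L)))
      ss <- colMeans(aperm(a^2, c(2L, 1L, 3L)))
      sqrt(pmax(ss - mu^2, 0))
    }))
    names(trial) <- x$subjects
  }
  structure(list(series = series, summary = summary, trial = trial,
                 times = x$times, sampling_rate = x$sampling_rate,
                 subjects = x$subjects,
                 target = attr(x, "target")),
            class = "gfp_series")
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf("<gfp_series> %d subjects, conditions: %s, %d timepoints\n",
              length(x$subjects), paste(names(x$series), collapse = ", "),
              length(x$times)))
  invisible(x)
}

#' Windowed group comparison of GFP between two conditions
#'
#' For every analysis window, each subject contributes one value per
#' condition: the window mean (or peak) of that subject's GFP series. A
#' two-sided paired t-test across subjects compares the two conditions.
#' Uncorrected p-values are returned by default; `fdr = TRUE` applies
#' Benjamini-Hochberg across the windows of this comparison.
#'
#' @param series a [gfp_series()] object.
#' @param comparison ordered pair of condition labels `c(cond1, cond2)`.
#' @param window_ms window length in ms.
#' @param stat window reduction: `"mean"` (default) or `"peak"` (max).
#' @param fdr logical; apply Benjamini-Hochberg across windows.
#' @param alpha significance level used for the `significant` flag.
#' @return object of class `gfp_test` with `table` (data.frame: window_start,
#'   window_end, diff_uV, t, p, significant) and metadata.
#' @export
gfp_compare <- function(series, comparison, window_ms, stat = c("mean", "peak"),
                        fdr = FALSE, alpha = 0.05) {
  stopifnot(inherits(series, "gfp_series"))
  stat <- match.arg(stat)
  if (length(series$subjects) < 2L)
    stopf("GFP comparison needs at least 2 subjects")
  missing <- setdiff(comparison, names(series$series))
  if (length(missing))
    stopf("condition(s) %s not present in the GFP series",
          paste(missing, collapse = ", "))
  win <- time_windows(series$times, window_ms, series$sampling_rate)
  red <- if (stat == "mean") rowMeans else function(m) apply(m, 1L, max)
  vals <- lapply(comparison, function(cn) {
    g <- series$series[[cn]]
    sapply(seq_len(nrow(win)), function(i)
      red(g[, seq.int(win$start_idx[i], win$end_idx[i]), drop = FALSE]))
  })
  d <- vals[[1]] - vals[[2]]                       # subjects x windows
  tt <- paired_t_cols(d)
  p <- if (fdr) stats::p.adjust(tt$p, "BH") else tt$p
  tab <- data.frame(window_start = win$start_ms, window_end = win$end_ms,
                    diff_uV = tt$mean, t = tt$t, p = p,
                    significant = p < alpha)
  structure(list(analysis_name = "gfp",
                 table = tab,
                 annotation = list(comparison = comparison,
                                   window_ms = window_ms, stat = stat,
                                   fdr = fdr, alpha = alpha,
                                   n_subjects = length(series$subjects))),
            class = c("gfp_test", "topostat_result"))
}
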