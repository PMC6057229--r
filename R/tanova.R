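#' Angle measure between two topographies
#'
#' The topographic similarity of two conditions is the cosine of the
#' high-dimensional angle between their sensor-space vectors,
#' \deqn{\cos\theta = \frac{\vec A \cdot \vec B}{|\vec A||\vec B|},}
#' where the number of dimensions is the number of sensors. A value of 1 is
#' an identical pattern, -1 an exactly opposite (polarity-reversed) pattern.
#' Because both vectors are normalized by their own magnitude, the measure is
#' unaffected by response magnitude.
#'
#' With `center = TRUE` (default) both vectors are average-referenced
#' (mean-subtracted) first, making the measure independent of the recording
#' reference, consistently with the GFP definition.
#'
#' @param a,b numeric vectors of per-sensor potentials, same length/order.
#' @param center logical; average-reference before computing the cosine.
#' @return the cosine, in `[-1, 1]`.
#' @export
angle_measure <- function(a, b, center = TRUE) {
  if (length(a) != length(b))
    stopf("topographies have mismatched sensor counts (%d vs %d)",
          length(a), length(b))
  if (center) {
    a <- a - mean(a)
    b <- b - mean(b)
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stopf("degenerate topography: zero norm%s",
          if (center) " after average-referencing" else "")
  max(-1, min(1, sum(a * b) / (na * nb)))
}

# Cosine between rows of two matrices (shuffles x sensors), optionally
# centered. Degenerate rows yield NA.
row_cosines <- function(A, B, center = TRUE) {
  if (center) {
    A <- A - rowMeans(A)
    B <- B - rowMeans(B)
  }
  num <- rowSums(A * B)
  den <- sqrt(rowSums(A^2) * rowSums(B^2))
  out <- ifelse(den > 0, num / den, NA_real_)
  pmax(-1, pmin(1, out))
}

#' Permutation null distribution of the angle measure
#'
#' Builds the null distribution of the topographic angle measure for one
#' comparison and one analysis window by re-labeling the data under one of
#' three strategies:
#'
#' * **Strategy 1** — pool all trials of both conditions across subjects,
#'   randomly re-assign condition labels to trials (preserving the original
#'   per-condition counts), average the pooled pseudo-condition trials, and
#'   record the angle measure between the two pseudo-condition window-mean
#'   topographies.
#' * **Strategy 2** — same trial re-labeling, but shuffling is restricted to
#'   each subject's own trial pool (per-subject counts preserved); subject
#'   pseudo-ERPs are averaged across subjects before the angle measure.
#' * **Strategy 3** — compute subject x condition ERPs once, then per shuffle
#'   independently swap (or not, with probability 1/2) the two condition
#'   labels within each subject, group-average, and record the angle measure.
#'
#' Strategy 3 operates on `S` subject-level sign choices; when `2^S <=
#' n_shuffles` the full set of `2^S` label assignments is enumerated exactly
#' instead of sampled (the result is then flagged `exhaustive` and `values`
#' has length `2^S`).
#'
#' @param x an `eeg_epochs` view containing both conditions.
#' @param comparison ordered pair of condition labels.
#' @param window either a row of [time_windows()] (list/data.frame with
#'   `start_idx`, `end_idx`) or an integer vector of sample indices.
#' @param strategy 1, 2 or 3.
#' @param n_shuffles number of re-labelings (default 1000).
#' @param seed integer seed; required, results are deterministic given it.
#' @param center average-reference topographies before the cosine.
#' @param workers number of worker processes for strategies 1-2 (each shuffle
#'   uses its own derived seed, so results do not depend on `workers`).
#' @return object of class `null_distribution`: list with `strategy`,
#'   `n_shuffles`, `values`, `seed`, `exhaustive`.
#' @export
null_distribution <- function(x, comparison, window, strategy = 3,
                              n_shuffles = 1000, seed, center = TRUE,
                              workers = 1L) {
  stopifnot(inherits(x, "eeg_epochs"))
  if (missing(seed)) stopf("'seed' is required for permutation analyses")
  if (n_shuffles < 1) stopf("'n_shuffles' must be >= 1")
  if (!strategy %in% 1:3) stopf("'strategy' must be 1, 2 or 3")
  idx <- if (is.list(window)) seq.int(window$start_idx[1], window$end_idx[1])
         else as.integer(window)
  vals <- switch(strategy,
    null_strategy12(x, comparison, idx, n_shuffles, seed, center,
                    within_subject = FALSE, workers = workers),
    null_strategy12(x, comparison, idx, n_shuffles, seed, center,
                    within_subject = TRUE, workers = workers),
    null_strategy3(x, comparison, idx, n_shuffles, seed, center))
  structure(list(strategy = strategy, n_shuffles = length(vals$values),
                 values = vals$values, seed = seed,
                 exhaustive = isTRUE(vals$exhaustive)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> strategy %d, %d values%s, seed %d\n",
              x$strategy, x$n_shuffles,
              if (x$exhaustive) " (exhaustive)" else "", x$seed))
  cat(sprintf("  cosine range [%.4f, %.4f], mean %.4f\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

# One-tailed left rank p-value of an observed cosine within a permutation
# null. Ties (null == observed, to 1e-12) count as extreme: conservative.
# Monte-Carlo nulls use the add-one rule (p never 0); exhaustive nulls use
# the exact permutation p, whose identity assignment guarantees p > 0.
rank_p <- function(values, obs, exhaustive = FALSE) {
  b <- sum(values <= obs + 1e-12)
  if (exhaustive) b / length(values) else (1 + b) / (1 + length(values))
}

# Window-mean trial topographies per subject: list over subjects of
# (trials x sensors) matrices per condition.
trial_topographies <- function(x, comparison, idx) {
  lapply(x$data, function(s) {
    lapply(s[comparison], function(a) {
      # mean over window samples -> trials x sensors
      rowMeans(a[, , idx, drop = FALSE], dims = 2L)
    })
  })
}

# Strategies 1 and 2: trial-level label permutation, pooled across subjects
# (strategy 1: pooled-trial averaging, subject identity discarded by
# construction) or within subject (strategy 2: subject pseudo-ERPs averaged
# across subjects).
null_strategy12 <- function(x, comparison, idx, n_shuffles, seed, center,
                            within_subject, workers = 1L) {
  tt <- trial_topographies(x, comparison, idx)
  seeds <- derive_seeds(seed, n_shuffles)
  if (!within_subject) {
    P <- do.call(rbind, lapply(tt, function(s) rbind(s[[1]], s[[2]])))
    n1 <- sum(vapply(tt, function(s) nrow(s[[1]]), 0L))
    N <- nrow(P)
    one <- function(i) with_seed(seeds[i], {
      perm <- sample.int(N)
      A <- colMeans(P[perm[seq_len(n1)], , drop = FALSE])
      B <- colMeans(P[perm[-seq_len(n1)], , drop = FALSE])
      angle_measure(A, B, center = center)
    })
  } else {
    counts <- lapply(tt, function(s) nrow(s[[1]]))
    pools <- lapply(tt, function(s) rbind(s[[1]], s[[2]]))
    S <- length(pools)
    one <- function(i) with_seed(seeds[i], {
      A <- 0; B <- 0
      for (s in seq_len(S)) {
        P <- pools[[s]]
        perm <- sample.int(nrow(P))
        k <- counts[[s]]
        A <- A + colMeans(P[perm[seq_len(k)], , drop = FALSE])
        B <- B + colMeans(P[perm[-seq_len(k)], , drop = FALSE])
      }
      angle_measure(A / S, B / S, center = center)
    })
  }
  vals <- if (workers > 1L) {
    unlist(parallel::mclapply(seq_len(n_shuffles), one, mc.cores = workers))
  } else {
    vapply(seq_len(n_shuffles), one, 0)
  }
  list(values = vals, exhaustive = FALSE)
}

# Strategy 3: per-subject condition-label swap of subject ERPs. With sign
# sigma_s = +-1 and per-subject window topographies A_s, B_s, the pseudo
# group averages are Mbar +- (1/S) sum sigma_s D_s with M = (A+B)/2,
# D = (A-B)/2, so all shuffles reduce to one matrix product.
null_strategy3 <- function(x, comparison, idx, n_shuffles, seed, center) {
  sub_erp <- erp(x, "subject")
  S <- length(x$subjects)
  A <- rowMeans(sub_erp[[comparison[1]]][, , idx, drop = FALSE], dims = 2L)
  B <- rowMeans(sub_erp[[comparison[2]]][, , idx, drop = FALSE], dims = 2L)
  M <- (A + B) / 2
  D <- (A - B) / 2
  Mbar <- colMeans(M)
  exhaustive <- S <= 30 && 2^S <= n_shuffles
  Sigma <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(1, -1)), S)))
  } else {
    with_seed(seed, matrix(sample(c(1, -1), n_shuffles * S, replace = TRUE),
                           ncol = S))
  }
  W <- (Sigma %*% D) / S                  # shuffles x sensors
  Am <- sweep(W, 2L, Mbar, `+`)
  Bm <- sweep(-W, 2L, Mbar, `+`)
  vals <- row_cosines(Am, Bm, center = center)
  if (anyNA(vals))
    stopf("degenerate topography (zero norm) in permutation null")
  list(values = as.numeric(vals), exhaustive = exhaustive)
}

#' Topographic analysis of variance (TANOVA)
#'
#' Tests, window by window, whether the topographic patterns of two
#' conditions differ. The observed statistic per window is the angle measure
#' (cosine) between the group-averaged ERP window-mean topographies of the
#' two conditions; its null distribution is built by permutation
#' ([null_distribution()]); the p-value is the rank position of the observed
#' cosine within the null.
#'
#' The test is one-tailed on the left: a low cosine means dissimilar
#' patterns, which is the alternative of interest. For Monte-Carlo nulls the
#' add-one rule \eqn{p = (1 + \#\{null \le obs\})/(1 + n)} is used (ties
#' count as extreme, p is never 0); for exhaustive strategy-3 nulls the
#' exact permutation p \eqn{\#\{null \le obs\}/2^S} is reported (the identity
#' assignment is part of the null, so p > 0).
#'
#' @inheritParams null_distribution
#' @param window_ms analysis window length in ms.
#' @param alpha significance level used for the `significant` flag.
#' @return object of class `tanova_result` with `table` (data.frame:
#'   window_start, window_end, cosine, p, significant), `nulls` (list of
#'   [null_distribution()] objects per window) and metadata. Windows with a
#'   degenerate (zero-norm) topography get `p = NA` and a warning.
#' @export
tanova <- function(x, comparison, window_ms, strategy = 3, n_shuffles = 1000,
                   seed, center = TRUE, alpha = 0.05, workers = 1L,
                   keep_nulls = FALSE) {
  stopifnot(inherits(x, "eeg_epochs"))
  if (missing(seed)) stopf("'seed' is required for permutation analyses")
  missing_c <- setdiff(comparison, x$conditions)
  if (length(missing_c))
    stopf("condition(s) %s not in view (available: %s)",
          paste(missing_c, collapse = ", "), paste(x$conditions, collapse = ", "))
  win <- time_windows(x$times, window_ms, x$sampling_rate)
  group <- erp(x, "group")
  wseeds <- derive_seeds(seed, nrow(win))
  cosine <- p <- rep(NA_real_, nrow(win))
  nulls <- vector("list", nrow(win))
  for (i in seq_len(nrow(win))) {
    topo <- window_topographies(group, comparison, win[i, ])
    obs <- tryCatch(angle_measure(topo$A, topo$B, center = center),
                    error = function(e) NA_real_)
    if (is.na(obs)) {
      warning(sprintf("window [%g, %g) ms: degenerate topography, p set to NA",
                      win$start_ms[i], win$end_ms[i]))
      next
    }
    nd <- null_distribution(x, comparison, win[i, ], strategy = strategy,
                            n_shuffles = n_shuffles, seed = wseeds[i],
                            center = center, workers = workers)
    cosine[i] <- obs
    p[i] <- rank_p(nd$values, obs, nd$exhaustive)
    if (keep_nulls) nulls[[i]] <- nd
  }
  tab <- data.frame(window_start = win$start_ms, window_end = win$end_ms,
                    cosine = cosine, p = p, significant = !is.na(p) & p < alpha)
  structure(list(analysis_name = "tanova", table = tab,
                 nulls = if (keep_nulls) nulls,
                 annotation = list(comparison = comparison,
                                   window_ms = window_ms, strategy = strategy,
                                   n_shuffles = n_shuffles, seed = seed,
                                   center = center, alpha = alpha,
                                   n_subjects = length(x$subjects))),
            class = c("tanova_result", "topostat_result"))
}

#' Temporal multiple-comparison correction of a windowed p-value series
#'
#' Two methods:
#' * `"cluster"` — keep a window significant only if it belongs to a maximal
#'   run of consecutive windows with `p < alpha` whose total duration exceeds
#'   `min_duration_ms` (default 20 ms). Requires a uniform window grid.
#' * `"fdr_bh"` — Benjamini-Hochberg across all windows of the comparison
#'   (via [stats::p.adjust()]); a window is significant if its adjusted
#'   p-value is below `alpha`.
#'
#' Corrected significance is always a subset of uncorrected significance.
#'
#' @param result a `tanova_result`, `classification_result` or `gfp_test`.
#' @param method `"cluster"` or `"fdr_bh"`.
#' @param alpha significance level.
#' @param min_duration_ms minimal duration of a significant run (cluster
#'   method).
#' @return the result object with columns `significant_corrected` (and
#'   `p_adjusted` for fdr_bh) added to its table and the correction recorded
#'   in its annotation.
#' @export
correct <- function(result, method = c("cluster", "fdr_bh"), alpha = 0.05,
                    min_duration_ms = 20) {
  stopifnot(inherits(result, "topostat_result"))
  method <- match.arg(method)
  tab <- result$table
  p <- tab$p
  if (method == "cluster") {
    widths <- tab$window_end - tab$window_start
    if (length(unique(round(widths[-length(widths)], 9))) > 1L)
      stopf("cluster correction requires a uniform window grid")
    sig <- !is.na(p) & p < alpha
    keep <- logical(length(sig))
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      dur <- tab$window_end[ends[j]] - tab$window_start[starts[j]]
      if (dur > min_duration_ms) keep[starts[j]:ends[j]] <- TRUE
    }
    tab$significant_corrected <- keep
  } else {
    padj <- stats::p.adjust(p, "BH")
    tab$p_adjusted <- padj
    tab$significant_corrected <- !is.na(padj) & padj < alpha
  }
  result$table <- tab
  result$annotation$correction <- list(method = method, alpha = alpha,
                                       min_duration_ms =
                                         if (method == "cluster") min_duration_ms)
  result
}
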