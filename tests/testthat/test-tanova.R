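test_that("angle measure matches its closed forms", {
  a <- c(3, -1, 2, -4)
  expect_equal(angle_measure(a, a), 1, tolerance = 1e-15)
  expect_equal(angle_measure(a, -a), -1, tolerance = 1e-15)

  # hand oracle with centering, n = 4: A = e1, B = e2 -> -1/3
  A <- c(1, 0, 0, 0); B <- c(0, 1, 0, 0)
  ac <- A - mean(A); bc <- B - mean(B)
  hand <- sum(ac * bc) / sqrt(sum(ac^2) * sum(bc^2))
  expect_equal(hand, -1 / 3, tolerance = 1e-15)
  expect_equal(angle_measure(A, B), -1 / 3, tolerance = 1e-15)

  # random vectors against an independent centered-cosine oracle
  set.seed(5)
  for (i in 1:50) {
    u <- rnorm(16); v <- rnorm(16)
    uc <- u - mean(u); vc <- v - mean(v)
    expect_equal(angle_measure(u, v),
                 sum(uc * vc) / (sqrt(sum(uc^2)) * sqrt(sum(vc^2))),
                 tolerance = 1e-12)
  }
})

test_that("angle measure is symmetric, scale-invariant, and guards degeneracy", {
  set.seed(6)
  u <- rnorm(8); v <- rnorm(8)
  expect_identical(angle_measure(u, v), angle_measure(v, u))
  for (lambda in c(1e-6, 0.5, 3, 1e6))
    expect_equal(angle_measure(u, lambda * v), angle_measure(u, v),
                 tolerance = 1e-12)
  expect_error(angle_measure(u, rep(0, 8)), "zero norm")
  # a constant vector is zero after average-referencing
  expect_error(angle_measure(u, rep(2, 8)), "zero norm")
  expect_equal(angle_measure(u, rep(2, 8), center = FALSE),
               sum(u * 2) / (sqrt(sum(u^2)) * sqrt(sum(rep(4, 8)))),
               tolerance = 1e-12)
  expect_error(angle_measure(u, rnorm(7)), "mismatched")
})

test_that("rank p-value follows the documented conventions", {
  rank_p <- topostat:::rank_p
  null999 <- seq(0.5, 0.999, length.out = 999)
  expect_equal(rank_p(null999, 0.1), 1 / 1000)         # below all nulls
  expect_equal(rank_p(null999, 1), 1)                  # at/above the maximum
  expect_equal(rank_p(null999, 0.999), 1)              # tie with max counts
  # monotone: p non-increasing as the observed cosine decreases
  ps <- vapply(c(0.9, 0.7, 0.6, 0.49), function(o) rank_p(null999, o), 0)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps > 0))
  # exhaustive convention: exact permutation p
  expect_equal(rank_p(c(0.2, 0.5, 0.8, 1.0), 0.2, exhaustive = TRUE), 1 / 4)
})

test_that("identical trials give a null concentrated at cosine 1", {
  p <- c(1, -1, 2, -2)
  x <- make_epochs(n_subjects = 3, gen = function(s, cn, tr) matrix(p, 4, 10))
  for (st in 1:3) {
    nd <- null_distribution(x, c("A", "B"), 1:10, strategy = st,
                            n_shuffles = 50, seed = 4)
    expect_true(all(abs(nd$values - 1) < 1e-12))
  }
})

test_that("strategy 3 with 2 subjects enumerates all 4 assignments exactly", {
  set.seed(11)
  maps <- replicate(4, matrix(rnorm(40), 4, 10), simplify = FALSE)
  x <- make_epochs(n_subjects = 2, gen = function(s, cn, tr)
    maps[[(s - 1) * 2 + (cn == "B") + 1]])
  nd <- null_distribution(x, c("A", "B"), 1:10, strategy = 3,
                          n_shuffles = 1000, seed = 1)
  expect_true(nd$exhaustive)
  expect_length(nd$values, 4L)

  # brute-force oracle: enumerate the label swaps by hand
  se <- erp(x, "subject")
  topoA <- rowMeans(se$A, dims = 2L)   # subjects x sensors window means
  topoB <- rowMeans(se$B, dims = 2L)
  oracle <- c()
  for (s1 in c(FALSE, TRUE)) for (s2 in c(FALSE, TRUE)) {
    a1 <- if (s1) topoB[1, ] else topoA[1, ]
    b1 <- if (s1) topoA[1, ] else topoB[1, ]
    a2 <- if (s2) topoB[2, ] else topoA[2, ]
    b2 <- if (s2) topoA[2, ] else topoB[2, ]
    oracle <- c(oracle, angle_measure((a1 + a2) / 2, (b1 + b2) / 2))
  }
  expect_equal(sort(nd$values), sort(oracle), tolerance = 1e-12)
})

test_that("the three null strategies agree on fully exchangeable null data", {
  # trials iid across subjects and conditions (no signal, no between-subject
  # topography variability): the three re-labeling schemes then target the
  # same null. Every strategy's null mean carries a common dataset-level
  # random offset that does not shrink with more shuffles, so agreement is
  # assessed by paired differences of null means across replicate datasets.
  R <- 20
  diffs <- t(sapply(seq_len(R), function(r) {
    spec <- quick_spec(seed = 500 + r, n_subjects = 6, n_sensors = 8,
                       n_trials = 12,
                       noise = list(sensor_sd = 2,
                                    subject_pattern_jitter_sd = 0,
                                    trial_amplitude_jitter_sd = 0))
    spec$sources[[1]]$time_course <-
      rep(0, length(spec$sources[[1]]$time_course))
    v <- extract_epochs(simulate_epochs(spec),
                        analysis_target(c("A", "B"), list(c("A", "B")),
                                        c(0, 150)))
    win <- time_windows(v$times, 50, v$sampling_rate)[2, ]
    m <- vapply(1:3, function(st)
      mean(null_distribution(v, c("A", "B"), win, strategy = st,
                             n_shuffles = 300, seed = 700 + r)$values), 0)
    c(m[1] - m[2], m[1] - m[3], m[2] - m[3])
  }))
  for (k in 1:3) {
    se <- stats::sd(diffs[, k]) / sqrt(R)
    expect_lt(abs(mean(diffs[, k])), 3 * se)
  }
})

test_that("tanova separates pattern effects and reports valid p-values", {
  spec <- quick_spec(seed = 60)
  alt <- quick_alt(spec)
  spec_pat <- quick_spec(seed = 60, effects = list(list(
    kind = "pattern_swap", condition = "A", onset_ms = 50, offset_ms = 150,
    alternate_pattern = alt)))
  v <- extract_epochs(simulate_epochs(spec_pat),
                      analysis_target(c("A", "B"), list(c("A", "B")), c(0, 150)))
  tv <- tanova(v, c("A", "B"), 50, strategy = 3, n_shuffles = 1000, seed = 9)
  expect_true(all(tv$table$p > 0 & tv$table$p <= 1))
  expect_true(all(tv$table$p[2:3] < 0.01))
  # observed cosines in effect windows are far from 1
  expect_true(all(tv$table$cosine[2:3] < 0.5))
  expect_error(tanova(v, c("A", "Z"), 50, seed = 1), "not in view")
  expect_error(tanova(v, c("A", "B"), 50), "'seed' is required")
})

test_that("magnitude-only effects leave tanova at the null", {
  spec_mag <- quick_spec(seed = 61, effects = list(list(
    kind = "magnitude_scale", condition = "A", onset_ms = 50,
    offset_ms = 150, scale = 1.5)))
  v <- extract_epochs(simulate_epochs(spec_mag),
                      analysis_target(c("A", "B"), list(c("A", "B")), c(0, 150)))
  tv <- tanova(v, c("A", "B"), 50, strategy = 3, n_shuffles = 1000, seed = 10)
  # patterns are unchanged: observed cosine near 1 in signal windows
  expect_true(all(tv$table$cosine[2:3] > 0.99))
})

test_that("cluster correction keeps only runs longer than the minimum duration", {
  # 5 ms windows: a 25 ms significant run survives min_duration 20 ms, an
  # isolated 15 ms run does not
  ws <- seq(0, 95, by = 5)
  p <- rep(0.5, 20)
  p[3:7] <- 0.01    # 25 ms run
  p[12:14] <- 0.01  # 15 ms run
  res <- structure(list(analysis_name = "tanova",
                        table = data.frame(window_start = ws,
                                           window_end = ws + 5,
                                           cosine = 0.5, p = p,
                                           significant = p < 0.05),
                        annotation = list(comparison = c("A", "B"))),
                   class = c("tanova_result", "topostat_result"))
  cc <- correct(res, "cluster", alpha = 0.05, min_duration_ms = 20)
  expect_identical(which(cc$table$significant_corrected), 3:7)
  # corrected significance is a subset of uncorrected
  expect_true(all(cc$table$significant[cc$table$significant_corrected]))

  # all p = 1: nothing survives either method
  res1 <- res; res1$table$p <- 1; res1$table$significant <- FALSE
  expect_false(any(correct(res1, "cluster")$table$significant_corrected))
  expect_false(any(correct(res1, "fdr_bh")$table$significant_corrected))
})

test_that("BH correction matches the hand computation", {
  ws <- seq(0, 15, by = 5)
  pv <- c(0.001, 0.02, 0.03, 0.9)
  res <- structure(list(analysis_name = "tanova",
                        table = data.frame(window_start = ws,
                                           window_end = ws + 5,
                                           cosine = 0.5, p = pv,
                                           significant = pv < 0.05),
                        annotation = list()),
                   class = c("tanova_result", "topostat_result"))
  cc <- correct(res, "fdr_bh", alpha = 0.05)
  # hand BH: compare sorted p(i) <= i * alpha / m -> first three rejected
  m <- 4
  hand <- logical(m)
  srt <- sort(pv, index.return = TRUE)
  cutoff <- max(c(0, which(srt$x <= seq_len(m) * 0.05 / m)))
  if (cutoff > 0) hand[srt$ix[seq_len(cutoff)]] <- TRUE
  expect_identical(cc$table$significant_corrected, hand)
  expect_identical(sum(cc$table$significant_corrected), 3L)
})
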