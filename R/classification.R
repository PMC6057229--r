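#' Classification configuration
#'
#' @param model `"logistic_regression"` (default: L2-regularized logistic
#'   regression, fixed penalty 1.0, unpenalized intercept, features
#'   standardized on the training fold only) or a plug-in model: a list with
#'   elements `fit(x, y)` returning a fitted object and `score(fit, x)`
#'   returning a real-valued score for the positive class (any strictly
#'   monotone transform of it gives the same AUC).
#' @param window_ms analysis window length in ms.
#' @param test_size fraction of samples randomly held out as the test set in
#'   each fold (default 0.3).
#' @param folds number of random stratified train/test splits (default 25).
#' @param score classification score; only `"auc"` is implemented. AUC is
#'   robust to unbalanced trial counts between the two labels.
#' @param seed integer seed for the splits.
#' @return object of class `classification_config`.
#' @export
classification_config <- function(model = "logistic_regression", window_ms,
                                  test_size = 0.3, folds = 25,
                                  score = "auc", seed) {
  if (missing(seed)) stopf("'seed' is required for classification")
  if (test_size <= 0 || test_size >= 1) stopf("'test_size' must be in (0, 1)")
  if (folds < 2) stopf("'folds' must be >= 2")
  score <- match.arg(score, "auc")
  if (is.character(model)) {
    model <- match.arg(model, "logistic_regression")
  } else if (!is.list(model) || !is.function(model$fit) || !is.function(model$score)) {
    stopf("plug-in 'model' must be a list with functions fit(x, y) and score(fit, x)")
  }
  structure(list(model = model, window_ms = window_ms, test_size = test_size,
                 folds = as.integer(folds), score = score,
                 seed = as.integer(seed)),
            class = "classification_config")
}

#' Labeled sample set for one subject and window
#'
#' One sample per trial: the window-mean topography (one feature per sensor);
#' the label is the condition. Trial-level samples keep the within-subject
#' variability the classifier must generalize over.
#'
#' @param x an `eeg_epochs` view.
#' @param subject subject identifier.
#' @param comparison ordered pair of condition labels; the first label is
#'   the positive class.
#' @param window a row of [time_windows()] or an integer vector of sample
#'   indices.
#' @return list with `x` (samples x sensors feature matrix) and `y`
#'   (0/1 labels, 1 = first condition of the comparison).
#' @export
window_samples <- function(x, subject, comparison, window) {
  stopifnot(inherits(x, "eeg_epochs"))
  if (!subject %in% x$subjects) stopf("unknown subject '%s'", subject)
  idx <- if (is.list(window)) seq.int(window$start_idx[1], window$end_idx[1])
         else as.integer(window)
  blocks <- lapply(comparison, function(cn) {
    a <- x$data[[subject]][[cn]]
    if (is.null(a)) stopf("subject '%s' is missing condition '%s'", subject, cn)
    rowMeans(a[, , idx, drop = FALSE], dims = 2L)     # trials x sensors
  })
  n <- vapply(blocks, nrow, 0L)
  if (any(n < 4L))
    stopf("subject '%s': need >= 4 trials per condition in window, got %s",
          subject, paste(n, collapse = "/"))
  list(x = do.call(rbind, blocks),
       y = rep(c(1L, 0L), n))
}

# Rank-based AUC (Mann-Whitney identity): probability that a random positive
# scores above a random negative, ties counted 1/2.
auc_score <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Ridge-penalized logistic regression by iteratively reweighted least
# squares: minimize -loglik + (lambda/2)||beta||^2, intercept unpenalized.
ridge_logistic_fit <- function(x, y, lambda = 1.0, max_iter = 50L,
                               tol = 1e-9) {
  X <- cbind(1, x)
  p <- ncol(X)
  R <- diag(c(0, rep(lambda, p - 1L)))
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(X, y - mu)) - drop(R %*% beta)
    H <- crossprod(X * w, X) + R
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

standardize_fit <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sdv <- sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1L))
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
standardize_apply <- function(x, st) {
  t((t(x) - st$mu) / st$sd)
}

default_model <- list(
  fit = function(x, y) {
    st <- standardize_fit(x)
    list(beta = ridge_logistic_fit(standardize_apply(x, st), y), st = st)
  },
  score = function(fit, x) {
    drop(cbind(1, standardize_apply(x, fit$st)) %*% fit$beta)
  })

#' Cross-validated classification score for one sample set
#'
#' Repeated random stratified splitting: in each of `folds` iterations,
#' `test_size` of each class is drawn as the test set, the classifier is fit
#' on the rest and its AUC evaluated on the held-out samples; the mean AUC
#' over folds is returned.
#'
#' @param samples a [window_samples()] sample set.
#' @param config a [classification_config()].
#' @return mean cross-validated AUC in `[0, 1]`.
#' @export
subject_score <- function(samples, config) {
  stopifnot(inherits(config, "classification_config"))
  y <- samples$y
  if (length(unique(y)) != 2L) stopf("samples must have exactly 2 classes")
  model <- if (is.character(config$model)) default_model else config$model
  i1 <- which(y == 1L); i0 <- which(y == 0L)
  n1 <- max(1L, round(length(i1) * config$test_size))
  n0 <- max(1L, round(length(i0) * config$test_size))
  fold_seeds <- derive_seeds(config$seed, config$folds)
  aucs <- vapply(seq_len(config$folds), function(f) {
    test <- with_seed(fold_seeds[f], c(sample(i1, n1), sample(i0, n0)))
    fit <- model$fit(samples$x[-test, , drop = FALSE], y[-test])
    auc_score(model$score(fit, samples$x[test, , drop = FALSE]), y[test])
  }, 0)
  mean(aucs)
}

#' Group-level sign-flip permutation test of scores against chance
#'
#' One-sided test that subject scores exceed the chance level: with
#' \eqn{d_s = score_s - chance}, the statistic is \eqn{mean(d)}; the null is
#' built by independently flipping the sign of each subject's deviation.
#' When `2^S <= n_permutations` all sign assignments are enumerated and the
#' exact permutation p-value \eqn{\#\{null \ge obs\}/2^S} is reported (the
#' identity assignment makes p > 0); otherwise Monte-Carlo sampling with the
#' add-one rule \eqn{(1 + \#\{null \ge obs\})/(1 + n)} is used, ties counted
#' as extreme.
#'
#' @param scores per-subject classification scores.
#' @param chance chance level (0.5 for two-alternative classification).
#' @param n_permutations number of sign assignments to sample.
#' @param seed integer seed (Monte-Carlo path).
#' @return one-sided p-value in `(0, 1]`.
#' @export
group_test <- function(scores, chance = 0.5, n_permutations = 10000, seed) {
  if (length(scores) < 2L)
    stopf("group test needs at least 2 subjects, got %d", length(scores))
  if (missing(seed)) stopf("'seed' is required for permutation analyses")
  d <- scores - chance
  S <- length(d)
  obs <- mean(d)
  if (S <= 30 && 2^S <= n_permutations) {
    Sigma <- as.matrix(expand.grid(rep(list(c(1, -1)), S)))
    null <- drop(Sigma %*% d) / S
    sum(null >= obs - 1e-12) / length(null)
  } else {
    Sigma <- with_seed(seed, matrix(sample(c(1, -1), n_permutations * S,
                                           replace = TRUE), ncol = S))
    null <- drop(Sigma %*% d) / S
    (1 + sum(null >= obs - 1e-12)) / (1 + n_permutations)
  }
}

#' Sliding-window pattern classification with group inference
#'
#' For every analysis window: build trial-level window-mean samples per
#' subject ([window_samples()]), compute each subject's cross-validated AUC
#' ([subject_score()]), and test the group of subject scores against the
#' chance level 0.5 with a sign-flip permutation test ([group_test()]).
#' Because the classifier uses the full topography, it is sensitive to both
#' response-magnitude and pattern differences (and their interaction).
#'
#' @param x an `eeg_epochs` view containing both conditions.
#' @param comparison ordered pair of condition labels.
#' @param config a [classification_config()].
#' @param n_permutations sign-flip permutations for the group test.
#' @param alpha significance level for the `significant` flag.
#' @param workers number of worker processes over subjects.
#' @return object of class `classification_result` with `table` (data.frame:
#'   window_start, window_end, mean_auc, p, significant), `scores`
#'   (subjects x windows AUC matrix) and metadata.
#' @export
classify <- function(x, comparison, config, n_permutations = 10000,
                     alpha = 0.05, workers = 1L) {
  stopifnot(inherits(x, "eeg_epochs"), inherits(config, "classification_config"))
  missing_c <- setdiff(comparison, x$conditions)
  if (length(missing_c))
    stopf("condition(s) %s not in view (available: %s)",
          paste(missing_c, collapse = ", "), paste(x$conditions, collapse = ", "))
  win <- time_windows(x$times, config$window_ms, x$sampling_rate)
  S <- length(x$subjects)
  seeds <- matrix(derive_seeds(config$seed, nrow(win) * (S + 1L)),
                  nrow = S + 1L)
  score_one <- function(s) {
    vapply(seq_len(nrow(win)), function(i) {
      samples <- window_samples(x, x$subjects[s], comparison, win[i, ])
      cfg <- config
      cfg$seed <- seeds[s, i]
      tryCatch(subject_score(samples, cfg),
               error = function(e) stopf("window [%g, %g) ms, subject %s: %s",
                                         win$start_ms[i], win$end_ms[i],
                                         x$subjects[s], conditionMessage(e)))
    }, 0)
  }
  scores <- if (workers > 1L) {
    do.call(rbind, parallel::mclapply(seq_len(S), score_one, mc.cores = workers))
  } else {
    do.call(rbind, lapply(seq_len(S), score_one))
  }
  dimnames(scores) <- list(x$subjects, NULL)
  p <- vapply(seq_len(nrow(win)), function(i)
    group_test(scores[, i], 0.5, n_permutations, seed = seeds[S + 1L, i]), 0)
  tab <- data.frame(window_start = win$start_ms, window_end = win$end_ms,
                    mean_auc = colMeans(scores), p = p, significant = p < alpha)
  structure(list(analysis_name = "classification", table = tab,
                 scores = scores,
                 annotation = list(comparison = comparison,
                                   window_ms = config$window_ms,
                                   model = if (is.character(config$model))
                                     config$model else "plug-in",
                                   test_size = config$test_size,
                                   folds = config$folds,
                                   n_permutations = n_permutations,
                                   seed = config$seed, alpha = alpha,
                                   n_subjects = S)),
            class = c("classification_result", "topostat_result"))
}
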