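# Internal helpers shared across modules.

# Round half away from zero (base round() rounds half to even, which would
# make window boundaries depend on parity of the sample index).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded analyses do not disturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive independent sub-seeds from one master seed, e.g. one per window or
# per permutation worker chunk. Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Vectorized two-sided paired t-test on a subjects x variables matrix of
# differences. Returns list(mean, t, p). Constant all-zero columns get
# t = 0, p = 1 (no evidence); constant non-zero columns get p = 0
# (degenerate but directional). Equality with stats::t.test is asserted in
# the unit tests.
paired_t_cols <- function(d) {
  n <- nrow(d)
  if (n < 2L) stop("paired t-test needs at least 2 subjects, got ", n)
  m <- colMeans(d)
  s <- sqrt(colSums(sweep(d, 2L, m)^2) / (n - 1L))
  t <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1L)
  zero_sd <- s == 0
  p[zero_sd & m == 0] <- 1
  t[zero_sd & m == 0] <- 0
  p[zero_sd & m != 0] <- 0
  list(mean = m, t = t, p = p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
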