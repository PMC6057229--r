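#' Spatially smooth random topographic pattern
#'
#' Draws a pattern as white noise over a ring layout of sensors, circularly
#' smoothed by a moving average, then average-referenced (zero mean) and
#' scaled to unit norm. Centered unit-norm patterns all have the same GFP
#' (\eqn{1/\sqrt{n}}), which lets pattern effects be injected with the
#' response magnitude exactly matched.
#'
#' @param n_sensors number of sensors.
#' @param smooth half-width of the circular moving average (sensors);
#'   defaults to `max(1, n_sensors %/% 8)`.
#' @return unit-norm, zero-mean numeric vector of length `n_sensors`.
#' @export
smooth_pattern <- function(n_sensors, smooth = max(1L, n_sensors %/% 8L)) {
  z <- stats::rnorm(n_sensors)
  k <- 2L * smooth + 1L
  idx <- outer(seq_len(n_sensors), -smooth:smooth, `+`)
  idx <- (idx - 1L) %% n_sensors + 1L
  s <- rowMeans(matrix(z[idx], nrow = n_sensors))
  s <- s - mean(s)
  s / sqrt(sum(s^2))
}

#' Pattern orthogonal to a given pattern
#'
#' Draws a smooth pattern and removes its projection onto `to`
#' (Gram-Schmidt), returning a centered unit-norm pattern orthogonal to `to`
#' — the building block for pure pattern effects with matched GFP.
#'
#' @param to centered unit-norm pattern to be orthogonal to.
#' @inheritParams smooth_pattern
#' @return unit-norm, zero-mean vector orthogonal to `to`.
#' @export
orthogonal_pattern <- function(to, smooth = max(1L, length(to) %/% 8L)) {
  q <- smooth_pattern(length(to), smooth)
  q <- q - sum(q * to) * to
  q <- q - mean(q)
  q / sqrt(sum(q^2))
}

#' Half-sine response time course
#'
#' @param times timepoints in ms.
#' @param onset_ms,offset_ms support of the bump.
#' @param peak peak amplitude (arbitrary source units).
#' @return numeric vector over `times`, zero outside `[onset, offset)`.
#' @export
half_sine <- function(times, onset_ms, offset_ms, peak = 1) {
  a <- numeric(length(times))
  inside <- times >= onset_ms & times < offset_ms
  a[inside] <- peak * sin(pi * (times[inside] - onset_ms) / (offset_ms - onset_ms))
  a
}

#' Simulation specification for synthetic multi-subject epochs
#'
#' Describes a study to simulate: dimensions, neural sources (a topographic
#' pattern with an amplitude time course each), condition effects of two
#' separable kinds, and noise. Defaults emulate a typical mid-size ERP group
#' study: 16 subjects, 70 sensors, two conditions with 50 trials each,
#' 0-600 ms epochs at 250 Hz, and one source active 100-500 ms whose peak
#' gives a group GFP of a few microvolts.
#'
#' Effect kinds:
#' * `magnitude_scale` — inside `[onset_ms, offset_ms)` the source amplitude
#'   of `condition` is multiplied by `scale` (response magnitude changes,
#'   topographic pattern does not);
#' * `pattern_swap` — inside the window the source pattern of `condition` is
#'   replaced by `alternate_pattern` (topographic pattern changes; with a
#'   centered unit-norm alternate the GFP is matched by construction).
#'
#' @param n_subjects,n_sensors study dimensions.
#' @param conditions condition labels.
#' @param n_trials trials per condition: a single number or a vector named by
#'   condition (unbalanced designs are supported).
#' @param sampling_rate Hz.
#' @param epoch_ms epoch span `[start_ms, end_ms)`.
#' @param sources list of `list(pattern =, time_course =)`; `pattern` a
#'   unit-norm zero-mean sensor vector, `time_course` an amplitude vector
#'   over the epoch timepoints (µV-scaled source units). Default: one smooth
#'   pattern with a half-sine bump over 100-500 ms, peak 25 (group GFP
#'   around 3 µV at 70 sensors).
#' @param effects list of effects, each
#'   `list(kind = "magnitude_scale"|"pattern_swap", condition =, source = 1,
#'   onset_ms =, offset_ms =, scale =  or alternate_pattern = )`.
#' @param noise `list(sensor_sd =, subject_pattern_jitter_sd =,
#'   trial_amplitude_jitter_sd =)`: white sensor noise sd per sample (µV),
#'   sd of the per-subject additive pattern jitter (re-centered and
#'   re-normalized, so GFP matching is preserved), and sd of the
#'   multiplicative per-trial amplitude jitter around 1.
#' @param seed integer seed; the simulation is deterministic given it.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_subjects = 16, n_sensors = 70,
                            conditions = c("A", "B"), n_trials = 50,
                            sampling_rate = 250, epoch_ms = c(0, 600),
                            sources = NULL, effects = list(),
                            noise = list(sensor_sd = 2,
                                         subject_pattern_jitter_sd = 0.1,
                                         trial_amplitude_jitter_sd = 0.1),
                            seed) {
  if (missing(seed)) stopf("'seed' is required for simulation")
  if (n_subjects < 1) stopf("'n_subjects' must be >= 1")
  if (n_sensors < 2) stopf("'n_sensors' must be >= 2")
  if (length(epoch_ms) != 2L || epoch_ms[1] >= epoch_ms[2])
    stopf("'epoch_ms' must be [start, end) with start < end")
  if (length(n_trials) == 1L)
    n_trials <- stats::setNames(rep(n_trials, length(conditions)), conditions)
  if (!all(conditions %in% names(n_trials)))
    stopf("'n_trials' must name every condition")
  if (any(n_trials < 1)) stopf("'n_trials' must be >= 1 per condition")
  times <- epoch_times(epoch_ms, sampling_rate)
  if (is.null(sources)) {
    pattern <- with_seed(seed, smooth_pattern(n_sensors))
    sources <- list(list(pattern = pattern,
                         time_course = half_sine(times, 100, 500, peak = 25)))
  }
  for (k in seq_along(sources)) {
    src <- sources[[k]]
    if (length(src$pattern) != n_sensors)
      stopf("source %d: pattern length %d != n_sensors %d", k,
            length(src$pattern), n_sensors)
    if (abs(sqrt(sum(src$pattern^2)) - 1) > 1e-6)
      stopf("source %d: pattern must have unit norm", k)
    if (length(src$time_course) != length(times))
      stopf("source %d: time_course length %d != %d timepoints", k,
            length(src$time_course), length(times))
  }
  for (j in seq_along(effects)) {
    ef <- effects[[j]]
    if (!ef$kind %in% c("magnitude_scale", "pattern_swap"))
      stopf("effect %d: unknown kind '%s'", j, ef$kind)
    if (!ef$condition %in% conditions)
      stopf("effect %d: condition '%s' not in conditions", j, ef$condition)
    if (is.null(ef$onset_ms) || is.null(ef$offset_ms) ||
        ef$onset_ms >= ef$offset_ms)
      stopf("effect %d: need onset_ms < offset_ms", j)
    if (ef$kind == "magnitude_scale" && is.null(ef$scale))
      stopf("effect %d: magnitude_scale needs 'scale'", j)
    if (ef$kind == "pattern_swap") {
      if (is.null(ef$alternate_pattern))
        stopf("effect %d: pattern_swap needs 'alternate_pattern'", j)
      if (length(ef$alternate_pattern) != n_sensors)
        stopf("effect %d: alternate_pattern length mismatch", j)
    }
    effects[[j]]$source <- ef$source %||% 1L
  }
  for (f in c("sensor_sd", "subject_pattern_jitter_sd",
              "trial_amplitude_jitter_sd")) {
    noise[[f]] <- noise[[f]] %||% 0
    if (noise[[f]] < 0) stopf("noise$%s must be >= 0", f)
  }
  structure(list(n_subjects = n_subjects, n_sensors = n_sensors,
                 conditions = conditions, n_trials = n_trials,
                 sampling_rate = sampling_rate, epoch_ms = epoch_ms,
                 times = times, sources = sources, effects = effects,
                 noise = noise, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Strip all condition effects from a simulation spec
#'
#' Returns the same study under the global null: identical generative model
#' for every condition, noise and structure preserved. Used by every
#' type-I-error simulation.
#'
#' @param base a [simulation_spec()].
#' @return the spec with `effects = list()`.
#' @export
null_spec <- function(base) {
  stopifnot(inherits(base, "simulation_spec"))
  base$effects <- list()
  base
}

# jitter a pattern per subject: additive sensor noise, re-centered and
# re-normalized so centered unit norm (hence GFP) is preserved.
jitter_pattern <- function(pattern, sd) {
  if (sd == 0) return(pattern)
  p <- pattern + stats::rnorm(length(pattern), sd = sd)
  p <- p - mean(p)
  p / sqrt(sum(p^2))
}

#' Simulate a multi-subject epochs dataset
#'
#' Per subject and trial, the signal is
#' \eqn{x(t) = \sum_k a_k(t) \, g \, p_{s,k} + \epsilon(t)}: each source's
#' amplitude time course times its subject-specific pattern (the spec
#' pattern plus jitter, re-centered and re-normalized), with a multiplicative
#' per-trial amplitude factor \eqn{g} and white sensor noise. Condition
#' effects modify \eqn{a_k(t)} (`magnitude_scale`) or \eqn{p_{s,k}}
#' (`pattern_swap`) inside their `[onset_ms, offset_ms)` window.
#'
#' @param spec a [simulation_spec()].
#' @return a valid [eeg_epochs()] dataset, deterministic given `spec$seed`.
#' @export
simulate_epochs <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    times <- spec$times
    n_t <- length(times)
    n_sens <- spec$n_sensors
    K <- length(spec$sources)
    subjects <- sprintf("sub%02d", seq_len(spec$n_subjects))
    data <- vector("list", spec$n_subjects)
    names(data) <- subjects
    for (s in seq_len(spec$n_subjects)) {
      # subject realization of every source pattern, and of every effect's
      # alternate pattern (jittered through the same process)
      pat <- lapply(spec$sources, function(src)
        jitter_pattern(src$pattern, spec$noise$subject_pattern_jitter_sd))
      alt <- lapply(spec$effects, function(ef)
        if (ef$kind == "pattern_swap")
          jitter_pattern(ef$alternate_pattern,
                         spec$noise$subject_pattern_jitter_sd))
      blocks <- vector("list", length(spec$conditions))
      names(blocks) <- spec$conditions
      for (cn in spec$conditions) {
        # per-source sensors x time signal template for this condition
        sig <- matrix(0, n_sens, n_t)
        for (k in seq_len(K)) {
          a <- spec$sources[[k]]$time_course
          p_t <- matrix(pat[[k]], n_sens, n_t)      # pattern per timepoint
          for (j in seq_along(spec$effects)) {
            ef <- spec$effects[[j]]
            if (ef$condition != cn || (ef$source %||% 1L) != k) next
            inside <- times >= ef$onset_ms & times < ef$offset_ms
            if (ef$kind == "magnitude_scale") {
              a <- ifelse(inside, a * ef$scale, a)
            } else {
              p_t[, inside] <- alt[[j]]
            }
          }
          sig <- sig + p_t * rep(a, each = n_sens)
        }
        n_tr <- spec$n_trials[[cn]]
        g <- 1 + stats::rnorm(n_tr, sd = spec$noise$trial_amplitude_jitter_sd)
        block <- array(0, c(n_tr, n_sens, n_t))
        for (tr in seq_len(n_tr)) {
          eps <- if (spec$noise$sensor_sd > 0)
            matrix(stats::rnorm(n_sens * n_t, sd = spec$noise$sensor_sd),
                   n_sens, n_t) else 0
          block[tr, , ] <- g[tr] * sig + eps
        }
        blocks[[cn]] <- block
      }
      data[[s]] <- blocks
    }
    eeg_epochs(data, sprintf("E%03d", seq_len(n_sens)), times,
               spec$sampling_rate)
  })
}

#' Read a simulation spec from a JSON document
#'
#' JSON mirror of [simulation_spec()]; `sources` may give patterns as vectors
#' or `"smooth"`/`"orthogonal_to:<k>"` shorthands resolved under the spec
#' seed; `time_course` may be `{"half_sine": [onset, offset, peak]}`.
#'
#' @param path path to a JSON file.
#' @return a [simulation_spec()].
#' @export
read_simulation_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(doc$seed)) stopf("simulation spec is missing 'seed'")
  times <- epoch_times(doc$epoch_ms, doc$sampling_rate)
  resolve <- function() {
    srcs <- NULL
    if (!is.null(doc$sources)) {
      srcs <- lapply(seq_len(nrow_or_len(doc$sources)), function(k) {
        src <- pick(doc$sources, k)
        pattern <- src$pattern
        if (is.character(pattern) && pattern == "smooth")
          pattern <- smooth_pattern(doc$n_sensors)
        tc <- src$time_course
        if (is.list(tc) && !is.null(tc$half_sine))
          tc <- half_sine(times, tc$half_sine[1], tc$half_sine[2],
                          tc$half_sine[3])
        list(pattern = as.numeric(pattern), time_course = as.numeric(tc))
      })
    }
    effects <- list()
    if (!is.null(doc$effects)) {
      effects <- lapply(seq_len(nrow_or_len(doc$effects)), function(j) {
        ef <- as.list(pick(doc$effects, j))
        ap <- ef$alternate_pattern
        if (!is.null(ap) && is.character(ap) &&
            startsWith(ap, "orthogonal_to:")) {
          k <- as.integer(sub("orthogonal_to:", "", ap))
          ef$alternate_pattern <- orthogonal_pattern(srcs[[k]]$pattern)
        }
        ef
      })
    }
    list(sources = srcs, effects = effects)
  }
  r <- with_seed(doc$seed, resolve())
  simulation_spec(n_subjects = doc$n_subjects %||% 16,
                  n_sensors = doc$n_sensors %||% 70,
                  conditions = doc$conditions %||% c("A", "B"),
                  n_trials = unlist(doc$n_trials %||% 50),
                  sampling_rate = doc$sampling_rate %||% 250,
                  epoch_ms = doc$epoch_ms %||% c(0, 600),
                  sources = r$sources, effects = r$effects,
                  noise = as.list(doc$noise %||%
                                    list(sensor_sd = 2,
                                         subject_pattern_jitter_sd = 0.1,
                                         trial_amplitude_jitter_sd = 0.1)),
                  seed = doc$seed)
}

# half-open [start, end): exactly (end - start) * rate / 1000 samples
epoch_times <- function(epoch_ms, sampling_rate) {
  n <- as.integer(round((epoch_ms[2] - epoch_ms[1]) * sampling_rate / 1000))
  epoch_ms[1] + (seq_len(n) - 1L) * 1000 / sampling_rate
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
pick <- function(x, i) if (is.data.frame(x)) as.list(x[i, ]) else x[[i]]
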