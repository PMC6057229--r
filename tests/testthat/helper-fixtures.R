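# Fixture builders used across the test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# Tiny epochs dataset built from a per-(subject, condition, trial) generator
# function: gen(subject_index, condition_label, trial_index) -> sensors x
# timepoints matrix.
make_epochs <- function(n_subjects = 2, conditions = c("A", "B"),
                        n_trials = 3, n_sensors = 4, n_times = 10,
                        sampling_rate = 100, t0 = 0,
                        gen = function(s, cn, tr)
                          matrix(0, n_sensors, n_times)) {
  times <- t0 + (seq_len(n_times) - 1L) * 1000 / sampling_rate
  data <- lapply(seq_len(n_subjects), function(s) {
    blocks <- lapply(conditions, function(cn) {
      a <- array(0, c(n_trials, n_sensors, n_times))
      for (tr in seq_len(n_trials)) a[tr, , ] <- gen(s, cn, tr)
      a
    })
    names(blocks) <- conditions
    blocks
  })
  names(data) <- sprintf("s%02d", seq_len(n_subjects))
  eeg_epochs(data, paste0("E", seq_len(n_sensors)), times, sampling_rate)
}

# Small simulation spec for fast end-to-end tests.
quick_spec <- function(seed, n_subjects = 8, n_sensors = 16, n_trials = 20,
                       effects = list(), noise = list(
                         sensor_sd = 2, subject_pattern_jitter_sd = 0.1,
                         trial_amplitude_jitter_sd = 0.1)) {
  times <- seq(0, 149.999, by = 5)
  simulation_spec(
    n_subjects = n_subjects, n_sensors = n_sensors, n_trials = n_trials,
    sampling_rate = 200, epoch_ms = c(0, 150),
    sources = list(list(
      pattern = topostat:::with_seed(1000 + seed, smooth_pattern(n_sensors)),
      time_course = half_sine(seq(0, 145, by = 5), 25, 150, peak = 25))),
    effects = effects, noise = noise, seed = seed)
}

# Orthogonal alternate pattern for a quick_spec source.
quick_alt <- function(spec, seed = 17) {
  topostat:::with_seed(seed, orthogonal_pattern(spec$sources[[1]]$pattern))
}

expect_tables_identical <- function(f1, f2) {
  expect_identical(readBin(f1, "raw", file.info(f1)$size),
                   readBin(f2, "raw", file.info(f2)$size))
}
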