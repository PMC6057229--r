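test_that("patterns are centered, unit-norm and spatially smooth; orthogonalization works", {
  p <- topostat:::with_seed(1, smooth_pattern(70))
  expect_equal(mean(p), 0, tolerance = 1e-14)
  expect_equal(sum(p^2), 1, tolerance = 1e-14)
  q <- topostat:::with_seed(2, orthogonal_pattern(p))
  expect_equal(mean(q), 0, tolerance = 1e-14)
  expect_equal(sum(q^2), 1, tolerance = 1e-14)
  expect_equal(sum(p * q), 0, tolerance = 1e-12)
  # centered unit-norm patterns share the same GFP: 1/sqrt(n)
  expect_equal(gfp(p), 1 / sqrt(70), tolerance = 1e-12)
  expect_equal(gfp(q), 1 / sqrt(70), tolerance = 1e-12)
})

test_that("the epoch time axis is half-open with exact sample count", {
  t1 <- topostat:::epoch_times(c(0, 600), 250)
  expect_length(t1, 150L)
  expect_identical(t1[1], 0)
  expect_equal(max(t1), 596, tolerance = 1e-12)
  t2 <- topostat:::epoch_times(c(-200, 600), 1000)
  expect_length(t2, 800L)
})

test_that("zero noise and no effects give identical trials with closed-form GFP", {
  spec <- simulation_spec(n_subjects = 2, n_sensors = 12, n_trials = 5,
                          sampling_rate = 100, epoch_ms = c(0, 200),
                          noise = list(sensor_sd = 0,
                                       subject_pattern_jitter_sd = 0,
                                       trial_amplitude_jitter_sd = 0),
                          seed = 7)
  x <- simulate_epochs(spec)
  a <- x$data$sub01$A
  for (tr in 2:5) expect_identical(a[tr, , ], a[1, , ])
  expect_identical(x$data$sub01$A, x$data$sub01$B)
  expect_identical(x$data$sub01$A, x$data$sub02$A)
  # GFP(t) = |a(t)| * gfp(pattern)
  tc <- spec$sources[[1]]$time_course
  pat <- spec$sources[[1]]$pattern
  g <- apply(a[1, , ], 2, gfp)
  expect_equal(g, abs(tc) * gfp(pat), tolerance = 1e-12)
})

test_that("no-op effects are statistically inert at zero noise", {
  noise0 <- list(sensor_sd = 0, subject_pattern_jitter_sd = 0,
                 trial_amplitude_jitter_sd = 0)
  base <- simulation_spec(n_subjects = 2, n_sensors = 12, n_trials = 3,
                          sampling_rate = 100, epoch_ms = c(0, 200),
                          noise = noise0, seed = 8)
  s_scale1 <- base
  s_scale1$effects <- list(list(kind = "magnitude_scale", condition = "A",
                                onset_ms = 50, offset_ms = 150, scale = 1,
                                source = 1L))
  x <- simulate_epochs(s_scale1)
  expect_identical(x$data$sub01$A, x$data$sub01$B)

  s_swap_same <- base
  s_swap_same$effects <- list(list(kind = "pattern_swap", condition = "A",
                                   onset_ms = 50, offset_ms = 150,
                                   alternate_pattern = base$sources[[1]]$pattern,
                                   source = 1L))
  x2 <- simulate_epochs(s_swap_same)
  expect_equal(x2$data$sub01$A, x2$data$sub01$B, tolerance = 1e-12)
})

test_that("orthogonal pattern swap reproduces the hand-computed angle at zero noise", {
  noise0 <- list(sensor_sd = 0, subject_pattern_jitter_sd = 0,
                 trial_amplitude_jitter_sd = 0)
  pat <- topostat:::with_seed(29, smooth_pattern(12))
  base <- simulation_spec(n_subjects = 2, n_sensors = 12, n_trials = 3,
                          sampling_rate = 100, epoch_ms = c(0, 200),
                          sources = list(list(
                            pattern = pat,
                            time_course = half_sine(topostat:::epoch_times(
                              c(0, 200), 100), 0, 200, 25))),
                          noise = noise0, seed = 9)
  alt <- topostat:::with_seed(30, orthogonal_pattern(pat))
  spec <- base
  spec$effects <- list(list(kind = "pattern_swap", condition = "A",
                            onset_ms = 100, offset_ms = 200,
                            alternate_pattern = alt, source = 1L))
  x <- simulate_epochs(spec)
  g <- erp(x, "group")
  win <- time_windows(x$times, 50, x$sampling_rate)
  inside <- window_topographies(g <- erp(x, "group"), c("A", "B"), win[3, ])
  expect_equal(angle_measure(inside$A, inside$B),
               angle_measure(alt, base$sources[[1]]$pattern),
               tolerance = 1e-10)
  expect_equal(angle_measure(inside$A, inside$B), 0, tolerance = 1e-10)
  # before onset the patterns are identical
  before <- window_topographies(g, c("A", "B"), win[1, ])
  expect_equal(angle_measure(before$A, before$B), 1, tolerance = 1e-12)
})

test_that("magnitude effects preserve per-subject patterns without jitter", {
  spec <- simulation_spec(n_subjects = 3, n_sensors = 12, n_trials = 20,
                          sampling_rate = 100, epoch_ms = c(0, 200),
                          noise = list(sensor_sd = 0.01,
                                       subject_pattern_jitter_sd = 0,
                                       trial_amplitude_jitter_sd = 0),
                          effects = list(list(kind = "magnitude_scale",
                                              condition = "A", onset_ms = 0,
                                              offset_ms = 200, scale = 1.5)),
                          seed = 10)
  x <- simulate_epochs(spec)
  se <- erp(x, "subject")
  for (s in 1:3) {
    a <- rowMeans(se$A[s, , 5:15]); b <- rowMeans(se$B[s, , 5:15])
    expect_gt(angle_measure(a, b), 0.999)
  }
})

test_that("simulation is deterministic and null_spec strips effects", {
  spec <- quick_spec(seed = 33, effects = list(list(
    kind = "magnitude_scale", condition = "A", onset_ms = 50,
    offset_ms = 150, scale = 2)))
  expect_length(spec$effects, 1L)
  ns <- null_spec(spec)
  expect_length(ns$effects, 0L)
  expect_identical(ns$n_trials, spec$n_trials)
  expect_identical(ns$noise, spec$noise)
  x1 <- simulate_epochs(spec)
  x2 <- simulate_epochs(spec)
  expect_identical(x1, x2)
})

test_that("unbalanced trial counts are honored per condition", {
  spec <- simulation_spec(n_subjects = 2, n_sensors = 8,
                          n_trials = c(A = 12, B = 30), sampling_rate = 100,
                          epoch_ms = c(0, 100), seed = 12)
  x <- simulate_epochs(spec)
  expect_identical(dim(x$data$sub01$A)[1], 12L)
  expect_identical(dim(x$data$sub01$B)[1], 30L)
})

test_that("spec validation names the offending field", {
  expect_error(simulation_spec(seed = 1, epoch_ms = c(100, 100)), "epoch_ms")
  expect_error(simulation_spec(seed = 1, effects = list(
    list(kind = "whatever", condition = "A", onset_ms = 0, offset_ms = 10))),
    "kind")
  expect_error(simulation_spec(seed = 1, effects = list(
    list(kind = "magnitude_scale", condition = "Z", onset_ms = 0,
         offset_ms = 10, scale = 2))), "condition")
  expect_error(simulation_spec(seed = 1, effects = list(
    list(kind = "magnitude_scale", condition = "A", onset_ms = 10,
         offset_ms = 10, scale = 2))), "onset_ms")
  expect_error(simulation_spec(seed = 1,
                               noise = list(sensor_sd = -1)), "sensor_sd")
  expect_error(simulation_spec(n_sensors = 1, seed = 1), "n_sensors")
})

test_that("JSON simulation specs resolve shorthands deterministically", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "n_subjects": 2, "n_sensors": 8, "conditions": ["A", "B"],
    "n_trials": {"A": 5, "B": 5}, "sampling_rate": 100, "epoch_ms": [0, 100],
    "sources": [{"pattern": "smooth", "time_course": {"half_sine": [20, 90, 10]}}],
    "effects": [{"kind": "pattern_swap", "condition": "A", "onset_ms": 50,
                 "offset_ms": 100, "alternate_pattern": "orthogonal_to:1"}],
    "noise": {"sensor_sd": 0.5, "subject_pattern_jitter_sd": 0,
              "trial_amplitude_jitter_sd": 0},
    "seed": 99}', f)
  spec <- read_simulation_spec(f)
  expect_s3_class(spec, "simulation_spec")
  expect_equal(sum(spec$sources[[1]]$pattern *
                     spec$effects[[1]]$alternate_pattern), 0,
               tolerance = 1e-12)
  spec2 <- read_simulation_spec(f)
  expect_identical(simulate_epochs(spec), simulate_epochs(spec2))
})
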