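---
title: "Group-level topographic analysis of epoched EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level topographic analysis of epoched EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Classical ERP analysis reduces the EEG montage to a handful of hand-picked
sensors. That practice cannot distinguish two fundamentally different ways a
pair of experimental conditions may diverge: the same neural configuration
responding more or less strongly (a *magnitude* change), or a different
configuration of generators becoming active (a *pattern* change, visible as a
change in the topography's shape). It also invites selection bias and
multiple-comparison inflation across sensors, and it struggles with
between-subject variability in where effects appear on the scalp.

`topostat` implements a family of group-level analyses that always use the
full topography — the vector of all sensor potentials at a timepoint or
window — and that separate those two dimensions:

| analysis | sensitive to | blind to |
|---|---|---|
| `sensor_tests()` | per-sensor amplitude differences | (descriptive; uncorrected by default) |
| `gfp_compare()` | response magnitude | topographic pattern |
| `tanova()` | topographic pattern | response magnitude |
| `classify()` | both, including their interaction | — |

Used together, the four views localize an effect in time and attribute it to
magnitude, pattern, or both.

## Data model

An `eeg_epochs` object holds, per subject and condition, a
trials × sensors × timepoints array in microvolts on shared sensor and time
axes (strictly increasing, constant step). Datasets travel as HDF5
containers: root attributes `sampling_rate`, `times`, `sensor_names`; one
group per subject; one float dataset per condition with C-order shape
(trials, sensors, timepoints), so the same file reads naturally from R and
Python.

An `analysis_target` names the conditions, the ordered pairwise comparisons,
the time range, and the window length. `extract_epochs()` applies it and, by
default, re-references every sample to the across-sensor mean (average
reference). The topographic statistics assume a reference-free
representation; the flag exists because re-referencing interacts with sensor
subsetting, which is left to the user's judgment.

### Windows and rounding

Time slicing is half-open, `[start, end)` in ms. Boundaries map to sample
indices by rounding `(t - times[1]) * rate / 1000` half away from zero; this
makes adjacent windows partition the samples exactly even at awkward rates
(5 ms windows at 1100 Hz hold 5 or 6 samples, with no sample claimed twice
or dropped inside the range). A trailing remainder shorter than half a
window is dropped; a longer one is kept as a short final window. Group ERPs
weight each subject equally regardless of trial counts, matching
group-level inference.

## Global field power

GFP is the root mean square of the mean-referenced sensor values —
the population standard deviation of the topography:
$$\mathrm{GFP} = \sqrt{\tfrac{1}{n}\sum_i (U_i - \bar U)^2}.$$
It is invariant to the recording reference and scales linearly with
amplitude, which makes it a pure magnitude summary. Because GFP is
non-linear, the GFP of a group-averaged ERP is *not* the average of
individual GFPs (two subjects with opposed patterns average to a flat map
with zero GFP while each subject's GFP is positive); group curves are
therefore always the mean of per-subject GFP series, with between-subject
SEM. The windowed group test takes each subject's window mean of GFP
(window peak by option) per condition and applies a two-sided paired t-test.

## TANOVA: the angle measure and its permutation nulls

Pattern similarity between two topographies $\vec A, \vec B$ is the cosine
of their high-dimensional angle,
$$\cos\theta = \frac{\vec A\cdot\vec B}{|\vec A||\vec B|},$$
computed after average-referencing both vectors (a flag disables centering;
it is on by default for consistency with the GFP definition and reference
invariance). 1 means identical patterns, −1 polarity-reversed patterns, and
the normalization makes the measure magnitude-blind.

The observed statistic per window is the cosine between the group-averaged
ERP window-mean topographies of the two conditions. Its null distribution is
built by re-labeling under one of three strategies:

1. **pooled trials** — all trials of all subjects in one pool, labels
   re-assigned at random preserving the original per-condition counts,
   pseudo-condition pooled averages compared;
2. **within-subject trials** — the same, but each subject's trials are
   shuffled only among themselves (per-subject counts preserved), subject
   pseudo-ERPs averaged across subjects;
3. **within-subject ERPs** — subject × condition ERPs computed once, then
   each subject's two condition labels are swapped independently with
   probability ½ per shuffle.

Strategy 3 is orders of magnitude cheaper (it reduces to one matrix product
over sign vectors) and is the recommended first pass; strategies 1–2 remain
available for validation, optionally parallelized with per-shuffle derived
seeds so the result is identical for any worker count. When the number of
subjects $S$ satisfies $2^S \le$ `n_shuffles`, strategy 3 enumerates all
$2^S$ assignments exactly instead of sampling. The three strategies target
the same null only under full exchangeability: with subject-specific
topographies, strategy 1 pools away the subject structure and its null mean
genuinely drifts from strategies 2–3 — one reason the within-subject
strategies are preferred.

### p-value conventions

The test is one-tailed on the left (small cosine = dissimilar patterns, the
alternative of interest). For Monte-Carlo nulls,
$p = (1 + \#\{\mathrm{null} \le \mathrm{obs}\})/(1 + N)$ — the add-one rule,
so $p$ is never 0 and ties (to $10^{-12}$) count as extreme, which is
conservative. For exhaustive nulls the exact permutation p-value
$\#\{\mathrm{null} \le \mathrm{obs}\}/2^S$ is used; the identity assignment
is part of the null, so $p \ge 2^{-S} > 0$. A window whose topography has
zero norm after centering (no signal at all) cannot be tested: it is flagged,
given `p = NA`, and reported with a warning rather than silently skipped.

### Temporal correction

`correct(result, "cluster", alpha, min_duration_ms = 20)` keeps a window
significant only inside a maximal run of consecutive sub-threshold windows
whose total duration *exceeds* 20 ms; `correct(result, "fdr_bh")` applies
Benjamini–Hochberg across the comparison's windows instead. Corrected
significance is always a subset of uncorrected. Note the interaction between
grid and threshold: at 25 ms windows a single significant window already
survives a 20 ms minimum; onset estimation should use a grid at least three
windows per minimum duration.

## Sliding-window classification

Each trial's window-mean topography is one sample; the condition is its
label; classification runs per subject. The default model is L2-regularized
logistic regression (fixed penalty 1.0, unpenalized intercept) on features
standardized using the training fold only — a deliberately simple, nearly
hyperparameter-free linear model appropriate for the few hundred trials of a
typical EEG study. Any plug-in supplying `fit(x, y)` and a real-valued
positive-class `score(fit, x)` can replace it; AUC is invariant to monotone
transforms of the score.

Cross-validation uses repeated random stratified splits (default: 25 folds
of 30% test), scored by AUC, which is robust to unbalanced trial counts.
Group inference compares subject AUCs to chance 0.5 with a one-sided
sign-flip permutation test on $d_s = \mathrm{AUC}_s - 0.5$: the statistic is
$\bar d$, the null flips each subject's sign independently, exact
enumeration replaces sampling when $2^S \le$ `n_permutations` (exact p
$\#\{\mathrm{null}\ge\mathrm{obs}\}/2^S$; Monte-Carlo uses the add-one
rule). Because the classifier sees the whole topography, it responds to
magnitude changes, pattern changes, and their interaction — useful as a
cross-check on the GFP/TANOVA dissociation, at the price of attribution.

One calibration note: under the null, cross-validated scores carry a small
negative bias (a direction overfit to the training folds is anti-correlated
with the held-out complement of the same finite sample), so the one-sided
group test against 0.5 tends to be slightly conservative — rejection rates
at or just below α, never above, in the shipped calibration study.

## The synthetic generator

`simulation_spec()` + `simulate_epochs()` generate multi-subject epochs from
a controlled source model: each source is a spatial pattern with an
amplitude time course; per subject and trial,
$$x(t) = \sum_k a_k(t)\, g \,p_{s,k} + \varepsilon(t),$$
with per-subject pattern jitter (re-centered, re-normalized), a
multiplicative per-trial amplitude factor $g \sim N(1, \sigma_g)$, and white
sensor noise. Patterns are smoothed white noise on a ring of sensors,
centered and unit-normed — real electrode geometry is irrelevant to the
statistics under test, while spatial smoothness keeps the patterns
ERP-plausible. Centered unit-norm patterns all share GFP $1/\sqrt{n}$, so a
`pattern_swap` effect to an orthogonal pattern changes the topography with
response magnitude matched *by construction*, and a `magnitude_scale` effect
does the opposite. `null_spec()` strips all effects for type-I studies.

Defaults describe a mid-size group study: 16 subjects, 70 sensors, two
conditions × 50 trials, 0–600 ms epochs at 250 Hz (a standard ERP working
rate), one source active 100–500 ms with peak amplitude 25 source units —
about 3 µV of group GFP at 70 sensors — sensor noise 2 µV per sample,
pattern jitter 0.1, amplitude jitter 0.1. What the generator does *not*
emulate: 1/f and oscillatory background, volume-conduction sensor
correlations, artifacts, latency jitter across trials, and realistic head
geometry. Tests passing on this generator validate the statistical
machinery — calibration, dissociation, onset recovery — not robustness to
every property of real recordings.

## Validation studies shipped with the package

The test suite validates, among the unit-level oracles:

* **calibration** — on 200 null datasets (16 subjects, 32 sensors, 2 × 40
  trials, 200 Hz, three 50 ms windows), per-window rejection rates of all
  four analyses at α = 0.05 stay within ±3 Monte-Carlo SE of α;
* **dissociation** — on 100 magnitude-only (scale 1.5) and 100 pattern-only
  (orthogonal swap, GFP-matched) datasets, the magnitude-blind and
  pattern-blind tests each hold power ≥ 0.9 on their own dimension while the
  other stays at its null rate; classification detects both;
* **onset recovery** — with strong pattern effects injected at 150 ms into
  0–300 ms epochs, the first cluster-corrected significant window of TANOVA
  and classification lands within one 10 ms window of the onset, 20/20
  replicates.

The short epochs and coarse grids are a deliberate choice to keep hundreds
of replicates cheap; all statistics are windowed, so nothing in the code
depends on epoch length.

## Numerical and design notes

* Paired t-tests are computed vectorized across sensors/windows; columns
  with zero-variance, zero-mean differences give t = 0, p = 1 (identical
  data is evidence of nothing), and zero-variance non-zero differences give
  p = 0 (degenerate but directional).
* Seeds are required arguments wherever randomness enters (simulation,
  permutation, cross-validation splits) and are echoed into every result's
  annotation and serialized sidecar; a permutation result without a seed is
  rejected on load as malformed.
* Per-window, per-subject and per-shuffle sub-seeds are derived from the
  master seed, so results are independent of iteration order and worker
  count, and byte-identical across runs.
* Significant-sensor maps are uncorrected by default — the analysis is
  framed as a descriptive visualization of spatial extent, in the spirit of
  uncorrected display thresholds in neuroimaging; an FDR flag is available.
  α for the maps is a required, visible parameter rather than a baked-in
  default.
* Multi-condition (>2) omnibus TANOVA is out of scope; comparisons are
  pairwise. Sensors absent for any subject must be dropped consistently
  before analysis; no imputation is attempted.

## Worked example

```{r example}
library(topostat)

spec <- simulation_spec(
  n_subjects = 16, n_sensors = 32, n_trials = 40,
  sampling_rate = 200, epoch_ms = c(0, 150),
  effects = list(list(kind = "magnitude_scale", condition = "A",
                      onset_ms = 50, offset_ms = 150, scale = 1.5)),
  seed = 42)
x <- simulate_epochs(spec)

target <- analysis_target(c("A", "B"), list(c("A", "B")), c(0, 150),
                          window_ms = 50)
v <- extract_epochs(x, target)

gfp_compare(gfp_series(v), c("A", "B"), 50)       # magnitude: detected
tanova(v, c("A", "B"), 50, seed = 7)              # pattern: null, as designed
classify(v, c("A", "B"),
         classification_config(window_ms = 50, seed = 7))   # detected
```
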