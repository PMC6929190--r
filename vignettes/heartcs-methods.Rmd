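---
title: "Methods: compressed sensing and identification for cardiac signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compressed sensing and identification for cardiac signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartcs)
```

This vignette is the package's own account of its models, defaults and
numerical choices: what each stage assumes, which knobs matter, and
what the synthetic-data tests do and do not establish about real
recordings.

## Signal model and synthetic generators

`heartcs` treats a cardiac recording as a uniformly sampled
single-channel series (default 500 Hz, the common rate for wearable
ECG front-ends). The synthetic ECG beat is a sum of five Gaussian
bumps — P, Q, R, S, T — repeated at the heart rate; the PPG beat is a
systolic Gaussian plus a dicrotic Gaussian, with the inter-beat valley
emerging from their tails. Default ECG amplitudes (R = 1.0 mV,
P = 0.15 mV, Q = −0.10 mV, S = −0.15 mV, T = 0.30 mV) resemble a
lead-I trace; widths are kept narrow enough (σ of 7–9 ms for the QRS
components) that adjacent waves overlap by well under 1% of their
peaks, so each landmark's location is analytically unambiguous. Wave
onset/offset ground truth is defined as center ± 3σ, which covers
more than 99% of each Gaussian's energy and is exact by construction.

This model was chosen over dynamical-systems ECG simulators precisely
because its fiducials are closed-form: every detector claim in the
test suite is checked against exact indices rather than against
another algorithm's output. The cost is physiological realism — no
beat-to-beat variability, no arrhythmia, no asymmetric T waves, no
motion artifacts. Noise is additive and stationary (white Gaussian,
sinusoidal baseline wander, sinusoidal mains interference). Passing
tests therefore demonstrate algorithmic correctness on morphologically
plausible inputs, not clinical-grade robustness.

The population generator perturbs a base template multiplicatively
(amplitudes and inter-wave gaps, factors `1 + N(0, jitter)` floored at
0.5; gap-wise jitter keeps the P < Q < R < S < T order valid by
construction). No published morphology statistics back the default
`jitter = 0.1`; it is an arbitrary but conventional choice producing
clearly distinct yet physiological-looking subjects, and it is exposed
as a parameter everywhere it is used.

All generators draw randomness through one explicit seed; no function
touches the global RNG state observably (the caller's `.Random.seed`
is saved and restored).

## Sparse domains

Two representations are provided. The orthonormal DCT-II basis is
exact and parameter-free. The redundant K-SVD dictionary is trained on
non-overlapping windows of a recording (classically 1024-sample
windows, K = 800 atoms); training alternates OMP sparse coding with
per-atom rank-1 SVD updates restricted to the segments that use the
atom. Choices the method itself does not fix:

* **Initialization** — K distinct training segments, seeded draw,
  normalized (the K-SVD default).
* **Coding sparsity** — `ceiling(N/20)` nonzeros per segment (≈51 at
  N = 1024), configurable; iteration count defaults to 30.
* **Dead atoms** — an atom selected by no segment is replaced by the
  currently worst-represented segment, normalized.
* **Sign convention** — after each update the first nonzero entry of
  an atom is made non-negative, so persisted dictionaries and
  round-trip tests are stable under the SVD's sign ambiguity.
* **Monotonicity guard** — a segment's fresh OMP code is kept only if
  it does not increase that segment's residual. Greedy coding alone
  carries no such guarantee; with the guard the mean squared
  representation error is provably non-increasing, which the tests
  assert on every iteration.

## Sensing

Measurements are `y = Φx` with Φ i.i.d. Gaussian, `M = round(CR·N)`
rows (round half away from zero) and entry variance 1/M. The 1/M
scaling makes `‖Φv‖ ≈ ‖v‖` for unit-norm v, so the
restricted-isometry constant `δk` that drives SWAMP's initial
sparsity estimate refers to a near-isometric operator; unit variance
is available for completeness. Ensembles are never persisted — the
`(N, CR, seed)` triple regenerates them bit-exactly. Solvers
correlate against the column-normalized `A = ΦD` by default so the
weak threshold compares atoms fairly; coefficient estimates are
rescaled back to dictionary scale before synthesis.

## Greedy recovery

All three solvers re-fit by least squares on the current support after
every selection (rank-revealing QR; minimum-norm SVD solution with a
warning if the support matrix loses rank), which keeps the residual
orthogonal to the selected atoms and its norm non-increasing — both
asserted as invariants. Ties in any correlation ranking break toward
the lower atom index.

SWAMP specifics, where the staged procedure leaves room:

* The selection threshold is `α` **times the maximum** correlation
  magnitude; α defaults to 0.83, the standard ECG setting at CR 0.7
  (0.7 is typical for PPG at CR 0.5).
* The initial sparsity test uses `sqrt((1−δk)/(1+δk))` with
  `δk = 0.3` by default. Since the candidate set Λ0 consists of the
  top-k0 entries of `|Aᵀy|`, the test reduces to cumulative sums of
  the sorted squared correlations and is evaluated in one pass.
* Threshold correction is multiplicative (`α ← α·0.95` to admit more
  atoms, `α ← min(1, α/0.95)` to admit fewer), bounded at 100
  adjustments before raising a configuration error naming the
  bracket.
* Step growth is linear, `L = stage·L0` with `L0 = 5`; compounding
  growth is available behind a flag.
* Correlations are recomputed from the current residual every stage
  (the only reading consistent with matching-pursuit logic); already
  selected atoms are excluded from re-selection since projection
  leaves them with near-zero correlation anyway.
* When a stage's admissions would push the support past
  `Smax = floor(M/2)`, the solver terminates and returns the previous
  support's estimate (`terminated_by = "support_cap"`).
* `ε1 = 10⁻³` is absolute by default (appropriate for unit-to-mV
  scale signals), with a relative-to-`‖y‖` option.
* A zero observation returns an empty support with zero residual
  rather than an error, so batch sweeps aggregate cleanly; the same
  philosophy gives SNR an explicit `+Inf` sentinel at exact equality.

## Quality metrics

SNR, MR and RMSE all derive from the ratio `‖x−x̂‖/‖x‖`, giving the
identities `SNR = −20·log10(1−MR)` and `RMSE = (1−MR)·‖x‖/√N` that the
tests assert on random pairs. These identities also mean a published
MR and SNR for the same reconstruction cannot disagree; the package
computes all three from the definitions and reports them together.

## Denoising

Multilevel periodized DWT with coif3 (analysis filters frozen at full
double precision; the filter bank is orthogonal, so synthesis is its
transpose and reconstruction is exact to machine precision —
Parseval and round-trip are tested). The wavelet family is the one
with the strongest track record for cardiac denoising; depth, rule
and mode are not dictated by it, so the defaults are: universal
threshold `σ̂·sqrt(2·ln n)` with `σ̂ = median(|d₁|)/0.6745`, soft
thresholding, all detail levels thresholded, depth
`min(8, floor(log2 n))` (at 500 Hz depth 8 puts the approximation
below ~1 Hz, the baseline-wander band, which `remove_baseline = TRUE`
zeroes). Signals are reflect-padded to a multiple of `2^levels` and
trimmed back, so length is preserved for any input length.

## Fiducial detection and features

QRS detection runs on detail levels 3–5 of the coif3 decomposition
(≈8–60 Hz at 500 Hz) through a moving-RMS energy envelope (~80 ms).
The envelope matters: the decimated transform is translation-variant,
so raw subband amplitude varies severalfold between identical beats
depending on their phase against the dyadic grid, while windowed
energy is stable. Bursts above 40% of the envelope maximum, separated
by a 250 ms refractory window, are refined to the local signal
maximum (±50 ms). Q/S are the nearest minima within ±60 ms of R; P is
the maximum 80–280 ms before R; T the maximum 80–450 ms after R;
onsets/offsets are where the wave falls to 10% of its local amplitude
over the adjacent baseline. All thresholds are relative, so detection
is exactly invariant to amplitude scaling (tested). These windows and
fractions are standard physiology-motivated defaults — the detection
method itself prescribes none of them, which is the largest gap the
implementation had to fill; every one is a `fiducial_config()`
parameter.

Distance features are index differences in seconds divided by the
recording's mean RR (PPG: mean peak-to-peak) interval, making them
heart-rate-free; amplitude features are signed value differences,
first-named point minus second. The ECG vector has exactly 21 entries
(15 distances, 6 amplitudes), the PPG vector 12 (8 + 4); the
duplicate pair names appearing in both the distance and amplitude
lists (e.g. P–PD) are distinct quantities — an interval and a voltage
difference. A recording with fewer than two anchor peaks falls back
to plain seconds with a warning; beats missing any landmark are
excluded and counted.

## Identification

One binary RBF-SVM per unordered class pair, majority voting, ties
toward the lowest label with a warning. Feature normalization is
min-max to [0, 1] fitted on training data only (z-score available); C
and gamma come from stratified cross-validated grid search (default
10-fold, reduced to the smallest class size when necessary; default
grids 10⁻²–10³ × 10⁻³–10¹). The end-to-end harness
`recognition_experiment()` uses a smaller 3×3 grid and 3 folds as its
own default to keep a full 23-subject run quick; "three sets of
features" per subject is interpreted as three independent signal
windows each contributing one beat-averaged vector, and the
windows-per-subject counts are parameters.

## Problem sizes in the test suite

The suite exercises the full benchmark regime where it is cheap
(N = 1024, k = 100, CR 0.7 for the headline SWAMP runs; 20
repetitions) and scaled-down versions elsewhere as a deliberate
design choice: dictionary recovery on a planted 64×32 dictionary with
400 exactly 3-sparse segments and 30 iterations, phase-transition and
oracle checks at N ≤ 256, and a 5-subject recognition harness. The
exhaustive-subset oracle enumerates all C(12,2) supports on 8×12
instances; near that size OMP sits below its ~2k·ln N measurement
threshold, so the tests require oracle agreement on at least 80% of
draws plus exact agreement whenever OMP reaches a zero residual,
rather than near-certain success.

## Known limitations

* The generators produce strictly periodic, noise-stationary beats;
  detector robustness to ectopy, motion artifact or electrode noise
  is untested and out of scope.
* K-SVD training is plain R and comfortable at the hundreds-of-atoms
  scale; an 800-atom, 1000-segment training run is minutes, not
  seconds.
* The identification stage is a closed-set classifier: it always
  answers with one of the trained subjects and performs no impostor
  rejection.
* Real recordings are only approximately sparse; SWAMP on raw ECG
  windows typically terminates at the support cap rather than the
  residual tolerance, and fidelity is bounded by the signal's
  compressibility rather than by the solver.
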