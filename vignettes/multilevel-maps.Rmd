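---
title: "Multilevel time-scale maps of eye-movement dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel time-scale maps of eye-movement dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculomap)
```

This vignette is the package's account of its method: the measures and
their conventions, the map construction, the classifier, the synthetic
generator, and the design choices made where more than one reasonable
option existed.

## 1. The problem

Eye-movement event detection asks, for a stretch of recorded gaze
velocity, *which oculomotor regime produced it*: saccadic latency (the
programming delay after a stimulus jump), the saccade itself, or
fixation. Threshold detectors (velocity or dispersion) need user-tuned
cutoffs that transfer poorly across people and trackers. The approach
implemented here instead characterises signal *dynamics* — regularity
and trajectory divergence — on a hierarchy of time scales, and lets a
classifier find the regimes in that representation.

## 2. Measures and conventions

All three measures operate on a scalar velocity segment; entropy
tolerances are scaled by the standard deviation of the **full
1024-sample parent series**, not the segment (`r_scope = "whole_series"`,
the default; a segment-scope option exists for sensitivity analysis).
This matters: it makes a quiet segment of a loud series legible as
"quiet", which is precisely what distinguishes the saccade window.

**Conventions fixed by this package** (each has a one-line rationale;
all are tested):

* *SD convention*: population SD (divide by N). At N = 1024 the choice
  is numerically irrelevant (< 0.05 %), but one convention must be
  fixed.
* *Logarithms*: natural throughout; entropies are in nats.
* *Self-matches*: included for ApEn (every count is then positive, the
  estimator is total), excluded for FuzEn — this asymmetry follows the
  measures' defining formulas and is intentional.
* *FuzEn pattern counts*: both φ^m and φ^{m+1} average over the N − m
  patterns for which the (m+1)-length extension exists (the original
  fuzzy-entropy convention).
* *Degenerate FuzEn* (φ underflows to 0 because the tolerance is far too
  small for the segment): an error, which the map layer records as a
  missing cell — never silently zero or infinite.
* *Scale behaviour*: FuzEn's membership is exp(−dⁿ/r), so it is
  invariant under u → c·u only when r → cⁿ·r. With the study's r ∝ SD(u)
  and n = 2, fuzzy entropy is therefore *not* unit-free; tests assert
  the correct cⁿ invariance.

Defaults m = 2 with r = 0.2·SD for ApEn, and m = 2, n = 2 with
r = 0.075·SD for FuzEn. The FuzEn (n, r) pair is the region where the
across-series SD of the measure, tabulated by `fuzen_param_sweep()` over
a small calibration collection, begins to decrease slowly — the sweep is
shipped as a diagnostic so users can repeat the selection on their own
data.

## 3. Lyapunov estimation

The largest Lyapunov exponent is estimated from nearest-neighbour
divergence in a delay embedding. Design choices, in decreasing order of
consequence:

* **Embedding per series, not per segment.** τ (first minimum of lagged
  mutual information) and m (false nearest neighbours) are estimated
  once per 1024-sample series and reused for every map cell; 64-sample
  segments are too short for reliable selection. Segments where
  M = N − (m−1)τ leaves fewer than `min_vectors + follow_steps` states
  fall back to a fixed (m = 2, τ = 1).
* **Fallback on flagged selection.** For noise-like series MI has no
  meaningful minimum and FNN never plateaus; both selectors then flag
  their output and the map layer uses the fixed embedding instead of an
  arbitrary argmin.
* **Temporal (Theiler) exclusion** of neighbours closer than m·τ
  samples in time, capped at a quarter of the usable reference range so
  short segments retain admissible neighbours. The plain divergence
  formula has no such exclusion, but without it trivially adjacent
  samples dominate every pairing.
* **Numerically coincident neighbours are skipped.** Exactly periodic
  signals revisit states to within float rounding; log-ratios of
  rounding noise would masquerade as divergence. Neighbour search
  ignores candidates closer than 1e−9 × SD.
* **Two modes.** `horizon_average` evaluates (1/iΔt)·ln(d(i)/d(0)) at the
  single horizon i = `follow_steps` (default 10 samples) and averages
  over reference states — the direct reading of the divergence formula.
  `rosenstein_slope` fits the least-squares slope of ⟨ln d(i)⟩ over
  i = 0…`follow_steps` — the robust estimator, used for calibration. On
  a bounded attractor the log-separation curve saturates after roughly
  ln(attractor size / d₀)/λ steps, so calibration on the fully chaotic
  logistic map (true λ = ln 2 per step) uses a horizon of 5 steps inside
  the linear region; map cells keep the default 10.
* The single-horizon average is sensitive to the choice of i (its known
  weakness); both modes agree on regime classification
  (divergent/neutral/convergent) across chaotic, periodic and noise
  test signals, which is what the tests pin down.

A caveat documented rather than hidden: the histogram MI of a *pure*
noiseless sinusoid carries binning ripples that can pull the "first
minimum" below the quarter-period; the selector therefore smooths the
curve (3-point mean) and requires a candidate to undercut its ±3-lag
neighbourhood. Any realistic (noisy) signal yields the textbook
quarter-period lag.

## 4. Map, normalisation, classification

`segment_bounds()` tiles the series with half-open dyadic windows
[start, end); 1-based (level, index) labels match the field's "3rd and
4th segments" phrasing. Cell (l+1, s) spans exactly cells (l, 2s−1) and
(l, 2s) — tested for every cell.

Min-max normalisation is applied per measure and per level, pooled over
all series and segment indices of that stratum, **before**
cross-validation splitting — replicating the study pipeline's ordering.
That ordering leaks test-fold extrema into the rescaling; a fold-safe
variant (`knn_loso_cv(..., normalization = "fold_safe")`, fed raw
features) refits the rescale on training folds only. Whether the
normalisation is per measure or pooled across measures was an open
choice; per measure was chosen since the per-level curves of different
measures live on incomparable scales.

The class count for a feature set anchored at finest level lX is
NEMr/(Nss·2^(lX−1)) = 16, 8, 4, 2 for lX = 1…4. (The printed form of
this formula in the source material reads NEMr/Nss × 2^(lX−1), which
contradicts its own enumerated values; the package implements the
enumeration.)

kNN uses Euclidean distance and majority vote — the classifier is named
but not parameterised in the source — with ties broken toward the lowest
class index and distance ties by training-row order, making every run
bit-reproducible. Per-class accuracy is pooled over folds by default
(`accuracy = "per_fold"` averages within folds first); the study does
not say which it used. Reports default to the first four segments,
where the events of interest live; the full table is available.

## 5. The synthetic generator

No recording from the original experiment is available, so the
generator is the package's test bed. It emulates, per trial (1024 ms at
1000 Hz):

* **Latency**: duration ~ truncated normal (170 ± 25 ms, clipped to
  100–250 ms). Fixational micro-movement continues (the eye is still
  fixating the old target) plus a *preparatory component*: a weakly
  unstable AR(2) oscillation (30 Hz, poles at radius 1.01, tanh
  saturation at 8 °/s, innovation SD 2.5 °/s) whose locally divergent
  trajectories give the latency window its positive Lyapunov signature;
  it tapers out over the last 40 ms before onset.
* **Saccade**: duration ~ U(30, 80) ms, amplitude ~ U(12, 30)°,
  raised-cosine velocity pulse with peak 2A/duration **capped at
  500 °/s** — the cap models main-sequence velocity saturation and
  gives large fast saccades a velocity plateau, as real ones have.
* **Fixation**: stochastic tremor band (stable AR(2) resonant at 80 Hz,
  innovation 1.5 °/s, realised SD ≈ 9 °/s), drift random walk
  (0.35 °/s per sample), microsaccades (Poisson, 1.5 s⁻¹, raised-cosine
  pulses of 10–20 ms peaking at 15–40 °/s).
* **Peri-saccadic suppression**: micro-movement is attenuated to 10 %
  from 60 ms before saccade onset to 40 ms after its end, with 30 ms
  cosine ramps — modelling the documented inhibition of microsaccades
  and drift around target-elicited saccades.
* **Measurement noise**: white, SD 3 °/s, everywhere.

The spec-level distributions (latency, duration, peak cap, the
three-regime layout) are the study conditions; the remaining amplitudes
are this package's choices, set once on physiological grounds. The
suppression and saturation elements are what make the saccade window the
*entropy minimum* of the map — with them, averaged synthetic maps
reproduce the qualitative map signature of real data: lowest ApEn and
FuzEn in level-1 cells 3–4 and level-2 cell 2 (the 128–256 ms saccade
window), positive LLE in the latency cells, and homogeneous fixation
cells.

What the generator does **not** reproduce: tracker-specific noise
spectra and artifacts, binocular disparity, inter-participant
idiosyncrasy beyond seed-to-seed variation, post-saccadic glissades,
smooth pursuit, and the real covariance between latency, amplitude and
duration. Passing tests therefore demonstrate that the pipeline detects
the modelled structure, not that it attains any particular accuracy on
real recordings; the study's absolute accuracy tables depend on the
undeposited dataset and are out of reach at desk scale.

Individual 64 ms cells are noisy: the strict per-series statement
"cells (1,3), (1,4) and (2,2) are the minima of their levels" holds for
averaged maps (and is asserted over batches of seeded series) but only
for a minority of single series. This mirrors why the classifier, which
sees single-series cells, sits far from ceiling.

## 6. Numerical and scale choices

* Entropy implementations are vectorised distance-matrix computations,
  verified to 1e−12 against literal loop transcriptions of the defining
  formulas on 200 random series per run.
* Test and acceptance problem sizes — batches of 30 series (10 batches,
  300 series total) for the map-signature check, 60-series datasets for
  pipeline tests, N ≤ 96 for oracle comparisons — were chosen so the
  whole suite completes in minutes on one core while leaving the
  signature margins wide; the signature check's margins at these sizes
  are large (the saccade-window cells sit 20–40 % below their
  neighbours).
* All randomness flows through R's RNG; dataset-level seeds derive
  per-series seeds arithmetically (kept below 2³¹), so any series is
  reproducible in isolation.

## 7. Known limitations

* ApEn is biased for short segments (64 samples is short for m = 2);
  the maps inherit that bias uniformly across cells, so comparisons
  within a map remain meaningful while absolute values should not be
  compared across segment lengths.
* The LLE of stochastic signals is not a Lyapunov exponent in the
  dynamical-systems sense; positive values on noisy segments reflect
  noise-driven separation. The map uses it, as the study does, as a
  relative descriptor.
* Pooled min-max normalisation (the replicated ordering) slightly
  inflates cross-validated accuracy; use the fold-safe option when the
  absolute number matters.
* `fuzen_param_sweep()` reports the SD diagnostic only; choosing the
  "slow decrease" point is left to the analyst, as in the original
  procedure.
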