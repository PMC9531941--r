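---
title: "Neural state segmentation: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural state segmentation: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurostates)
```

## The model

During naturalistic stimulation, the multi-voxel activity pattern of a
brain region is well described as a sequence of *neural states*: periods in
which the pattern is relatively stable, separated by abrupt transitions.
`neurostates` models a region's time series as a timepoints x voxels
matrix (`bold_matrix`) that is piecewise stationary: each state `j` has a
mean pattern, and a boundary at timepoint `t` means `t` starts a new state
(timepoint 1 is never a boundary, so `k` states correspond to `k - 1`
boundaries).

### Greedy state boundary search (GSBS)

`gsbs()` searches for boundary locations that maximize the *fit*: the mean
over timepoints of the Pearson correlation (across voxels) between each
timepoint's pattern and the mean pattern of its state. Each iteration

1. finds the single boundary that maximizes the fit;
2. finds the best *pair* of boundaries, both interior to one existing state
   — this carves out a new state in one step, rather than a new border, and
   protects against strong transitions surfacing too late in the greedy
   sequence;
3. adopts whichever of the two candidate segmentations has the higher
   t-distance (see below); a single boundary wins ties and is used whenever
   no legal pair exists or a pair would exceed `k_max`;
4. fine-tunes: all current boundaries are swept once, from the weakest to
   the strongest, and each is shifted by 1 TR (earlier or later) when that
   improves the fit.

The search stops at `k_max` states (default 100, roughly half the number
of timepoints of a typical short naturalistic scan) or when no legal
placement remains.

The candidate searches use an algebraic shortcut: with per-timepoint
z-scored data and running column sums, the summed correlation between a
segment's timepoints and its own mean pattern reduces to differences of
precomputed cross-product cumulative sums, so each candidate split costs
O(1) after an O(n²v) setup. The tests assert exact agreement (1e-8) between
this machinery and the naive per-timepoint definition.

### The t-distance and model selection

`t_distance()` contrasts the Pearson correlations of timepoint pairs that
fall *within* one state against pairs in *consecutive* states, as a
pooled-variance two-sample t-statistic. It is large when states are
internally coherent and mutually distinct. `select_k()` picks the number of
states at the maximum of the t-distance over the search path, breaking
ties toward fewer states. The value is undefined (NA, never silently zero)
when either pair set has fewer than two members — e.g. a segmentation made
entirely of length-1 states.

Choices the metric's name does not fix, and what this package does:

* **t variant** — pooled-variance two-sample t.
* **minimum state length** — 1 TR during the search; length-1 states simply
  contribute no within-state pairs.
* **fit definition** — the mean of per-timepoint correlations with the
  state mean (the alternative, correlating flattened matrices, weighs
  long states differently; we fix the former).
* **1-vs-2 adoption** — candidates are compared *before* fine-tuning and
  the adopted segmentation is fine-tuned afterwards.
* **tie-breaks** — smallest candidate location on equal fit; equal-strength
  boundaries are fine-tuned in order of position; a 1-TR shift to earlier
  wins over an equally good shift to later. All are arbitrary but fixed, so
  runs are reproducible.
* **degenerate patterns** — correlations involving a zero-variance pattern
  (timepoint or state mean) count as 0, with a warning.

**Limitation — voxel count.** Model selection relies on between-state
pattern correlations concentrating near their expectation. With very few
voxels (about 10) and many states, chance correlations between state
patterns (sd roughly `1/sqrt(v)`) can make a coarser or finer segmentation
outscore the exact one, and `select_k` misses the planted k even on
noiseless data. From about 40 voxels — the simulator default, comparable to
real searchlight sizes — noiseless selection is exact in our tests.
Searchlights should therefore not be much smaller than the default
16-voxel floor.

### Boundary strength and durations

`boundary_strengths()` is the Pearson correlation distance (1 − r, range
[0, 2]) between the mean patterns flanking each boundary.
`state_duration_summary()` reports the median state duration in seconds
and the IQR divided by the median — a nonparametric analogue of the
coefficient of variation; quartiles interpolate linearly between order
statistics.

## Temporal preprocessing

All steps are linear, so their order is interchangeable up to numerical
noise (asserted in tests); the pipeline applies high-pass → deconvolution →
group averaging.

* `canonical_hrf(tr)` — the standard double-gamma: response peak delay 6 s,
  undershoot delay 16 s, both dispersions 1 s, undershoot ratio 1/6, 32 s
  support, unit peak. "Canonical" in the fMRI literature denotes exactly
  this kernel.
* `highpass(x, cutoff_hz = 0.008)` — 5th-order Butterworth, applied
  forward and backward so phase (and hence boundary timing) is untouched.
  Plain forward-backward filtering of a low-cutoff high-pass filter leaves
  large edge transients; we use odd-reflection padding with steady-state
  initial conditions, so a constant series filters to numerical zero.
* `wiener_deconvolve(x, hrf, noise_reg)` — the non-iterative frequency
  domain Wiener inverse `conj(H)·Y / (|H|² + λ)` per voxel. The default
  regularizer is `0.1 · mean(|H|²)`. Two boundary treatments matter: the
  FFT length is the next power of two at least twice the (extended) series
  length, preventing circular wrap-around; and the series is first extended
  by holding its last sample for one kernel length, because the scan
  truncates the convolution tail and a bare zero-padded inverse concentrates
  error in the final kernel-length of samples. Round-trip fidelity
  (convolve, then deconvolve at negligible λ) exceeds r = 0.99 and degrades
  monotonically as λ grows.
* `group_average(xs)` — element-wise mean across subjects. Single-subject
  boundary estimates are unreliable; averaging ~17+ hyperaligned subjects
  suppresses subject noise in proportion to the group size.

## Boundary overlap statistics

Boundary series are length-n vectors, zero where nothing changes and
positive at transitions (`boundary_series`). For event annotations,
`events_to_series()` keeps onsets marked by at least 5 observers
(salience) and maps an onset to the TR containing it,
`floor(onset / tr) + 1`; the mapping rule is configurable since different
conventions shift marks by one TR. Overlap requires exact same-TR
coincidence — no tolerance window — because hemodynamic lag is already
removed by deconvolution; no extra lag is applied to event onsets.

With `O = Σ e·s` the raw overlap and `OE = Σe · Σs / n` its expectation
under independence:

* absolute overlap `OA = (O − OE) / (Σs − OE)` — 0 at chance, 1 when every
  state boundary coincides with an event; also valid for weighted series
  (strength weighting via `weight_by_strength()`, co-occurrence weighting
  via `weight_by_cooccurrence()`), and invariant to uniform weight scaling;
* relative overlap `OR = (O − OE) / (min(Σa, Σb) − OE)` — 1 when the
  smaller boundary set is fully covered, so regions with different numbers
  of states compare fairly; symmetric for binary series.

Zero or degenerate denominators yield NA with a warning, and NAs propagate
(pairwise matrices record them as missing); silently imputing zero would
bias the group tests. `shared_unique_decomposition()` splits two binary
series into pointwise-product shared marks and the remainders, an exact
conservation (`shared + unique = input`); `shared_vs_unique_statistic()`
compares the event overlap of shared boundaries against the better of the
two unique baselines.

## Searchlight mapping

`build_searchlights()` scans spheres (default radius 3 voxels, 123 offsets
when complete) over a step-2 lattice anchored at the minimum corner of the
mask bounding box (the anchor is a free choice; fixing it makes runs
reproducible), keeping in-mask member voxels and dropping searchlights
with fewer than 16 members. `segment_searchlights()` runs GSBS per
searchlight, recording failures without stopping the run.
`reliability_filter()` screens searchlights by the relative overlap of
their boundaries across two independent subject groups; the default
threshold 0 excludes only undefined overlaps. This split-group proxy
stands in for a reliability criterion whose exact form is not fixed here;
the threshold is exposed. `project_to_voxels()` averages searchlight
scalars (including averaged p-values, which are then thresholded against
the FDR critical value) over the searchlights covering each voxel, and
masks voxels where fewer than half of the covering searchlights carry a
defined value.

## Network partitioning

Pairwise relative-overlap matrices are partitioned with Louvain
optimization of the *asymmetric signed modularity*
`Q* = Q⁺ − Q⁻ · v⁻/(v⁺ + v⁻)`, which down-weights the (rare) negative
overlap weights by their share of total strength. Missing matrix entries
count as zero weight (logged), zero being the neutral element of the
modularity sums. `louvain_once()` adds a node-level fine-tuning pass that
reassigns single nodes while Q* improves; `consensus_partition()` repeats
the stochastic partitioning (default 100 times), forms the co-assignment
consensus matrix, zeroes entries below chance, and re-partitions until the
consensus matrix is binary. The chance level is estimated from 1000 random
label assignments; under random assignment every pair has the same
co-assignment probability `Σ n_m(n_m−1)/(n(n−1))`, so each draw contributes
that exact value for a randomly chosen repetition's module sizes.
`gamma_sweep()` scans the resolution parameter over 1–3 in steps of 0.1
(fine enough to resolve one-decimal winners) and returns the partition
most similar to a reference labelling by adjusted mutual information;
`searchlight_reference_labels()` maps a voxelwise reference atlas to
searchlights by member-voxel majority vote. aMI uses the max-entropy
normalization; when both labelings are degenerate (normalizer equals the
expected MI) the convention is 1 for identical partitions, else 0.

## Group inference

`split_groups()` partitions subjects into balanced random groups (sizes
differing by at most one; e.g. 265 subjects into 15 groups of 17/18). The
per-group pipeline must be re-run independently per group — independence
is what validates the test. Per searchlight, `wilcoxon_signed_rank()`
tests the per-group statistic against zero: zeros dropped, midranks for
ties, the exact null (convolution over sign assignments, valid with
midranks) up to n = 25 — comfortably covering 15 groups — and a normal
approximation with continuity correction beyond; fewer than 5 usable
values yield NA. `fdr_bh()` applies Benjamini–Hochberg step-up control
(via `stats::p.adjust`) and reports the critical p used to threshold
projected maps; correction is applied at the voxel-averaged level, with
searchlight-level correction available. `sign_consistency()` vetoes
effects whose pooled sign contradicts the mean group effect. Under a
simulated complete null the flagged fraction stays below q = 0.05.

## What the simulator does and does not emulate

`sim_config()` / `generate_dataset()` produce multi-region, multi-subject
data with planted ground truth:

* piecewise-constant state patterns, one iid standard-normal value per
  voxel per state, shared across subjects — the pattern model implicit in
  GSBS;
* regions assigned round-robin to networks; within a network the region
  with most states draws boundaries first and slower regions copy each
  boundary from that reference set with probability `nestedness` —
  a direct dial for hierarchically nested boundary sharing;
* event boundaries as a random half (default) of the boundaries of the
  slowest region of the slowest network, mirroring the idea that perceived
  events coincide with widely shared state transitions;
* boundaries drawn without replacement with a minimum state length of
  2 TRs (length-1 states leave within-state correlations undefined);
* additive Gaussian noise per subject, SD relative to the unit pattern SD,
  white by default with an optional AR(1) coefficient to exercise
  filtering/deconvolution robustness;
* optional convolution of the noiseless pattern course with the canonical
  HRF before noise.

Defaults (193 timepoints, TR 2.47 s, 40 voxels per region, noise SD 1, 20
subjects, 10–20 states per region, nestedness 0.5) describe a short
naturalistic fMRI scan at searchlight scale. Not emulated: hemodynamic
nonlinearity, physiological noise, head motion, spatial noise correlations,
and hyperalignment residuals. Passing recovery tests on these simulations
therefore demonstrates algorithmic correctness under the stated model, not
robustness to every property of real data.

## Problem sizes used by the test suite

The suite exercises: exhaustive t-distance oracle comparisons at 12
timepoints and up to 4 states; boundary recovery on 200 timepoints x 40
voxels with 15 planted states averaged over 20 simulated subjects at noise
SD 1; overlap null calibration over 10,000 Monte-Carlo draws; consensus
recovery on 40-node planted 4-block matrices with 100 repetitions; FDR
calibration over 1,000 simulated null maps of 40 searchlights x 15 groups;
and nestedness monotonicity over 15 ground-truth draws per level. These
sizes were chosen so each property is measured with comfortable
Monte-Carlo margins while the whole suite stays quick on a laptop.
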