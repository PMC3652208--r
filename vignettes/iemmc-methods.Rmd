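---
title: "Methods: the iemmc arrhythmia detection system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the iemmc arrhythmia detection system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the numerical and design choices
made where the method left them open.

## 1. The detection system

The package detects arrhythmias in single-lead ECG without labelled
training data, in three stages: adaptive filtering, rule-based waveform
delineation with time-domain feature extraction, and maximum-margin
clustering driven by an immune evolutionary search. Each stage is usable
on its own; `runPipeline()` composes them.

## 2. Wavelet-transform adaptive filtering

ECG recordings carry electromyographic (EMG) noise at high frequencies
and baseline wander (BW) plus motion artifact below a few hertz; the
latter band overlaps the ECG's own P/T energy, which rules out plain
band-stop filtering without waveform distortion.

The filter is a two-input adaptive noise canceller built from wavelet
approximations:

1. `selectDecompositionLevels(fs, fLow, fHigh)` picks the least depth
   `i` whose approximation band edge `fs/2^(i+1)` is at or below `fHigh`
   (default 50 Hz — retains QRS energy), and the least additional depth
   `j` whose edge is at or below `fLow`.
2. `waveletDenoiseHigh()` reconstructs the depth-`i` approximation with
   all detail coefficients zeroed — removal, not shrinkage — giving the
   primary input E1.
3. `extractLowReference()` applies `j` further levels to E1 and
   reconstructs the approximation: E2, the drift estimate.
4. `lmsFilter()` subtracts from E1 the component predictable from E2 by
   an adaptive FIR filter.

**Discrete wavelet transform.** The DWT (Daubechies db2/db4/db6 filter
banks, symmetric edge-repeating extension, redundant boundary
coefficients) is implemented in the package itself; the scheme is an
exact analysis/synthesis pair for arbitrary signal lengths, and the test
suite asserts perfect reconstruction, DC preservation and band-edge
attenuation. db4 is the default family: its compact support matches
QRS-like transients. Boundary handling uses symmetric extension to avoid
edge spikes that would corrupt R detection.

**Choice of `fLow` (default 0.8 Hz).** The noise band the filter targets
extends to roughly 7 Hz, but the *reference* must contain drift, not
signal: wavelet approximations leak a substantial share of transient
QRS/T energy far above their nominal band edge, so a reference cut near
the noise-band bound swallows most of the ECG and the canceller then
removes signal rather than noise. The default instead follows the
standard ambulatory-monitoring baseline-wander cutoff (≈ 0.67 Hz),
rounded to the nearest achievable dyadic edge (0.70 Hz at fs = 360 Hz,
i.e. `i = 2, j = 6`). The level-selection rule itself is independent of
this default and can be driven with any `(fLow, fHigh)`.

**LMS step (default μ = 0.001, order M = 8).** The update is normalized
by a leaky-average estimate of the reference power rather than the
instantaneous tap power: narrowband references pass through zero, where
instantaneous normalization makes the step explode. The step size trades
convergence speed against weight jitter driven by the ECG itself (which
acts as gradient noise); the default converges within a few seconds at
common ECG sampling rates while keeping the steady-state residual of a
coherent 0.3 Hz interferer more than 20 dB down — both properties are
asserted in the acceptance tests. Divergence (grossly overlarge μ)
raises an error naming μ.

**Known limitation.** An adaptive canceller whose reference is a
low-passed version of its primary input always cancels a little genuine
in-band signal; on a perfectly clean record the filter output is
therefore slightly *less* correlated with the input than unity (the test
suite asserts > 0.9 at defaults). On noisy records the cancellation
gains far outweigh this loss, and the suite asserts that filtering never
reduces correlation with the clean signal relative to the noisy input.

## 3. Waveform delineation

R peaks carry the steepest slope of the cardiac cycle, so detection
operates on the rectified first difference, lightly smoothed by a 20 ms
moving average — without smoothing, broadband noise spikes are accepted
as peaks, drag the adaptive threshold down and trigger a false-positive
cascade. Candidates must exceed an adaptive lower limit (default 0.4 of
the running mean of the last 8 accepted slope-peak heights), detections
within the 200 ms refractory period of the previous beat are suppressed
(the tall-T guard), and RR intervals longer than 1.66× the median
(a classic escaped-beat heuristic) are re-scanned at half threshold.
Detected indices are local maxima of the raw voltage.

Q and S are the turning points connecting baseline and QRS edges,
operationalized as the first local extremum — or slope flattening below
10 % of the QR slope — scanning outward from R within 0.1 s. P is the
voltage maximum within 0.16 s before Q; T is the voltage maximum between
S and the next beat's P (final beat: a 0.4 s fallback window, flagged).
Beats whose windows are truncated by a record edge are flagged invalid
rather than raising; absent-P morphologies (ventricular beats) still
return an argmax but are flagged low-confidence below a 0.05 mV
amplitude floor.

## 4. Features

Nine time-domain quantities per beat, spanning two succeeding cardiac
periods: the preceding and following RR intervals, QRS (Q→S), PR (P→R),
QT (Q→T-peak), ST (S→T-peak) durations in seconds, and R/P/T amplitudes
in millivolts above a per-beat baseline estimated as the median of the
PR segment (between P and Q). Two definitional points were open:

* **QT** is measured Q-peak to T-peak, consistent with ST = S→T-peak;
  T-wave end is never delineated, so a Q-to-T-end reading would be
  uncomputable.
* **"Normalized"** features are plain physical units (s, mV) — the
  magnitudes of the packaged reference rows (RR ≈ 0.85 s, R ≈ 1.8 mV)
  are only consistent with that reading. An optional z-score step
  (`normalizeFeatures`) equalizes scales before clustering; constant
  columns map to zeros, never NaN.

Beats lacking a landmark or neighbour, or with non-positive intervals,
are dropped with a warning.

## 5. Maximum-margin clustering with immune evolution

For labels `y` fixed, minimizing `½‖w‖² + C/2 Σ ηᵢ²` under the equality
constraints `yᵢ(w·φ(xᵢ)+b) = 1−ηᵢ` is the least-squares SVM problem; its
KKT conditions form one linear system per labeling, solved exactly
(`innerSolve`). The slack is per-sample: a single shared slack would
make the KKT system degenerate. Near-singular systems (duplicate points)
receive a 1e−10 ridge, with a message. The affinity of a labeling is
`F(y) = exp(−J)`.

**Bias/label refinement.** With the direction `w` fixed, the remaining
problem is to minimize `Σ (sᵢ + b − yᵢ)²` over the bias and a balanced
labeling, where `sᵢ` are raw scores. Sorting the scores, every split
position `p` (the `p` lowest scores labelled −1) defines one threshold
labeling; positions violating the balance constraint `|Σyᵢ| ≤ ℓ` —
equivalently `p` outside `[(n−ℓ)/2, (n+ℓ)/2]`, with the bound rounded
outward when `n` and `ℓ` have different parity so the candidate set is
never empty — are discarded. For each surviving labeling the optimal
bias is the closed form `b = mean(y − s)`. An exchange argument (swapping
a −1 above a +1 strictly lowers the objective at any bias) shows the
joint optimum over *all* balanced labelings is attained at a threshold
labeling, so this search is exact; the test suite confirms it against
exhaustive enumeration over all 2ⁿ sign vectors.

**The immune loop.** Candidate labelings ("antibodies") are evolved by
clonal selection: evaluate affinities; clone the `N_c` best with
rank-proportional copy counts; hypermutate the next `N_m` by flipping
opposite-signed label *pairs* (conserving `Σy` exactly), with flip count
growing linearly from 1 (best) to `f_max` (worst) and mutants kept only
on improvement; reselect the best distinct antibodies; and
receptor-edit the worst fraction with fresh random balanced labelings.
Evaluation is Lamarckian: the solve→refine cycle iterates to a fixed
point (capped at 25 rounds) and the refined labeling replaces the
antibody when it lowers J. A single refinement step is enough for linear
kernels but strands RBF search in memorization plateaus; the iterated
descent is what lets random initializations reach the optimum, which the
acceptance harness checks both at toy scale (exhaustive enumeration over
all balanced labelings at n = 10) and on separated Gaussian blobs
(20/20 seeded random-init runs).

**Kernel and its calibration.** The default kernel is the unsquared-norm
RBF `k(x,x′) = exp(−‖x−x′‖/σ²)` (the form used throughout the
clustering stage), with the conventional squared variant and a linear
kernel selectable. Two couplings matter:

* `C` (default 1): the loss is *summed* over samples, so moderate `C`
  already weights data heavily. Large `C` lets the kernel machine drive
  the slacks toward zero for *any* labeling — every antibody looks
  equally good, the refinement landscape flattens, and random-init
  recovery fails. The conventional scan set {1, 10, 100, 500} remains
  available.
* `σ` (default: widened median heuristic, median pairwise kernel value
  ≈ 0.9): for the same reason, the kernel must be smooth at the cluster
  scale so that scores average over neighbourhoods instead of
  memorizing labels.

**Balance.** The bound defaults to `ℓ = ⌊0.2 n⌋`, preventing the trivial
one-cluster and single-outlier solutions. Recursive multiclass
bipartition (`recursiveMulticlass`, always splitting the current largest
cluster) relaxes intermediate splits to `ℓ = ⌊m/3⌋`: an intermediate
cluster legitimately holds several classes, so 1:2 splits must remain
feasible — at `0.2 m` a three-way-equal cluster cannot be cut at its
natural boundary at all. The multiclass mechanism itself is a package
design choice; the binary objective does not prescribe one.

**Other conventions.** Sign ties `sign(0)` map to +1. All reported
labelings are canonicalized (first component forced positive), and
`J(y) = J(−y)` exactly. The suppression threshold `t_s` (default n/10,
canonical-sign Hamming distance) de-duplicates the initial population.
Every random draw flows from one master seed through named substreams
(initialization, mutation, editing, per-generation), making runs
bit-reproducible. Elitism guarantees a non-decreasing best-affinity
history; stalling (default 10 generations without improvement, cap 50)
terminates the loop.

## 6. Evaluation

Unsupervised clusters are matched to classes by exhaustive permutation
(k ≤ 8), which is exact at trivial cost; unequal counts fall back to the
best injective assignment. Metrics follow the standard one-vs-rest
confusion-matrix definitions — sensitivity TP/(TP+FN), specificity
TN/(FP+TN), accuracy (TP+TN)/n, in percent — with the pooled (micro)
sensitivity `100·trace/total`. Empty classes yield NA, never NaN. The
packaged reference tables ship verbatim; in the bundled
confusion-matrix layout the cluster columns are already positionally
matched to the class rows (the row labels of the two ventricular-related
classes appear swapped relative to the inventory table, visible in the
row sums), so the loader names cluster columns `c1..c5` and the
positional diagonal is the matched diagonal. A seeded Lloyd K-means
(`stats::kmeans`) is the baseline partitioner.

## 7. The synthetic generators

`genSyntheticECG()` builds each beat as five Gaussian bumps (P, Q, R, S,
T) with per-class amplitude/offset/width parameters and per-class mean
RR, summed on a scheduled beat grid — chosen over dynamical-model ECG
synthesis because the landmark ground truth is then exact and
closed-form, which is what scores the delineators. AAMI classes are
parameter shifts: S has short preceding RR and a small P; V a wide QRS
and no P; F intermediate QRS; Q aberrant (low) amplitudes. Noise is
additive: a sub-7 Hz baseline sinusoid, a powerline sinusoid, and white
broadband EMG-like noise, each seeded; the deterministic components
compose exactly additively. `genClusterData()` draws unit-sd Gaussian
blobs on a regular simplex scaled to a requested centroid separation.

Default study conditions used by the harnesses: fs = 360 Hz, 10 s
records, RR jitter 0.04 s for detection fixtures; baseline wander
0.9 mV at 0.3 Hz plus 0.12 mV broadband noise for filter fixtures
(severe but realistic ambulatory contamination); blob fixtures n = 60,
separation 6 sd, balanced; the end-to-end pipeline check uses a 91 s
two-class (N/V) record, about 120 beats, with moderate noise. Problem
sizes for the oracle comparisons are n ≤ 8 (solver, 50 seeds × 3 values
of C), n ≤ 10 (refinement, 20 seeds; toy global optimum via full 2¹⁰
enumeration).

What the fixtures do **not** emulate: real inter-patient morphology
variability, non-sinusoidal wander, electrode motion transients,
overlapping P-on-T at high rates, or the class-frequency imbalance of
clinical archives. Passing tests therefore demonstrate correctness of
the algorithms under controlled conditions, not clinical performance.

## 8. Numerical choices and degenerate inputs

* KKT systems: dense `solve()`; ridge 1e−10 on near-singularity.
* Objective values clipped at 0 against roundoff; improvement
  comparisons use 1e−12 tolerances.
* All-identical scores in refinement: error (no split exists).
* All-same-sign labelings cannot be pair-mutated: error; balance ℓ < n
  excludes them upstream.
* A flat signal yields an empty R-peak set with a warning, not an
  exception; fewer than 3 R peaks is an error because two succeeding
  periods are required for features.
* Detection indices are 1-based throughout, matching R convention;
  intervals are reported in seconds and amplitudes in mV.

## 9. Known limitations

* The clustering cost is one (n+1)×(n+1) linear solve per evaluated
  labeling — fine for a few hundred beats, not for full 24 h recordings
  without windowing.
* Recursive bipartition cannot merge; a class split across two branches
  early is never reunited.
* The delineators assume upright R waves; inverted-lead recordings
  would need a polarity flip upstream.
* T-end (hence clinical QT) is out of scope; QT here is Q-peak→T-peak.
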