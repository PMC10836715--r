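---
title: "Quantifying the arrow of time in multichannel neural recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the arrow of time in multichannel neural recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A system in thermodynamic equilibrium is statistically time-reversible:
nothing in its trajectories distinguishes forward from backward time. Ongoing
brain activity is not such a system — it consumes energy, breaks detailed
balance, and the degree of that breakage ("irreversibility", the arrow of
time) differs between behavioral states such as active wakefulness, quiet
rest and slow-wave sleep. `neuroarrow` implements a complete analysis chain
for measuring this on multichannel surface recordings (ECoG/LFP-like
signals): a model-free pairwise irreversibility estimator, its decomposition
across cortical systems and frequency bands, a spectral behavioral-stage
classifier, discrete network-state dynamics with information-theoretic
summaries, and an autoencoder latent-space analysis. Because real recordings
carry no ground truth, a synthetic generator with planted structure is a
first-class part of the package, and all validation is against planted
truth.

## The irreversibility estimator

For channels $x$ and $y$, the forward time-shifted correlation at lag
$\Delta t$ is $C_{\mathrm{fwd}} = \langle x(t),\, y(t+\Delta t)\rangle$
(Pearson), and the reversal correlation is the same statistic after flipping
the time order of both series. The pairwise irreversibility at shift $T$ is

$$ I_{x,y}(T) \;=\; \bigl|\,C_{\mathrm{fwd}}(T) - C_{\mathrm{rev}}(T)\,\bigr| . $$

`irreversibility_windows()` evaluates this in non-overlapping 1-s windows at
a 100-Hz analysis rate with a one-frame shift ($\Delta t = 1/f_s$), the
least arbitrary choice of temporal scale. Algebraically
$C_{\mathrm{rev}}(x, y) = C_{\mathrm{fwd}}(y, x)$ at the same shift, so the
pair value is identical for both orderings; we therefore compute the full
lagged cross-correlation matrix per window and read both directions off it
($I = |C - C^\top|$ elementwise), storing one symmetric matrix per window
with a zero diagonal.

**Aggregation across windows.** The per-window value $|c_f - c_r|$ of a
*reversible* process does not vanish: it is the absolute value of a noisy
difference of two windowed correlations, whose expectation is a positive
folded-normal noise floor (about $0.8\sqrt{2/n_w}$ per pair for white noise
with $n_w$ frames per window). A time average of per-window absolute values
therefore converges to that floor, not to zero. For long-run summaries,
`aggregate_irreversibility()` instead averages the *signed* differences
across windows per pair before taking the absolute value; this estimator is
consistent (it converges to 0 for reversible processes as the window count
grows) and is used for all stage-level, system-level and band-level
summaries. The per-window absolute values are retained for time courses,
where the instantaneous magnitude is the quantity of interest.

**Numerical choices.** Pearson correlations use per-window means and SDs,
making windows exchangeable. Channel pairs with a zero-variance segment are
excluded pairwise, not globally. A trailing partial window is discarded with
a log message. Resampling to the analysis rate (`resample_recording()`) uses
polyphase FIR anti-aliased resampling; upsampling is refused.

## System and frequency decompositions

`group_by_system()` averages pair values with both channels inside one
cortical system, over all same-system pairs ("within"), and over
cross-system pairs ("between"); with a stage sequence supplied, windows are
grouped by majority stage label. Systems with fewer than two channels report
a missing within value.

`band_sweep()` filters the recording into contiguous 1-Hz bins from 0 to
50 Hz (zero-phase 4th-order Butterworth, applied forward-backward — a
zero-phase filter is essential here, since a causal filter would itself
inject temporal asymmetry) and runs the estimator per bin. The DC bin is
narrowed to 0.5–1 Hz. Canonical bands are delta 1–3, theta 4–6, alpha 8–16,
beta 17–30 and gamma 30–50 Hz; a bin belongs to a band when its lower edge
lies in the band's range, which leaves the bins starting at 0, 7 and 16 Hz
deliberately unassigned (the band table has gaps there). Band means are
arithmetic means of member bins. Note that 1-Hz-wide signals are strongly
autocorrelated within a 1-s window, so per-bin estimates carry a much higher
sampling floor than broadband ones; planted effects must be judged against
that floor, which is why the band tests compare bins against each other
rather than against zero.

## Behavioral staging

`compute_stage_features()` builds a per-channel spectrogram (60-s Hann
windows, 5-s steps) at 14 log-spaced center frequencies. Log spacing cannot
start at 0 Hz, so the centers run from 0.5 to 128 Hz, 0.5 Hz being the
smallest physiologically meaningful lower edge; each center integrates the
periodogram over its log-spaced neighborhood. Each channel's log-power is
z-scored per frequency across epochs (equalizing the weight of all
frequencies), channels are averaged into a global spectrogram, and the
average is re-standardized per frequency — the final standardization keeps
the artifact threshold and the clustering scale-free regardless of how many
channels were averaged. Epochs with mean z above 10 are rejected together
with everything within ±10 s (`reject_artifacts()`). `cluster_stages()`
projects non-artifact epochs on the 8 strongest principal components and
k-means-clusters them (k = 3, 10 restarts, fixed seed); artifact epochs get
no label rather than an imputed one.

Cluster-to-stage naming (`assign_stage_names()`) is a heuristic of this
package: the cluster with the highest low-frequency (≤ 4 Hz) z-power is
slow-wave sleep; of the rest, the one with more high-frequency (≥ 30 Hz)
power is the active-awake/REM analog and the other quiet-awake. Ties break
by cluster size (largest to SWS, the most occupied stage). The assignment
depends only on spectral content, never on k-means label order.

## Network states and information metrics

For the embedded dynamics, each cortical system is reduced to its first
principal component (`region_pca_signals()`, sign-aligned with the system
mean), and the three region signals are symmetrically orthogonalized
(`leakage_correct()`, Löwdin $C^{-1/2}$ transform) so zero-lag leakage
between adjacent systems cannot masquerade as shared dynamics.
`fit_network_states()` then fits a K-state hidden Markov model with
full-covariance Gaussian emissions by Baum–Welch EM (forward–backward in
compiled code, scaled recursions; restarts from k-means initializations;
relative log-likelihood tolerance 1e-6, 500-iteration cap; optional time
embedding of lagged frames for spectral sensitivity). A full variational
multivariate-autoregressive HMM is published external software and out of
scope; the downstream metrics need only a decoded K-state sequence, which
the Gaussian HMM supplies with testable EM semantics (monotone likelihood,
planted-regime recovery). States are decoded by per-frame posterior argmax,
and transition statistics are counted on that hard sequence. K defaults to
5, with `choose_n_states()` sweeping 4–7 and picking the K whose decoded
occupancy shows no predominant state (smallest excess of max fractional
occupancy over 1/K) — our operationalization of a heterogeneous state
distribution.

On state sequences the package computes the switching rate (fraction of
changed consecutive frames), fractional occupancy and its maximum, average
visit lifetimes, and on transition models: entropy production
$S = \sum_{ij} P(i{\to}j)\,\ln [P(i{\to}j)/P(j{\to}i)]$ (nats by
thermodynamic convention; zero iff detailed balance), determinism and
degeneracy (normalized row-entropy and mean-out-distribution-entropy of the
conditional matrix, in bits as their definitions are written), and
past–future mutual information (bits). Transition estimation uses no
pseudocount by default, so closed-form test values are exact; pipeline
paths use a $1/(TK^2)$ pseudocount, flagged in the documentation, to keep
entropy production finite when a reverse transition is unobserved.
Per-stage metrics (`per_stage_metrics()`) align stage labels to the network
time base by nearest frame and exclude transitions spanning a stage
boundary from both stages — a transition across a boundary belongs to
neither.

## Latent-space analysis

`train_autoencoder()` implements the bottleneck architecture
$n$–$n/2$–$n/4$–$d$–$n/4$–$n/2$–$n$ (64–32–16–$d$–16–32–64 at 64 channels;
widths scale proportionally otherwise) with batch normalization and ReLU on
all layers except the latent and output layers, which are linear. Training
minimizes mean-squared reconstruction error with Adam (learning rate 1e-3,
batch 256 frames) on per-channel z-scored frames, a random 70/30
train/validation split, at most 400 epochs with 50-epoch early-stopping
patience, keeping the best-validation weights. The implementation is plain
matrix algebra; its gradients are verified against numerical
differentiation in the test suite, and its capacity against an optimal
rank-k PCA reconstruction on planted low-rank data. Latent coordinates are
binarized at zero (the per-channel mean, post z-scoring), and
`entropy_feature_windows()` turns each non-overlapping 5-s window into a
$d(d-1)/2$-vector of pairwise entropy productions of the binarized
coordinates.

`balanced_stage_classification()` follows the repeated-balancing protocol:
under-sample without replacement to the smallest class (50 times by
default), split 80/20 (50 times per balancing, stratified so every class
appears in training), fit a random forest (500 trees by default, via
`ranger`) and record test accuracy. `dimension_sweep()` repeats the whole
chain per candidate latent dimension and reports the smallest $d$ within
one standard error of the maximal mean accuracy — the accuracy plateau.

## The synthetic generator

`gen_stage_recording()` emulates the structure of a 64-channel
micro-ECoG session: systems of 30 visual, 21 auditory and 13 parietal
channels; three behavioral stages with distinct band-power signatures,
distinct cross-channel coupling asymmetry and exponential dwell times
(memoryless switching — the simplest generator consistent with Markovian
stage dynamics; dwell distribution is a modeling choice, configurable); and
a hidden 5-state Markov network-state chain whose persistence, cycle bias
and occupancy skew derive from the stage parameters, emitted as mean
offsets per system. Within each stage segment, white noise is bandpass
filtered per band, the VAR(1) coupling (with the stage's asymmetry) is
applied *to the band components after filtering*, and the uncoupled
broadband floor is added last — this is what makes the planted arrow of
time band-localized: since Pearson correlations are scale-invariant, a
coupling applied to the summed signal would be visible in every frequency
bin regardless of the power spectrum. Segments are floored at ~50 ms so
per-segment filtering stays well posed.

Default stage conditions: an active-awake/REM analog (theta- and
gamma-rich, coupling asymmetry 0.9, 120-s mean dwell), a quiet-awake analog
(alpha-dominant, asymmetry 0.5, 120 s) and a slow-wave-sleep analog
(delta-dominant, asymmetry 0.1, 240 s — the most occupied stage). The
asymmetry gradient plants the expected ordering of irreversibility across
stages; dwell times of minutes reflect a species with fast sleep–wake
alternation while keeping 60-s spectrogram epochs mostly stage-pure.
`gen_var_recording()` (pure VAR with arbitrary coupling) and
`gen_markov_sequence()` (stationary-start chains with known transition
matrices) provide the low-level oracles; `gen_latent_recording()` plants a
known latent dimensionality k: k latent VAR coordinates whose directed
coupling asymmetry switches with the stage, mixed into 64 channels through
a random orthonormal map plus white sensor noise.

What the generator does **not** emulate: volume conduction and spatially
correlated sensor noise, 1/f background spectra, non-exponential bout
structure, nonstationarities within a stage, artifacts from movement or
electrode drift, and any biophysics of the underlying tissue. Passing tests
on these data therefore demonstrate estimator correctness and recoverable
planted structure, not performance guarantees on real recordings.

## Problem sizes and tolerances

The validation suite and the acceptance script run everything at desk
scale, chosen to keep total runtime modest while leaving comfortable
statistical margins: 600-s recordings at 100 Hz for null calibration and
ordering checks (600 analysis windows), a 30-minute 256-Hz recording for
stage-classifier recovery, 1e5-step chains for entropy-production
consistency (sampling error well under the 2 % check), 900-s recordings
for the latent sweep with autoencoder training capped at 150 epochs
(40-epoch patience) on a 30 000-frame subsample (training is frame-wise, so
decimated training with full-resolution encoding is unbiased), and reduced
classification repetitions (5 balancings × 10 splits, 300 trees) whose
mean-accuracy standard error stays near 0.01. Encoder quality — and hence
the latent basis the binarized entropy features live in — varies across
random initializations, which makes the accuracy-versus-dimension curve
intrinsically noisy beyond the planted rank; this is a property of the
method (reconstruction loss does not pin down the latent basis), not of
the implementation. Closed-form checks (worked determinism /
degeneracy / mutual-information values, cycle-chain entropy production,
oracle equivalence at 1e-12) do not depend on problem size.

## Known limitations

- The irreversibility measure is pairwise and lag-1 only; higher-order or
  model-based estimates are out of scope.
- The Gaussian-emission HMM ignores spectral content unless time embedding
  is enabled; it is a stand-in for richer observation models.
- The stage-naming heuristic encodes conventional spectral physiology; on
  data where those conventions fail (e.g. pathological states) names
  should be assigned manually.
- Per-window irreversibility values carry a positive noise floor that
  depends on window length and the signal's autocorrelation; comparisons
  are meaningful within a fixed windowing scheme only.
- The autoencoder trains on CPU-scale matrix algebra; it is deliberately
  small, and very high-dimensional inputs would need proportionally wider
  layers and longer training.
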