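# neuroarrow

Nonequilibrium analysis of multichannel neural recordings: signal
irreversibility (the arrow of time), behavioral staging, hidden-Markov
network-state dynamics and autoencoder latent-space analysis, validated end
to end on synthetic recordings with planted ground truth.

## Who this is for

Electrophysiologists and computational neuroscientists working with
multichannel surface recordings (ECoG / LFP-like signals) who want to
quantify how far brain dynamics depart from thermodynamic equilibrium in
different behavioral states — and anyone who needs a tested, model-free
irreversibility estimator for multivariate time series in general.

## What it computes

A stationary, time-reversible process has identical statistics forward and
backward in time. For two channels $x, y$ the package compares the forward
time-shifted Pearson correlation with its time-reversed counterpart,

$$ C_{\mathrm{fwd}}(\Delta t) = \langle x(t),\, y(t+\Delta t) \rangle,
\qquad
C_{\mathrm{rev}}(\Delta t) = \langle x^{(r)}(t),\, y^{(r)}(t+\Delta t) \rangle, $$

and measures the pairwise irreversibility
$I_{x,y} = |C_{\mathrm{fwd}} - C_{\mathrm{rev}}|$ in non-overlapping 1-s
windows at 100 Hz with a one-frame shift. On top of this estimator the
package provides:

- **Decompositions**: within/between cortical systems
  (`group_by_system()`) and per 1-Hz frequency bin from 0–50 Hz with
  canonical band summaries (`band_sweep()`).
- **Staging**: a data-driven behavioral-stage classifier from a
  channel-averaged z-scored spectrogram (60-s epochs, 14 log-spaced
  frequencies, PCA + k-means, artifact rejection) with physiological stage
  naming (`compute_stage_features()`, `cluster_stages()`,
  `assign_stage_names()`).
- **Network-state dynamics**: region PCA, symmetric leakage correction, a
  Gaussian-emission hidden Markov model (`fit_network_states()`), and
  state-sequence metrics — switching rate, fractional occupancy, lifetimes,
  entropy production
  $S=\sum_{ij}P(i{\to}j)\ln\frac{P(i{\to}j)}{P(j{\to}i)}$, determinism,
  degeneracy, mutual information (`per_stage_metrics()`).
- **Latent space**: a 64–32–16–d–16–32–64 autoencoder, zero-cutoff
  binarization, windowed pairwise entropy-production features, and balanced
  random-forest stage classification across latent dimensions
  (`train_autoencoder()`, `entropy_feature_windows()`,
  `dimension_sweep()`).
- **Synthetic ground truth**: generators that plant coupling asymmetry,
  spectral stage signatures, Markov network states and latent
  dimensionality (`gen_var_recording()`, `gen_stage_recording()`,
  `gen_markov_sequence()`, `gen_latent_recording()`), so every estimator is
  testable without external data.
- **Orchestration**: `run_full(run_config(...))` executes the whole chain
  and writes per-stage CSV outputs plus a JSON reproducibility manifest.

## Worked example

```r
library(neuroarrow)

# a 2-channel recording in which channel 1 drives channel 2
A <- matrix(0, 2, 2)
A[2, 1] <- 0.8
rec <- gen_var_recording(2, A, duration_s = 600, seed = 1)
ser <- irreversibility_windows(rec, window_s = 1, shift_frames = 1)
ser
#> <irrev_series> 600 windows of 1 s (shift 1 frame(s)), 2 channels
#>   per-window scalar: mean 0.6235, time-averaged signed 0.6235

# the same geometry with symmetric coupling is reversible in expectation
A_sym <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
ser_sym <- irreversibility_windows(
  gen_var_recording(2, A_sym, duration_s = 600, seed = 1))
aggregate_irreversibility(ser_sym)
#> [1] 0.003930286
```

The directed pair shows a large, stable irreversibility (0.62 — the
forward and reversed lagged correlations differ strongly in every window),
while the symmetrically coupled pair's time-averaged signed estimate sits
at its sampling floor near zero: no arrow of time.

```r
# entropy production of a biased 3-state cycle vs its closed form
P <- matrix(0.1, 3, 3); diag(P) <- 0
P[cbind(1:3, c(2, 3, 1))] <- 0.9          # i -> i+1 with p = 0.9
seq <- gen_markov_sequence(P, 1e5, seed = 1)
entropy_production(estimate_transitions(seq))
#> [1] 1.743908
0.8 * log(9)                              # closed form for this chain
#> [1] 1.75778

tm <- transition_model(matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE) * 0.5)
c(determinism = determinism(tm), degeneracy = degeneracy(tm))
#> determinism  degeneracy
#>   0.2655022   0.1187091
```

The estimated entropy production of the sampled cycle chain lands within
1 % of the closed form $0.8\ln 9$; the determinism/degeneracy values match
their hand-computed entropies exactly.

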