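---
title: "Phase-locking networks and K-order propagation importance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking networks and K-order propagation importance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wkpnet)
```

## The pipeline

`wkpnet` implements a functional-brain-network analysis chain for
multichannel narrowband signals (EEG being the motivating case):

1. **Pre-processing** (`preprocess`): zero-phase 0.5–60 Hz band-pass, 50 Hz
   notch, segmentation into non-overlapping 10 s epochs, per-epoch baseline
   correction.
2. **Spectral analysis** (`welch_band_power`, `paired_band_test`): Welch band
   power in the standard theta (3–7 Hz), alpha (7–13 Hz), beta (13–30 Hz)
   and gamma (30–60 Hz) bands, with paired two-sided t-tests between task
   states.
3. **Connectivity** (`plv_matrix`): the phase locking value between each pair
   of channels,
   $\mathrm{PLV} = \left|\frac{1}{T}\sum_t e^{i\,\Delta\phi(t)}\right|$,
   where $\Delta\phi(t)$ is the difference of the instantaneous phases
   obtained from the analytic (Hilbert) signal of each channel.
4. **Binarization** (`surrogate_threshold`, `binarize`): an edge is kept when
   its PLV strictly exceeds a per-band threshold taken as the
   $(1-\alpha)$ percentile of circular-time-shift surrogate PLVs pooled over
   epochs and pairs. Circular shifting preserves each channel's spectrum and
   amplitude distribution while destroying cross-channel phase alignment.
5. **Node importance** (`node_importance`): the weighted K-order propagation
   number (WKPN) score described below, with weighted degree centrality
   (`wdc`) and weighted PageRank (`wpr`) as comparators.
6. **State classification** (`build_features`, `evaluate_states`): an
   RBF-kernel SVM on per-epoch node-importance vectors, evaluated over
   repeated stratified 3:2 train:test splits.

## The WKPN score

For a binary undirected network with node set $V$ ($|V| = n$) and hop
distances $D(u,v)$, the K-order propagation number of node $v$ is

$$N_v^K = \#\{u \in V : D(v,u) \le K\}, \qquad K = 0, 1, \ldots, d,$$

where $d$ is the largest finite hop distance in the network. $N_v^K$ is the
number of nodes "infected" after $K$ propagation steps when $v$ is the
infection source (the node itself included, so $N_v^0 = 1$). Unreachable
nodes are never counted, and on an edgeless network $d = 0$.

Each order $K$ gets a structure entropy

$$H_K = -\sum_{v} p_v \log p_v, \qquad p_v = \frac{N_v^K}{\sum_u N_u^K},$$

a measure of how heterogeneous the network looks at that propagation
horizon. Since every $N_v^K \ge 1$, all shares are positive and
$0 < H_K \le \log n$, with equality exactly when all counts agree (always at
$K = 0$). The importance score averages the per-order node shares with
entropy weights:

$$Q_v = \sum_{K=0}^{d} c_K\, S_v^K, \qquad
  c_K = \frac{H_K}{\sum_{K'} H_{K'}}, \qquad
  S_v^K = \frac{N_v^K}{\sum_u N_u^K}.$$

Both normalizations are sums, so each column of $S$ and the weight vector
$c$ are probability distributions and $\sum_v Q_v = 1$. Nodes are ranked by
decreasing $Q$, ties broken by node label for determinism.

Three modelling choices deserve comment:

* **Log base.** Natural log. $c_K$ is a ratio of entropies, so the base
  cancels out of $Q$ entirely; it only affects reported $H$ values.
* **Weight direction.** Entropy weighting as written gives the *largest*
  weight to the most heterogeneous-looking orders. One can argue the
  opposite convention (down-weighting orders where nodes differ least is
  achieved by up-weighting low-entropy orders); `invert_weights = TRUE`
  provides the complement weighting $c_K \propto 1 - H_K/\sum H$, but the
  literal form is the default.
* **Normalization.** `normalization = "minmax"` replaces the sum shares with
  min–max scaled columns (renormalized to sum 1 so $Q$ remains a
  distribution). The sum form is the default.

`mark_nodes` min–max normalizes $Q$ to $[0,1]$ and marks nodes exceeding a
threshold (default 0.8), the reporting rule used for topographic displays.

## The synthetic-signal generator

Real recordings for this paradigm are not publicly deposited, so every stage
is validated against a coupled-oscillator generator (`oscillator_spec`,
`generate_epoch`, `generate_dataset`) whose statistical structure is exactly
what the PLV analysis assumes:

* Each **coupling group** of channels shares one *driver*: complex Gaussian
  noise with a flat one-sided spectrum on the requested band (default
  alpha-like, 10 ± 3 Hz), synthesized in the frequency domain so the series
  is exactly analytic. A channel is the real part of the driver with
  per-channel **phase jitter** $\varepsilon_c(t)$ added to the instantaneous
  phase: $x_c(t) = A(t)\cos(\phi(t) + \varepsilon_c(t))$.
* The jitter is zero-mean Gaussian with marginal standard deviation
  $\sigma$ and is **band-limited** (default bandwidth
  $\min(8\,\mathrm{Hz}, \text{band low edge})$). Band-limiting matters: the
  phase of the analytic signal is itself a smooth functional of the data, so
  white per-sample jitter would be partially averaged away by the Hilbert
  phase extraction and the realized phase locking would exceed its nominal
  design value. With jitter slow enough to be tracked, the phase difference
  of a coupled pair is Gaussian with variance $2\sigma^2$ and the expected
  PLV has the closed form $e^{-\sigma^2}$, which the test suite verifies by
  Monte-Carlo at $\sigma \in \{0.3, 0.6, 1.0\}$ over 50 epochs.
* Channels outside every group receive independent drivers, so their
  expected PLV is the finite-sample floor
  $\sqrt{\pi}/(2\sqrt{N})$ for $N$ independent phase samples.
* Defaults mirror the recording conditions the pipeline targets: 500 Hz
  sampling, 10 s epochs, and the 62-channel extended 10–20 montage (64
  electrodes minus the M1/M2 references).

The generator does **not** emulate volume conduction, 1/f background
spectra, artifacts, or non-stationarity. Passing tests therefore demonstrate
the correctness and calibration of the algorithms under their own model
assumptions, not performance on real EEG.

## Numerical choices

* **Welch PSD**: 2 s Hann windows, 50% overlap, one-sided density. Two
  seconds gives at least six cycles of the lowest theta frequency per
  window. The estimator satisfies Parseval within 5% on white noise.
* **Filtering**: FIR band-pass (Hamming window, order about three cycles of
  the low cutoff) applied forward–backward (`filtfilt`) for zero net phase
  shift — mandatory upstream of any phase metric. Pre-processing uses
  cascaded Butterworth high/low-pass and a second-order 50 Hz band-stop,
  also forward–backward.
* **Hilbert edge effects**: 0.25 s at each epoch end are discarded before
  any phase averaging (configurable via `edge_trim`).
* **Surrogates**: circular shifts of at least 1 s, drawn uniformly;
  defaults $\alpha = 0.05$ with 200 draws. The threshold is *pooled*: one
  $T$ per band over all epochs and pairs, so every epoch's network in a band
  is binarized against the same standard.
* **Degenerate cases**: a paired test with all-zero differences returns
  $p = 1$; constant channels raise an error in phase extraction (their phase
  is undefined); an edgeless network has $d = 0$ and uniform $Q = 1/n$;
  constant $Q$ produces no marked nodes, with a warning.
* **SVM**: RBF kernel, $C = 1$, kernel width $1/(m \cdot \mathrm{Var})$ of
  the standardized training features. Splits are stratified; feature
  standardization and top-$m$ node selection (when a reduced feature length
  is requested) are computed on the training fold only, so no information
  leaks from test folds. A pure-noise leakage probe in the test suite checks
  that accuracy stays at chance.

## Design of the validation experiments

The package's own validation experiments (the acceptance test file and
`scripts/acceptance.R`) use the following problem sizes: 50 epochs per
calibration point, 36 eight-channel epochs (1008 pairs) for false-positive
calibration, 50 replicate 62-channel networks for hub recovery, and
40 epochs per state for classification with 20 repeated splits.

Two levels of the edge-significance parameter $\alpha$ appear, and the
distinction is deliberate:

* For **edge-wise calibration** the question is "does the threshold pass
  about $\alpha$ of truly independent pairs?", so the nominal
  $\alpha = 0.05$ is used, with 1000 surrogate draws so that the quantile
  estimate itself does not dominate the measurement.
* For **hub localization and classification** the question is whether
  planted structure dominates the ranking of a *single* 62-node network
  built from 1891 simultaneous edge decisions. At $\alpha = 0.05$ roughly
  95 spurious edges appear and percolate into a large random background
  component whose members out-cover a small planted clique at intermediate
  $K$ — the experiment would measure background percolation, not ranking
  quality. These experiments therefore budget the *expected number* of
  spurious edges to about two per network ($\alpha = 0.001$ for hub
  recovery, $0.002$ for the two-state classification dataset), the same
  logic that motivates family-wise control when single networks are
  interpreted edge by edge. The surrogate count is raised to
  $1/\alpha \times$ a few (2500–5000) so the extreme percentile is
  estimable.

The planted configuration is one six-channel frontal–parietal group
(`F3 FZ F4 P3 PZ P4`) with $\sigma = 0.3$ rad jitter in the hard state and
no coupling in the easy state — a strong, unambiguous effect by design, so
that failures indicate algorithmic defects rather than borderline signal.

## Known limitations

* WKPN is defined on binary networks; a weighted-distance variant is out of
  scope.
* Gamma-band networks are not constructed by default: narrowband PLV in the
  gamma range is low and thresholds become unstable.
* Entropy weighting aggregates all orders $K = 0..d$; $K = 0$ contributes a
  uniform share to every node (rank-neutral) and is kept for fidelity to the
  definition.
* The artifact-removal steps that real EEG requires (ICA, EOG regression)
  are not implemented; `preprocess` covers filtering, epoching and baseline
  correction only.
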