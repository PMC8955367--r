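# wkpnet

Functional brain networks from phase-locking connectivity, with K-order
propagation node importance and state classification.

`wkpnet` is for researchers who analyze multichannel narrowband recordings
(EEG in particular) as networks: which electrodes act as hubs, how hub
structure differs between task states, and whether those differences are
strong enough to classify the states. The package covers the full chain —
spectral pre-processing, phase-locking-value (PLV) connectivity,
surrogate-data edge significance, node-importance ranking, and SVM state
classification — plus a coupled-oscillator signal generator that makes every
stage testable with known ground truth.

## The method

**Connectivity.** For channels $x_1, x_2$ the instantaneous phases
$\phi_1(t), \phi_2(t)$ come from the analytic signal
$Z(t) = X(t) + i\,HT(X(t))$, and

$$\mathrm{PLV} = \Bigl|\tfrac{1}{T}\textstyle\sum_t e^{i(\phi_1(t)-\phi_2(t))}\Bigr| \in [0,1].$$

Edges of the binarized network are pairs whose PLV exceeds the
$(1-\alpha)$ percentile of circular-time-shift surrogate PLVs (same spectra,
no phase relation), pooled into one threshold per frequency band.

**Node importance (WKPN).** With hop distances $D$, the K-order propagation
number $N_v^K = \#\{u : D(v,u) \le K\}$ counts the nodes infected after $K$
propagation steps from source $v$. Orders $K = 0..d$ (where $d$ is the
largest finite distance) are combined through the structure entropy
$H_K$ of each order's count distribution:

$$Q_v = \sum_{K=0}^{d} c_K S_v^K,\quad
c_K = \frac{H_K}{\sum_{K'}H_{K'}},\quad
S_v^K = \frac{N_v^K}{\sum_u N_u^K},$$

so $\sum_v Q_v = 1$. Weighted degree centrality (`wdc`) and weighted
PageRank (`wpr`) are included as comparator rankers, and an RBF-kernel SVM
harness classifies two task states from per-epoch importance vectors over
repeated stratified 3:2 splits.

See `vignettes/wkpnet-methods.Rmd` for assumptions, parameter defaults and
the design of the validation experiments.

## Worked example

Two synthetic task states on the standard 62-channel montage: the hard state
plants one coupled frontal–parietal group (`F3 FZ F4 P3 PZ P4`, phase jitter
0.3 rad), the easy state has independent channels.

```r
library(wkpnet)

specs <- two_state_specs(seed = 1, n_epochs = 20)
ds <- generate_dataset(specs$easy, specs$hard)
ds$epochs[[1]]
#> <multichannel_epoch> 62 channels x 5000 samples @ 500 Hz (10.0 s)

thr <- surrogate_threshold(ds$epochs, n_surrogates = 2500, alpha = 0.002,
                           seed = 1)
thr
#> <threshold_spec> band NA: T = 0.2845 (alpha = 0.002, 2500 circular-shift surrogates)

nets <- lapply(ds$epochs, function(ep) binarize(plv_matrix(ep), thr))
nets[[40]]   # a hard-state epoch
#> <binary_network> 62 nodes, 18 edges, band NA

prof <- node_importance(nets[[40]])
round(head(sort(prof$Q, decreasing = TRUE), 8), 4)
#>     F3     FZ     F4     P3     PZ     P4     F7     F5
#> 0.0379 0.0379 0.0379 0.0379 0.0379 0.0379 0.0182 0.0182

mark_nodes(prof)$marked
#> [1] "F3" "FZ" "F4" "P3" "PZ" "P4"

profiles <- lapply(nets, node_importance)
feats <- build_features(profiles, ds$labels)
evaluate_states(feats, n_repetitions = 20, seed = 1)
#> <eval_report> mean accuracy 0.919 over 20 splits (60/40 train/test)
```

The six planted channels share the top importance (0.0379 each, versus a
1/62 = 0.0161 baseline), are exactly the marked set at the 0.8 reporting
threshold, and the planted coupling difference classifies the two states at
92% accuracy from 20 epochs per state.

A full multi-band run (`run_pipeline`) writes PLV matrices, edge lists,
importance profiles and classification reports per band under a run
directory with a config hash and log; a thin command-line front end is
installed at `inst/cli/wkpnet.R` (subcommands `synth`, `rank`, `classify`,
`run`).

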