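---
title: "Methods: dual-scale connectivity graph networks for sleep staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-scale connectivity graph networks for sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepgcn)
```

## The problem

Clinical sleep staging assigns one of five stages — Wake, N1, N2, N3, REM —
to each 30 s epoch of an overnight polysomnogram. The classifier implemented
here treats the six EEG-like channels of an epoch (6 × 6000 samples at
200 Hz) as a small brain graph whose connectivity evolves within the epoch,
and combines four ideas:

1. **Dual-scale dynamic functional connectivity.** Stepping second by second
   through the epoch, two Pearson-correlation adjacency matrices are built
   per step: a *fast* graph over the current 1 s window and a *slow* graph
   over the trailing 5 s (truncated, never padded, at the epoch start).
   The two timescales bracket the characteristic durations of transient
   thalamocortical coupling and sustained slow-wave propagation, so lagged
   coupling that a single zero-lag graph would miss appears as a
   fast/slow discrepancy. Each graph is sparsified to its per-row top-k
   (k = 3) entries by absolute correlation — absolute value, because
   anti-correlated coupling is still coupling; ties break toward the lower
   channel index so the masks are reproducible. Node features of each step
   (the raw 1 s sample windows) are then fused by learnable per-source-channel
   gains: `e_i = x_i + sum_j alpha_j maskS[i,j] x_j + beta_j maskF[i,j] x_j`.
   A GRU (update/reset gates, candidate state gated by `z_t`) encodes the
   30-step fused sequence; its final hidden state is the 128-dim
   connectivity embedding.

2. **Multi-scale morphological branches.** Six parallel 1-D convolution
   branches with kernel widths {50, 100, 200, 400, 700, 1000} samples
   (0.25–5 s at 200 Hz) span sleep biomarkers from beta transients through
   spindles (0.5–1.5 s) and K-complexes (0.5–2 s) to slow waves. Each
   branch applies valid stride-1 convolution, feature normalisation, ReLU
   and stride-2 max pooling, then scaled dot-product self-attention
   (`Z = softmax(QK'/sqrt(d_k)) V`) over temporal positions within each
   channel. Global averaging yields 64 features per branch; concatenation
   gives the 384-dim morphological embedding.

3. **Adaptive spatio-temporal graph convolution with expert fusion.**
   The joint vector `Hjoint = [Hmorph ⊕ Hconn]` (512-dim) gates a mixture
   of six experts, one per branch scale. Each expert sees its branch's
   per-channel feature matrix, computes a bilinear spatial attention over
   channels, mixes node signals with it, and filters them with a K = 3
   Chebyshev polynomial of the scaled normalised Laplacian
   `L~ = 2L/lambda_max − I` of the epoch-level graph (the slow adjacency,
   averaged in absolute value under its mask across the 30 steps — the
   stabler topology; the fast scale already acts through the fusion gains).
   A bilinear temporal attention over the 30 GRU states supplies the
   temporal context each expert consumes. The softmax gate
   `G = softmax(Wg Hjoint + bg)` convexly combines the six 256-dim expert
   outputs into the final embedding.

4. **Adversarial subject invariance.** A subject discriminator reads the
   final embedding through a gradient-reversal layer (identity forward,
   gradient scaled by −lambda backward, lambda = 0.4 by default). Training
   minimises stage cross-entropy plus discriminator cross-entropy; through
   the reversal, the feature extractor is simultaneously pushed to *remove*
   subject-identifying structure while the discriminator sharpens —
   the minimax objective `min_{f,y} max_d  Lclass − Ldomain`.

The classifier head is a single affine map 256 → 5 with softmax, behind
dropout 0.5. Training uses Adam, initial learning rate 3e-4 halved every
10 epochs, batch size 128–256, 100 epochs, Glorot-uniform initialisation —
all exposed in `train_config()`.

## Autodiff

No tensor framework is assumed: the package carries a small reverse-mode
automatic-differentiation tape (`R/autodiff.R`) over plain R matrices.
Operations accept nodes or constants; constants cost nothing. Two fused
nodes keep tapes short where it matters: the fusion + GRU sequence (one
node with hand-written backpropagation-through-time) and batched branch
attention (channels attend jointly under a block-diagonal softmax mask,
which is exactly per-channel attention). The gradient-reversal layer is a
first-class tape op, so the adversarial gradient flow is the real one, not
a simulation — the test suite checks the full composed model against
central finite differences at lambda ∈ {0, 0.4, 1}.

## Design choices where the architecture was open

* **Window stepping.** The dual-scale windows advance in 1 s strides,
  matching the fast scale and giving a 30-step sequence per epoch.
* **GRU state equation.** The candidate state is gated by `z_t` and the
  history by `1 − z_t` (so all-zero parameters give `h_t = 0.5 h_{t−1}`,
  a decaying state). This is the mirror of the more common convention and
  is implemented exactly as specified.
* **Fusion neighbourhood.** The fused edge set is the union of the fast and
  slow masks, entering through two separate indicator terms with their own
  gains; gains are per *source* channel, initialised at 0.1 so early
  training stays near the identity map.
* **Bilinear attention shapes.** The spatial/temporal attention score is
  `(H W1) W2 (H W3)' + b` followed by a logistic nonlinearity, a learnable
  row mixer `V` and a row softmax. Published descriptions of this attention
  family leave the projection shapes open; this 2-D transcription is
  oracle-tested exactly as implemented.
* **Attention axis in the branches.** Branch self-attention runs across
  temporal positions within each channel (shared projections), not across
  branches; the branch dimension is fused later by the expert gate.
* **Expert inputs.** Expert *i* consumes its own branch's per-channel
  features (spatially attended, Chebyshev-filtered, node-averaged)
  concatenated with the temporally attended connectivity context. Experts
  are fixed-width (post-pooling), which keeps the gate a convex combination
  of comparable vectors.
* **Degenerate graphs.** Constant channels get zero correlation (the
  formula is 0/0 there); isolated nodes get unit degree with a warning;
  `lambda_max` is floored at 1e-6 so empty graphs scale to `−I` instead of
  dividing by zero.
* **Normalisation in the branches.** Feature maps are normalised per
  feature over the temporal positions of the sample (with learnable scale
  and shift). The training loop builds one tape per sample, so cross-batch
  statistics would couple tapes; per-sample normalisation keeps samples
  independent and evaluation deterministic.
* **Metrics.** The chance-agreement term of Cohen's kappa uses the
  multiclass marginal-product form; the headline F1 is the unweighted
  macro average; 0/0 rates are defined as 0 so small test folds stay
  finite.

## The synthetic cohort generator

`cohort_spec()` + `generate_cohort()` simulate labelled PSG cohorts with the
statistical structure the model assumes, so the whole pipeline is testable
without any recording:

* **Stage sequences** follow a first-order Markov chain (default: 0.85
  self-transition with physiologically ordered off-diagonals, e.g. N3
  returns through N2). `stationary_transition()` builds a chain with any
  prescribed stationary mix, e.g. the published ISRUC stage distribution.
* **Spectral signatures** per stage are sums of band-limited oscillations
  (delta 0.5–4, theta 4–8, alpha 8–13, sigma 11–16, beta 13–30 Hz) with
  stage-specific amplitudes: delta-dominant N3, sigma-rich N2, theta N1,
  alpha Wake, mixed theta/beta REM.
* **Transient events**: Hann-enveloped 11–16 Hz spindle bursts of 0.5–1.5 s
  and biphasic K-complex templates of 0.5–2 s, at per-stage Poisson rates
  (N2-dominant).
* **Propagation lags**: a shared broadband component is delayed per channel
  by an integer-sample shift from a channel × channel lag matrix (default
  15 ms per channel step, inside the 10–100 ms physiological range), which
  makes the time-lag claim directly testable by cross-correlation.
* **Subject structure**: one multiplicative log-normal gain per subject
  (SD 0.2 on the log scale) plus a small alpha-peak frequency offset
  (SD 0.4 Hz) — a real signal for the discriminator to remove, of which
  only the frequency offset survives per-epoch z-scoring.
* Amplitudes are arbitrary units; the pipeline z-scores each epoch per
  channel.

What the generator does *not* emulate: biophysical neural-mass dynamics,
EOG/EMG/ECG modalities, artifacts, arousals, or ultradian cycle structure.
Passing tests on this cohort therefore demonstrate that the implementation
learns the statistical regularities it claims to model — not clinical-grade
performance on real polysomnography.

## Desk-scale configuration and problem sizes

All experiments shipped with the package run on one CPU core.
`sleepgcn_config_reduced()` divides the hidden widths by four (16 filters
per branch, 32-unit GRU, 64-wide experts) and adds two pure compute
reductions: the wide kernels are evaluated at stride width/2 (the
receptive fields still tile the epoch with 50 % overlap) and the 1 s
node-feature windows entering the GRU are decimated 4×. These change
arithmetic cost, not the architecture or the task.

The packaged experiments use: a 2-subject × 200-epoch cohort for the
learnability study (train on one subject, evaluate on the held-out
subject; 10 training passes at learning rate 2e-3), and five paired
2-subject × 30-epoch runs for the adversarial comparison of lambda = 0
versus lambda = 0.4. The oracle-equivalence suite checks every core
operation against brute-force re-implementations on 50 random instances
each.

## Known limitations

* The reference training protocol (100 epochs, batch 256, full widths) is
  exposed but not exercised end-to-end in the tests; desk-scale runs use
  the reduced configuration.
* EDF support covers continuous recordings with one common sampling rate;
  discontinuous EDF+ sessions are out of scope.
* Resampling is left to the caller: the pipeline assumes 200 Hz throughout,
  and the simulator treats all channels as EEG-like (which six channels a
  clinical montage would contribute, EEG-only or mixed EEG/EOG, is left
  open).
* The stochastic experiments (learnability, adversarial effect) are seeded
  and reproducible, but their margins vary across seeds as any small-sample
  training run does.
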