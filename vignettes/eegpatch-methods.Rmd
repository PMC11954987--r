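---
title: "Patch-based Transformer decoding of multichannel EEG: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based Transformer decoding of multichannel EEG: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegpatch)
```

## The problem

Motor-imagery brain-computer interfaces classify short multichannel EEG
segments — imagined left-hand versus right-hand movement, feet, rest — from
scalp voltage recordings. Two properties make this hard for flexible
models: public datasets are small (tens of subjects, a few hundred labeled
trials each), and recording montages differ between datasets, so a model
with a fixed input layout cannot pool them. `eegpatch` implements a
channel-flexible Transformer that addresses both: trials of any montage
and duration map to a variable-length token sequence, so heterogeneous
datasets can be mixed during pre-training and the learned weights
transferred to a new sensor arrangement for fine-tuning.

## The model

A preprocessed trial is a matrix \(X \in \mathbb{R}^{C \times T}\)
(channels by samples). The tokenizer slices each channel independently
into contiguous patches of \(D\) samples, channel-major, discarding the
trailing \(T \bmod D\) samples, giving
\(N = C \lfloor T / D \rfloor\) patches
\(X_P \in \mathbb{R}^{N \times D}\). Patches are embedded by a pure linear
map \(X_E = X_P W_E^{\top}\) with \(W_E \in \mathbb{R}^{d \times D}\) and
\(d = 2D\). A learned classification token is prepended and a learned
positional embedding added:

\[ X_{\mathrm{pos}} = \begin{bmatrix} \mathrm{cls} \\ X_E \end{bmatrix} + W_{\mathrm{pos}}. \]

The positional embedding is stored as a registry keyed by
(channel name, time slot) rather than a flat \((N+1) \times d\) table:
montages of any size share rows for common channels, which is what makes
cross-montage transfer well-defined. Each encoder block is the pre-LN
variant,

\[ X' = \mathrm{MHSA}(\mathrm{LN}(X)) + X, \qquad
   X'' = \mathrm{FFN}(\mathrm{LN}(X')) + X', \]

with multi-head self-attention (heads of size \(d/h\)), a two-layer GELU
feed-forward network, and dropout on attention weights and feed-forward
outputs. After the last block a final layer norm is applied and the class
probabilities are read from the classification token only:
\(y = \mathrm{softmax}(\mathrm{cls}\, W_{\mathrm{class}}^{\top} + b_{\mathrm{class}})\).
The reference configuration — \(D = 64\) (0.256 s at 250 Hz), \(d = 128\),
four blocks, hidden width 512, four heads, dropout 0.1 — has about 884k
trainable parameters when instantiated on a 64-channel montage, which
`count_params()` reproduces to within one percent.

Because layer norm standardizes every token, the network is structurally
insensitive to per-trial amplitude scaling and DC offsets; the package
asserts this only as the operator-level identity
\(\mathrm{LN}(a v + c\mathbf{1}) = \mathrm{LN}(v)\), not as a model-level
invariance claim.

## Preprocessing

Standard motor-imagery preprocessing, applied before fitting:

* **Bandpass 8–45 Hz** — a 4th-order Butterworth IIR run forward and
  backward (zero phase) per channel. The order and phase policy are this
  package's choice; the band covers the alpha/beta/low-gamma rhythms that
  carry the class signal. The realized forward–backward response passes
  25 Hz essentially unattenuated and suppresses 2 Hz by more than 90 dB.
* **Resampling** to a common rate (250 Hz for mixed-dataset pre-training)
  is done in the Fourier domain: exact zero phase and an exact output
  length of `round(T * target_fs / fs)` samples. A polyphase FIR
  implementation was considered and rejected because the available routine
  leaves a residual group delay of a few samples, which breaks zero-lag
  alignment tests.
* **Session z-scoring** — each channel is standardized with mean and
  population standard deviation pooled over *all* trials of one recording
  session, training and evaluation sessions separately. This preserves
  within-session amplitude ratios between channels. A zero-variance
  channel raises an error naming the channel rather than silently adding
  an epsilon.

## Data augmentation

Four per-trial operators, applied after z-scoring (their magnitudes are in
z-scored units): additive Gaussian noise (sd 0.1), a single
\(N(0, 0.1^2)\) DC offset per trial, a single \(N(1, 0.1^2)\) amplitude
factor per trial, and time-shift cropping — a `crop_window`-sample window
(default 512 = 8 patches of 64) placed uniformly at random each epoch
during training and at the trial center at evaluation time. The DC and
scale draws are one scalar per trial, applied to all channels, so relative
channel amplitudes are preserved. Slot indices are relative to the window,
so shifting never changes the positional embedding. For multi-dataset
pre-training, channels can additionally be subsampled with an independent
keep probability per channel (floor of one channel); no distributional
form for this is canonical, so independent Bernoulli keeps were chosen.

## Self-supervised pre-training

Masked-patch reconstruction in the BERT style. Time slots are selected
independently with probability 0.3; each selected slot receives one
action with ratios 0.8/0.1/0.1 — replace the embedded patches by a learned
mask token, replace them by a random embedded patch from the current
batch, or keep them. Selection operates on whole time slots across all
channels: EEG channels are referenced voltages, so a single masked sensor
could be interpolated from its spatial neighbors and the task would be
trivial. Two further conventions were open and are fixed here as in BERT:
keep-action patches still enter the loss, and the action draw is per slot
rather than per patch. An extra linear projection maps output tokens back
to \(D\)-sample patches, trained with the cosine loss
\(\mathcal{L} = 1 - \frac{x_p \cdot \hat{x}_p}{\lVert x_p\rVert\,\lVert\hat{x}_p\rVert}\)
averaged over manipulated patches only. Random-replacement embeddings are
treated as constants in the backward pass (no gradient flows to the donor
patch); gradients are accumulated per trial, and the effect of this
detachment on the objective is negligible.

## Optimization

AdamW with betas (0.9, 0.95) and decoupled weight decay 0.01 on the
embedding, attention, feed-forward and reconstruction weights; no decay on
biases, layer-norm parameters, the positional registry, the
classification token or the mask token. The classification head is also
exempt, except during supervised pre-training where its decay is raised to
1 because the head is discarded before fine-tuning. The learning rate
ramps linearly from 0 to \(3\cdot 10^{-4}\) over the warm-up and follows a
cosine decay to \(3\cdot 10^{-5}\); the schedule is stepped per optimizer
step with `warmup_steps = warmup_epochs * steps_per_epoch`. Gradients are
clipped at global norm 1. Supervised pre-training defaults to 600 epochs
with 100 warm-up epochs (`pretrain_policy()`); fine-tuning epoch counts
are dataset-dependent and left to the user. Every fit is exactly
reproducible from `policy$rng_seed`.

Mixed-dataset batches are handled per trial: each trial is tokenized with
its own montage, gradients are accumulated over the batch and averaged, so
no padding is needed in the default path. The encoder nevertheless
supports padded token rows excluded from attention (for callers that
prefer rectangular batches), and the test suite verifies padded positions
contribute exactly zero gradient.

For supervised pre-training across datasets, native labels are amalgamated
into five unified classes (LEFT_HAND, RIGHT_HAND, FEET, REST, BOTH_HANDS)
via a label map; unmapped labels raise an error naming the dataset and
label. `transfer_weights()` then moves the embedding, encoder,
classification token and all matching positional rows to a new montage,
initializing rows for unseen (channel, slot) keys afresh and
reinitializing the head for the new class count.

## Interpretability

* `filter_spectra()` treats each row of \(W_E\) as a length-\(D\) temporal
  filter and reports the dominant frequency of its magnitude spectrum;
  \(k\) cycles per 64-sample patch at 250 Hz is \(3.90625\,k\) Hz
  (approximately \(4k\)). Constant rows report 0 Hz.
* `pos_similarity()` summarizes each channel's positional embedding by the
  mean over its time-slot rows — the registry is per patch but sensor-level
  maps want one vector per sensor, and the mean is the simplest aggregate —
  and returns the cosine-similarity matrix between channels.
* `attention_rollout()` multiplies head-averaged, residual-corrected
  attention matrices \(\tilde{A} = \tfrac{1}{2}(A + I)\) (rows
  renormalized) across layers; the classification-token row, reshaped to a
  channel-by-slot grid, is the per-patch importance map rendered by
  `render_importance_map()`.

## The synthetic generator

`synth_generate()` emulates the statistical structure the classifier
exploits in real motor-imagery EEG, not its biophysics. Each trial is a
per-subject gain times 1/f-shaped Gaussian background noise plus alpha
(9–11 Hz, amplitude 1) and beta (18–24 Hz, amplitude 0.5) oscillations
with random frequency and phase per channel. Class information enters as
event-related desynchronization: on the class's motor channel (C3 for
right-hand, C4 for left-hand, Cz for feet, C3+C4 for both hands) the
oscillation amplitudes are scaled by `1 - effect_size`; REST is
unmodulated. Defaults are 4-second trials at 250 Hz — 1000 samples per
channel, matching common motor-imagery recordings — and a moderate default
effect size of 0.5. What the generator deliberately lacks: volume
conduction and realistic channel covariance, artifacts (blinks, EMG),
non-stationarity within a session, and between-session drift. Tests that
pass on this generator therefore demonstrate that the pipeline learns
lateralized band-power structure from noisy multichannel series; they do
not certify performance on real recordings.

## Numerical choices and degenerate inputs

Layer norm uses population variance with epsilon \(10^{-8}\), small
enough that the affine-invariance identity holds to \(10^{-6}\) even for
down-scaled tokens. Weights are initialized \(N(0, 0.02^2)\), layer-norm
gains at 1, biases at 0. Softmax rows with all keys masked cannot occur
(the classification token is never masked). The cosine loss raises an
error on zero-norm patches rather than regularizing silently. Ties in the
classification argmax resolve to the first class in sorted label order.
Windows shorter than one patch, band edges outside \((0, f_s/2)\),
inconsistent montages within a session, and unregistered
(channel, slot) keys all raise informative errors.

## Desk-scale study sizes

The shipped tests and examples run the full pipeline at reduced scale,
chosen so the whole suite completes on one CPU core: a 3-channel montage
(C3, Cz, C4), 32-sample patches with a 256-sample window, two encoder
blocks with two heads, 100–200 trials, and 15–25 epochs. At these sizes
the from-scratch classifier exceeds 80% held-out accuracy at effect size
0.8, stays at chance on null data (effect 0), supervised pre-training on
a 5-channel synthetic dataset transfers to the 3-channel montage and
reaches threshold accuracy in no more epochs than training from scratch,
and the 6-regime-by-4-fraction augmentation ablation on a fixed 30%
evaluation split reproduces the qualitative ordering in which time-shift
augmentation dominates no augmentation. These are directional, scaled-down
analogues of the full-scale experiments, not reproductions of their
absolute accuracies.

## Known limitations

The implementation is plain R and single-threaded; it is meant for
desk-scale experimentation, method study and teaching, not for training
the reference configuration on 42k trials. No EDF/BDF reader is included;
sessions use a JSON container (lossless for doubles) behind
`read_session()`/`write_session()`, and public-dataset download is out of
scope. Self-supervised pre-training is implemented and tested, but — as in
the supervised-vs-self-supervised comparisons that motivated this
design — supervised pre-training is the recommended default.
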