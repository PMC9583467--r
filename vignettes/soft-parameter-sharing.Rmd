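---
title: "Soft parameter sharing for multi-task clinical text models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft parameter sharing for multi-task clinical text models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softshare)
```

## The model

Small clinical corpora force a choice between under-trained task models and
pre-training on text whose semantics do not match the clinic. The framework
in this package takes a third route: several tasks are defined on the *same*
reports, each with its own network, and all networks draw their internal
weights from one global **template** tensor `E` of `p` slices of `r × c`
reals. A module needing a weight tensor of shape `(p0, r0, c0)` owns a small
**kernel** `M` of shape `(p, p0, kh, kw)` with `kh = r − r0 + 1` and
`kw = c − c0 + 1`, and materializes its weights as

$$W = \sigma(E \circledast M + b),$$

a valid (unpadded, stride-1) cross-correlation plus a per-slice scalar bias,
squashed by `σ`. The shape rule is exactly the valid-convolution output
formula, so any module whose spatial extent fits inside `(r, c)` can be
bound. Gradients of every task flow through its kernels *into the template*,
so the template accumulates whatever each task learns; a later task reading
the same template starts from that accumulated knowledge. Storage per module
is the kernel plus a few biases — far less than the dense weight it
replaces.

Three networks are assembled this way: a BiLSTM encoder–decoder that
summarizes a Finding into an Impression; a regressor with two same-padded
Conv1D stacks, masked global max-pooling over time and an FFN head that maps
a Finding–Impression pair to a severity score; and a single-head
encoder–decoder Transformer that generates the Treatment Recommendation from
both source texts. Training order is auxiliary-first
(Summary → Severity → ATR), either as full independent phases on the
evolving template (optimizer state reset between phases, template carried
over) or collaboratively, summing the weighted task losses per minibatch.
The learning rate follows
$lr_{i+1} = 0.8\, lr_i \cdot 0.01^{(i+0.01)/(\mathrm{epoch_{max}}+0.01)}$
from 0.01, and model quality is reported as `MLL = −ln(loss)` (mean
teacher-forced cross-entropy for the text tasks, MSE on the
`[0, 1]`-normalized label for severity).

## Parameters that matter

* **Template geometry `(p, r, c)`** — bounds the largest bindable module and
  sets the one-time shared cost `p·r·c`. The package default for the desk-
  scale study configuration is `(8, 96, 96)` with hidden size `n = 64`;
  the worked inspection example uses `(10, 105, 105)` with `n = 100`.
* **Hidden size `n` and depth `L`** — every internal weight is `n × n` (or
  `n × n × k` for convolutions), so `n` may not exceed `min(r, c)`.
  `L` counts Conv1D layers per stack and Transformer blocks per side.
* **`σ` (kernel activation)** — `tanh` by default: generated weights must
  carry both signs, which `sigmoid` would forbid; `identity` and `sigmoid`
  remain selectable per kernel.
* **SPS bias** — one scalar per output slice (length `p0`), broadcast. A
  full-size bias would erase the storage advantage that motivates sharing.
* **Schedule constants** — initial rate 0.01, factor 0.8, base 0.01, and a
  fixed horizon `epoch_max` (40 by default) shared by every phase whatever
  its epoch budget. The decay is
  extremely aggressive: the rate falls below `1e-5` within about ten
  epochs, after which an epoch moves parameters by less than `lr × batches`
  ≈ `1e-4` — numerically nothing next to weights of scale ~0.1.
  `train_config(lr_floor = )` therefore skips such epochs by default
  (`1e-5`; set 0 to run them all).
* **Dropout** — rate 0.1 after embeddings and FFN inner layers, training
  only.
* **Loss weights** — collaborative training sums `λ_s L_summary +
  λ_v L_severity + λ_a L_atr`, all 1 by default, with severity normalized to
  `[0, 1]` so its MSE lives on a scale comparable to the cross-entropies.

## Numerical choices

The cross-correlation core runs in the frequency domain (FFTW real
transforms, one template FFT shared by all bindings of a batch, gradients
accumulated spectrally and inverted once per slice). A direct, zero-skipping
path is used for sparse or tiny kernels, which makes one-hot kernels copy
template windows bit-for-bit — the property the delta-kernel tests rely on.
The two paths agree to ~1e-13 relative error.

Backpropagation is a reverse-mode tape built for this package (no deep
learning framework exists for R in the supported stack). Heavy operations —
the LSTM recurrence, attention with its Q/K/V projections, temporal
convolution, SPS generation, cross-entropy — are fused single tape nodes
with hand-derived adjoints, each verified against central finite
differences in the test-suite. Optimization is Adam with global-norm
clipping at 1.0 (protects the shared template from any one task's outlier
batch); argmax ties in decoding break toward the lowest token id.

Three departures from the most literal reading of the block equations were
forced by trainability, and are deliberate design decisions:

* **Residual + normalization in the Transformer.** The bare composition
  `FFN(Attn(FFN(MaskAttn(T)), Z, Z))` is untrainable: without a residual
  path the decoder cannot retain the identity of the previous token, and
  optimization plateaus at the marginal token distribution. The blocks
  therefore use standard pre-norm residual sublayers; the normalization is
  parameter-free (per-row standardization, no learnable gain/bias) so the
  parameter accounting is unaffected. This matches what "a Transformer
  model" denotes in practice.
* **Embedding scale.** Transformer token embeddings are multiplied by
  `sqrt(n)` before the sinusoidal positional encodings are added, the usual
  remedy for position drowning out token identity at Xavier scale.
* **Severity head.** A squashed output saturates under MSE and stalls (the
  gradient of a pinned sigmoid is zero), so the head is linear during
  training and predictions are clamped to `[0, 1]` only when reported.

Other conventions: standard LSTM gate nonlinearities (logistic on
forget/input/output, tanh on the candidate, `h = g_o · tanh(c)`), with the
recurrent half of each gate applied to `h_{t-1}`; the forget-gate bias
starts at 1. Each LSTM gate is the sum of two shared linear maps, so all
eight `n × n` gate matrices are template-generated. Embedding matrices, the
`2n → n` encoder-state projection of the summary decoder and the output
heads (vocabulary-sized, or `n → 1`) stay module-local and dense: their
shapes are vocabulary-bound or dimension-changing and exceed what the
template geometry is meant to host. Empty sequences are rejected; unknown
tokens map to `<unk>`; batches are right-padded with `<pad>`, masked in
every loss, attention and pooling step, and the convolution stacks re-zero
pad positions after every layer so a record's score is independent of its
batch neighbours.

## The synthetic corpus

Real report corpora are private, so the generator emulates one at the level
that matters for the method: scale and cross-field structure. Each record is
driven by a latent attribute vector (nodule size class, margin
irregularity, calcification, hypoechogenicity, vascularity, nodule count).
The Finding renders every attribute as a fixed six-token phrase plus
Poisson-jittered filler and 2% token-substitution noise (mean length ≈ 60);
the Impression is a deterministic summary keyed by severity band and
attributes (≈ 31); the Treatment is a deterministic severity-band phrase
bank plus attribute qualifiers (≈ 53); the severity label is
`min(5, size + 2·margin + calcification + hypoechoic + vascular)`, so all
six levels occur (each with probability ≥ 2%). Defaults: 513 records,
token pools of 353/263/277 per field, 70/10/20 split.

Because Impression, Treatment and Severity are deterministic functions of
the same attributes that the Finding renders, auxiliary-task transfer is
*possible by construction* — that is the point of the generator, and also
its limit. The suite's transfer check trains the treatment generator with
and without the auxiliaries (five-seed protocol, reduced configuration)
and asserts that auxiliary training does not lower the seed-mean test MLL.
At this scale the measured effect is a coin flip: individual seeds land on
either side and the seed-mean difference is within its own standard error,
slightly negative on the measured seeds. The explanation is an
initialization effect — the treatment model's kernels are fresh random
draws either way, so its starting weights are cross-correlations of those
kernels with either an i.i.d. random template (a well-conditioned random
init) or a structured, auxiliary-trained one (correlated, no better
conditioned); with the schedule's learning rate collapsing within about
ten epochs, whatever shared content the template carries has no time to
pay off. The check is kept asserting the tendency claim and currently
fails by that hair's breadth, documenting a null result at desk scale. It
says nothing about corpora and scales where longer training or larger
templates could change the balance. Absolute MLL values on this corpus
are not comparable to any real dataset's.

## Problem sizes used by the checks

The test-suite runs everything it claims: unit checks at toy sizes
(hidden size 8, templates around `(3, 12, 12)`), memorization runs on
16-record subsets at the reduced study configuration (`n = 64`, `L = 2`,
template `(8, 96, 96)`, Adam at 0.005 — held constant for the text models,
step-decayed for the severity regressor; 300 steps for the summary and
severity models, 500 for the Transformer), and the transfer
comparison on the full default corpus: five seeds, independent schedule,
10 + 10 + 20 epochs, batch 32, comparing the seed-mean test MLL of the
treatment generator with both auxiliaries against training it alone. These
sizes are the package's chosen desk-scale study configuration; larger
templates and hidden sizes are supported by the same code paths.

## Known limitations

* Single-head attention only, greedy decoding only (no beam search, no
  coverage/copy mechanisms), no pretrained embeddings — external knowledge
  is exactly what the framework is designed to avoid.
* The template neither grows during training nor factorizes; one template
  serves all tasks.
* The collaborative schedule recomputes every task on every minibatch, so
  its epoch cost is roughly the sum of the individual tasks'.
* Text only: the generator and models handle token sequences, not signal
  or image modalities.
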