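---
title: "Methods: the ddxnet architecture, featurizers and training recipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ddxnet architecture, featurizers and training recipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddxnet)
```

## The model

`ddxnet` implements a single fully convolutional architecture for
classifying time-varying clinical measurements — multichannel EEG,
single-lead ECG heartbeats, and gridded EHR episodes — without
modality-specific architectural changes. Three ideas carry the design:

1. **Causal convolutions.** Inside every dense block, the activation at
   time-step $t$ is a function only of inputs at times $\le t$, realized by
   left-padding each convolution with $(k-1)d$ zeros. For non-stationary
   physiological signals this prevents features from leaking backwards in
   time. The entry and transition blocks use ordinary symmetric ("same")
   padding: they perform spatial mixing and temporal aggregation, not
   temporal feature extraction.

2. **Adaptive dilation.** The $i$-th dense block of a stage (0-based, the
   index resetting at every stage) uses dilation
   $d_i = \min(128,\, 2^{\,i+2})$, so tap spacings run 4, 8, 16, … and
   saturate at 128. Stacking these within a stage yields receptive fields
   that grow geometrically — `receptive_field()` computes
   $1 + \sum_i (k_i - 1)\, d_i \prod_{j<i} s_j$ — so one stage sees both
   beat-scale and rhythm-scale structure without extra pooling. The cap at
   128 reflects that, at common clinical sampling rates, longer contexts
   stop generalizing.

3. **Dense connectivity.** Each block appends `growth_rate` new channels to
   its input by concatenation (never summation), so every later block sees
   all earlier feature maps. A block is bottleneck conv (kernel 3, dilation
   1, width `bottleneck_mult * growth_rate`) → ReLU → dilated conv
   (kernel 3, dilation $d_i$, width `growth_rate`) → ReLU → concatenate.

The full network is: entry block (same-padded conv, kernel 7, stride 2, to
`2 * growth_rate` channels; max pool window 3 stride 2), four stages of
2/6/8/4 dense blocks by default, a transition block after every stage
(average pool window 2 stride 2, then a kernel-1 conv compressing channels
by `compression`), and a head (global average pool over time, one affine
layer). There is deliberately **no batch normalization and no dropout**
anywhere: both were found to hurt convergence or accuracy for this model
family. The head emits raw scores; softmax/sigmoid live in the loss and in
`predict(type = "prob")` for numerical stability.

With the defaults (`growth_rate` 32, `compression` 0.5) the channel
arithmetic is fixed by the concatenative recurrence: entry 64, stages
128→64, 256→128, 384→192, 320→160, head input 160. `channel_plan()` exposes
this bookkeeping without building parameters, and the test suite verifies
that built models realize it exactly.

### Choices the architecture description leaves open

Several constants are not pinned down by the architecture's published
description; the package fixes them as follows (all configurable through
`model_config()`):

* **Growth rate 32, bottleneck width $4g$** — the standard dense-network
  convention for mid-sized models.
* **Both in-block convolutions causal, only the second dilated** — one
  $d_i$ exists per block, so assigning it to the main conv (bottleneck at
  $d = 1$) keeps the schedule well-defined. The stated kernel 3 is applied
  to both convs.
* **Entry stride 2 with max pool 3/2; transition compression 0.5** —
  the dense-network entry/transition convention the design mirrors.
* **ReLU after every conv except the kernel-1 transition conv and the
  head** — no activation is named in the description; ReLU is the
  convention of the model family.
* **A transition follows every stage including the last** ("after each
  stage"), then global average pooling.
* **0-based block index** in the dilation rule: the first block of every
  stage then gets dilation $2^2 = 4$, and the cap 128 is actually reached
  within the 6- and 8-block stages — consistent with the emphasis placed
  on the cap.

The engine itself (im2col convolution, pooling, backpropagation, Adam) is
written in base R matrix algebra, verified against a naive triple-loop
convolution oracle and finite-difference gradients in the test suite.

## Featurization

**EEG.** A referential (AR) recording is converted to the 22-pair
transverse central parietal (TCP) bipolar montage — `tcp_montage_pairs()`
ships the standard pair list as editable data — and each montage channel is
turned into MFCCs: resample 250→100 Hz (polyphase, `signal::resample`),
centred short-time analysis with a 2000-sample Hann window hopped by 100
samples, 2000-point FFT power spectrum, 40 triangular mel filters
(HTK scale, 0–Nyquist), log floored at $10^{-10}$, orthonormal DCT-II
keeping all 40 coefficients. Stacking 22 channels × 40 coefficients gives
880 rows; a 5-minute snapshot gives $1 + \lfloor 30000/100 \rfloor = 301$
frames. The hop-100 reading of the framing is forced: it is the only one
that reproduces 301 frames for a 5-minute 100 Hz signal. Keeping all 40
cepstral coefficients is likewise forced by $880 = 22 \times 40$.

**ECG.** The lead is resampled to 125 Hz, split into non-overlapping 10 s
windows, and each window min–max normalized to $[0,1]$ (flat windows are
skipped with a warning). R-peaks are local maxima at or above 0.9 of the
normalized range with a 0.36 s refractory gap; detection happens on a
7-sample (56 ms) moving-average-smoothed copy of the window — narrower than
a QRS complex, so the R-wave survives while isolated noise extrema are
suppressed — and each accepted peak is refined to the local maximum of the
unsmoothed trace within half a smoother width. Per window, each beat is cut
from its peak spanning 1.2× the median R–R interval and zero-padded or
truncated to 187 samples. Windows with fewer than two accepted peaks define
no R–R interval and contribute no beats.

**EHR.** A timestamped (feature, value) episode table is gridded onto 256
bins of 2 h, anchored at the first observation: the last observation within
a bin wins, gaps are forward-filled from the most recent observation, and
leading gaps take the per-feature default 0 (the convention appropriate
after per-feature standardization). The result is the 76 × 256 model
input. Re-gridding an already-gridded episode is a no-op, which the suite
checks.

## Training recipe

`fit()` runs mini-batch Adam with, per the recipe:

| parameter | default | note |
|---|---|---|
| learning rate | 1e-4 | peak rate at every (re)start |
| batch size | 64 | |
| epochs | 100 | |
| weight L2 | 0.01 | explicit penalty `0.01 * sum(w^2)` over **all** parameters, added to the loss |
| gradient clipping | 1.0 | global norm, applied after the L2 gradient |
| label smoothing | 0.1 | loss-level: `(1-eps) CE(labels) + eps CE(uniform)` |
| warm restarts | T0 = 10, mult = 2 | cosine annealing, epoch granularity |

Clipping threshold, smoothing mass and restart cadence are the cited
conventions for those techniques; the L2 penalty is implemented as an
explicit loss term (not optimizer-coupled decay) because it is stated to
cover all network parameters, and biases are therefore included. The
learning rate is updated per epoch, matching how schedule effects are
reported at epoch scale. Losses: label-smoothed categorical cross entropy
(multiclass head), element-wise binary cross entropy with targets relaxed
to $\{\varepsilon/2, 1-\varepsilon/2\}$ (binary and multilabel heads).

Determinism: `build_model()` draws He-uniform weights in a fixed order from
its seed, and `fit()` seeds its shuffling; two runs with identical seeds
produce bit-identical parameter vectors and loss histories. Training stops
with an explicit error naming the epoch if the loss goes non-finite.

## Synthetic data: what it emulates, and what it does not

The generators produce desk-scale data with the statistical structure each
pipeline stage assumes, so everything is testable without credentialed
downloads.

* `gen_multiscale()` — the architectural claim operationalized. Each class
  is a sum of a short-period and a long-period sinusoid (periods from a
  fixed 2 × 2 grid: 8/12 samples crossed with 96/128 samples, every
  long/short ratio ≥ 8) with per-sample random phases and i.i.d. Gaussian
  noise (σ = 0.3 by default). Because classes share each single scale
  pairwise, no single scale separates them all: a model must combine both.
  The suite shows a single undilated kernel-3 layer with a trained readout
  stays below 0.7 accuracy on a pair differing only at the long scale,
  while the dilated network exceeds 0.9. Noise is white by design — the
  simplest null under which the separability argument is reviewable.
* `gen_ecg_like()` — Gaussian-bump R-peaks at class-specific rates and
  morphology widths with jittered inter-beat intervals, returning planted
  peak indices so detector recall is measured against ground truth, not
  against another detector.
* `gen_ehr_multilabel()` — independent labels at stated prevalences; each
  label step-shifts the mean of its own disjoint triplet of features from
  a random onset; observation times are per-feature Poisson processes, so
  the episodes are genuinely irregular.

None of these are physiological simulations: there is no dynamical heart or
brain model, no 1/f background, no artifacts, no inter-subject variability,
no label noise. Passing tests therefore demonstrate that the pipeline is
implemented correctly and that the architecture extracts multi-scale
structure when it is present — not that benchmark-level clinical accuracy
would be reproduced on real recordings.

## Numerical choices and degenerate inputs

* Causal padding is explicit left zero-padding of length $(k-1)d$, which
  preserves length at stride 1 and makes the dependency cone exact; the
  suite asserts bitwise equality of activations on shared prefixes.
* Same-padding at stride 2 yields $\lceil T/2 \rceil$ outputs; pooling uses
  no padding and errors on windows that do not fit.
  `min_input_length()` reports the shortest supported input for a built
  model, and `model_forward()` rejects shorter inputs up front.
* The log in the MFCC pipeline is floored at $10^{-10}$, so all-zero
  signals featurize to finite values.
* Metrics with zero denominators are reported as 0 and flagged rather than
  NaN; degenerate label columns are excluded from macro/weighted AUROC with
  a warning instead of being scored 0.5.
* AUROC uses the rank statistic with averaged ties, which the suite checks
  is *exactly* the pairwise concordance probability.
* Multiclass prediction ties break toward the lower class index,
  deterministically.

## Problem sizes in the test suite

The suite is designed to run on one CPU in a few minutes: convolution and
AUROC oracles use 100 random small instances each; causality and
channel-bookkeeping sweeps use 20 random configurations; the learning
checks train the shrunk network (stages `c(1, 2)`, growth rate 8) on 400
sequences of length 256 for 30 epochs, three seeds, with a learning rate of
1e-3 — the small-model variant of the recipe, since the 1e-4 default is
matched to the full 20-block network and 100-epoch schedules. These sizes
are the package's chosen desk-scale experimental conditions, reported as
such in the README.

## Known limitations

* The engine is CPU-only base R; it is meant for desk-scale experiments and
  correctness, not for training the full default network on benchmark-sized
  corpora.
* EDF and WFDB readers are not bundled; recordings enter as matrices /
  CSV / RDS. The montage, featurizers and CLI operate on those
  representations.
* The R-peak detector is a thresholded local-maximum detector with
  smoothing and refinement — adequate for normalized single-lead windows,
  not a full QRS delineator (no P/T segmentation).
* Checkpoints embed config and seed but store parameters as R objects;
  there is no cross-language serialization format.
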