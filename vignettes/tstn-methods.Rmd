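---
title: "Decoding motor imagery with a spatial-temporal transformer: models, assumptions and design choices"
author: "tstn package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery with a spatial-temporal transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the signal model behind the synthetic sessions, the classifier and its
training protocol, the numerical choices that required a decision, and
what the test battery does and does not establish about real recordings.

## The decoding problem

A three-class motor-imagery brain-computer interface must decide, from a
2-s EEG epoch, whether the user imagined raising the left arm, the right
arm, or rested. The physiological carrier of that information is the mu
(alpha, 8–13 Hz) rhythm over sensorimotor cortex: imagery suppresses its
band power (event-related desynchronization, ERD) relative to rest. Every
component of this package — the generator, the CSP features, the pooled
classifier head, the ERD maps — is organized around that one statistic:
*band power changes tied to task windows*.

## The synthetic session generator

No subject recordings ship with the package; the generator
(`generateSession()`) is first-class, tested code that emulates the study
conditions all other modules are verified under.

**Signal model.** Each channel is the sum of three parts, in microvolts:

* a 1/f ("pink") background with unit spectral slope and 2 µV standard
  deviation — the dominant broadband character of resting EEG;
* a white noise floor of 1 µV — sensor and amplifier noise;
* a mu-band sinusoid at 10 Hz whose amplitude profile peaks over
  sensorimotor sites (10 µV on C3/Cz/C4, 6 µV on FC1/FC2/P1/P2, 4 µV
  elsewhere), with an independent random phase per trial.

During a task block of class *k*, the instantaneous mu band *power* on
channel *c* is multiplied by `1 − erdDepth · profile[[k]][c]` — an
amplitude step of `sqrt()` that factor. This is deliberately the simplest
model in which ERD is the *only* class-discriminative feature: a
classifier that scores above chance on these sessions can only be reading
band-power modulation, which is exactly the claim under test.

**Session structure.** An AO+MI (action observation + motor imagery)
session has 300 trials (150 left, 150 right), each trial being two AO+MI
blocks and one MI block of 2 s, each preceded by a rest period drawn
uniformly from 5–7 s. An MI-FB session has 150 trials (50 per class
including rest), each a 5–7 s preparation period, a 3-s task block, and a
2-s feedback interval that we model as additional rest (rendering the
feedback itself is out of scope). The montage uses the seven named 10-20
sites FC1, FC2, C3, Cz, C4, P1, P2; the hardware this emulates is an
eight-channel system whose eighth label is not documented, so the default
adds a configurable placeholder channel `EX8` rather than guessing.

**Lateralization.** The default ERD profile is lateralized (left-hand
imagery suppresses contralateral C4, right-hand C3, half-weight on Cz).
Real group data need not lateralize; the profile is a plain per-class,
per-channel weight table, so a symmetric regime is one argument away. A
discriminative profile of *some* kind is required — with identical
profiles for left and right the classes are statistically
indistinguishable by construction.

**What the generator does not emulate.** No volume conduction or forward
modeling, no ocular/muscle artifacts, no non-stationary baseline drift,
no inter-subject variability. Tests passing on these sessions therefore
establish the *correctness of the machinery* (features, gradients,
selection logic, power estimation), not field performance on human EEG.

**Between-session drift.** `simulateSessionDrift()` deepens `erdDepth`
geometrically by 15% per step (capped at 0.9), emulating the sharper
sensorimotor modulation users develop across feedback sessions. It is the
knob that makes the continual-learning cascade testable: later sessions
are genuinely different from, and easier than, earlier ones.

## Preprocessing

4–40 Hz 3rd-order Butterworth band-pass, applied forward–backward: offline
analysis has no causality constraint, and zero-phase filtering avoids
group-delay misalignment between the event table and the epochs.
Decimation to 250 Hz uses a zero-phase anti-aliasing IIR design
(`signal::decimate`). All downstream stages operate on the decimated
signal, so a 2-s epoch is T = 500 samples — the dimension the spatial
attention stage is sized for.

Epoch assembly follows the session structure: AO+MI sessions yield two
task epochs per trial plus one REST-class epoch taken as the last 2 s of
the trial's first rest period (the choice furthest from any task
activity; the protocol needs rest-class examples and no other source is
defined), and the per-trial MI blocks become a separate test set — the
"MI without feedback" stage of the cascade. Task blocks shorter than the
epoch length are skipped with a warning. Epoch windows are half-open
`[start, end)` with onsets in seconds from recording start.

## The classifier

The stack is: one-versus-rest CSP → spatial self-attention →
convolutional patch embedding → temporal multi-head attention → pooled,
normalized fully-connected head. Architecture constants: `Wq/Wk/Wv` are
500 × 500; conv1 has 2 filters of kernel 51; conv2 has 10 filters of
kernel 6 × 5 with time stride 5, giving 10 patches × 90 samples; 5
temporal heads with 2 × 2 projections and key dimension 90; the head maps
10 pooled features to 3 classes. Dropout is 0.3 after spatial attention
and 0.5 after temporal attention, in training mode only.

Decisions the architecture description leaves open, and how we resolved
them:

* **What the spatial attention tokens are.** The six CSP feature-channel
  time vectors. The stated projection dimension d = 500 equals the epoch
  length, which forces this reading.
* **Input scaling.** Each feature epoch is normalized by its RMS (one
  scalar per epoch) before attention. Raw microvolt-scale dot products of
  500-vectors overflow the softmax; a per-epoch scalar preserves the
  relative channel variances that carry the class information.
* **Convolution strides.** Conv1 stride 1 and conv2 stride (1, 5) with no
  padding are the unique simple choices that produce the stated
  10 × 90 output from a 6 × 500 input.
* **Pooling.** The head pools each patch row to its **log mean power**
  rather than its arithmetic mean. Every stage before the pool is linear
  or odd-symmetric in the signal (attention weights are bilinear forms,
  invariant under a global sign flip, while the values flip), and the
  generator's classes differ only in band power with random phase per
  trial — so the class-conditional distribution of a mean-pooled feature
  is symmetric around zero and carries no usable information, while its
  *power* is precisely the discriminant. Log-variance is also the
  canonical readout of CSP features, and rectification before pooling is
  standard in this architecture family.
* **Head normalization.** Layer-style: the pooled 10-vector is centered
  and scaled to unit variance (variance floor 1e-5), then given a learned
  per-feature scale and shift. Together with log pooling this makes the
  classifier invariant to global amplitude scaling of the recording.
* **Multi-head output mixing.** The concatenated heads are
  left-multiplied by `Wo` (`F = Wo · Concat`); the alternative
  right-multiplication is dimensionally inconsistent for 10 × 90
  concatenations and a 10 × 10 mixing matrix.
* **Patch partition.** Consecutive pairs in filter order.
* **No positional encoding** — none is part of this architecture.
* **Initialization.** Attention projections start at identity plus
  uniform noise (±0.01), so the untrained network is a near pass-through
  and the unusually large 500 × 500 projections do not destabilize early
  training; all other weights are scaled-uniform (Glorot-style). Seeded.

Numerical constants: softmax rows are max-subtracted; the pooling log
adds 1e-8; prediction ties break toward the lowest class index (LEFT <
RIGHT < REST). Probability rows sum to 1 to machine precision.

The batched forward and backward passes are implemented in C++
(RcppArmadillo); the exported R stage functions (`spatialAttention()`,
`embedPatches()`, `temporalMHA()`, `classifyHead()`) are the readable
reference implementation, and the test suite holds the two paths equal to
1e-8 against an independent nested-loop oracle. The two convolutions are
algebraically collapsed in the C++ path into a single effective kernel
(conv2's stride equals its width, so the composition is one 55-tap
convolution per channel); the collapse is exact and is covered by the
same oracle tests. Analytic gradients of the full stack are checked
against central finite differences to 1e-5 relative.

## Training protocol

Adam (learning rate 2e-4, β = 0.9/0.999, ε = 1e-8), batch size 50,
cross-entropy loss, dropout as above. `fitTSTN()` runs ten-fold cross
validation: per fold, the CSP bank is fitted on the 90% training split
only (no leakage through the spatial filters), the network trains with
early stopping on the 10% held-out loss, and the fold's held-out accuracy
at its best epoch is recorded. The returned model is refitted on all data
for the median of the per-fold best epochs. The gradient-epoch budget —
at most 100 epochs with patience 20 — is a package default; the reference
protocol does not state one.

**Continual learning.** `continualStep()` evaluates the frozen current
model on the new session (that number is the reported per-stage test
accuracy — each stage's model is tested on the *next* dataset), selects
the correctly classified trials, appends them to the cumulative pool, and
warm-starts training from the current parameters with the CSP bank
refitted on the pool. Cumulative warm-start (rather than training from
scratch on new trials only) prevents catastrophic forgetting and matches
the idea of continually *improving* one model. Whether the reference
protocol retrained from scratch, and whether earlier trials stayed in the
pool, is undocumented; these are our choices. The warm-start fit uses a
single random 10% holdout for early stopping instead of the full fold
loop. A step that selects zero trials advances the stage with the model
unchanged and a warning.

`replayOnline()` replays an MI-FB session trial by trial under a frozen
model — the offline equivalent of the online feedback loop; its decision
sequence equals batch evaluation, which the tests assert.

## Metrics

Accuracy is the confusion-matrix trace over the total; specificity and F1
are computed one-versus-rest per class and macro-averaged — the
symmetric convention for a three-class task whose reporting format gives
a single value per quantity without defining the averaging. Conventions
for empty cells: precision/recall/F1 are 0 when undefined; specificity is
1 when no negatives exist or none were predicted positive.

## ERD/ERS relative power

`erdMap()` quantifies ERD as `RP(%) = (A − R)/R × 100` per time bin and
channel, with `R` the mean band power of the −2–0 s pre-task reference
window and band power estimated as band-pass (8–13 Hz, 4th-order
zero-phase Butterworth) followed by the squared analytic amplitude,
averaged over trials — the canonical ERD/ERS estimator. Epochs destined
for ERD analysis are cut with 2 s of pre-onset context
(`assembleEpochs(..., preOnset = 2)`); the epoch window metadata
disambiguates the two epoch kinds.

Two numerical guards matter here. First, each epoch is reflection-padded
by 1 s before filtering and Hilbert demodulation, so the filter start-up
and the FFT wrap-around fall on padding. Second, even with padding a
narrowband oscillation's envelope estimate is unreliable within roughly a
quarter second of an epoch edge (the reflected continuation is phase
reversed), so `rpConfig()` trims `edgeTrim = 0.3` s from both epoch ends
before binning. The default map resolution is 0.1 s per bin; it is a
rendering choice, not part of the estimator.

When analyzing classifier output, pass the correctly classified trials as
the trial mask, so the map describes the trials the model actually
selected — the maps' ERD deepens across cascade stages exactly because
selection keeps the high-contrast trials.

## Problem sizes used in the test battery

The verification suite states its own scales:

* Classifier calibration runs at the full reference size — 900 training
  epochs (300 per class) from a 300-trial AO+MI session — with ten-fold
  cross validation, at ERD depth 0.4 (expected accuracy ≥ 0.85) and depth
  0 (expected within the 3-class chance band). These runs use a 15-epoch
  gradient budget with patience 6: on these sessions validation loss
  plateaus within a handful of epochs, and accuracy is insensitive to
  longer training.
* The continual-learning trend uses 60-trial AO+MI and 45-trial MI-FB
  sessions over 5 master seeds, base ERD depth 0.2 with the drift
  schedule above, the holdout fit mode, and a 12-epoch budget — sizes at
  which the full cascade remains a few minutes of CPU while the accuracy
  trend is still informative rather than saturated at the start.
* ERD recovery uses ≥ 100 task epochs per programmed depth; CSP and
  forward/gradient oracles use 200 random 8 × 8 covariance pairs and 50
  random parameter draws on a reduced geometry (d = 40) plus a
  reference-geometry check.

## Known limitations

* The generator's phase-random sinusoid has a line-like mu spectrum;
  real mu rhythm is broader band and amplitude-modulated over seconds.
* REST-class training epochs come from rest periods of the AO+MI session;
  if real protocols derive them differently, the epoch-assembly rule is
  the single place to change.
* The continual cascade assumes each new session arrives fully labeled
  (labels are needed to select correct trials); unsupervised adaptation
  is out of scope.
* Specificity/F1 macro-averaging is a convention choice; micro-averaged
  values differ under class imbalance.
* Model files are R-native serialized archives, versioned but not
  portable to other languages.
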