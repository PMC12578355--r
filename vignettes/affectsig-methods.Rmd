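---
title: "Methods: affective-state classification with per-indicator networks and symbolic distillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: affective-state classification with per-indicator networks and symbolic distillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Wearable devices record several physiological channels at different rates —
accelerometry (ACC), blood-volume pulse (BVP), electrodermal activity (EDA),
electromyography (EMG), electrocardiography (ECG), skin temperature (TEMP)
and respiration (RESP). `affectsig` classifies a wearer's affective state at
each moment into three classes (0 baseline, 1 amusement/excited, 2 stressed)
from windowed features of these channels plus static subject attributes
(age, gender, height, weight, smoking, exercised-today), and then *distills*
the fitted network into closed-form laws, one per physiological indicator,
so the model's use of each indicator is inspectable.

## The model

Let $A \in \mathbb{R}^k$ be the encoded attributes and, for indicator $j$,
let $B_j \in \mathbb{R}^{\xi \times m_j}$ be its features over the $\xi$
windows of one subject's recording. All three network stages are trained
jointly on the composite loss below.

1. **Contribution network** (one per indicator): a two-layer ReLU
   perceptron on the standardised fused input $[A \mid B_j]$ producing one
   scalar $\alpha_q$ per window — how strongly window $q$ should contribute
   to the temporal encoding.
2. **Causal temporal embedding**:
   $\beta_{qf} = \sum_{t \le q} \alpha_t B_{j,tf}$, an upper-triangular
   (causal) weighting: window $q$'s embedding depends only on the present
   and past, never on later windows. This is exact, and the test suite
   checks bit-identity of earlier outputs under perturbation of later
   windows.
3. **Affect network** (one per indicator): an $l$-layer ReLU perceptron
   (default $l = 3$) on the standardised $[A \mid \beta]$ producing one
   scalar affect level $\theta_q$ per window.
4. **Fusion analyser**: the per-indicator levels are stacked into
   $\Theta \in \mathbb{R}^{\xi \times M}$, shifted by a learnable baseline
   $u \in \mathbb{R}^M$ ($\Phi = \Theta + u$, initialised at zero), and
   passed through two purely linear layers to 3-class logits. Ties at the
   argmax resolve to the lowest class index.

**Loss.** Mean cross-entropy over windows plus
$\lambda \cdot \mathrm{mean}_j\,\mathrm{mean}_q\,(\alpha_{jq}-1)^2$
(default $\lambda = 0.01$): the regulariser anchors window contributions
near 1, so the embedding stays close to a plain cumulative sum unless the
data argue otherwise.

**Training.** RMSprop (accumulator decay 0.9, $\epsilon = 10^{-8}$),
initial learning rate $10^{-4}$ halved every 30 epochs, at most 150 epochs.
Each epoch visits the training subjects in a seeded shuffled order and takes
one optimiser step per subject on that subject's full window set. Early
stopping (patience 15) monitors the cross-entropy on a seeded 10% window
split held in from the *training* subjects only, and the best-validation
checkpoint is returned. Evaluation is leave-one-subject-out (LOSO): each
fold holds out every window of one subject; we report both pooled metrics
over the concatenated fold predictions and per-fold accuracies, since
either convention appears in practice.

All forward/backward passes are written in base R with exact analytic
gradients (verified against central finite differences in the tests); no
autograd framework is involved.

## Design choices in open territory

* **Input normalisation.** Each network standardises its input
  feature-wise. The statistics are calibrated once from the pooled training
  windows when fitting starts and then frozen. True per-batch statistics
  are unusable here: a batch is one subject's windows, so attribute columns
  are batch-constant (zero variance), and running-average statistics then
  explode at evaluation. Freezing also keeps the whole evaluation pass
  strictly causal. Globally constant columns get unit scale (centred,
  passed through). Gradients treat the statistics as constants.
* **Initialisation.** Weights are scaled-uniform
  $U(\pm\sqrt{6/(\mathrm{fan_{in}}+\mathrm{fan_{out}})})$; biases zero
  except the contribution network's output bias, which starts at 1 so the
  embedding begins exactly as a cumulative sum — the state the regulariser
  pulls toward. The analyser hidden width defaults to 32.
* **Scalar $\alpha$ and $\theta$ per window** is the one reading under
  which the second contribution-layer shape ($1 \times H$) and the
  $M \to 3$ analyser are consistent; $u$ is a per-indicator $M$-vector.
* **Window labels** use a purity rule: a window is kept only when every
  label sample inside it agrees (majority vote is available via
  `label_rule = "majority"`). Protocol blocks are long relative to the
  30 s default window, so purity costs at most one window per transition
  and avoids label noise.

## Feature extraction

Windows are non-overlapping, half-open $[(q-1)T, qT)$, with
$\xi = \lfloor L/T \rfloor$ and the trailing remainder discarded; $T$
defaults to 30 s (60/90/120 are common alternatives). Denoising is a
zero-phase (forward-backward) Butterworth low-pass — zero phase so features
are not shifted relative to labels; the cost is doubled attenuation in dB
(−6.02 dB at the cutoff instead of −3.01). The implementation designs the
filter with `signal::butter` and applies it with odd-reflection padding
scaled to ~1.5 cutoff periods plus steady-state initial conditions, so a
constant signal passes through to machine precision even at very low
cutoffs.

Per window: basic statistics are mean, population SD, max, min. ACC yields
per-axis statistics plus statistics of the per-sample sum x+y+z (16
features; the Euclidean norm is available via `acc_net = "l2"`). EDA is
low-passed at 1 Hz and split into tonic (0.05 Hz low-pass), phasic
(residual; tonic + phasic reconstructs the window exactly) and driver (the
positive rate of change of the phasic component, gated to rising stretches
whose phasic deflection exceeds 1% of the window peak so slow tonic leakage
does not register as events) — 12 features. BVP gives the peak frequency
and SDNN/RMSSD of inter-peak intervals (peak detection: prominence at half
the window SD, 0.4 s minimum separation, parabolic sub-sample refinement —
without refinement HRV statistics are quantised to the sampling grid). ECG
R peaks follow a Pan–Tompkins-style chain (5–15 Hz band-pass, squaring,
150 ms integration, adaptive threshold, refinement on the raw trace) and
yield SDNN (sample SD, $n-1$, the HRV convention) and RMSSD. TEMP adds the
least-squares slope in °C/s; EMG and RESP are low-passed statistics.
Degenerate windows (flat signal, fewer than 3 beats) produce zeros plus a
flag, never NaN. Attributes are one-hot encoded for categorical/boolean
fields and passed through raw for continuous ones ($k = 9$ under the
default schema).

## The synthetic cohort

The generator emulates the structure of a chest+wrist stress-protocol
recording: block schedules of the three states, multi-rate channels (wrist:
ACC 32 Hz, BVP 64 Hz, EDA 4 Hz, TEMP 4 Hz; chest: all channels at 700 Hz),
and state-dependent signal statistics. Defaults, chosen once as typical
physiology: heart rate 70/80/95 bpm with inter-beat jitter of SDNN scale
50/40/25 ms for baseline/amusement/stress; EDA tonic 2/4/7 µS with
skin-conductance responses at 2/6/12 events/min (bi-exponential kernel,
0.75 s rise, 2 s decay); respiration 14/17/22 breaths/min; temperature
drift 0/+0.01/−0.02 °C/min; motion intensity 0.10/0.50/0.30 g. Between
subjects: heart-rate shifts (SD 3 bpm plus −0.2 bpm per year of age from
30), EDA offsets (SD 0.3 µS), temperature baselines (SD 0.3 °C). The
default schedule is a half-scale version of a typical protocol: 600 s
baseline, 300 s amusement, 600 s stress (50 windows per subject at
T = 30 s). All randomness flows through one seeded generator per call.

What it does *not* emulate: realistic ECG/BVP morphology (only beat timing
statistics), motion artifacts, sensor dropout, label noise, and the
individual variability of real populations. Passing the test suite
therefore demonstrates that the pipeline is correct and that the
architecture can learn cross-subject structure under controlled conditions
— not field performance on real recordings.

## Symbolic distillation

For each indicator the per-window affect level $\theta$ is the distillation
target. Feature importance is the normalised column sum of
$|\partial \sum_q \theta_q / \partial X|$ over the indicator's raw inputs
$X = [A \mid B_j]$, computed analytically through both paths (the affect
network, and the contribution network via the embedding); scores are
non-negative and sum to 1. The ten highest-scoring features (ties to
manifest order) feed a genetic-programming symbolic regression over
\{+, −, ×, sin, cos, log, exp, pow\} minimising mean absolute error, with
protected semantics (log of |x|+1e−12, exp clipped at ±50, sign-safe
magnitude power with the exponent clipped to ±5) so every candidate is
finite. Complexity is the expression node count, capped at 15. The search
(population 500, 40 generations, tournament 5, subtree crossover, point and
subtree mutation, elitism of the front) keeps the best expression per
complexity level; constants are refined by deterministic golden-section
coordinate descent on front candidates. Inputs are z-scored before the
search and the transform is stored with the law.

The reported law is chosen from the complexity–loss front as follows: the
*converged* set is the maximal suffix of the curve in which each step
improves the loss by at most 1% (measured against the larger of the
previous loss and 1, so the rule acts absolutely once losses are small —
this is the reading of "converged" consistent with a curve that flattens
after sufficient complexity); among converged laws the fewest distinct
variables wins, with ties to lower complexity then lower loss. A
still-falling curve has no converged suffix, and the lowest-loss law is
returned. Law quality is $R^2 = 1 - SS_{res}/SS_{tot}$ against the
surrogate target (defined as 1 for a zero-variance target with vanishing
residuals, 0 otherwise; negative values are reported as computed).

## Numerical choices and degenerate inputs

* Checkpoints serialise every parameter at 17 significant digits;
  save → load → forward is bit-identical.
* Cross-entropy uses the log-sum-exp stabilisation; MSE is computed on the
  integer class codes, the only reading under which a squared error applies
  to a 3-class label.
* Per-class F1 defines 0/0 as 0; the headline F1 is the unweighted macro
  mean.
* Empty kept-window sets, too-short windows, cutoffs at or above Nyquist,
  fewer than 2 HRV intervals, and expressions over undeclared variables all
  raise typed errors (`config` vs `data`), mapped to exit codes 2/3 by the
  CLI.
* LOSO fold seeds, epoch shuffles and the validation split all derive from
  one master seed; a full run is bit-reproducible.

## Problem sizes

The test suite and the acceptance script run, as the package's reference
experiment, an 8-subject cohort with the default schedule (400 windows
pooled over LOSO folds), 200-sample symbolic-regression benchmarks over 10
seeds, and a 2-subject planted-driver cohort (50 single-window sequences).
These sizes exercise every stage end-to-end while keeping a full run in the
minutes range on one CPU.

## Known limitations

* The cumulative embedding makes window representations grow with session
  position; constant per-subject feature offsets are amplified linearly in
  time, which is the main driver of cross-subject errors. The attribute
  pathway can partially compensate (subject effects correlate with
  attributes in the generator, as they do in physiology).
* The GP engine is compact by design; it recovers laws of moderate
  complexity reliably but is not a substitute for large-scale SR tooling
  on hard targets.
* Frequency-domain HRV, convex-optimisation EDA deconvolution and
  respiration-effort analytics are out of scope.
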