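---
title: "Feature-free decoding of motor intent from raw EEG epochs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-free decoding of motor intent from raw EEG epochs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Most EEG brain-computer interfaces (BCIs) classify hand-crafted features —
band powers, event-related desynchronization, spatial filters — chosen from
prior knowledge of sensorimotor physiology. Those features transfer poorly
across tasks, recording modalities and users. `bcinet` implements the
opposite design: the classifier input is the *raw* time-domain epoch. Every
sample of every channel feeds a fully connected multilayer perceptron
(MLP), so the first hidden layer is free to form its own spatio-temporal
filters, and what the network "looks at" is read off afterwards from its
weights rather than decided in advance.

Three search/training components make this workable despite the very high
input dimension (channels × samples, typically 10^3–10^4 inputs against
10^2–10^3 training epochs):

1. **Scaled conjugate gradient (SCG) backpropagation** trains each network.
   SCG is a full-batch conjugate-gradient method that sizes its steps from
   a one-sided finite-difference curvature estimate along the search
   direction plus a Levenberg–Marquardt-style scale parameter, so there is
   no learning rate to tune. Training loss never increases across accepted
   steps.
2. **Simulated annealing (SA)** wraps training: after SCG converges, every
   weight `w` is perturbed by adding a draw from `Uniform(-w, w)`, the
   network is retrained, and the retrained network is adopted if its
   validation kappa improved — or, with exponentially decreasing
   probability, even if it degraded. Ten cycles are the default. This
   escapes poor local minima and, empirically, both raises the mean
   validation kappa and shrinks its spread on small training sets.
3. **A genetic algorithm (GA)** searches the structure space: one to three
   hidden layers, 1–500 tanh neurons each. Structures are encoded as
   29-bit genomes (2 bits layer count, three 9-bit neuron fields), combined
   by roulette-wheel parent selection plus single-point crossover, mutated
   with a 2% per-individual single-bit flip, with one elite carried
   unchanged. Fitness is the validation Cohen's kappa of the trained
   network.

Performance is always reported as Cohen's kappa,
`kappa = (p_o - p_e) / (1 - p_e)`, which corrects accuracy for the
agreement expected by chance; kappa 0 is chance level for any number of
classes, which makes two- and three-class results comparable. Significance
against chance uses the large-sample null standard error
`SE0 = sqrt(p_e + p_e^2 - sum_i p_i. p.i (p_i. + p.i)) / ((1 - p_e) sqrt(N))`
with a two-sided normal p-value.

## From continuous recordings to labeled epochs

For self-paced movement data there is no stimulus marker; epochs are
labeled from simultaneously recorded forearm EMG. The pipeline
(`label_recording()`):

* causal sliding RMS of each EMG channel over 0.5 s windows
  (`sliding_rms()`); the window is trailing so no post-onset energy leaks
  into pre-onset samples;
* an onset where a trace first rises above its per-side threshold
  (`detect_onsets()`), with a 300 ms refractory period so one clench is
  never counted twice. The threshold is deliberately manual (the protocol
  it mirrors set it by inspecting baseline RMS against clench RMS);
  `suggest_threshold()` offers a reproducible default (99th percentile of
  a user-marked movement-free stretch) but tests and examples pass an
  explicit value;
* movement epochs covering 100 ms before to 300 ms after onset (0.4 s at
  250 Hz = 100 samples), EEG channels only;
* optional rest epochs of the same length tiled from stretches at least
  0.5 s clear of any detected movement, giving the three-class problem
  (LEFT, RIGHT, NO_MOVEMENT).

Each epoch is demeaned per channel before entering the network
(`demean_epochs()`); variance is *not* standardized, because epoch variance
is expected to carry task information. Demeaning per channel (rather than
one mean per epoch) is the interpretation that removes per-electrode DC
offsets; a global mode is available via `per_channel = FALSE`.

Continuous data can be read from plain EDF (`read_edf()`); offline
preprocessing mirrors a standard acquisition chain: zero-phase windowed-sinc
FIR band-pass plus mains notch (`bandpass_notch()`) and anti-aliased
decimation to 250 Hz (`decimate_recording()`).

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| GA population / generations / elites | 30 / 20 / 1 | study conditions for the full-scale search |
| Mutation rate | 2% per individual | single random bit flip |
| SA cycles | 10 | balance of cost and benefit |
| SA acceptance decay `tau` | 2 | `p(k) = exp(-k/tau)`; only "exponentially decreasing" is prescribed, the constant is this package's choice |
| Hidden layers / neurons | ≤ 3 / ≤ 500 | structure search bounds |
| Epoch window | −0.1 s … +0.3 s | movement-locked window at 250 Hz |
| EMG RMS window / refractory / quiet gap | 0.5 / 0.3 / 0.5 s | labeling protocol |
| SCG `sigma` / `lambda0` | 5e-5 / 5e-7 | the published defaults of the algorithm |
| Validation fraction | 0.2 | internal early-stopping/fitness split; not prescribed by the protocol, exposed in `train_config()` |
| Early-stopping patience | 6 | consecutive validation failures |

## Numerical and design choices

* **Output layer.** Default is softmax with cross-entropy
  (`SOFTMAX_XENT`), matching the behaviour of the pattern-recognition
  networks this design is modeled on; a tanh output trained by summed
  squares (`TANH_SSE`) is available for fidelity experiments. Class =
  argmax of the output neurons; exact ties go to the lowest class index.
* **Flattening order** is channel-major (all samples of channel 1, then
  channel 2, …) and fixed; the weight analyses invert exactly this order.
* **Snapshot rule.** Training returns the weights with the best validation
  kappa; among snapshots with *equal* validation kappa the latest is kept,
  because training loss is monotone so later means better fitted. Early
  stopping fires after `patience` consecutive steps without a strict
  improvement.
* **Validation optimism.** Because the returned kappa is a maximum over
  the training trajectory (and over SA cycles), it is optimistically
  biased on small validation sets; with ~40 validation epochs the bias on
  null data is below 0.1. Fitness values are therefore comparable between
  genomes (same split, same optimism) but are not unbiased estimates of
  generalization — the cross-validated test kappa is.
* **One split per GA run.** All fitness evaluations inside one `run_ga()`
  call share a single stratified validation split (fixed by the training
  seed), so fitness differences reflect structure, not split luck.
  Likewise one `sa_train()` call compares all cycles on one split.
* **SA accept/reject.** Improvement is always adopted; degradation is
  adopted with `exp(-k/tau)`. The returned model is the best ever seen,
  even if a later cycle moved away from it — strictly safer than returning
  the final state.
* **Genome layout** (2 + 3×9 = 29 bits) is this package's encoding; only
  "a binary string" is prescribed. 9-bit fields cover 0–511 and are
  clamped to [1, 500]; the layer-count code 0b11 clamps to 3. Decoding is
  total, so crossover and mutation can never produce an invalid structure.
* **Roulette-wheel reproduction** is read as fitness-proportional *parent
  selection* followed by single-point crossover (the standard
  interpretation). Selection weights are `f - min(f) + 1e-6`, valid for
  negative kappas; all-equal fitness degrades to uniform selection.
* **Zero-phase filtering** uses odd-length symmetric windowed-sinc (Hann)
  kernels applied forward and backward over reflection-padded signals.
  Kernel order is `3 fs / low_edge`, capped at a third of the signal
  length; the decimation low-pass cuts at 80% of the target Nyquist with
  its DC gain normalized to exactly 1.
* **Rest placement.** Rest epochs tile quiet intervals from their start,
  deterministically, with optional seeded subsampling; the RMS hop is one
  sample. Neither is prescribed by the protocol; both are exposed.
* **Simultaneous left/right threshold crossings** in the same sample
  resolve to LEFT with a message; an alternating-hands task should never
  produce them.
* **Three-class decomposition** (`detection_and_laterality()`): laterality
  accuracy conditions on movement trials *predicted as movement*
  (consistent with "once a movement had been correctly identified");
  detection accuracy is over all true movement trials.
* **Rank-sum comparison** of selected layer counts uses midranks with
  exact enumeration when both groups have ≤ 10 values — layer counts are
  small integers, so ties are the rule and the usual exact tables do not
  apply — and a tie-corrected normal approximation otherwise.
* **Weight analyses.** The spatial map averages *absolute* first-layer
  weights over time and neurons per channel, then min-max normalizes to
  [0, 1]; fold-averaged maps average the raw per-fold maps before
  normalizing. The temporal spectrum averages *signed* weights over
  channels and neurons (preserving oscillatory structure; an absolute-value
  flag exists), removes DC, and takes a one-sided rectangular-window
  periodogram whose scaling satisfies Parseval's identity.

## What the synthetic generators emulate — and what they do not

`synth_epochs()` builds class-conditional epochs: pink (1/f) background
noise on every channel plus, for each movement class, an onset-locked
Hann-enveloped 8 Hz oscillation on that class's planted channels. The
defaults — 8 channels at 250 Hz, 0.4 s epochs, 2 uV effect in 2 uV noise
(single-trial SNR 1) — are chosen so that a trained two-class classifier
operates around kappa 0.5–0.6, the regime the method targets on real
scalp EEG. `synth_stream()` embeds the same evoked components in a
continuous recording and adds two EMG channels whose clench bursts are
200 ms of broadband noise at 40× the relaxed baseline (real clench EMG sits
two to three orders of magnitude above baseline; a strong burst also keeps
the causal RMS crossing latency within a few samples of the true onset).

The generators deliberately model an *evoked*, phase-locked component
rather than induced desynchronization, and contain no eye-blink or jaw
artifacts, no non-stationarity, and no inter-channel correlation beyond
the planted effect. Passing the recovery and separability tests therefore
demonstrates that the estimators and search machinery work — not that any
particular performance level will be reached on real recordings.

## Problem sizes used by the tests and acceptance script

All experiments are scaled to run quickly on a single CPU as the package's
own verification budget: spatial-map recovery uses 150 epochs/class
(comparable to a real session) with 16 hidden neurons over 5 CV folds; the
SA-versus-backpropagation comparison uses 60-epoch training sets paired
over 20 seeds with 10 SA cycles; subject-specificity uses two 12-channel
synthetic subjects with disjoint planted channel pairs; GA invariants run
a population of 6 for 4 generations with neuron sampling capped at 32.
Full-scale defaults (population 30, 20 generations, 500 neurons) remain
the configuration defaults.

## Known limitations

* Offline classification only; no online/streaming loop.
* No artifact rejection (ICA etc.) — by design, the method is given raw
  signals.
* The kappa significance test is asymptotic; for very small test folds
  prefer the permutation approach used in the test suite as an oracle.
* EDF support covers plain continuous EDF with a common sampling rate;
  proprietary acquisition formats are out of scope.
* The GA explores a minima-rich space in which many structures perform
  similarly; it constrains rather than optimizes, and near-random search
  behaviour at small population sizes is expected.
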