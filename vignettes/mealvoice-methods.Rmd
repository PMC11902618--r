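---
title: "Methods: simultaneous speech and eating-sound recognition"
author: "mealvoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simultaneous speech and eating-sound recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures implemented in `mealvoice`,
the choices made where the design was genuinely open, and what the packaged
desk-scale experiments do and do not demonstrate.

## The problem

A skin-contact (throat) microphone picks up both speech and the
body-conducted sounds of eating — chew clicks and swallow gulps — that
ordinary microphones miss. A single model that transcribes speech *and*
detects timed eating events would support daily health monitoring (chewing
rate, swallowing function, speech-based cognitive markers). The obstacle is
domain mismatch: speech recognition needs fine-grained linguistic
representations over a large vocabulary, while eating-behaviour recognition
is a sparse event-detection task over two classes. Training naively on one
domain destroys competence in the other.

## Signal model and front end

Input audio is PCM WAV (16-bit integer or float32), any rate and channel
count. Skin-contact microphones also pick up blood-flow rumble, so the front
end applies a high-pass before anything else. The filter realization is a
**zero-phase 4th-order Butterworth** (forward–backward `filtfilt`), chosen
to avoid phase distortion of the transient chew clicks the whole pipeline
depends on; attenuation at cutoff/4 is below 0.1 and passband gain at
4×cutoff above 0.9 in amplitude. Default cutoff: **100 Hz**. Resampling to
the **16 kHz** working rate uses the polyphase rational resampler from the
`signal` package (44.1 kHz → 16 kHz is the 160/441 ratio). Multi-channel
recordings are **summed raw, then peak-normalized once**
(`sum_channels()`); normalization maps the peak to |x| = 1 and leaves silent
clips untouched.

## Labels

Strong labels are `(start, end, symbol)` intervals in seconds (Audacity
label-track TSV, 6-decimal canonical formatting), annotated against video at
collection time; they are used **only for evaluation**. Weak labels drop the
times and keep the order; they are the CTC training target. Reserved
symbols: `_` (CTC blank, never a label), `#` (one chew), `$` (one swallow —
the chew symbol is conventional, the swallow symbol is this package's
choice, configurable via the vocabulary file), and a space token that
delimits concatenated utterances inside synthetic mixtures.

## Synthetic mixed corpus

Real meals interleave talking and eating, but paired training data are
scarce. The generator manufactures them: every example is **exactly 10 s**.

* Source clips of **7–10 s** are embedded whole, with white noise appended
  to both ends (the left/right split is uniform random, seeded, so events
  appear at varied positions).
* Clips **shorter than 7 s** are concatenated with a partner whose domain
  (speech vs eating) is chosen to balance the **cumulative seconds** of
  speech and eating material; remaining room is filled with further randomly
  selected clips while they fit, then noise fills the gaps before, between
  and after.

Balance is tracked in seconds rather than clip counts because event density
differs wildly between domains. Same-domain pairs are allowed outcomes of
the balancer. The padding noise is Gaussian at **30 dB below the pool median
RMS** — audible padding that never masks events. All sample arithmetic is
integer-exact: sources are embedded bit-for-bit, and the per-example
manifest records `(source, domain, offset, duration)` for every segment.
Overlapping (simultaneous) speech-plus-chewing is deliberately out of scope.

## Model

The recognizer is a frame encoder followed by a fully connected head
emitting per-frame log-probabilities over the token vocabulary (blank
first) at a fixed **20 ms frame stride** — the rate every downstream
component assumes.

The full-scale design pairs a large pretrained self-supervised encoder
(frozen convolutional feature extractor, trainable transformer) with a head
of **4 FC layers × 1024 units, LeakyReLU, batch normalization, dropout
0.15**. This package ships a **CPU surrogate** with the same contract:

* a fixed spectral analysis (non-overlapping 20 ms Hann windows, power
  spectrum),
* a learnable triangular filterbank (24 filters) playing the role of the
  frozen feature extractor — `frozen_frontend = TRUE` by default, and
  `trainable_parameter_partition()` exposes the freeze semantics,
* per-clip cepstral mean/variance normalization of the log filterbank
  energies (without it the downstream `tanh` saturates on the raw
  log-energy range),
* context stacking (±2 frames) and one trainable `tanh` projection (the
  "encoder body", updated by the encoder optimizer group),
* the FC head and a linear projection to the vocabulary.

The head's output rows are near-uniform at initialization (entropy ≥ 0.9
log V) with the default zero blank bias. `build_model(blank_bias =)` can
start the blank token dominant; see *Toy-scale training dynamics*.

Batch normalization operates per feature over the batch×time axis; running
statistics (momentum 0.9) serve evaluation mode, so scoring is
deterministic. Checkpoints are single-file JSON archives with a mandatory
version field.

## CTC

Training minimizes the Connectionist Temporal Classification negative
log-likelihood: the probability of a weak label sequence is the sum over all
monotonic blank-augmented frame alignments. The recursions run in **scaled
linear space** (per-step renormalization) rather than log space — exact to
machine precision and considerably faster in R; the unit suite checks the
loss against exhaustive path enumeration to 1e-8 in log space and the
analytic gradient against central finite differences. Unalignable targets
return a clean `Inf` rather than a numeric overflow.

Decoding:

* **Best-path** — per-frame argmax (ties toward the lowest token index),
  collapse repeats, drop blanks; each emitted token is stamped with the
  first frame of its run.
* **Prefix beam search** — sums path mass per collapsed prefix. Defaults
  follow the recognition setup: beam width 100, beam pruning at −12.0
  (drop prefixes trailing the leader by more), token pruning at −1.2
  (only expand tokens above that frame log-probability), history pruning
  interpreted as the standard merge of identical prefixes by log-sum-exp,
  and no language model. With pruning disabled and a saturating beam the
  search provably returns the maximum total-probability labeling (checked
  against brute force).

CTC emits events as isolated peaks of 1–4 frames, so each decoded event
token becomes a single-frame interval for scoring (`peaks_to_events()`).
Transcripts are decoded with the beam; event timing uses best-path decoding,
which keeps every peak at its emitting frame.

## Two-stage fine-tuning and the comparative protocols

Speech recognition is the more complex task, so stage 1 adapts the model to
speech only; stage 2 continues on eating-related data. Seven protocols
(`protocol()`): single-stage baselines A1 (speech), A2 (eating), B1 (pooled
independent data), B2 (synthetic); two-stage C1 (→ eating only), C2
(→ pooled), C3 (→ synthetic). Stage 2 resumes from the stage-1 best
checkpoint with the vocabulary extended by the event tokens; the new output
rows start at small random values (the mechanism for introducing event
tokens into a speech-trained model is this package's interpretation — the
choice is not critical because those rows train quickly).

Optimization uses two groups: **AdaDelta** (lr 1.0, ρ 0.95, ε 1e−8) for the
head and **Adam** (lr 1e−4) for the encoder body; the frontend receives no
updates and holds no optimizer state while frozen. After each epoch the
validation loss is computed in evaluation mode; when the relative
improvement over the previous epoch is **below 0.25%**, the head rate is
multiplied by **0.8** and the encoder rate by **0.9**. The returned model is
always the **minimum-validation-loss checkpoint**. Data are split 9:1 into
train/validation by count (`round(0.9 N)`), deterministically per seed.

`optim_group_config(anneal_patience =)` generalizes the annealing rule: the
rate cut fires only after `patience` consecutive sub-threshold epochs (the
counter resets after each cut). The default 0 reproduces the plain
arithmetic exactly. The patience exists because the plain rule presumes
fine-tuning a pretrained encoder, where validation loss improves from the
first epoch; a surrogate trained **from scratch** passes through CTC's
blank-dominated warm-up plateau, during which per-epoch improvements sit
below the threshold for tens of epochs and the plain rule anneals the
learning rate to zero before learning begins (observed directly: lr ≈ 1e−4
by epoch 90, training dead). The toy benchmark runs patience 10.

## Evaluation

Speech: **character/token error rate** — minimum edit distance
(substitutions + deletions + insertions) over the reference length, with
event tokens, blanks and whitespace stripped first.

Events: each ground-truth interval is expanded by a per-class **allowance**
— 0.05 s for chews (chewing-rate estimation tolerates loose timing), a
strict 0.01 s for swallows (swallow timing matters medically). A prediction
is a true positive if its half-open interval overlaps a not-yet-matched
expanded entry of the same class; matching is **chronological greedy
one-to-one** (deterministic, standard in event-detection scoring, and
conservative for rapid chew trains — two peaks inside one chew count as one
TP plus one FP). The unit suite verifies the greedy matcher's count
identities against a brute-force optimal bipartite matcher; greedy is the
contract. F1 = 2PR/(P+R), defined 0 when P+R = 0. Reports carry
{error rate, chew F1 @ 0.05 s, swallow F1 @ 0.01 s}.

## The toy world

`gen_toy_dataset()` emulates the two private corpora so everything runs with
no downloads:

* **Speech** — each token of an 8-symbol vocabulary is a 140 ms tone burst
  at a distinct carrier (300 Hz – 0.85·Nyquist), ~5 tokens/s with jittered
  gaps; the transcript is exact. Each token's carrier is jittered ±8% per
  instance — a stand-in for speaker variability that makes adjacent
  carriers overlap, so the task has an irreducible confusion floor (~10%
  token error) like real speech recognition; without it every protocol
  decodes near-perfectly and retention comparisons degenerate into
  single-error quantization noise. Durations are stratified so both
  synthesis branches run (a third of clips in 7–9.5 s, the rest
  1.5–5.5 s).
* **Eating** — meals alternate chew runs and swallows (about one swallow
  per 3 s). Chews are 30 ms high-band (>600 Hz) noise clicks at 1.5 Hz with
  ±15% onset jitter; swallows are low-band (<450 Hz) gulp transients
  decaying over ~40 ms inside a 400 ms annotated interval. Strong labels
  carry the true onsets/offsets.
* Held-out test clips come from a disjoint seed group, emulating held-out
  subjects; all carriers sit above the 100 Hz high-pass.

A hand-coded reference detector (per-frame low/high band energies,
threshold, band-dominance classification) achieves F1 ≥ 0.99 on noise-free
toy clips — evidence that the task is solvable from the signal and the
labels are correct, independent of any trained model.

What the toy world does **not** model: real chew/swallow spectro-temporal
variability, speaker differences, coarticulation, recording-channel effects,
and overlapping speech-plus-eating. Passing toy benchmarks demonstrates the
pipeline's correctness and the qualitative training-protocol phenomena, not
field performance.

### Toy-scale training dynamics

Three design choices exist purely to make from-scratch CTC training
tractable in minutes on one core; all were validated by direct probes of the
gradients and occupancy posteriors:

* **Output initialization.** Output weights start at sd 0.5/√width — small
  enough that rows are near-uniform, large enough that the feature→token
  pathway carries signal; with a much smaller gain the symmetry-breaking
  phase of CTC training (where token identities first attach to frames)
  takes hundreds of epochs. For event-train targets the toy benchmark also
  starts the blank bias at 2.5: approached from the blank-dominant side,
  training localizes events at their acoustic frames, whereas from a
  uniform start it can settle into the degenerate all-event solution (emit
  the majority event everywhere with a small blank probability, which the
  combinatorics of alignment sums makes locally stable).
* **Event rendering.** A long homogeneous event is unlearnable for a
  frame-local model under CTC: the occupancy posterior spreads over the
  event's frames and the per-frame probability equilibrates at occupancy
  level (~1/frames), below the blank — so nothing is ever decoded. The toy
  swallow therefore concentrates its energy in a sharp transient; the
  annotated interval still spans the full 400 ms act.
* **Augmented corpora and budgets.** The benchmark expands each training
  pool fivefold with the standard augmentations (speed 0.9/1.1, one
  time-dropout, one frequency-dropout copy), and runs 70 stage-1 epochs /
  80 stage-2 epochs with minibatches of 4. The full-scale defaults
  (4×1024 head, dropout 0.15, patience 0) are untouched.

## The packaged benchmark

`run_toy_benchmark(seed)` builds the toy corpora, trains A1 and A2 from
scratch, reuses A1's checkpoint for the stage-2 protocols C1 and C3, and
evaluates all four on the held-out sets (about five minutes per seed on one
core). The acceptance suite runs seeds 1–3 and takes medians. The expected
qualitative pattern:

* A1 transcribes toy speech at low token error; A2 detects both event
  classes at high F1;
* C1 (stage-2 on eating only) multiplies A1's speech error several-fold —
  catastrophic overwriting of the linguistic mapping — while detecting
  chews well;
* C3 (stage-2 on synthetic mixtures) keeps speech error at A1's level and
  high chew F1 simultaneously.

Toy C3 runs typically miss the rare swallow class (its instances in the
small synthetic corpus are few and the stage-2 budget is short); chew
detection and speech retention carry the comparison. At a few hundred test
tokens a single substitution moves the token-error rate by ~0.5%, so
retention comparisons against a near-perfect A1 carry one decoding error of
slack.

## Numerical choices and degenerate inputs

* Silent clips pass through normalization unchanged; preprocessing is
  idempotent to within 0.5 dB per band.
* CTC: ties in best-path argmax break toward the lowest token index (blank
  first); unalignable targets yield `Inf`; beam search with `token_logp_min
  = 0` degenerates to the empty output on diffuse posteriors by design.
* Edit distance is unit-cost; the empty reference is an error, the empty
  hypothesis gives rate 1.
* Label files reject non-numeric times, `end ≤ start`, and blank symbols,
  naming the offending line.
* All randomness flows through explicit integer seeds (< 2³¹); every
  generator, training run and benchmark is bit-reproducible given its seed,
  and seeded helpers restore the caller's RNG state.

## Known limitations

* The surrogate encoder is frame-local (±2 frames of context); it cannot
  model long acoustic context the way a transformer encoder does, which is
  one reason toy C3 underperforms on rare swallows.
* The pretrained-SSL adapter is an interface seam only; no pretrained
  weights ship with the package.
* LISA segmentation and the B-protocols are implemented and tested but not
  part of the packaged benchmark, which runs the four protocols that carry
  the qualitative comparison.
* Event scoring is greedy one-to-one by design; optimal bipartite matching
  would score duplicate peaks slightly differently.
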