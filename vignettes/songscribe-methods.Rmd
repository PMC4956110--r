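---
title: "Methods: hybrid convolutional-network/HMM annotation of birdsong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid convolutional-network/HMM annotation of birdsong}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(songscribe)
```

# The problem

Birdsong — and many other sequential vocalizations — is a sequence of
discrete vocal elements ("notes") that (i) fall into a modest number of
classes, (ii) have behaviourally meaningful onset and offset times, and
(iii) are sequenced by a probabilistic syntax. Annotating long recordings
therefore requires three sub-tasks: **boundary detection** (BD; where are
the notes), **local classification** (LC; which class does each stretch of
sound belong to), and **global sequencing** (GS; which label sequences are
syntactically plausible). songscribe implements the three arrangements of
these steps that the package's central fitting function,
`song_annotator()`, exposes:

* `BD_LC_GS` — boundaries first, by amplitude/gap/duration thresholding of
  an amplitude envelope; classifier scores are then averaged within each
  detected interval and a label sequence is decoded under the syntax.
* `LC_BDGS` — the classifier labels every millisecond frame with one of
  `3n + 1` classes (three sub-divisions per note class plus silence), and a
  sub-state hidden Markov model decodes boundaries and labels jointly.
* `LCGS_BDGS` — as `LC_BDGS`, with the classifier's input window widened
  from 111 ms to 303 ms so the network itself can exploit syntactic context
  spanning roughly three notes.

# Front end

Spectrograms use a 512-sample short-time Fourier transform with a hop of 32
samples at 32 kHz — one frame per millisecond — tapered with the 0th-order
discrete prolate spheroidal sequence (half-bandwidth `W = 4/512`), the
taper with maximal spectral concentration at that bandwidth. Only bins with
centre frequencies in `[1, 8)` kHz are kept: 112 rows at 62.5 Hz spacing.
Log magnitudes are floored at `1e-10` before the logarithm so silent input
is finite. Normalization (subtract mean, divide by standard deviation;
population convention, global by default with a per-row option) is fitted
on each training fold only and stored with the classifier, so
cross-validation folds never share statistics.

Two amplitude envelopes are available for thresholding: the sum of the
log-magnitude band rows per frame (the default), and full-wave
rectification followed by a 4th-order zero-phase Butterworth low-pass at
200 Hz, log, and sampling at the frame centres. The spectral-sum envelope
is the pipeline default; the rectification variant is retained for
comparison.

**Frame alignment.** A frame is anchored at its starting sample
(frame `t` covers samples `[32t, 32t + 512)`), but describes the signal at
its centre. All conversions between annotations (milliseconds) and the
frame grid therefore shift by `fft/(2*hop) = 8` frames
(`annotation_to_frame_grid()` / `frame_grid_to_annotation()`). Intervals
are half-open `[onset, offset)` with 0-based frames throughout; the final
partial frame of a waveform is dropped.

# Boundary detection by thresholding

`detect_note_intervals()` applies three passes in fixed order: keep frames
strictly above the amplitude threshold; merge silent gaps strictly shorter
than the gap threshold; discard intervals strictly shorter than the
duration threshold. `fit_thresholds()` selects the triple by exhaustive
grid search — 64 envelope quantiles × gap 0–30 ms × duration 0–50 ms in
5 ms steps — minimizing the pooled timing error rate on the training
pairs, with ties resolved toward the smallest amplitude, then gap, then
duration threshold. The search evaluates the same interval-matching code
as the reported metric, so the optimized objective and the reported
objective cannot drift apart. This stage is where near-zero inter-note
gaps are fatal: an envelope cannot show a boundary that contains no
silence, which is the regime the sub-state HMM arrangements exist for.

# The frame classifier

`build_architecture()` constructs the fully convolutional stack: three
blocks of (5×5, 5×5, 4×4) convolution + 1×1 CCCP convolution + 2×2
stride-2 max-pooling (16 channels each), a 240-channel convolution of
height 11 and width 9 (exactly consuming a 112×96 window), and a 1×1
softmax convolution. For the wide arrangement a 25-frame convolution is
inserted before the softmax layer, consuming the 25 output frames the
fourth layer produces on a 288-frame window. One CCCP layer per block is
the default (`n_cccp` raises it). Shape traces are validated at
construction: every architecture must compose to a 1×1 output on its
declared window.

Weights start from zero-mean Gaussians with standard deviation
`sqrt(2/fan_in)` and zero biases, deterministic per seed. Training is plain
SGD on the cross-entropy of the softmax outputs at the stride-8 output
positions of whole padded sequences (fully convolutional training; the
temporal stride of 8 follows from the three pools). Mini-batches are
random training sequences totalling at most `batch_s` seconds. The
learning rate and initialization seed are selected jointly by probing each
candidate pair for a fixed number of iterations and keeping the pair with
the lowest sub-validation error seen; full training then halves the rate
each time the sub-validation error stops improving (a patience of
`patience` evaluations, one evaluation every `eval_every` iterations),
three halvings in total. The training fold is split into three sub-folds
and the three train-on-2/3 members form an ensemble whose softmax outputs
are averaged at recognition. For `LCGS_BDGS` the stack minus the inserted
layer is trained first; the layer is then inserted (fresh He
initialization, surrounding weights retained) and the whole stack is
fine-tuned at the pre-training's selected rate.

Dense per-frame scores despite the stride of 8 come from shift-and-stitch:
the stack is evaluated at the eight temporal phases of the reflect-padded
spectrogram and the outputs interleaved (`mode = "dense"`). A fast mode
evaluates one phase and fills intermediate frames with the nearest
computed column; it quantizes boundaries by at most 4 ms and is used for
the scaled-down benchmarks and smoke tests. Reflect padding by half the
input window gives every frame a centred window; sequences shorter than
half a window plus one frame are rejected.

The compute kernels (im2col convolution, pooling, backpropagation) are
RcppArmadillo with a reusable buffer pool; single precision is the default
compute path, with a double-precision path used by the finite-difference
gradient validation in the test suite (tolerance 1e-4 relative; the
double path agrees with analytic gradients to ~1e-8).

# Syntax model and decoders

`fit_syntax_model()` estimates second-order transition probabilities with
additive smoothing, `P(Z|XY) = (P0(Z|XY) + a) / (1 + n a)`; unseen
contexts and the first two notes of every sequence are uniform. The
smoothing constant is chosen from `{0, 1e-3, 1e-2, 1e-1, 1}` by three-fold
cross-validation within the training sequences on held-out log-likelihood
(the cheap, leakage-free surrogate for full-pipeline inner
cross-validation, which would require retraining classifiers per inner
fold).

`build_substate_hmm()` expands every context `(X, Y)` into four
left-to-right states — thirds of note Y plus trailing silence — with the
transition probabilities `P(XY_i|XY_i) = P(XY_{i+1}|XY_i) = 0.5` (i = 1, 2),
`P(XY_3|XY_3) = P(XY_s|XY_3) = 1/(n+2)`,
`P(YZ_1|XY_3) = n/(n+2) P(Z|XY)`, `P(XY_s|XY_s) = 1/(n+1)` and
`P(YZ_1|XY_s) = n/(n+1) P(Z|XY)`. Three sub-divisions are the minimum that
makes boundaries structurally unambiguous: with only two, a misclassified
sub-division inside a note could legally restart it, creating spurious
boundaries; with three, sub-state 1 can only follow sub-state 3 or
silence. Initial contexts (first element `e`) use uniform successor
probabilities, and a silence-emitting start state `(e, e)` precedes the
first note; decoding may begin either there or directly in a first-note
sub-state 1 (uniformly), since a sequence may begin mid-silence or at a
note onset. No termination penalty is applied — a path may end in any
state — matching the convention that sequence generation may stop
anywhere.

Both decoders are exact Viterbi in the log domain with `-Inf` structural
zeros and ties broken toward the lower state/class index. The interval
decoder maximizes summed syntax-plus-score log probability over label
sequences (contexts as states); the frame decoder runs over the sub-state
machine (C++ with sparse predecessor lists). Classifier posteriors can be
converted to scaled emission likelihoods by dividing by per-class priors
(Bayes' rule, priors = training-fold frame frequencies of the output
classes); whether the conversion is applied is decided within the
training data by decoding each ensemble member's sub-validation sequences
both ways with a syntax refit on that member's sub-training sequences, and
keeping the setting with the lower pooled note & timing error rate (ties
keep the unconverted posteriors). For the interval decoder the conversion
commutes with interval averaging, so it is applied to the averaged scores.

`path_to_annotation()` reads notes off the decoded path: onset at the
first frame of a sub-division-1 state following a third sub-division,
silence or the path start; offset one past the last frame of the
subsequent third-sub-division run; paths that end inside a note close it
at the end of its state run (a decoded sequence can legitimately end
mid-note).

# Evaluation measures

Six error rates are computed on truth/prediction pairs, pooled over
sequences by summing numerators and denominators:

* **note ER** — total Levenshtein distance between the label sequences
  over total true notes;
* **note & timing ER** — one minus the fraction of the timeline covered by
  correctly recognized intervals: for each true note, the same-class
  output note with the longest overlap (each output note used at most
  once, conflicts resolved greedily in descending overlap), plus
  true-silence frames the prediction leaves unlabelled;
* **timing ER** — the same with all classes collapsed: pure boundary
  accuracy. Collapsing classes can only enlarge the matchable set, so
  timing ER ≤ note & timing ER, a property the test suite asserts;
* **identification ER** — fraction of true notes whose nearest output note
  (absolute midpoint distance; exact ties count as errors) has the wrong
  class or does not exist;
* **duration ERs** — summed absolute duration differences over correctly
  identified notes (relative to their summed durations), and over mutually
  nearest gap pairs (unpaired true gaps count in full, relative to total
  true gap duration).

The greedy longest-overlap matching is not guaranteed optimal in
adversarial overlap configurations; an exhaustive optimal assignment is
available (`optimal = TRUE`) and the test suite verifies that the greedy
total equals the optimum on sampled realistic instances (≤ 6 notes).

# Synthetic songs

`generate_dataset()` renders seeded, exactly annotated song bouts: note
classes are harmonic stacks (fundamentals 1.15–2.6 kHz, 2–3 partials kept
inside the 1–8 kHz band, optional ±2 Hz/ms linear FM, 3 ms raised-cosine
ramps) plus a broadband aspiration component 20 dB below the tonal peak —
vocal sounds are never spectrally pure, and it is this wideband footprint
that summed-log-magnitude amplitude envelopes respond to — with
class-specific duration ranges spanning 40–180 ms; sequences
of 8–15 notes are drawn from a configurable second-order syntax (default:
a seeded, deliberately non-uniform random syntax); inter-note gaps are a
mixture of near-zero gaps (0–2 ms with probability `p_zero_gap`, default
0.05) and uniform 5–120 ms gaps; bouts carry 60–150 ms of leading and
trailing silence and sit in white Gaussian noise at a configurable SNR
(default 30 dB, note RMS over noise RMS). These defaults emulate the
statistics the annotator is built for — class counts near eight, note
durations of tens to hundreds of milliseconds, gaps down to zero — but
make no claim of acoustic realism: real song notes have richer spectral
shapes, amplitude modulation, inter-rendition variability and coloured
background noise. Passing tests on this generator demonstrates that the
machinery (front end, training, decoding, scoring) is correct and that
the arrangements order as expected when gaps vanish; it does not
demonstrate field-recording accuracy.

`extract_songs()` implements the bookkeeping rules for turning raw
annotations into training sequences (rare classes to unclassifiable;
songs = runs of > 7 notes between calls/≥ 300 ms gaps; splitting at
unclassifiable notes; dropping fragments < 3 notes; greedy chunking to
≤ 15 notes). Literal idempotence cannot hold for fragments shorter than
eight notes — re-extraction would discard them under the > 7 rule — so the
idempotence property is asserted for outputs that satisfy the song
criterion.

# Cross-validated benchmarking

`run_arrangement()` performs three-fold cross-validation over song
sequences: per fold, a training subset of the requested duration is drawn
from the non-validation sequences, every stage is fitted strictly inside
it (each fitted object records its fold's training sequences, which the
tests check against the fold assignment), and the held-out sequences are
decoded and scored. `compare_arrangements()` repeats this over
arrangements on identical folds and seeds. All randomness flows from one
master seed.

# Problem sizes used by the test suite

The package's automated checks run a deliberately scaled-down study: 5
note classes, about 3.5 minutes of synthetic audio per dataset (2-minute
training subsets, roughly one-minute validation folds) at 30 dB SNR, a
reduced hyper-parameter search (learning rates {0.005, 0.02}, one seed
each, 4 probe iterations, evaluation every 8 iterations with patience 2,
2-second mini-batches, at most 64 iterations per member — 40 for the
purely qualitative ordering checks), fast-mode (stride-8) validation
scoring, and a near-zero-gap variant (`p_zero_gap = 0.4`, shorter
training budget) for the arrangement comparison. The training-direction
check uses a paired learning-curve design: per seed, the one-minute
training subset is a prefix of the two-minute subset (same random
selection order) and both fits share an initialization seed, so the
comparison isolates the effect of data volume on single validation folds
across three seeds. With these sizes the full `LC_BDGS` pipeline reaches
a pooled note ER of 1-2% on the standard dataset. The full-protocol
defaults of `train_config()` (8 learning rates × 4 seeds, 32 probe
iterations, 32-second batches, evaluations every 50 iterations with
patience 5) remain the documented configuration for real use.

# Known limitations

* The sub-state decoder assumes every note passes through all three
  sub-divisions, imposing a 3-frame minimum note duration.
* The interval decoder trusts the boundary detector entirely; notes merged
  by thresholding cannot be split downstream (by design of that
  arrangement).
* Priors for the Bayes conversion come from training-fold frame
  frequencies; with very little training data they are noisy, which is why
  the conversion is switchable and selected on held-out data.
* The generator's noise is white and stationary; robustness to coloured or
  nonstationary noise is untested here.
* Audio I/O is mono PCM 16/24-bit WAV; other rates are accepted only via
  integer rescaling of `hop`/`fft_size` in `spectrogram_params()`.
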