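---
title: "Staging the AD spectrum from short task-based EEG: models and methods"
author: "adspectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging the AD spectrum from short task-based EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The Alzheimer's disease spectrum runs from subjective cognitive decline
(SCD, self-reported decline with normal test performance) through mild
cognitive impairment (MCI) to Alzheimer's dementia (AD). `adspectrum`
implements a complete, testable pipeline for staging this spectrum from two
short EEG protocols per participant: one minute of eyes-closed rest, and
roughly three minutes of a Simple Question Task (SQT) — ten auditory yes/no
questions about everyday knowledge, each under 2.2 s of audio, answered by
an O/X button press within 10 s. The classification target is the
participant's clinical group; the classifiers consume raw 1.5 s epochs
(768 samples x 19 channels at 512 Hz), not hand-crafted features.

Because the clinical recordings this design comes from are private, the
package ships a first-class synthetic cohort generator whose group-level
structure is part of the package's own ground truth. Every downstream
stage (preprocessing, the two deep classifiers, the shallow baseline, the
subject-wise evaluation, the behavioral statistics) is exercised end to end
against that generator.

## The synthetic cohort generator

Each subject's background EEG is a sum of independent broadband sources
with one-sided power spectral density

S(f) = A f^(-chi) + sum_b P_b N(f; mu_b, sigma_b),

an aperiodic 1/f component plus Gaussian-shaped oscillatory bumps for
delta, theta, alpha, beta and gamma. Sources are synthesized exactly in
the frequency domain (complex-Gaussian coefficients with variance
proportional to S(f)), mixed into channels by a fixed random matrix with
unit-norm rows — so every channel carries the subject's spectrum while the
channel covariance is non-diagonal — and topped with 2 uV white sensor
noise. Task recordings add a biphasic evoked deflection time-locked to each
question's audio offset, with a centro-parietal topography.

The groups differ by progressive spectral slowing, the generator's own
design decision (the field's canonical AD EEG signature): individual alpha
peak 10.5 / 9.5 / 8.5 Hz for SCD / MCI / AD, theta relative power rising
(0.15 / 0.22 / 0.30) while alpha falls (0.45 / 0.35 / 0.25), aperiodic
exponent steepening (1.0 / 1.2 / 1.4), and a smaller, later evoked
deflection (6 / 4.5 / 3 uV at 300 / 360 / 420 ms). Between-subject
variability is multiplicative (log-normal, mean-preserving) for positive
parameters and additive Gaussian for locations. The absolute power budget
(200 uV^2 oscillatory + 100 uV^2 aperiodic over 2–45 Hz) is a realistic
resting scalp EEG magnitude.

A single scalar `effectSize` rescales all between-group differences about
the grand mean: 0 gives three identical group distributions (used for null
calibration), 1 the defaults, 3 a "high-separability" cohort used for
parameter-recovery checks. This dial is part of the study conditions and
is never tuned per test.

Task timing is: 3 s lead-in, then per trial 2 s Ready screen, the
question audio (Table of listening times shipped in `inst/extdata/`), a
10 s response window, and a 2 s inter-trial interval — about 2.8 minutes
in total, matching the "approximately 3 minutes" of task EEG the protocol
targets. The protocol leaves the Ready and inter-trial durations open;
2 s each is our choice.

### Behavioral model

Per-subject accuracy is drawn from a Beta distribution moment-matched to
the group's accuracy mean and SD (90.0% (0.13) / 73.5% (0.216) / 64.0%
(0.237)); a truncated normal would bias the group mean at the boundary.
Reaction times are log-normal. Two observable-calibration corrections
matter:

* The recorded RTs are those inside the 10 s window, so the log-normal
  parameters are numerically moment-matched to the *conditional* (in-window)
  mean and SD rather than the raw ones.
* A 10-trial sample SD of a skewed distribution underestimates the
  generative SD by 3–30% depending on the coefficient of variation; the
  generative within-subject SD is inflated by a simulation-derived bias
  curve so the *observable* mean stdRT is calibrated.

Trial correctness is Bernoulli with the subject's accuracy parameter,
drawn first; correct trials always respond in-window, while incorrect
trials draw from the unconditional RT distribution and become non-responses
(scored incorrect, no RT) when the draw exceeds the window. This keeps
scored accuracy exactly calibrated while preserving the rule that a
non-response is an over-window RT. RT clock zero is the question audio
offset.

What the generator does *not* emulate: biophysical head geometry, real ERP
component families, non-stationarity within a recording, and artifact
classes beyond blinks and line noise. Passing tests therefore demonstrate
that the pipeline recovers the structure this model encodes — not clinical
performance on real recordings, which are not available.

## Preprocessing

Fixed order: decimate to 512 Hz (anti-aliased), 2–100 Hz band-pass, 60 Hz
notch, common average reference, optional ICA artifact removal, selection
of the canonical 19-channel montage, epoching. Filters are zero-phase
(forward–backward) so epoch timing is not shifted; the band-pass is a
4th-order Butterworth and the notch a biquad with Q = 30 — the filter
family and order are standard EEG practice, chosen here because the
protocol text does not pin them down.

ICA is a symmetric fixed-point decomposition (tanh contrast) on the
PCA-whitened signal with a fixed seed; whitening drops near-zero variance
directions, which also handles the rank deficiency introduced by average
referencing. Components are flagged automatically when their time course
correlates (|r| >= 0.8) with a blink template (the 5 Hz-low-passed Fp1/Fp2
average) or when more than half their power sits inside 58–62 Hz. ICA runs
before channel selection, on all available channels, and the whole stage is
optional — the synthetic CI profile disables it.

Task epochs are the half-open 1.5 s window ending at the question audio
offset, `[offset - 768, offset)` in 0-based samples; trials are epoched
regardless of behavioral correctness. Rest epochs are ten contiguous
non-overlapping 1.5 s cuts of the central 15 s of the rest recording — the
minimal span yielding ten trials, since "the middle portion" is otherwise
unquantified.

## The classifiers

No deep-learning framework is available to R in this environment, and the
two sequence models are the package's scientific core, so both are
implemented natively (RcppArmadillo): exact forward passes, exact
backpropagation (verified against finite differences in the test suite),
Adam, minibatching, inverted dropout.

**Attention-LSTM.** LSTM(128, full sequence) -> dropout 0.9 -> LSTM(64,
full sequence) -> dropout 0.8 -> additive temporal attention -> dense
softmax. The attention head scores each time step as
`e_t = v . tanh(W h_t + b)` with a 10-unit projection, softmax-normalises
the scores and returns the weighted sum of hidden states as the context
vector. We attach attention to the second LSTM's sequence (the layer
shapes force a single sequence), and we read "10 units" as the width of
the tanh projection — the additive-attention reading consistent with the
context-vector formulation. The dropout rates 0.9/0.8 are kept as stated
defaults even though they are unusually high; they apply to the output
sequences, not the recurrent state, and are config-overridable. Inputs are
standardized per trial and channel (z-scoring) before the network; raw
microvolt scales would otherwise dwarf the tanh nonlinearities.

**Convolution–transformer encoder.** Stage 1 is a factorized
spatio-temporal convolution: 40 shared temporal kernels of length 25
(same-padded) followed by spatial filters spanning all 19 channels —
algebraically fused into one 19 x 25 kernel per filter at run time — then
ELU, average pooling over time (length 75, stride 15, giving
floor((768 - 75)/15) + 1 = 47 tokens), dropout 0.5 and a linear projection
to a 40-dimensional embedding. Stage 2 stacks 6 pre-norm transformer
blocks with 10 heads and a 160-unit feed-forward sublayer; stage 3
flattens the tokens through 256- and 32-unit ELU layers (dropout 0.5/0.3)
to the softmax. Hyperparameters follow the cited architecture's published
defaults with the channel count adapted; pre-norm (rather than post-norm)
blocks were chosen for optimisation stability at these small batch counts.

**Shallow baseline.** Trials are flattened to 14592-vectors, centred,
projected onto the smallest number of principal components reaching 95%
explained variance (capped at the data rank), and classified by an RBF
SVM with default regularisation and no class weighting. The baseline is
deliberately untuned.

**Augmentation.** Segmentation-and-recombination: each synthetic trial of
class c concatenates, for each of 8 equal time segments, that segment from
a randomly chosen same-class trial; the number of augmented trials is
capped at 20% of the training set, and augmented trials are flagged so
they can never enter validation or test sets (asserted in the harness).

## Training and evaluation

Splits are subject-wise throughout: per group, round-half-up(20%) of
subjects (at least one) go to the test set — reproducing 4/6/2 test
subjects at the study's 20/28/10 group sizes — and the remaining subjects
are partitioned into 5 subject-wise folds. Validation folds are subject
level because trial-wise folds would leak subject identity, the very
problem subject-wise splitting exists to avoid.

Training minimises class-weighted categorical cross-entropy (balanced
weights N/(K n_c)) with Adam at learning rate 0.001, batch 64
(attention-LSTM) or 100 (conformer), up to 1000 epochs with early stopping:
patience 10 on validation loss, minimum improvement 0, best-epoch weights
restored. Validation loss is unweighted, mirroring the convention that
class weights shape the training objective only. Gradients are clipped to
a global L2 norm of 1 by default — without it the transformer's first
epochs can explode (loss spikes an order of magnitude) and early stopping
then restores a barely-trained model. The conformer additionally
halves its learning rate after 5 non-improving epochs (floor 1e-5). The
best fold model is chosen by validation accuracy, ties broken by validation
loss.

Metrics: the confusion matrix; accuracy, and precision/recall/F1 from
per-class one-vs-rest counts averaged with class-support weights; per-class
one-vs-rest ROC curves integrated by the trapezoid rule (identical to
Mann–Whitney pair counting, ties half-weighted). Participant-level calls
take the class predicted for more than 50% of a subject's 10 trials; an
exact 50/50 split is *indeterminate* — no call, scored incorrect — because
the protocol's own tie case reports both classes without resolving them.

## Behavioral statistics

Per subject: accuracy over all 10 trials (non-responses are errors), mean
RT and stdRT over responded trials only. Group comparison: Shapiro–Wilk
per group as a normality gate, Kruskal–Wallis omnibus (tie-corrected,
chi-square reference), then Dunn-type pooled-rank z tests with Bonferroni
adjustment over the three pairs — the default post hoc pairing with
Kruskal–Wallis in mainstream statistical software, chosen because the
analysis plan names only "post hoc pairwise comparisons". The omnibus and
normality tests delegate to base R (`kruskal.test`, `shapiro.test`); the
Dunn test is implemented here because no installed package provides it.

## Numerical and design notes

* All randomness flows through explicit integer seeds; recordings,
  behavior, splits, dropout and initialisation are bit-reproducible given
  the seed. Generated seeds stay below 2^31.
* Degenerate inputs: all-identical values give H = 0, p = 1 (flagged);
  constant groups are flagged by the normality gate; a rank-deficient
  recording aborts ICA with a channel-check diagnostic; classes with fewer
  than two trials skip augmentation with a warning.
* The epoch window convention (half-open, 0-based event samples) is
  defined once and asserted in tests; epoching never crosses trial
  boundaries.
* Fold-count, plateau and tie-break choices are documented above where the
  underlying protocol leaves them open.

## Problem sizes used by the test suite

The full study geometry (64 channels at 2048 Hz, 20/28/10 subjects,
1000-epoch budgets) is supported and exercised piecewise; the end-to-end
suites run a reduced profile chosen as the smallest cohort that still
exposes the pipeline's behaviour: 6 subjects per group, 19 channels
generated directly at 512 Hz, ICA off, epoch budgets of 12–25 with
patience 10, and a single validation fold for the recovery checks.
Parameter recovery uses `effectSize = 3`; null calibration uses
`effectSize = 0` and compares test accuracy to a trial-level binomial 95%
band around chance — approximate, since within-subject correlation makes
trials non-independent; with the small test sets this band is read as a
coarse sanity gate, not an exact size guarantee. Behavioral calibration
uses 500 subjects per group against the generator's group targets, with a
3-standard-error tolerance.

## Known limitations

* The generator's group structure is stylised; no claim transfers to real
  recordings, which this package has no access to.
* The ICA flagging rules are template-driven and tuned to the generator's
  two artifact classes (blinks, line noise).
* The shallow baseline is intentionally untuned and serves as a contrast,
  not a competitive method.
* Attention weights are exposed (`attentionWeights`) but no saliency or
  neurophysiological interpretation is attempted.
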