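---
title: "Isolating phonological wordform representations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating phonological wordform representations: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Spoken words activate two kinds of sound-pattern information that are hard
to pull apart: *segmental* structure (which phonemes occurred, in which
positions) and *lexical wordform* structure (the stored pattern that
identifies a particular word and mediates between sound and meaning). Both
are carried by overlapping populations in temporal cortex, and any
classifier trained to tell two spoken words apart can exploit either.

The experimental logic implemented here isolates wordform structure with a
*transfer* design built on phonological neighborhoods. Six consonant-
vowel-consonant (CVC) hub words each define a neighborhood of six
neighbors — three words and three nonwords — obtained by changing exactly
one phoneme, with the changed position (onset, vowel, coda)
counterbalanced within each lexicality. A linear classifier is trained to
discriminate *neighbors* of two hubs and then tested on the *hubs
themselves*, which it has never seen. Early in the epoch, transfer can
succeed through shared segments (a neighbor that shares the hub's initial
CV supports decoding while that material is being heard). After stimulus
offset, sustained transfer that occurs only when training items are real
words is the signature of a shared lexical wordform representation:
nonword neighbors have the same amount of segmental overlap but no stored
wordform.

A second stage asks whether regions whose activity supports such decoding
also *influence* decoding elsewhere — the functional criterion for calling
a pattern a representation. This is a decoding-informed Granger analysis:
can a source region's activity patterns improve one-step prediction of
another region's decoding-accuracy time course, beyond every other
region's activity?

The package implements the full pipeline — experimental design, synthetic
source-space data generation, preprocessing, per-timepoint transfer
decoding, cluster-based sign-flip permutation inference, and adaptive-MVAR
Granger analysis — so that every stage can be exercised and calibrated
against known ground truth without any recordings.

## The experimental design

`design_config()` encodes the study constants: 20 subjects, 8 virtual
talkers each owning two non-consecutive blocks (16 blocks), every hub
presented twice and every neighbor once per block (48 trials), stimuli
normalized to 350 ms, epochs of −100 to 1000 ms at 1 kHz, 39 cortical
ROIs split into 8 subdivisions whose averaged source time courses are the
decoding features. `make_schedule()` enforces the pseudo-randomization
constraint that a hub's second presentation never directly follows its
first, by reshuffle-and-check with a 1000-retry cap — at 48 trials per
block the constraint is loose, so exhaustion signals a degenerate
configuration rather than bad luck. Talker-to-block assignment uses the
same rejection-sampling idiom; any non-adjacent placement is accepted.

Phoneme content is deliberately abstract. Only the overlap *structure*
(lexicality, changed position, neighborhood membership) matters to any
downstream stage, so items carry generated labels with the six hub word
names attached for readability. Vowel-proximity constraints on real
stimuli are represented only through the overlap classes.

## The generative model behind the synthetic data

The synthetic module emulates ROI-subdivision source time courses at the
level the analyses consume; it makes no attempt at sensor physics, forward
models, or source-reconstruction crosstalk. Signals are additive on
Gaussian background noise (`noise_sd`, default 1; optional AR(1)
temporal correlation for stress-testing):

* **Segmental patterns.** Each neighborhood owns three unit-norm
  phoneme-slot patterns (onset, vowel, coda) per ROI. During the
  segmental window an item expresses the slot patterns it shares with its
  hub plus an item-specific vector for its changed phoneme, scaled by
  `segmental_amp`. This is what makes CV-overlap transfer work during the
  stimulus and guarantees that *all* conditions can decode early.
* **Lexical patterns.** Each neighborhood owns one unit-norm wordform
  pattern per ROI, expressed during the lexical window by the hub and its
  *word* neighbors only. Nonword neighbors never carry it — the
  generative counterpart of "nonwords have no stored wordform".
* **Subject variability.** All pattern vectors are rotated per subject by
  a Cayley-transform rotation with skew scale `subject_jitter_sd`
  (default 0.1): patterns stay unit-norm but become subject-specific,
  matching the within-subject decoding design.
* **Talkers.** Each virtual talker contributes a small additive offset
  (SD 0.1) to every item of its blocks during the stimulus window —
  nuisance spectral variability that pseudo-trial averaging should wash
  out.
* **Amplitude envelopes.** Window amplitudes are modulated by a smooth,
  subject-specific random envelope (`amp_jitter_sd`, default 0.5;
  smoothing 30 ms). This gives decoding accuracy trial-independent,
  subject-specific temporal structure — the substrate on which directed
  coupling acts.
* **Coupling.** Directed edges add a lag-shifted, gain-scaled copy of the
  source ROI's lexical amplitude envelope into the target ROI's envelope.
  Injection at the latent-amplitude level (not channel mixing) creates a
  ground-truth directed influence that the connectivity stage should
  recover without making decoding trivially cross-regional.

Time is sampled on the closed interval [−100, 1000] ms — 1101 samples at
1 kHz with onset at index 101 — and that convention is used everywhere.
Behavioral errors are marked per trial at lexicality-specific rates
(defaults 8% for words, 14% for nonwords, matching typical lexical-
decision asymmetry); only correct trials enter averaging and decoding.

What the generator does *not* emulate matters for interpreting green
tests: there is no source-leakage/crosstalk between ROIs, no 1/f or
oscillatory background, no latency jitter across trials, and patterns are
orthogonal-on-average random vectors rather than structured topographies.
Passing calibration and recovery tests therefore shows the *inference
machinery* is correct and calibrated under its own assumptions, not that
real MEG/EEG data meet those assumptions.

## Preprocessing

Baseline correction subtracts each epoch's per-channel mean over the
100-ms pre-stimulus period. Vector normalization scales, for every epoch
and timepoint, the 8-subdivision vector to unit Euclidean norm — by
default **within each ROI**, so each ROI's evidence is purely
pattern-directional. (Normalizing across all ROIs jointly is available via
`scope = "global"`; within-ROI is the default because decoding is per-ROI
on its own 8 features.) Exact zero vectors are left at zero. State flags
guard both operations against double application.

Pseudo-trials are formed by averaging random disjoint bins of 8 correct
trials within each condition; the random binning is repeated (100
assignments at full scale) and accuracy is averaged over assignments.
Leftover trials are dropped at random per assignment rather than forming a
short bin, keeping bin SNR homogeneous. Binning applies to both training
(neighbor) and test (hub) groups.

## Transfer decoding

The classifier is a linear soft-margin SVM with C = 1 and no feature
scaling beyond the pipeline's normalization. The inner loop — one fit per
timepoint, bin assignment, neighborhood pair, ROI, subject and condition —
is a compact SMO solver written in C++ for throughput (microseconds per
fit on ≤16-point problems); its weight vectors are verified against
libsvm (via e1071) in the test suite. Decision ties are broken toward the
first neighborhood of the pair, deterministically. Features are the 8
subdivision values at a single timepoint.

For a pair of neighborhoods the classifier trains on the neighbor bins
selected by the training condition (`words_only`, `nonwords_only`,
`cv_overlap`, `vc_overlap`) and is tested on the two hubs' bins; hub
trials never appear in training, and this is asserted on every call.
Accuracy is averaged over bin assignments, then over all 15 unordered
neighborhood pairs; chance is 0.5.

## Cluster-based sign-flip permutation inference

Group-level inference treats each ROI's subjects × timepoints accuracy
matrix with a one-sample, one-tailed t test against chance at each
timepoint (α = 0.05); clusters are maximal runs of consecutive
significant timepoints and the cluster statistic is run length. The null
flips each subject's deviation from chance by an independent random sign,
recomputes masks and clusters, and records the maximum cluster size per
permutation (1000 at full scale). Cluster p-values use the permutation
convention (k + 1)/(n + 1). Bonferroni control across the 39-ROI family
sets the significance cutoff at 0.05/39 ≈ 0.00128.

The between-condition test adds the dual constraint: a timepoint joins a
cluster favoring condition A only if A is above chance (one-tailed,
uncorrected α = 0.05) *and* the paired A−B difference is significant
(two-tailed, uncorrected α = 0.05) in A's favor. The permutation null
flips, per subject, the relationship of the data to both null values —
one Rademacher sign on the mean deviation from chance and an independent
one on the condition difference (a joint-flip variant is available), with
the maximum cluster over both directions recorded per permutation.

One property of sign-flip cluster tests is worth knowing when working
with synthetic data: when every subject carries a very strong, sustained
effect (per-subject SNR ≫ 1), flip patterns that negate only a few
subjects still leave the whole window significant, so the null max-size
distribution acquires a heavy tail and cluster p-values floor at a few
percent regardless of how obvious the effect is. The recovery simulations
therefore inject moderate amplitudes that put per-subject accuracy in the
classical regime, and cluster-extent checks use overlap semantics
(cluster boundaries are not pointwise-exact).

## Decoding-informed Granger causality

The connectivity stage asks, for each ordered pair of candidate
(decoding) ROIs, whether the source ROI's 8 subdivision event-related
time courses improve one-step prediction of the target ROI's decoding
accuracy time course (word-neighbor training, averaged over pairwise
contrasts) beyond all other ROIs' activity and the target's own past.

Signals are restricted to the analysis window (default 250–550 ms, the
lexical-processing window associated with the N400) plus a leading
adaptation segment, optionally decimated, ensemble-demeaned (the
cross-subject mean is removed so prediction operates on induced,
subject-specific fluctuations — the evoked component is shared between
regions and carries no directional information), and z-scored on the
window statistics. Predictor ROIs other than the tested source are
compressed to their first principal component by default, keeping the
model well-posed while honoring the contract that every ROI participates
in the predictive model; the tested source always contributes all 8
subdivision channels.

The one-step predictor is an adaptive MVAR estimated by a Kalman filter
with random-walk coefficients: state inflation `P ← (1+c)P`, adaptively
tracked observation noise, and a scalar adaptation constant `c` (default
0.02, i.e. a memory of ~50 samples). The GC index is
`ln(reduced / full)` smoothed squared one-step prediction error, floored
at zero; the error smoothing constant is separate from `c` so the index's
temporal resolution is not tied to coefficient forgetting. Model order
defaults to 5 lags on 4×-decimated (250 Hz) signals — about 20 ms of
history; at other sampling rates the order should be scaled to keep that
history (the coupling simulations use order 2 at 100 Hz).

Per-timepoint significance is calibrated against surrogate ensembles.
Three schemes are implemented:

* `donor_shift` (default): each target is re-paired with *another
  subject's* source channels, additionally rotated by a random circular
  shift. Re-pairing preserves every within-signal property — including
  the evoked variance profile and its alignment to stimulus onset — while
  destroying the subject-level dependence that carries genuine directed
  influence; the extra shift makes the surrogate pool effectively
  continuous, so ensemble quantiles are not deflated by the small number
  of subject pairings.
* `subject_shuffle`: re-pairing only.
* `circular_shift`: within-subject rotation only. This is exactly
  calibrated for stationary signals (and is used that way in the tests)
  but anticonservative when time-locked variance sits inside the analysis
  segment, which is why it is not the default for evoked data.

Thresholding uses the *unfloored* log ratio on both sides (flooring the
surrogates first would let any positive observed value beat a null that
is mostly negative). The strength of a connection is the count of
significant timepoints in the window, compared against a control pair of
ROIs with no decoding and no plausible processing relationship by an
exact one-tailed binomial test. Because the control pair contributes only
2 × window-length timepoints, its raw rate is shrunk toward the nominal
per-timepoint level with one pseudo-window of weight and floored at
1/window-length. Binomial p-values over the k(k−1) candidate directed
pairs are Benjamini–Hochberg corrected at q = 0.05; a pair is
*reciprocal* if both directions survive.

Two generative conditions are required for the coupling simulations to
have a one-way answer at all: the envelope's temporal memory must be
shorter than the coupling lag (otherwise the lagged copy of the source
envelope inside the target's channels predicts the source's own future —
a genuine, but unintended, reverse channel), and amplitudes must not
saturate accuracy at 1.0 (a saturated accuracy curve carries no envelope
information). The packaged coupling demonstration uses a 20-ms lag, gain
0.8, envelope memory 10 ms, and lexical amplitude 0.5.

## Desk-scale problem sizes

The full printed design (20 subjects, 39 ROIs, 1 kHz, 100 bin
assignments, 1000 permutations) is what `design_config()` encodes, but
simulation studies in the tests and the acceptance script run at reduced,
fixed sizes chosen once:

* **Null calibration** (chance convergence and family-wise error): 200
  zero-signal datasets, 8 subjects, 5 ROIs, 40 Hz, 3 bin assignments,
  200 permutations.
* **Recovery**: 10 subjects, 2 ROIs, 50 Hz, 5 assignments; lexical
  amplitude 0.8 in a 400–600 ms window, segmental amplitude 1.0 in the
  stimulus window.
* **Coupling**: 10 subjects, 5 ROIs, 100 Hz, 15 assignments, 150
  surrogates, candidates on 3 ROIs with one injected edge and a
  designated control pair on the remaining 2.

Sign-flip inference needs ≥ 10 subjects before its discrete null can beat
a Bonferroni-adjusted threshold comfortably (with 8 subjects the
minimum attainable two-sided mass is 9/256 ≈ 3.5%), which is why the
recovery runs use 10.

## Numerical choices and degenerate inputs

Zero subdivision vectors normalize to zero, not NaN. Accuracy arrays are
bounded in [0, 1] by construction. Permutation p-values are never zero
(k+1)/(n+1). The SMO solver uses a 1e−8 KKT gap tolerance with a 10,000
iteration cap and deterministic maximal-violating-pair selection; its
bias is the KKT-gap midpoint. The Kalman filter symmetrizes its
covariance each step and starts from a diffuse prior (P₀ = 10·I). All
randomness in every stage derives from explicit integer seeds through a
deterministic splitting function, so every result in this document and in
the test suite is exactly reproducible.

## Known limitations

Per-timepoint GC exceedance under the donor-based surrogates is mildly
inflated relative to the nominal alpha on evoked (nonstationary) data;
the design absorbs this by comparing candidate pairs against a control
pair measured with the identical machinery — the same reason the original
design carries a control pair. The binomial count test treats window
timepoints as independent, which is optimistic under error-smoothing;
the error-smoothing constant and the control-rate shrinkage keep this
manageable at the packaged problem sizes, but very long windows with
heavy smoothing would need a count-level permutation instead. Finally,
cluster extents are not pointwise-exact boundaries, and the synthetic
generator's idealizations (no crosstalk, white or AR(1) noise, random
patterns) mean calibration results transfer to real recordings only to
the extent those assumptions hold.
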