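---
title: "Evolving interpretable hyper-features for EEG seizure prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving interpretable hyper-features for EEG seizure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(evoseize)
```

## The problem

Seizure prediction aims to raise an alarm before a seizure starts, early
enough for an intervention (the seizure prediction horizon, SPH) and
precise enough that the seizure occurs within a bounded window after the
alarm (the seizure occurrence period, SOP). The pre-ictal period — the
transitional stretch of brain activity preceding a seizure — is not
clinically annotated, varies across and within patients, and has no known
universal signature. `evoseize` implements a patient-specific strategy:
instead of fixing a pre-ictal duration and a feature set a priori, a
genetic algorithm (GA) searches jointly over *which* EEG features, *where*
(electrode), *how aggregated* (operator and window), and *when* (offset on
a pre-seizure timeline), scoring every candidate by the performance of the
complete prediction pipeline. Because the deployed model is a logistic
regression over five interpretable features, the result can be audited by
a clinician rather than trusted blindly.

## From EEG to hyper-features

Scalp EEG (19 electrodes in the 10–20 placement, 256 Hz) is notch-filtered
at 50 Hz and band-passed to 0.1–120 Hz, then cut into non-overlapping 5-s
windows. Twelve *first-level features* are computed per window and
electrode: relative spectral power in delta (0.5–3.5 Hz), theta
(4–7.5 Hz), alpha (8–12 Hz), beta (13–35 Hz) and three gamma sub-bands
(36–50, 51–70, 71–90 Hz); average power; mean normalized frequency (the
spectral centroid); and the normalized mean amplitude, mean amplitude and
amplitude variance.

A *hyper-feature* is a second-level feature: one first-level feature from
one electrode, aggregated by a mathematical operator (mean, median,
variance, max or min) over a window of `w` minutes placed `t` minutes
before a reference time. An individual of the GA is a set of five
hyper-features, each encoded by seven genes: a dominant-feature flag
selecting whether the band-wave or the non-band-wave feature gene is
expressed, the two feature genes, operator, electrode, window length and
time instant. Decoding places the five hyper-features chronologically; the
pre-ictal duration is the configured minimum (40, 50 or 60 min) plus the
largest time instant, and SOP = pre-ictal − SPH with SPH fixed at 10 min.

## The fitness pipeline

For each candidate, hyper-feature series are built on a 1-min grid over
each 4-h pre-seizure training segment, lagged copies at 1–3 min are added
(20 columns), columns with absolute Pearson correlation above 0.95 against
an already-retained column are dropped, and the rest are z-scored with
training statistics. A logistic regression is fitted with class weights
inverse to class frequency (`w_c = N/(2 N_c)`). Its binary outputs
(p > 0.5) are regularized by the *Firing Power* — the trailing moving
average over a window equal to the pre-ictal duration — and an alarm fires
at upward crossings of 0.70. A tested seizure is scored by

\[
\mathrm{performance} = \frac{S_s + S_p}{2} - \mathrm{FPR/h}\,(1 + T_f),
\]

where \(S_s\) is the fraction of pre-ictal samples classified pre-ictal,
\(T_f\) the fraction of inter-ictal samples classified pre-ictal, \(S_p\)
is 1 iff an alarm falls inside `[onset − pre-ictal, onset − SPH)`, and
FPR/h counts false alarms per inter-ictal hour. Fitness evaluates
iteratively: train on seizures 1..j−1, score seizure j, average over j.
Prospective testing uses the same pipeline on the held-out continuous
record plus an SOP+SPH refractory period after each alarm; refractory time
is removed from the FPR/h denominator.

Design points the method leaves open, resolved here and configurable:
sample-level rates (\(S_s\), \(T_f\)) use raw classifier decisions while
alarm-level quantities (\(S_p\), FPR/h) use the Firing Power, matching
their definitions as sample ratios versus alarm properties; rows within
the SPH are excluded from both classes, as is a 30-min post-ictal guard;
the Firing Power emits partial means during warm-up so continuous records
are scored from the first sample; an individual whose model cannot be
fitted receives the sentinel fitness −10.

## The genetic algorithm

Population 100, initialized uniformly at random. Each generation, 50
parents are chosen by binary tournament (with replacement); 50 offspring
are produced, each by two-parent recombination with probability 0.80
(otherwise a copy of one selected parent), and every offspring then
mutates (rate 1.00) by a *unitary step*: one gene of one hyper-feature
moves to a neighbour in that gene's neighbourhood graph. Survivors are the
best 100 of the 150 parents plus offspring ((1+λ) elitist replacement), so
best fitness never decreases. Evolution stops at maximum fitness, after 50
generations without improvement, or at 15 000 evaluations; 30 independent
executions are run per patient and minimum pre-ictal period.

Neighbourhood graphs: ordinal genes (window length, time instant) and the
ordered categorical genes (bands in frequency order, non-band features,
operators) are chains; the electrode gene uses the spatial adjacency of
the 10–20 montage; the dominant flag is a two-node graph. Recombination
pairs the parents' hyper-features by time-instant rank (ties by electrode
order) and draws each offspring gene uniformly from the nodes on the
shortest paths between the two parent values, endpoints included.
Replacement ties are broken towards offspring so that equal-fitness
mutants can drift along fitness plateaus instead of freezing on them;
previously seen genotypes are served from a cache and only fresh
evaluations consume the budget. These choices — tournament sampling with
replacement, λ = 50, the clone fallback when recombination does not fire,
per-execution seeds derived as master + index — fill gaps the method
description leaves open, and all are configurable.

## Statistical validation

A surrogate predictor estimates chance level: keeping the alarm train
fixed, seizure onset times are shifted uniformly at random within the
record (each shifted pre-ictal window must fit inside it; overlapping
draws are resampled, 30 repetitions by default) and the surrogate
sensitivity is re-scored. An execution is *above chance* when a one-tailed
Welch t-test rejects at α = 0.01 and the real mean exceeds the surrogate
mean; when both groups are degenerate (zero variance) the test falls back
to an exact comparison of means. Across the 30 executions, the count of
above-chance executions is itself tested against a binomial null,

\[
P_{\mathrm{binom}}(i, I, \alpha) = \sum_{j=i}^{I} \binom{I}{j}
\alpha^j (1-\alpha)^{I-j},
\]

with α = 0.05, declaring the patient validated when the tail probability
is below 0.05.

## The phenotype study

Each execution's best individual is inspected for *presence* (a binary
indicator per gene value per hyper-feature, dominance-masked, normalized
to sum to 1 per dimension) and *predictive power*: a hyper-feature's
weight is the mean absolute logistic coefficient over its retained lagged
columns (configurable to the sum), and a gene value scores the summed
weight of the hyper-features carrying it, again normalized. Values roll up
from electrodes to lobes and hemispheres via a standard editable 10–20
table, and co-occurrence histograms count distinct window lengths, time
instants and lobes per individual. Coefficients come from the deployed
model — the one retrained on all training seizures.

## Synthetic patients and what they do (not) show

Real annotated long-term scalp EEG is access-restricted, so the package
ships a generator whose output exercises every stage with known ground
truth. Per channel the background is \(1/f^\gamma\) noise (γ = 1 by
default, scaled to 30 µV RMS) plus a 10 Hz oscillation (10 µV) and an
independent band-limited noise component (8 µV RMS, 4th-order Butterworth
shape) in the signature band. On signature electrodes the band component's
amplitude is ramped linearly from 1× to `effect_size`× across the planted
window. Ictal activity is only a flagged 60-s placeholder burst; the
method never consumes ictal samples. Training segments are the 4 h
preceding each training seizure (onset at the segment end); the test
record is continuous with a 2-h lead-in, 2-h inter-seizure gaps and a
30-min tail — sizes chosen so a full synthetic patient (3 training plus 2
testing seizures) prepares in a few minutes on one core. Noise is
synthesized spectrally (the Gaussian spectrum is drawn directly and
inverse-transformed, two real channels per complex FFT), and filtering
applies the combined squared magnitude response of the notch and band-pass
in the frequency domain with reflection padding — numerically equivalent
to a forward-backward IIR pass away from the record edges. The band-pass
is a 10th-order Butterworth: with the gentler default order the
second-pass attenuation near the band edges would change the RMS of
already-filtered noise by more than the 1% the package treats as its
idempotence tolerance.

The drift begins 60 min before onset by default, deliberately *before*
the earliest labelled pre-ictal boundary (40 min): the Firing Power needs
roughly 0.7 × pre-ictal-period minutes of pre-ictal classifications
before it can cross its threshold, so a drift confined to the labelled
window could never raise an alarm inside the SOP.

Two properties of this generator matter when reading test results. First,
a band-amplitude ramp moves *many* features at once: the signature band's
relative power rises, but the complementary bands' relative powers fall,
and the spectral centroid and amplitude summaries shift — several of these
carry the same discriminative information at equal or better
signal-to-noise ratio (wide bands are estimated with less variance than a
3.5-Hz-wide theta band). The GA therefore reliably recovers the planted
*electrodes*, but frequently expresses the planted *band* through a
complement band or the centroid rather than the theta gene itself. Second,
alarm timing on a linear ramp that peaks only at onset is intrinsically
marginal: classifiers detect the drift midway through, and the refractory
period after an early alarm can swallow the seizure, so prospective
seizure sensitivity hovers near the surrogate level even for strong
planted effects — mirroring the modest prospective sensitivities the
method reports on real data. Passing tests on this generator demonstrate
that the machinery is correct and calibrated, not that the method would
validate any particular patient. The generator does not model seizure
morphology, artifacts (blinks, EMG) or circadian structure.

## Numerical choices

* Welch PSD: 1-s Hann segments, 50% overlap, giving 1-Hz resolution on 5-s
  windows; relative powers are normalized by total power over 0.5–90 Hz
  (the union span of the analysis bands). An all-zero window yields zeros
  with a degenerate flag.
* The GA correctness benchmark used in the acceptance tests is a hidden-
  target problem graded per gene by neighbourhood-graph distance — the
  additive, monotone analogue of OneMax for graph-structured genes, with
  its optimum exactly at the hidden target. A fitness that scores only
  exact gene matches has no gradient along chain-shaped domains, and the
  deliberately greedy GA (unit-step mutation, 50-generation stagnation
  stop) cannot traverse such plateaus; the graded form is what the
  benchmark is meant to certify: selection, recombination, elitism and
  budget accounting drive the search to a known optimum.
* Problem sizes in the test-suite: the planted-signature study uses one
  synthetic patient (19 channels, 3 + 2 seizures), ten GA runs capped at
  2 000 evaluations; the null-calibration study uses 50 single-individual
  executions; unit tests run on minutes-long records and hand-built
  feature tensors.
* Surrogate shifts are uniform over onset placements whose pre-ictal
  window fits in the record; repetitions whose windows collide are
  resampled with a capped retry count.
* EDF output is 16-bit with per-channel full-range scaling; round trips
  are exact up to the per-channel quantization step.

## Known limitations

Only logistic regression is supported as the classifier, by design; there
is no artifact rejection, resampling or montage re-referencing; the
surrogate repetition count (30) and the exact recombination pairing rule
substitute for details the method description leaves unspecified, and are
configurable; synthetic data is the only bundled data source.
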