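---
title: "Decoding stimulus and choice from DMS spiking sessions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding stimulus and choice from DMS spiking sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dmsdecode` asks a single scientific question of multi-channel spiking data
recorded during a delayed match-to-sample (DMS) task: do the population
responses evoked by the test stimulus carry, besides the identity of that
stimulus, information about the animal's forthcoming choice — and if so, do
the two signals occupy separable subspaces of population activity? This
vignette documents the models, the tunable parameters, the synthetic-data
generator that makes the pipeline testable, and the numerical decisions
taken where the design was genuinely open.

## Task geometry and time base

All times are in milliseconds from fixation onset. The standard trial is
fixation 500 ms → sample 500 ms → delay 1500 ms → test ≤ 500 ms, so the
test stimulus appears at 2500 ms and the reaction time (RT) is measured
from that onset. The recording of a trial is taken to extend to
`2500 + max(500, rt)` ms. Response-aligned analyses shift each trial's
clock so that 0 marks the lever movement.

## The decoding model

All decoders are linear discriminant classifiers on channel firing-rate
vectors: Gaussian classes with a shared covariance, class means estimated
per class, and the pooled within-class covariance shrunk toward its
diagonal,

$$\Sigma_\lambda = (1-\lambda)\,S + \lambda\,\mathrm{diag}(S),
\qquad \lambda = 0.1 \text{ by default.}$$

Shrinkage is needed because a 20-fold split of a few hundred trials leaves
per-class sample counts close to the channel count (32); the unregularized
pooled covariance can be ill-conditioned. $\lambda = 0.1$ is a mild,
conventional choice; results are insensitive to it on well-powered
sessions. Priors default to empirical class frequencies, ties break toward
the lowest class label, and a zero-variance degenerate fit receives a
$10^{-8}$ ridge so that uninformative data fall back to the majority class
rather than erroring.

Firing rates come from **causal moving windows**: the bin labeled $t$
counts spikes in $(t-w, t]$, $w = 150$ ms, step 50 ms (10 ms for choice
decoding, where latency resolution matters). The half-open right-closed
convention means a spike exactly at the label time counts, and nothing
later than $t$ can influence the bin — a property the test suite checks
directly. Bin labels sit on the session grid (`t_range` start + k·step),
not per-trial phases.

Accuracy at each bin is the mean over 20 stratified cross-validation folds
(one 20-fold partition, not 20 repeats of an unspecified split; the
`n_repeats` argument exposes the alternative reading). Curves are
interpolated per session with natural cubic splines onto a 2 ms grid —
finer than the 5 ms the analysis requires — and only then averaged across
sessions; knot values are preserved exactly. Unless stated otherwise, only
correct trials are analyzed.

## Chance-crossing latency

The decoding latency is the first time after test onset at which the
session-averaged interpolated accuracy exceeds chance and stays above it
for a persistence window. Two numerical choices matter:

* **Persistence = 150 ms** (the causal window width) for latency
  *measurement*. Adjacent 10-ms-step bins share 140/150 of their data, so
  the accuracy curve's noise is correlated on the window timescale; a
  persistence shorter than the window cannot distinguish one noise
  excursion from a real onset. The function's default remains 50 ms for
  exploratory use.
* Latency is read off the **session-averaged** curve (as in the original
  analysis), not per session: single-session curves at realistic trial
  counts cross chance spuriously.

Because the simulator's choice signal ramps linearly over 100 ms, the
expected crossing sits near onset + half the ramp; the latency-recovery
test compares recovered crossings against that point and requires a median
error below 60 ms across injected latencies of 100–400 ms. For the 400 ms
latency the decoding grid must extend to 3150 ms so a crossing can persist
150 ms; bins beyond a trial's recorded span simply contain no spikes for
that trial.

## The correct→error transfer test

A decoder might separate match from nonmatch trials using stimulus-type
cues rather than a genuine choice signal. The cross-condition test
distinguishes the two: decoders are trained on correct trials at 2900 ms
(rate vectors from the causal 150 ms window ending there), and, inside each
cross-validation step, the same decoder predicts trial type on all error
trials. Trials with RT < 400 ms are excluded so the response has not yet
occurred at the decoded time. If the decoded quantity is the *choice* —
inverted relative to trial type on errors — transfer accuracy falls below
0.5, mirroring the correct-trial accuracy about chance; if it is the
physical match/nonmatch relation, the decoder generalizes and transfer
stays above 0.5. The simulator can produce both regimes
(`decision_signal = "choice"` vs `"trial_type"`), and the test suite checks
both signatures plus the zero-gain null.

## Subspace identification

At a reference time (default 2700 ms, 200 ms after test onset) the package
fits a 2-D stimulus subspace (discriminant projection on test-stimulus
labels; dimension = classes − 1) and a 1-D decision axis (match/nonmatch
labels) from the same correct-trial rate vectors. Columns are generalized
eigenvectors of between- vs within-class scatter, unit-norm, ordered by
eigenvalue, sign-fixed so the largest-magnitude entry is positive.

One design choice was genuinely open: what counts as "within-class noise"
for the decision fit. At any time when the test stimulus drives the
channels, stimulus-evoked variance is large and lies exactly in the
stimulus span; plain single-factor LDA treats it as noise, and its
whitening step then rotates the decision axis *away* from the stimulus span
(toward 90° regardless of the true geometry). By default the decision fit
therefore pools its within-scatter inside stimulus × decision cells
(`condition_decision_on_stimulus = TRUE`), so only genuine trial-to-trial
variability is whitened; class means, and hence the projection's target,
are unchanged. The plain fit remains available. When the decision labels
are not separable above chance at the reference time (cross-validated
accuracy < 0.55) the model warns that the decision axis may be noise —
with the default generator (choice-signal latency 150 ms + 100 ms ramp)
this is expected at 2700 ms, where the causal window barely overlaps the
ramp; 2900 ms is a better reference for the simulated conditions.

### Measuring the angle between the choice axis and the stimulus span

Even an unbiased axis estimate carries sampling noise, and in 32 dimensions
noise is almost entirely orthogonal to any low-dimensional span — so the
naive principal angle between a noisy 1-D axis and the 2-D stimulus span is
biased upward (small true angles inflate by 10–15° at 600 trials).
`debiased_axis_angle()` removes both artifacts:

* the choice contrast is computed *within* each stimulus class and
  averaged, eliminating the coherent in-span noise contributed by
  stimulus-evoked variance;
* the squared in-span and total magnitudes of the contrast are estimated
  from cross-products of two independent trial halves,
  $\langle P\hat\delta_1, P\hat\delta_2\rangle$ and
  $\langle\hat\delta_1,\hat\delta_2\rangle$, whose noise terms have zero
  expectation; the angle is $\arccos\sqrt{\text{in-span}/\text{total}}$,
  averaged over 20 random stratified half-splits.

This is the estimator used for geometry recovery: injected angles of
30/60/90° are recovered with median errors of a few degrees at 600 trials.
The quantity lives in raw rate space (no whitening), because the injected
angle is a statement about rate-space geometry.

Cluster structure in the fitted subspaces is quantified by the mean
silhouette width (`class_separation_score()`, Euclidean distance,
singleton classes scored 0): stimulus identity separates clearly in the
stimulus plane (silhouette > 0.5) while match/nonmatch conditions overlap
there (silhouette ≈ 0) — the dissociation the subspace analysis is meant to
exhibit.

## The synthetic-data generator

The generator is first-class, tested code: every downstream claim is
validated by recovering parameters it injected. Per channel and trial the
instantaneous rate is

$$r(t) = b \;+\; g_{\text{stim}}(c, s(t))\,[\text{stimulus on}] \;+\;
\pm\, a\, d_c\, \rho(t),$$

with baseline $b$, tuning gain matrix $g_{\text{stim}}$, and an additive
choice signal of amplitude $a$ along a unit population direction $d$,
signed by the choice (inverted relative to trial type on error trials),
switched on `decision_latency_ms` after test onset with a linear ramp
$\rho$ of 100 ms, and off at the response. Spikes are drawn by thinning a
homogeneous Poisson process — the simplest exact sampler for a bounded
rate. Rates are clipped at zero; configurations whose clipped mass would
exceed 1% of channel-time are rejected outright.

Default study conditions (chosen once, as plausible values for multi-unit
V1 recordings in this task):

| parameter | default | rationale |
|---|---|---|
| channels / stimuli | 32 / 3 | recording array and stimulus set size |
| baseline rate | 10 spikes/s | low-end multi-unit background |
| tuning gain | 15 spikes/s, round-robin preferred stimulus | strong but not saturating stimulus decodability |
| visual latency | 50 ms | V1 response latency |
| choice-signal amplitude | 10 spikes/s along unit $d$ | late-epoch choice accuracy ~0.8–0.9, comfortably above chance without being trivial |
| choice-signal latency / ramp | 150 / 100 ms | decodability emerging ~150–250 ms after test onset |
| decision angle | 90° | orthogonal subspaces unless specified |
| RT mean ± sd | 632 ± 174.7 ms, normal truncated at 0 | reported session statistics |
| p(match) / error rate | 0.5 / 0.22 | balanced design; ~78% behavioral accuracy |

The round-robin tuning assignment makes the pooled within-class variance
approximately homogeneous across channels, which keeps diagonal whitening
benign; the decision direction is constructed deterministically at the
requested principal angle to the span of tuning contrasts (verified exact
to < 1° by the test suite).

**What the generator does not emulate** — and what passing tests therefore
do not establish about real data: correlated noise between channels (spikes
are conditionally independent given the rate), rate adaptation and bursting,
eye-movement- or arousal-linked slow drifts, sessions with heterogeneous
channel quality, and any nonlinear mixing of stimulus and choice signals:
whether a cortical choice signal is additive, multiplicative or gain-like
is unknown, and the generator commits to the additive form (amplitude and
direction are free parameters). Recovery results bound estimator
behavior under the stated noise model, not under physiological noise.

## Problem sizes

The shipped tests run the full chain at deliberately modest scales — single
sessions of 240–600 trials, 3-session averages for latency recovery, 100
label permutations for chance calibration — sizes at which every property
under test is comfortably identifiable while the whole suite completes in a
few minutes on one core. `run_pipeline()` scales linearly in trials ×
channels × bins.

## Known limitations

* The latency estimator reports the first persistent crossing of the
  *mean* curve; it has a positive bias of roughly half the ramp time by
  construction and is undefined (NA) when decodability never persists.
* `align_to_response()` operates on event tables; response-aligned tensors
  are produced by re-binning, not by shifting an existing tensor.
* Session bundles are CSV/JSON only; tensors and trajectories are written
  as flat CSV. No NWB/TDT readers.
* The cross-condition test assumes enough error trials survive the RT
  exclusion (it errors otherwise, naming the cause).
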