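---
title: "Motion-onset ERPs and vection: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-onset ERPs and vection: models, defaults, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vection)
```

## The scientific problem

Vection is the illusion of self-motion induced in a stationary observer by
large-field visual motion. A standard way to probe its cortical basis is to
contrast EEG responses to *vection-consistent* motion (a rigid, coherent
rotation of a large dot field in the roll plane) with *vection-inconsistent*
motion (the same global rotation with an independent random sinusoidal
perturbation added to every dot, matched in mean global velocity). Both
stimuli deliver near-identical low-level motion energy, but only the
coherent field supports a stable self-motion interpretation.

This package implements the full sensor-level analysis for such an
experiment: motion-onset event-related potentials (ERPs) in two
post-stimulus windows, spatial cluster-based permutation statistics for the
condition contrast and for a left- versus right-hander contrast, behavioural
vection measures from button-press streams, and Spearman brain–behaviour
correlations. Because no public recording set accompanies the design, a
synthetic-data generator with a fully specified ground truth is a
first-class component: every downstream stage is tested against effects the
generator planted.

## Stimulus kinematics

The dot field contains 1000 dots placed uniformly by area over a disc
subtending 100 degrees of visual angle (radius 50 degrees), rotating about
the line of sight at 30 deg/s, clockwise or counter-clockwise. A trial shows
the dots stationary for a uniformly jittered 3–5 s, rotating for 20 s, then
stationary for 10 s. A session has 100 trials: 50 coherent and 50
incoherent, 25 per direction each, in blocks of 10.

In the incoherent condition each dot receives an additive sinusoidal offset
in X and in Y, with phase, amplitude and frequency drawn independently per
dot and axis. The source design does not state the perturbation
distributions; the package defaults are amplitude uniform on [0.5, 3]
degrees, frequency uniform on [0.2, 1] Hz, phase uniform on [0, 2pi) — local
motion that is clearly erratic at the dot level while leaving the across-dot
mean angular velocity at the nominal 30 deg/s. These are configuration
values, not claims about the original stimulus. `mean_global_angular_speed()`
verifies velocity matching: it unwraps each dot's polar angle about
fixation, divides the net displacement by the window length, and averages
across dots (dots passing within numerical distance of fixation would have
undefined angles and are excluded with a count; with default geometry none
are). For a coherent field the result is exactly the specified angular
velocity; for incoherent fields the sinusoid truncation at the segment
boundaries leaves a residual well inside 1 deg/s at 1000 dots.

## The data model and preprocessing chain

Continuous EEG is a channels-by-samples matrix in microvolts at 1000 Hz,
with 64 scalp channels in the 10-10 layout (FCz recording reference) plus
two bipolar EOG channels, read and written in the BrainVision
`.vhdr/.vmrk/.eeg` triad (multiplexed orientation, IEEE float32 or int16
with per-channel resolution; the vectorized orientation is rejected
explicitly). Trigger codes are site-specific, so marker descriptions map to
typed events through a user-supplied code map.

The preprocessing chain follows the conventional order:

1. **Filtering** — 50 and 100 Hz notch, then 0.1 Hz high-pass and 30 Hz
   low-pass. All filters are linear-phase FIR kernels (Hamming-window
   designs, orders set from the transition widths) applied zero-phase by
   symmetric-kernel FFT convolution, so ERP peak latencies are not
   displaced. The notch is a fixed band-stop: a regression-based line-noise
   remover would also fit the stated cutoffs, but a fixed FIR notch is
   deterministic and testable against its frequency response (the 50 Hz
   attenuation is verified to exceed 30 dB, passband gain unity within 5%).
2. **Common-average re-reference** — the scalp mean is subtracted at every
   sample; EOG channels are excluded from the average and left untouched.
3. **Epoching** — one 600 ms epoch per motion-onset event, -200 to +400 ms,
   i.e. samples at -200..+399 ms.
4. **Baseline correction** — per epoch and channel, the mean over
   [-200, 0) ms is subtracted. A state flag makes double application an
   error.
5. **Artifact rejection** — each epoch is scanned by a 200 ms window moving
   in 50 ms steps (nine full windows; partial windows are not evaluated). An
   epoch is rejected if any window shows (a) a standard deviation above
   35 microvolts in the EOG pair, Fp1, Fp2 or Fz, or (b) a range above
   100 microvolts. Both thresholds are strict inequalities; the SD uses the
   unbiased n-1 denominator. The range rule's channel scope is not pinned
   down by the design; the package applies it to all scalp EEG channels
   (configurable), the conventional reading. The log records the first
   triggering window, rule and channel per epoch.
6. **Inclusion** — a participant enters the EEG analyses only with at least
   30 artifact-free epochs in each condition. The stated exclusion rule
   mentions "in two or more electrodes", which has no direct meaning for
   epoch-level rejection; the package applies the per-condition count rule
   globally and documents the ambiguity here.

Clockwise and counter-clockwise trials are collapsed within condition
before averaging. Window mean amplitudes use inclusive bounds (61 samples
for 160–220 ms, 41 for 260–300 ms); grand averages weight subjects equally
rather than pooling epochs, matching the subject-level statistics.

## Cluster-based permutation tests

Electrode-level statistics are t tests — one-sample on per-subject
coherent-minus-incoherent differences for the condition contrast, two-sample
pooled-variance on those differences for the handedness contrast. The
electrode-level test family is a design choice (only the p < 0.01 threshold
is inherited); t tests make the threshold well defined and are the standard
choice in this framework. Zero-variance electrodes get t = 0, p = 1 rather
than a division by zero.

Electrodes with p < 0.01 are partitioned into maximal spatially connected
components whose t values share a sign; a cluster's mass is the exact sum of
its member t values. Spatial adjacency comes from a Delaunay triangulation
of the montage's 2D azimuthal-equidistant projection with edges longer than
1.5 times the median edge length pruned (long rim edges are not
physiological neighbours); a fixed-radius method is available and is the
automatic fallback for degenerate layouts. On the shipped 64-channel montage
the graph is connected with a median of 5 neighbours per electrode.

The null distribution of the maximum absolute cluster mass is built from
1000 permutations (per-subject sign flips for the paired design, group-label
permutations for the independent design). The decision rule compares the
observed largest mass against the 99th percentile of that null; the
permutation p value uses the +1/+1 correction and the observed statistic is
not included among the permutations. When fewer than 100 distinct
permutations exist the test warns and enumerates the space exhaustively;
exact enumeration is also available on request and doubles as the oracle in
the test suite. Ties for "largest cluster" break by absolute mass, then
electrode count, then lexicographic member order, so results are
reproducible. Secondary clusters are reported, but the significance decision
rests on the largest, as specified.

## Behavioural measures

Button presses yield per-trial vection intervals (onset/offset pairs in time
order; an offset before any onset is dropped with a warning; an interval
still open at trial end closes there — intervals may extend into the 10 s
post-motion period). Presence is at least one interval; onset latency is
first onset minus motion onset; duration is the *total* vection time in the
trial. "How long a period of vection lasted" is ambiguous for multi-interval
trials; totals were chosen because they match the magnitude of typical
summaries (12–14 s of a 20 s stimulus) and degrade gracefully to the single
interval case.

Participant summaries are medians: presence count over all condition trials,
latency and duration over vection-present trials only, strength (0–10
verbal rating) over all trials with absent trials contributing their 0.
Group contrasts use the Wilcoxon rank-sum normal approximation with average
ranks, tie-corrected variance and continuity correction, signed left minus
right, with r = Z/sqrt(N) and Bonferroni correction over the default family
of 8 (4 measures x 2 conditions; the family size is configurable because the
original correction family is unstated). Per-subject summaries — not pooled
trials — are the unit of observation.

## Brain–behaviour correlations

For each window, the largest significant cluster of the pooled condition
contrast defines an electrode set; each subject's coherent-condition window
amplitudes are averaged over it and correlated with the four behavioural
measures (groups pooled) using Spearman's rho with the t approximation at
n - 2 degrees of freedom, Bonferroni-corrected over the 4 measures per
window (run separately per window). An exact permutation p is implemented
for small n as a test oracle.

## The synthetic cohort: what it emulates, and what it does not

`simulate_subject_epochs()` builds each epoch as template + 1/f noise +
white noise. The template has two components with Gaussian time courses and
Gaussian spatial topographies over the projected montage:

* early: peak 190 ms (SD 20 ms), -6 microvolts at Cz, spatial SD 0.45
  projection units — a central negativity inside the 160–220 ms window;
* late: peak 280 ms (SD 15 ms), +5 microvolts at CPz — the polarity
  reversal of the later window.

The coherent condition multiplies each component by an attenuation factor
(default 0.7 at the topography centre for right-handers). Left-handers'
early-window attenuation depth is scaled by `group_effect_ratio` (default
1.6), so the early condition difference is larger in left-handers and the
late difference carries no group effect — the qualitative pattern the
analysis must recover (condition clusters in both windows, handedness
cluster in the early window only). Attenuating a negative early component
makes the coherent-minus-incoherent difference *positive* in the early
window and *negative* in the late one, matching the planted polarity
reversal.

Noise defaults are 4 microvolts per-sample SD of 1/f-shaped noise (30% of
its variance shared across channels, mimicking spatially correlated EEG
background) plus 4 microvolts white noise. Under these defaults the
artifact-rejection false-positive rate on clean epochs is far below 5%, and
a 57-subject cohort recovers the planted clusters decisively. Between-
subject variability enters through a log-normal amplitude scale (SD log
0.15) and a log-normal jitter on the attenuation depth driven by a latent
"susceptibility" z (SD log 0.25).

Behaviour is generated per trial: presence Bernoulli (0.95 coherent, 0.08
incoherent), log-normal onset latency (median 6 s / 12 s) truncated to the
motion period, log-normal duration (median 13 s / 4.5 s) capped at trial
end, and an integer 0–10 strength built from a per-subject centre plus
trial jitter, clipped to the scale. The subject strength centre couples to
the *same* latent z through a Gaussian copula (coupling 0.8), so planted
attenuation and reported strength agree at rank level — which is exactly
what Spearman's rho measures. The coupling latent is deliberately the
within-group susceptibility rather than the group-scaled attenuation depth:
coupling to the scaled depth would plant a left/right strength difference,
and the emulated study found no behavioural group differences. A consequence
of the geometry is the sign of the recovered correlation: attenuation pulls
the negative early amplitudes up (positive rho with strength) and the
positive late amplitudes down (negative rho).

Artifacts are injected on demand with ground-truth labels: 150-microvolt
Gaussian blinks (SD 40 ms) in Fp1/Fp2/VEOG sized to violate the windowed-SD
rule, and 130-microvolt half-sine excursions violating the range rule in a
random scalp channel. Default per-epoch rates are 5% and 2%, leaving all
simulated participants above the 30-trial inclusion bound almost surely.

The generator does **not** model dipolar forward physics (no leadfields),
CW/CCW asymmetries (collapsed in all analyses), latency jitter between
trials, or non-stationary noise. Passing tests therefore demonstrate that
the pipeline recovers effects with this additive spatiotemporal structure,
not that it would behave identically on recorded EEG with richer artifact
and source dynamics.

## Numerical choices and degenerate inputs

* Window SD exactly at threshold is kept (strict inequality); the test
  suite pins this with a construction whose computed SD is exactly 35.0 in
  double precision.
* The planted electrode set used for recovery scoring is the set of
  channels carrying at least 25% of a component's peak spatial weight.
* The 99th percentile of the null uses the default empirical quantile
  (type 7); with 1000 permutations the interpolation effect is negligible
  but the choice is pinned for reproducibility.
* Montage projection: positions are re-centred on a least-squares sphere
  fit before the azimuthal-equidistant projection; layouts too small to fit
  a sphere are assumed already head-centred.
* Every stochastic stage takes an explicit seed; per-subject seeds derive
  from the master seed by a fixed affine map below 2^31. Two runs with the
  same configuration produce byte-identical output files.

## Problem sizes in the test suite

Unit tests run on cohorts of 2–20 subjects with 2–20 trials per condition;
the recovery checks run one full-scale cohort (28 + 29 subjects, 50 trials
per condition, 1000 permutations) and the type-I calibration uses 500
replicate 20-subject null cohorts at 500 permutations, sizes at which the
binomial check around the nominal 1% rate is informative while the whole
suite stays inside a coffee break.

## Known limitations

Sensor-level only (no source localization); no ICA or regression-based
ocular correction and no channel interpolation; a fixed notch rather than a
regression-based line-noise remover; spatial-only clustering on window mean
amplitudes (no temporal or spatio-temporal clustering, no TFCE); the
BrainVision reader supports the multiplexed float32/int16 dialects only.
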