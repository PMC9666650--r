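# vection

Sensor-level EEG analysis of motion-onset event-related potentials (ERPs)
elicited by vection-consistent versus vection-inconsistent visual motion.

Vection — illusory self-motion in a stationary observer — can be probed by
contrasting a rigid, coherent roll-plane rotation of a large dot field
against the same global rotation with independent random sinusoidal
perturbations added per dot, matched at a mean global velocity of 30 deg/s.
This package provides a tested, reproducible implementation of the complete
analysis for that design, for EEG researchers who want the full chain from
raw BrainVision files (or a synthetic stand-in cohort) to cluster-level
statistics and brain–behaviour correlations:

* **Stimulus kinematics** — coherent and incoherent rotating dot-field
  trajectories with verifiable velocity statistics
  (`generate_coherent()`, `generate_incoherent()`,
  `mean_global_angular_speed()`, `make_session_schedule()`).
* **IO** — BrainVision `.vhdr/.vmrk/.eeg` reader/writer (multiplexed
  float32/int16), typed event tables via a user-supplied trigger code map,
  CSV behaviour tables.
* **Preprocessing** — 50/100 Hz notch + 0.1–30 Hz band-pass (zero-phase
  FIR), common-average re-reference (EOG excluded), epoching at
  −200..+400 ms around motion onset, baseline correction, sliding-window
  artifact rejection (200 ms windows, 50 ms steps; SD > 35 µV in
  EOG/Fp1/Fp2/Fz or range > 100 µV), and the ≥ 30 clean-trials-per-condition
  inclusion rule.
* **ERP measures** — condition averages (CW/CCW collapsed), difference
  waves, per-electrode mean amplitudes in the early (160–220 ms) and late
  (260–300 ms) windows.
* **Statistics** — spatial cluster-based permutation tests (electrode
  t statistics thresholded at p < 0.01, same-sign spatially adjacent
  clusters, cluster mass = summed t, max-mass null from 1000 permutations,
  99th-percentile decision rule) for the condition contrast (paired,
  sign-flip null) and the handedness contrast (independent, label-permutation
  null); Wilcoxon rank-sum behavioural group comparisons with tie-corrected
  normal approximation, Bonferroni correction and effect sizes r = Z/√N;
  Spearman brain–behaviour correlations over the significant cluster's mean
  amplitude.
* **Synthetic cohorts** — a generator that plants a two-component ERP
  template (central attenuation in the coherent condition, a larger early
  condition difference in left-handers), 1/f + white noise, labelled
  blink/range artifacts, and button-press behaviour coupled to the planted
  attenuation through a Gaussian copula — so every stage is testable against
  ground truth without any recorded data.

The statistical core in brief: per electrode *e*, a t statistic on
per-subject window-mean differences; clusters *C* of spatially adjacent,
same-sign suprathreshold electrodes score mass(C) = Σ₍e∈C₎ t(e); the largest
|mass| is referred to the 99th percentile of the permutation distribution of
the maximum |mass| (1000 permutations; sign flips for paired designs, group
relabelings for independent ones), with p = (1 + #{null ≥ observed})/(N+1).

## Worked example

A reduced synthetic cohort (12 + 12 subjects, 40 trials per condition; the
defaults are the full study scale of 28 + 29 subjects and 50 trials):

```r
library(vection)
cfg <- pipeline_config(
  cohort = cohort_spec(n_left = 12, n_right = 12,
                       trials_per_condition = 40, seed = 42),
  n_perm = 500, seed = 42)
res <- run_all(cfg)

res$cluster_tests$condition_pooled_early
#> <cluster_test_result> paired design, 500 permutations
#>   clusters: 1; max |mass| = 63.893; critical (99th pct) = 6.833; p = 0.0020 *
res$cluster_tests$condition_pooled_early$largest_cluster$members
#> "Fz" "FC1" "FC2" "C1" "Cz" "C2" "CP1" "CPz" "CP2" "Pz"
```

The coherent–incoherent contrast finds the planted central cluster
(centred on Cz/CPz, extending frontally and parietally): its mass 63.9 far
exceeds the 99th-percentile critical value 6.8, so the condition effect is
significant (permutation p = 0.002, the smallest value 500 permutations can
resolve). Behavioural group comparisons on the same run, coherent condition:

```r
subset(res$behavior_comparisons, condition == "coherent",
       c(measure, Z, p, p_adjusted, r, median_left, median_right))
#>          measure      Z     p p_adjusted       r median_left median_right
#> 1 presence_count -1.014 0.311          1 -0.2070       47.50        48.00
#> 2  onset_latency -1.299 0.194          1 -0.2652        5.62         5.98
#> 3       duration -0.953 0.341          1 -0.1945       12.87        13.37
#> 4       strength -0.322 0.747          1 -0.0658        4.50         5.00
```

No behavioural group differences are planted and none are found (all
Bonferroni-adjusted p = 1); medians sit at the generator's study-shaped
values (vection on ~47–48 of 50 coherent trials, ~6 s onset latency, ~13 s
duration, strength ~5). The handedness ERP contrast at this reduced scale
shows the planted direction but needs the full cohort for significance
(`handedness_early`: mass 4.1 vs critical 4.5); the full-scale recovery —
condition clusters in both windows, handedness cluster in the early window
only — is exercised by the acceptance suite
(`tests/testthat/test-acceptance.R`).

## Layout

```
R/                   implementation (stimulus, IO, synthetic cohorts,
                     preprocessing, ERP, cluster permutation, behaviour,
                     correlation, pipeline driver)
inst/extdata/        64-channel 10-10 montage coordinates (TSV)
tests/testthat/      unit, property and acceptance tests
scripts/acceptance.R headline-quantity reproduction script
vignettes/           methods vignette (models, defaults, design choices)
```
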