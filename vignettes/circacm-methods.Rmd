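---
title: "Methods: non-parametric circadian analysis of ambulatory recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-parametric circadian analysis of ambulatory recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circacm)
```

## The measurement problem

Ambulatory circadian monitoring (ACM) characterizes a person's circadian
system under free-living conditions from a week of passive wearable
recordings. `circacm` works with two sensor streams: wrist skin temperature
(WT), sampled every 10 minutes by a thermochron-style button logger worn
over the radial artery, and the tilt angle of the upper arm, sampled every
30 seconds by a pendant accelerometer. Two derived channels come from the
tilt stream: **motor activity**, the rate of angle change in degrees per
minute, and **body position**, the angle between the device X-axis and the
horizontal plane (0° lying, 90° upright). All channels are averaged onto a
common 10-minute grid (144 bins per day, bins `[t, t+10)` anchored at local
midnight).

WT is roughly antiphase to activity — the wrist vasodilates and warms
during sleep — so the three channels are combined into the integrated
variable **TAP**: each channel is normalized to [0, 1] per subject, WT is
inverted, and the three are averaged bin-wise. TAP ≈ 1 marks active,
upright, cold-wrist wakefulness; TAP ≈ 0 marks warm-wrist, still,
horizontal sleep. Integration buffers the masking that afflicts any single
marker rhythm (a cold office inflates WT-only estimates; quiet reading
deflates activity-only ones).

The motivating clinical application is sleep-disordered breathing (SDB):
nocturnal apnoea events trigger arousals and sympathetic activation that
fragment the rest-activity rhythm, raise nocturnal activity, and blunt the
day-night contrast, in proportion to severity (the apnoea-hypopnoea index,
AHI: mild < 15 events/h, moderate 15-30, severe > 30), while CPAP treatment
reverses much of the activity-pattern damage. The package therefore ends in
a deliberately simple screening stage: a one-decision threshold on a single
circadian parameter.

## Non-parametric circadian parameters

For a regularized series $x_1,\dots,x_N$ over $d$ days with $p$
time-of-day bins:

* **Interdaily stability** $IS = \dfrac{N\sum_b(\bar x_b-\bar
  x)^2}{p\sum_i(x_i-\bar x)^2}$ — the fraction of variance explained by the
  mean daily waveform. 1 when all days are identical; ~$1/d$ for white
  noise. With missing bins the between-bin sum of squares is
  count-weighted, $\sum_b n_b(\bar x_b - \bar x)^2 / \sum_i (x_i-\bar
  x)^2$, which is identical to the classical form for complete data and
  cannot leave [0, 1].
* **Intradaily variability** $IV = \dfrac{N\sum_{i\ge2}(x_i-x_{i-1})^2}
  {(N-1)\sum_i(x_i-\bar x)^2}$ — fragmentation. Near 0 for smooth slow
  rhythms, 2 for white noise, up to 4 for strict alternation. Differences
  are never taken across masked gaps; with $m$ valid consecutive pairs the
  $N-1$ in the denominator generalizes to $m$ (the two coincide when
  nothing is masked).
* **M10 / L5**: the means over the 10 consecutive hours of maximum and the
  5 consecutive hours of minimum values of the mean daily waveform, both
  searched circularly over all 144 possible onsets (windows may wrap across
  midnight). Their onsets, **TM10** and **TL5**, serve as diurnal and
  nocturnal phase markers. Ties resolve to the earliest onset; toolkits
  differ on reporting the window onset vs its midpoint, and the onset
  convention is this package's fixed choice.
* **Relative amplitude** $RA = (M10-L5)/(M10+L5)$, defined for
  non-negative channels with a daytime acrophase (activity, position, TAP).
* **Circadian function index** $CFI = \big(IS + \tfrac{2-\min(IV,2)}{2} +
  RA\big)/3$ — a 0-1 composite of stability, consolidation and amplitude.
  Each term is itself in [0, 1] (IV is clipped at its white-noise level of
  2), and the combination is linear in each argument on $IV \in [0,2]$.
  Because it is linear, it commutes with group averaging, which is what
  lets published group-mean CFIs be recomputed from published group-mean
  (IS, IV, RA) triples — the package's tests use exactly that
  internal-consistency check.

Undefined statistics — IS or IV on a zero-variance series, RA when
$M10+L5=0$ — are reported as `NA`, never silently as 0 or 1.

IS and IV depend on the analysis grid. The default is the native 10-minute
grid ($p = 144$); `np_bin_minutes = 60` selects the classical hourly
variant. The choice is exposed because the literature uses both and
rarely says which; on noisy data the hourly variant runs higher in IS
(within-hour noise is averaged out before the ratio is formed).

## Preprocessing choices

* **WT filter**: values outside 20-40 °C are masked as off-wrist/ambient;
  an isolated jump > 2 °C per 10-min step that returns to within 2 °C of
  the pre-jump level within 2 samples is masked as a spike. The thresholds
  are configuration keys (`wt_range`, `wt_spike_delta`), not physiology:
  they are this package's artifact definition, and the masked fraction is
  always reported so a user can judge data quality.
* **Missing data** are masked, never imputed; every metric excludes masked
  bins from its sums and variances.
* **Normalization** for TAP clips at the subject's 5th-95th percentiles
  before the linear map (robust to burst artifacts); plain min-max is
  available via `lo_pct = 0, hi_pct = 100`. A masked bin in any channel
  masks the TAP bin by default (`missing = "renormalize"` averages the
  surviving channels instead).
* **Timestamps** are local wall-clock; no DST handling (a 7-day window
  rarely spans a transition, and wall-clock time is what anchors the
  time-of-day bins). This is a documented limitation.
* A non-parametric summary requires at least 6 whole recorded days
  (`min_days = 6`), the conventional minimum for reliable IS/IV
  estimation from weekly actigraphy.

## The screening stage

The screener is intentionally a decision stump: one variable, one cut-off.
Candidate cut-offs are midpoints between consecutive distinct values;
selection maximizes Shannon information gain in bits (the criterion a C4.5
tree restricted to a single split applies), with ties broken by higher
training agreement and then the lower cut-off; the side predicting the
positive class is chosen to maximize agreement. No gain ratio and no
pruning are involved — both are moot with a single decision.

Evaluation mirrors the repeated-split protocol: 100 iterations, 66% of
each class to train, the exact 34% complement to test (quoting "33%" for
the complement of 66% is treated as informal rounding). Splits are
stratified by class so that both partitions always contain both classes;
this is a deliberate, documented deviation from plain random splitting,
which occasionally produces unusable one-class partitions at these sample
sizes (an unstratified mode with redrawing is available). The reported
rule is the best iteration by test agreement (ties: higher test AUC, then
lower iteration index), and a refit on all data is also emitted because a
published cut-off may come from either.

All confusion metrics carry explicit class labels. Clinical papers are
not consistent about which group "sensitivity" refers to; rather than
guess, `evaluate_rule()` names its positive class in the output, and any
orientation can be reproduced by setting `positive` accordingly. ROC
curves are swept over all cut-offs of the variable; the trapezoidal AUC
equals the rank-sum statistic $U/(n_1 n_2)$ with ties counted ½ (a test
asserts this identity to 1e-12, and cross-checks against an independent
ROC implementation). Candidate variables are compared by a two-sided
Wilcoxon signed-rank test on per-iteration metrics, paired by iteration
across protocols run with the same seed — the pairing unit is recorded in
the output because other pairings (e.g. by subject) are defensible too.

## The simulator

No public dataset accompanies the clinical study this design targets, so
the package carries a seeded generative model whose defaults encode the
study conditions; it is first-class, tested code, and its parameters are
not tuned after the fact.

Per night, sleep onset is 23:30 plus Gaussian jitter (SD
`phase_jitter_sd`), duration 8 h. Wake tilt fluctuates around a raised
baseline (45° plus a shallow diel modulation, Gaussian noise SD 15°);
sleep tilt is near-horizontal with 5% of the wake noise. Nocturnal
arousals form a homogeneous Poisson process within the sleep window at
`arousal_rate × cpap_factor` events per hour, with `arousal_rate = 0.25 ×
AHI` by default; each burst raises tilt by an exponential amplitude
(mean 30°) for 1-3 consecutive 30-s samples and triggers a transient WT
drop (0.5 °C, 20-min exponential decay) standing in for the sympathetic
skin-vasoconstriction response to an arousal. WT otherwise follows the
inverse circadian profile: 33.5 °C awake, +2 °C during the (smoothed)
sleep window, plus a small 24-h harmonic and Gaussian noise (SD 0.3 °C).
An optional afternoon nap (probability 0.3/day, ~60 min around 14:30)
lowers position only. Phenotype defaults: AHI 2/7/22/40 for
healthy/mild/moderate/severe, phase jitter 15/20/25/30 min, and
`cpap_factor = 0.3` for the treated phenotype — values chosen once to
produce realistic weekly actigraphy with the ordering the clinical
literature reports, not to match any published absolute means.

What the simulator does **not** model: real apnoea physiology (SpO₂,
respiratory effort), posture-specific apnoea rates, environmental masking
of WT (showers, ambient cold), sensor drift, non-wear. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers the
direction and ordering of group effects from data with the assumed
statistical structure — not that it reproduces clinical effect sizes on
real patients.

## Numerical and design notes

* Seeded determinism everywhere: `generate_subject` is bit-identical given
  `(spec, days, seed)`; cohort subject seeds derive from the cohort seed;
  the split protocol derives all splits from one seed; `run_pipeline`
  output files carry an MD5 hash of the analysis-relevant configuration.
* The simulator's diel profiles are tiled from a single day's time-of-day
  vector so that a noise-free, jitter-free specification yields bitwise
  identical days (and hence IS exactly 1) — a useful degenerate test.
* Window searches and the stump are validated against brute-force oracles
  (exhaustive 144-onset search; exhaustive midpoint enumeration over all
  binary labelings up to n = 12).
* Group tables report mean ± SEM per group × channel; inferential
  modelling (GLM adjustment for age/sex/BMI, mixed models) is deliberately
  out of scope — the tidy summary CSV is designed to be carried into any
  statistics environment.
* Problem sizes in the shipped tests and the acceptance script — cohorts
  of 20 subjects per group, 7-day recordings, 100-iteration protocols,
  hundreds of Monte-Carlo seeds for direction checks — were chosen as the
  smallest sizes at which the group structure is unambiguous.

## Worked example

```{r example, eval = FALSE}
cs <- cohort_spec(list(list(spec = phenotype_spec("healthy"), n = 8),
                       list(spec = phenotype_spec("severe"), n = 8)),
                  days = 7, seed = 11)
cohort <- generate_cohort(cs)
summaries <- summarize_cohort(cohort$recordings, cohort$manifest)
group_table(summaries)[, c("group", "channel", "IS_mean", "CFI_mean")]

act <- subset(summaries, channel == "activity")
split_protocol(act$L5, act$group, n_iter = 100, seed = 7,
               positive = "severe", variable = "activity_L5")
```

## Known limitations

* The WT spike filter is a stated stand-in for device-specific artifact
  handling; its thresholds are honest configuration, not validated
  clinical constants.
* TM10/TL5 use the window-onset convention; toolkits using midpoints will
  differ by a constant 5 h (M10) or 2.5 h (L5).
* Whether a published group RA is the mean of individual RAs or the RA of
  group means is generally ambiguous; the near-agreement of the two for
  smooth group waveforms is a consistency check, not an identity, and this
  package always computes per-subject parameters first.
* No sleep scoring is performed: TAP is used as a circadian variable, not
  thresholded into sleep/wake epochs.
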