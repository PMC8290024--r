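# circacm

Ambulatory circadian monitoring (ACM) analysis in R: from raw
wrist-temperature and tilt-accelerometer logs to the integrated **TAP**
variable, the non-parametric circadian parameters, and a one-decision
threshold screener for sleep-disordered breathing (SDB) status, severity,
and CPAP treatment effect.

## Who this is for

Chronobiology and sleep-medicine groups who record free-living subjects
for a week with a wrist thermochron (one wrist-temperature sample per
10 min) and an arm-worn pendant accelerometer (one tilt sample per 30 s),
and who want reproducible, scriptable computation of the standard
non-parametric rhythm statistics and a transparent screening rule —
without a GUI and without black-box sleep scoring.

## What it computes

From the tilt channel the package derives **motor activity** (rate of
angle change, °/min) and **body position** (angle of the arm's X-axis to
the horizontal, °). Wrist temperature (WT) is filtered for off-wrist and
spike artifacts. All channels are averaged onto a common 10-min grid and
combined into the integrated variable

**TAP** = mean of per-subject normalized (inverted WT, activity, position),

so TAP ≈ 1 is active upright wakefulness and TAP ≈ 0 is sleep-like rest.
For any channel the per-subject circadian parameter block is:

* `IS` — interdaily stability, variance explained by the mean daily
  waveform: IS = N·Σ_b(x̄_b − x̄)² / (p·Σ_i(x_i − x̄)²) ∈ [0, 1]
* `IV` — intradaily variability (fragmentation):
  IV = N·Σ(x_i − x_{i−1})² / ((N−1)·Σ(x_i − x̄)²), ≈ 0 smooth … 2 noise
* `M10`, `L5` — means of the 10 h of maximum / 5 h of minimum values of
  the daily waveform (circular window search); `TM10`, `TL5` their onset
  clock times (phase markers)
* `RA` — relative amplitude (M10 − L5)/(M10 + L5)
* `CFI` — circadian function index (IS + (2 − min(IV, 2))/2 + RA)/3 ∈ [0, 1]

The screening stage fits a decision stump — one variable, one cut-off,
selected by Shannon information gain — and evaluates it with the repeated
protocol (100 random stratified 66/34 train/test splits, best iteration
by test agreement), reporting confusion metrics with explicit class
labels, ROC/AUC, and paired Wilcoxon comparisons between candidate
variables.

A seeded simulator generates week-long recordings for healthy, mild,
moderate, severe-SDB and CPAP-treated phenotypes (AHI-linked Poisson
arousal bursts during the sleep window, day-to-day phase jitter, inverse
WT profile), so the whole pipeline is testable without clinical data.

## Worked example

```r
library(circacm)

cs <- cohort_spec(list(list(spec = phenotype_spec("healthy"), n = 8),
                       list(spec = phenotype_spec("severe"), n = 8)),
                  days = 7, seed = 11)
cohort    <- generate_cohort(cs)
summaries <- summarize_cohort(cohort$recordings, cohort$manifest)
group_table(summaries)
```

```
   group  channel n IS_mean  IS_sem IV_mean L5_mean CFI_mean
 healthy activity 8   0.832 0.00461  0.2887  1.3886    0.869
 healthy      tap 8   0.939 0.00337  0.0711  0.0425    0.936
  severe activity 8   0.643 0.01075  0.5991  9.1996    0.636
  severe      tap 8   0.806 0.00997  0.1931  0.2119    0.763
```

Simulated severe SDB shows the expected pattern: lower stability (IS
0.64 vs 0.83 for activity), more fragmentation (IV 0.60 vs 0.29), higher
nocturnal activity (L5 9.2 vs 1.4 °/min) and a weaker TAP rhythm (CFI
0.76 vs 0.94). Screening on nocturnal activity separates the groups:

```r
act <- subset(summaries, channel == "activity")
split_protocol(act$L5, act$group, n_iter = 100, seed = 7,
               positive = "severe", variable = "activity_L5")
```

```
<split_protocol_result> 100 x 66/34 splits (seed 7)
  best iteration 1: cutoff 5.037 (>), test agreement 100.0%, test AUC 1.000
  refit-on-all cutoff 5.127
```

i.e. a single rule "L5 of activity > 5.0 °/min → severe" classifies every
held-out subject of this synthetic cohort correctly. Per-subject
summaries work the same way:

```r
rec <- generate_subject(phenotype_spec("severe"), days = 7, seed = 42)
np_summary(process_recording(rec)$tap)
#> <np_summary> tap: IS=0.821 IV=0.216 RA=0.556 CFI=0.756 M10=0.786
#>   L5=0.224 TM10=11:30 TL5=00:10 (7 days, 0.1% masked)
```

The full pipeline (simulate or ingest device CSVs → preprocess → TAP →
summaries → group tables/waveforms → screening) runs from one config:

```r
run_pipeline("config.yaml")   # see ?run_pipeline for the schema
```

or from the shell via `inst/scripts/acm-pipeline.R`
(`simulate | analyze | screen | report` subcommands).

## Documentation

The methods vignette (`vignettes/circacm-methods.Rmd`) documents the
model and its assumptions, every tunable parameter with units and
defaults, what the simulator does and does not emulate, numerical
conventions (masking, tie-breaks, degenerate inputs), and known
limitations.
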