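# actirhythms

Sleep and circadian rest-activity rhythm analysis for wrist actigraphy, built
for cross-sectional cohort studies that compare diagnostic and age groups
(e.g. Down syndrome vs typical development across childhood, adolescence and
young adulthood) and relate rhythm stability to cognitive outcomes.

From a week of 30-s activity-count epochs per participant, the package
computes:

* **Sleep**: total sleep time (TST), sleep efficiency (SE) and wake after
  sleep onset (WASO) from an Actiware-style weighted-moving-average scorer
  (central weight 2, ±1–2 epochs 1/5, ±3–4 epochs 1/25, wake threshold 40)
  applied inside diary-anchored nightly rest intervals.
* **Phase**: daily activity onsets and offsets by step-template matching
  (5 h inactivity then 5 h activity, and its mirror) on median-binarized
  activity, plus MESOR, amplitude and acrophase from a 24-h cosinor fit
  `M + A·cos(2π(t − φ)/24)` per day, averaged with circular statistics.
* **Robustness**: the van Someren non-parametric indices

  `IS = N·Σ_h (x̄_h − x̄)² / (p·Σ_i (x_i − x̄)²)`,
  `IV = N·Σ (x_i − x_{i−1})² / ((N−1)·Σ (x_i − x̄)²)`,

  L5/M10 over all 24 wrap-around windows of the average day,
  `RA = (M10 − L5)/(M10 + L5)`, and the peak relative spectral power in the
  18–30 h band of the epoch-resolution periodogram.
* **Inference**: residual-normality-gated two-factor comparisons — Type-II
  Freedman–Lane permutation ANOVA (seeded, 9,999 permutations) or per-factor
  Kruskal–Wallis — with Holm correction across outcome families, and
  hierarchical linear models `outcome ~ IS + SE + age + gender +
  weekend days` with the study's transforms, 3-SD outlier rule and
  IS×age interaction trimming.
* **Synthetic cohorts**: a seeded actogram generator with exactly known
  ground truth (nightly rest windows, arousal minutes, phases, planted
  regression coefficients). Its six presets are calibrated so the measured
  pipeline output reproduces the reference cohort's printed group means of
  TST/SE/WASO/onset/offset/IS/IV within 3 SE over 50-seed ensembles.

## Worked example

```r
library(actirhythms)

# one synthetic child with the DS-children preset, 7 nights of 30-s epochs
sim <- generate_participant(reference_presets()$child_DS, seed = 101,
                            participant_id = "child_DS_example")
participant_metrics(sim$series, sim$diary)
```

```
  n_days tst_min se_pct waso_min onset_hours offset_hours acrophase_hours    is
1      6     484 84.587   75.786       5.935        19.18          12.888 0.869
     iv     l5     m10    ra fft_relpower
1 0.454 19.892 626.573 0.938        0.379
```

Reading: across 6 complete recorded days this participant slept 484 min per
night at 84.6% efficiency with 75.8 min of wake after sleep onset; activity
reliably stopped near 19:11 and resumed near 05:56, peaking at 12:53; the
day-to-day pattern is highly stable (IS 0.87), transitions are few
(IV 0.45), nights are quiet relative to days (L5 19.9 vs M10 626.6 counts
per epoch, RA 0.94), and 38% of non-DC spectral power sits at the circadian
peak. Individual draws scatter around the preset's group means (TST 469.37,
SE 83.85, WASO 83.18, ...), which the calibration tests check at the
ensemble level.

The full study-shaped analysis — six groups, 101 participants, QC, the group
summary and DS-vs-TD / age-shift contrasts, permutation ANOVAs and the
cognition models — is the `analysis/` workflow:

```sh
Rscript analysis/01_simulate.R           # cohort -> scratch/cohort, results/cohort_info.csv
Rscript analysis/02_participant_metrics.R
Rscript analysis/03_group_comparisons.R
Rscript analysis/04_cognitive_models.R
Rscript analysis/05_figures.R
```

Tables land in `results/` (participant metrics, group summary, contrasts,
ANOVA and model tables) and figures in `results/figures/`. With the default
seed the contrast table reports, for example, a 104-min later bedtime for TD
adolescents than TD children alongside a 14-min shift for DS adolescents,
and the cognition step recovers the planted positive IS-reaction-time
association (Holm-corrected p < 0.01).

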