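---
title: "Measuring sleep and rest-activity rhythms from wrist actigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sleep and rest-activity rhythms from wrist actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actirhythms)
```

## The problem

Wrist actigraphy records movement counts in fixed epochs (here 30 s) over
about a week of free living. From that single stream one can estimate three
distinct families of quantities:

* **sleep quantity and quality** — total sleep time (TST, min), sleep
  efficiency (SE, % of the in-bed interval spent asleep), and wake after
  sleep onset (WASO, min);
* **circadian phase** — the clock times at which rest reliably begins
  (offset), activity reliably resumes (onset), and activity peaks
  (acrophase);
* **circadian robustness** — how regular and consolidated the rest-activity
  rhythm is: interdaily stability (IS), intradaily variability (IV), the
  least-active 5-h and most-active 10-h levels (L5, M10), relative
  amplitude (RA), and the share of spectral power near 24 h.

`actirhythms` implements this measurement chain end to end and the
inferential protocol used to compare diagnostic and age groups
(cross-sectionally, e.g. Down syndrome vs typical development across
childhood, adolescence and adulthood) and to relate rhythm stability to
cognitive outcomes. Because the cohort it was built around is not publicly
redistributable, the package carries a synthetic-cohort generator with
exactly known ground truth; every stage is validated against it.

## The measurement chain

### Epochs, days and quality control

A recording enters as an `epoch_series`: uniformly spaced non-negative
counts anchored to naive local clock time (no time-zone arithmetic; a QC
flag, not an exclusion, is raised if the window overlaps a supplied
daylight-saving date list). `trim_to_full_days()` discards leading and
trailing partial days relative to a configurable boundary (default
midnight, the actogram convention; the source study does not state its
boundary) and produces a `D x B` day matrix — `B = 2880` for raw 30-s
epochs, `B = 24` after hourly rebinning by arithmetic mean, which conserves
the grand mean exactly. Missing epochs are never imputed: a gap invalidates
the file at read time, because the non-parametric statistics below assume a
complete series.

`qc_inclusion()` retains a participant only when at least five consecutive
complete 24-h days survive. Night-only wear is flagged by a configurable
rule: a day fails when 20% or more of its 08:00–20:00 epochs sit in
zero-count runs of at least 30 min (or are off-wrist-flagged), and more
than one failing day excludes the participant. The thresholds are explicit
arguments because the underlying field rules are qualitative.

### Sleep scoring

Epoch-level sleep/wake labels come from the weighted-moving-average rule
used by the dominant wrist-actigraphy software family, adapted to 30-s
epochs: an epoch is wake when

$$2 a_0 + \tfrac15 (a_{\pm1} + a_{\pm2}) + \tfrac1{25}(a_{\pm3} + a_{\pm4}) > \theta,$$

with wake threshold $\theta = 40$ counts ("medium") and zero padding at the
edges. The proprietary scorer the study used is not published, so this
documented standard stands in for it; kernel and threshold are fully
configurable, and emulation fidelity cannot be verified beyond the
published rule. Scoring happens inside nightly rest intervals taken from
the sleep diary (used verbatim by default; optional snapping to the
steepest smoothed activity transition within a +/-60-min window; without a
diary, the template phase markers supply the interval). Sleep onset is the
first run of 10 consecutive sleep-scored minutes; TST is the sleep-scored
minutes in the interval; WASO the wake-scored minutes from onset to the end
of the interval; SE is `100 * TST / duration`. The identity
`TST + WASO + pre-onset wake = duration` holds exactly every night, and
per-participant values are plain means over retained nights. Diary naps are
scored identically but excluded from nightly summaries.

### Phase markers

Onsets and offsets use step-template matching on binarized activity: a bin
is active iff its count exceeds the participant's median bin count
(scale-free; in the degenerate two-level case where the median equals the
maximum, bins at the median count as active). The onset template is 5 h of
inactivity followed by 5 h of activity (+1 active, -1 inactive, dot
product); the offset template is its mirror. All bin boundaries are
scanned with circular wrap over the whole recording, ties resolve to the
earliest maximal boundary, constant days are flagged, and per-day times are
averaged on the 24-h circle (mean resultant vector), which matters for
offsets near midnight. The acrophase, MESOR and amplitude come from an
ordinary least-squares fit of $M + A\cos(2\pi(t-\varphi)/24)$ to each
day's profile in the linear sine/cosine parameterization; a zero-variance
day yields amplitude 0 with the acrophase flagged undefined.

### Non-parametric circadian statistics

On hourly bins (the classical convention for these indices, and the scale
on which the reference values were produced):

$$IS = \frac{N \sum_h (\bar x_h - \bar x)^2}{p \sum_i (x_i - \bar x)^2},
\qquad
IV = \frac{N \sum_{i=2}^{N} (x_i - x_{i-1})^2}{(N-1) \sum_i (x_i - \bar x)^2},$$

with `p = 24` bins per day and `N` total hours. IS is 1 for a perfectly
repeated day and tends to `1/D` for exchangeable noise; IV tends to 0 for a
slowly varying profile and to 2 for independent noise (slightly above 2 for
anticorrelated series). IV runs over the concatenated retained days without
resetting at day boundaries. L5 and M10 scan all 24 wrap-around windows of
5 h and 10 h on the participant's *average* 24-h profile (the default; a
per-day variant is available) with earliest-start tie-breaking, and
`RA = (M10 - L5)/(M10 + L5)`. Zero-variance inputs are flagged (`NA` with a
warning), never silently numeric.

### Spectral rhythm strength

The periodogram mean-subtracts the series, applies an optional Hann taper,
and normalizes the discrete Fourier power against the series' non-DC
energy, so the relative power of an on-grid periodic component is invariant
to zero-padding and the whole grid sums to 1 when unpadded. The circadian
index is the *peak* relative power over grid periods in the 18–30 h band
(a band-integral mode is provided, since the convention of the original
circadian software is not published). It is computed on the
epoch-resolution series (2880 points per day), matching the workflow in
which that software ingests the exported epoch files; at that resolution
realistic epoch-level count dispersion places the index in the 0.1–0.35
range that the reference cohort reports, whereas hourly pre-binning would
roughly double it.

### Inference

Group comparisons follow a gated two-factor protocol
(`anova_protocol()`): a Shapiro–Wilk test on the residuals of the
cell-means model (alpha 0.05) routes each measure either to a permutation
ANOVA or to per-factor Kruskal–Wallis tests (tie-corrected, no interaction
term). The permutation ANOVA uses Type-II sums of squares with
Freedman–Lane permutation of reduced-model residuals — the accepted default
for factorial designs, since the source protocol names neither scheme nor
count — with 9,999 permutations by default,
`p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})`, and bit-exact reproducibility
under a fixed seed. Holm correction is applied within per-term families
across outcomes (all "group" tests one family, etc.); per-outcome families
are available because the source description is ambiguous. Holm output
dominates the raw p-values and is order-invariant; it is *not* idempotent
(no step-down procedure is), so that is not asserted anywhere.

Cognition models (`fit_hierarchical_model()`) regress each outcome on IS
with covariates SE, age (continuous), gender and the number of full weekend
days recorded; reaction time is additionally covaried on task accuracy.
Verbal recall and object-context binding are log-transformed and visual
recall square-root-transformed before fitting; outcome values more than
3 SD from the mean (on the transformed scale) are excluded and their ids
logged; the IS x age interaction enters second and is retained only if its
p-value is at most 0.10 or a nested-model F-test at alpha 0.05 shows it
contributes to the multiple R^2 — the latter operationalizes an otherwise
unstated "contributes significantly" criterion.

## The synthetic cohort

`generate_participant()` builds each night as: daytime activity, a quiet
pre-bed wind-down, in-bed settling (scored wake), sleep with
Poisson-placed arousal bouts of elevated counts, the diary-recorded wake
time, and a quiet lie-in before activity resumes. Wake counts are gamma
with a smooth diurnal envelope, an ultradian modulation phase-locked to
clock time within a participant (a daily routine, so it enriches the
repeatable profile rather than degrading IS), an AR(1) lognormal hourly
behavioural factor, and brief elevated "transition routines" at getting-up
and pre-wind-down times. Diaries record the drawn bed and wake times
exactly by default, so any scoring error is attributable to the scorer.
Everything is deterministic given `(params, seed)`.

The six `reference_presets()` groups are calibrated so that the *measured*
pipeline output reproduces the reference cohort's printed group means. The
calibration anchors are arithmetic identities — interval duration
`= TST/(SE/100)`, settling minutes `= interval - TST - WASO`, and the
onset-offset span fixing wind-down plus lie-in — plus one dial per
remaining measure: night-to-night phase jitter for IS, the hourly factor's
sdlog for IV, arousal rate for WASO, epoch-count dispersion for the
spectral index, daytime mean for M10 and sleep-epoch counts for L5. A
50-participant ensemble per group reproduces TST, SE, WASO, onset, offset,
IS and IV within 3 SE of the printed values (SE computed from the printed
SDs); this is a tuning check of the generator, not evidence about real
recordings. Known residual: the cosinor acrophase of two groups
(adolescent-DS, adult-TD) sits 0.5–0.9 h earlier than its printed value,
because the generator anchors peak activity near the mid-wake span and
tilting the envelope far enough to move it breaks onset detection; the
acrophase anchors that are checked (children-DS) verify.

What the generator does *not* emulate: naps and irregular daytime rest,
off-wrist artefacts, seasonal/weekend structure beyond the weekend-day
count, device saturation, and any physiology beyond what the measures are
sensitive to. Passing tests therefore certify the estimators against a
known mechanism, not against polysomnography.

Cognitive outcomes are linked to the *generated* IS by
`y = b_0 + b_{IS} \cdot IS + b_{age} \cdot age + \varepsilon` on each
outcome's model scale (log/sqrt outcomes are back-transformed, so the
pipeline's transform recovers the linear model). Default coefficients
reproduce the reference sign structure — positive IS and age slopes for
reaction time (tuned so the fitted model's R^2 is near the reference
~0.50), negative IS slopes for verbal and scene recall, a positive age
slope for object-context binding, null otherwise.

## Numerical and design choices

* Day boundary: midnight local clock, configurable.
* Template matching at 6-min bins (240/day): fine enough that boundary
  quantization (+/-3 min) is negligible against the 3-SE tolerances.
* Circular statistics for all clock-time averaging and for group summaries
  of hour-valued measures; arithmetic means of offsets straddling midnight
  would collapse toward midday.
* Binarization threshold: the participant median (scale-free), with the
  degenerate-tie rule above.
* Earliest-maximum tie-breaks in template matching and window searches:
  deterministic and reproducible.
* Gender enters models as a two-level indicator; rows with missing
  covariates are dropped per model (complete-case), so n varies by outcome.
* Permutation p-values use the add-one estimator; seeds are explicit
  arguments everywhere randomness exists.

Problem sizes in the shipped tests were chosen to keep the full suite
around a minute on one core while leaving every statistical check
well-powered: 50-participant ensembles per preset for calibration, 1,000
null replicates at 999 permutations for the type-I calibration of the
permutation ANOVA, 100 seeds for regression-coefficient coverage, and 200
replicates for the IV noise bound.

## The analysis workflow

The `analysis/` directory re-runs the study-shaped analysis on a synthetic
cohort with the reference group sizes (20/20/28/13/10/10): `01_simulate.R`
generates and writes the cohort (epoch CSVs under `scratch/`, regenerable),
`02_participant_metrics.R` runs QC and the full measurement chain and
writes the participant table, group summary and contrasts,
`03_group_comparisons.R` runs the gated permutation-ANOVA protocol,
`04_cognitive_models.R` fits the hierarchical cognition models for the DS
subset, and `05_figures.R` renders actograms, 24-h profiles and the
IS-reaction-time scatter. These scripts, together with the exported
functions they are thin wrappers over (`generate_cohort()`,
`run_pipeline()`, `anova_protocol()`, `fit_hierarchical_model()`,
`derive_group_contrasts()`), are the package's interface; no shell CLI is
provided because the artifact is an analysis, not a deployment tool.

## Limitations

Actigraphy under-detects quiet wake, so absolute TST/WASO levels inherit
the scorer's biases; the in-package scorer follows the published rule, not
the proprietary implementation the reference data were scored with. The
template markers carry a small estimator offset that the presets absorb;
on real data those offsets depend on behaviour near the rest transitions.
Single simulated cohorts at the reference group sizes wobble visibly around
the calibrated means (e.g. a planted verbal-recall slope can be washed out
by IS-age collinearity in one draw); the calibration claims concern
ensemble means, not individual cohorts. RA has no printed reference value
anywhere, so it is validated only through its definition and invariants.
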