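---
title: "Estimating upper-limb clinical scores from wearable accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating upper-limb clinical scores from wearable accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(senscore)
```

## The estimation problem

Clinician-rated outcome measures for upper-limb hemiparesis — the upper-limb
Fugl-Meyer Assessment (FMA, 0–66 points, higher = less impaired) and the
Functional Ability Scale (FAS, 0–5, rated on Wolf Motor Function Test items,
higher = better movement quality) — are too time-consuming to administer more
than a few times per episode of care. `senscore` implements a pipeline that
estimates both scores from body-worn accelerometers recorded while the
patient performs eight WMFT tasks (four reaching: forearm to table,
extend elbow, hand to table, reach-and-retrieve; four manipulation: lift can,
lift pencil, flip cards, turn key), each up to three times. Six sensor sites
are used: sternum, affected upper arm, both wrists, and the affected thumb
and index finger (the finger units are two-axis, the rest three-axis).

The pipeline has five stages:

1. **Segmentation** — each trial is cropped to its digital-marker window,
   treated as half-open `[start, end)` to avoid off-by-one ambiguity.
2. **Band filtering** — 8 Hz low-pass then 0.25 Hz high-pass, both
   sixth-order Butterworth, applied with zero phase. The high-pass doubles
   as the gravity/postural-drift remover.
3. **Kinematic series** — per axis, velocity and displacement are obtained
   by trapezoidal integration (each re-high-passed at 0.25 Hz to suppress
   integration drift) and jerk by central differences; each series is
   collapsed to its Euclidean norm across axes.
4. **Features and selection** — nine feature families per placement and
   series (min/max/mean, RMS, dominant-frequency power ratio, jerk summary,
   skewness, histogram entropy, excess kurtosis, inter-placement and
   inter-axis correlations, duration), then correlation-based feature
   selection (CFS) with best-first search, re-run inside every training
   fold.
5. **Estimation** — per-task random-forest regressions (100 trees) and a
   50-tree aggregator forest, evaluated under leave-one-subject-out (LOSO)
   cross-validation.

## The estimators

The FAS estimator fits one 100-tree random forest per task on the selected
features, averages the per-repetition estimates within each task, sums the
eight per-task means, and maps the sum through the calibrated linear
aggregation

$$\widehat{\mathrm{FAS}}_{\mathrm{Total}} =
  \frac{\left(\sum_i \widehat{\mathrm{FAS}}_i \right)\times 1.78 + 2.97}{15},$$

clipped to $[0, 5]$ (so the all-zero input maps to 0.198 and the all-five
input to about 4.945).

Four FMA estimators of increasing sophistication are implemented and
compared:

* **Method 1 (linear regression on $\widehat{\mathrm{FAS}}$)** — ordinary
  least squares of FMA on the clinician FAS totals of the training
  subjects, evaluated at the sensor-derived $\widehat{\mathrm{FAS}}$ of the
  held-out subject. Its accuracy is capped by how much of FMA the FAS
  construct explains at all.
* **Method 2 (random forest)** — a 100-tree forest per task estimates FMA
  from that task's features; a 50-tree forest aggregates the eight per-task
  estimates. The aggregator is trained on the training subjects' *per-task
  LOSO estimates* (each computed with that subject held out), so its
  training inputs are identically distributed to the held-out input it is
  asked to aggregate. Training it on in-sample or out-of-bag module-1
  estimates instead miscalibrates it: those are optimistic, and worse, any
  subject-constant input (such as Method 4's FAS estimate) then acts as a
  subject identifier through which a tree can reach the same subject's
  other repetitions.
* **Method 3 (balanced random forest)** — Method 2 with every bootstrap
  drawn class-balanced over five FMA classes with the printed edges
  (≤30, 30–38, 38–47, 47–56, >56), countering the regression-to-the-mean
  that a nonuniform score distribution induces.
* **Method 4 (proposed)** — Method 3 with $\widehat{\mathrm{FAS}}$ added
  as an aggregator input alongside the eight per-task estimates. Where the
  FAS estimate enters is a genuinely open design point; we place it at the
  aggregator because that is where it helps and the alternative
  demonstrably hurts: appended to the per-task forests it is constant
  across a training subject's repetitions, so trees use it as a subject
  identifier and generalize worse to the held-out subject, whereas the
  cross-task information it carries is a subject-level quantity that
  belongs with the subject-level aggregation stage.

All estimates are clipped to the scale range after aggregation. Accuracy is
summarized by RMSE, $r^2 = 1 - \mathrm{SSE}/\mathrm{SST}$, and bias
(`mean(estimate − truth)`; note $\mathrm{RMSE}^2 = \mathrm{bias}^2 +
\mathrm{Var}(\mathrm{error})$), plus per-class signed-error quartiles and
paired t tests on per-subject absolute errors between methods.

```{r}
cohort <- simulate_cohort(sim_config(n_subjects = 40, seed = 1))
feats <- cohort_features(cohort)
est <- run_estimation(feats, seed = 1)
eval_report(est, feats$truth)
```

## Design choices where the method description is open

Several details are under-determined by the published description; the
package fixes them as follows and exposes each as a parameter.

**Zero-phase filtering.** Offline analysis calls for zero-phase filtering so
that features are not phase-distorted. We realize it in the frequency
domain: the signal is extended by even reflection (making it symmetric, so
no wrap-around discontinuity) and multiplied by the *squared* Butterworth
magnitude response — exactly the response an ideal forward–backward pass
realizes (effective order 12; a 20 Hz component at 50 Hz sampling is
attenuated by ≈99.998 % in amplitude). Unlike a time-domain
forward–backward pass, this has no start-up transients — relevant because a
0.25 Hz sixth-order high-pass has transients that outlive a typical 2–8 s
trial — and is exactly equivariant under time reversal.

**Order of operations.** Trials are segmented first and filtered second;
the marker window is what defines the movement of interest.

**Integration drift.** Velocity and displacement inherit low-frequency
drift from integration; each integration is followed by the same 0.25 Hz
zero-phase high-pass. No explicit gravity-vector estimation is done: the
high-pass is the gravity/posture remover.

**Feature conventions.** "Signal entropy" is the Shannon entropy (nats) of
a 16-bin histogram of the min–max-normalized series (bin count
configurable); skewness and kurtosis are the bias-corrected (type 2)
estimators, kurtosis as excess; the dominant-frequency ratio is the largest
periodogram ordinate over total power with the DC bin excluded (the
high-pass already removed DC); the jerk feature is the RMS of the jerk
magnitude; the correlation family includes both inter-placement
correlations of acceleration magnitudes (capturing, e.g., trunk
compensation as chest–wrist coupling) and intra-sensor inter-axis
correlations, covering both readings of "correlations between different
axes"; duration is the segmented trial length in seconds. Sub-movement
decomposition is not attempted — duration is the whole-trial duration — a
known fidelity gap.

**CFS.** Subset merit is $M_S = k\,\bar r_{cf} / \sqrt{k + k(k-1)\bar
r_{ff}}$; best-first search stops after five consecutive non-improving
expansions. For tractability the search is restricted to the 60 candidates
with the highest $|r_{cf}|$; on small problems (≤10 features) the search
agrees with exhaustive enumeration in ≥95 % of random instances. Selection
runs inside each training fold only — selecting on the full cohort before
cross-validation leaks the test subject, and the package keeps that
(deliberately wrong) option only to demonstrate its optimism.

**Balanced bootstrap.** The per-tree draw is `per_class_draw` samples with
replacement from each nonempty class. The default draw is
`ceiling(n/classes)` per class, which keeps the bag near the plain
bootstrap size and balances by oversampling minorities. The classical
convention (downsampling to the smallest class) is available as
`"min-class"`, but with near-singleton classes it produces 3–5-sample bags
on which regression trees cannot split, collapsing the forest toward a
constant predictor; tree minimum node size is scaled down for small bags
for the same reason. Balancing is applied to the aggregator forest as well
(`balance_aggregator = FALSE` switches it off), and tree parameters not
fixed by the method description follow common random-forest regression
defaults (unlimited depth, `mtry = p/3`).

**Leakage control for Method 4.** The $\widehat{\mathrm{FAS}}$ inputs are
produced by a single LOSO pass: every subject's FAS estimate comes from
models never trained on that subject. A fully nested protocol (re-running
the FAS LOSO inside every FMA training fold) would multiply cost roughly
40-fold while protecting against only a second-order effect (training
subjects' FAS models having seen the held-out subject's FAS labels — never
its FMA labels); the single-pass design keeps the quantity being protected
— no model that scores a subject has seen any of that subject's data.

**Method 1 regression scope** is per training fold, not fit once on the
whole sample; **repetition handling** averages estimates across up to three
repetitions before any cross-task aggregation, for FAS and FMA alike.

**Per-class analysis** groups signed errors (`estimate − truth`) by the
*true* score's class, uses type-7 (linear interpolation) quantiles, and
compares methods by two-sided paired t tests on per-subject absolute
errors ("improvement" semantics; signed comparison available). Zero
variance or fewer than two pairs yield `NA` rather than a fabricated
p-value.

## The synthetic cohort generator

No public accession exists for the original patient recordings, so the
package ships a generator whose defaults encode the study conditions: 40
subjects, eight tasks × three repetitions × six sensors at 50 Hz (the
hardware rate is unpublished; 50 Hz is ample for an 8 Hz low-pass
pipeline), acceleration in g, and a deliberately nonuniform FMA
distribution with per-class weights 2/8/15/8/4 (per-class counts of the
published sample ranged from 2 to 15). Class membership is allocated by
largest-remainder quota — emulating recruitment stratified across severity,
as the study's FMA 15–55 inclusion band enforced — with integer FMA drawn
uniformly within the class and subject order shuffled.

Each trial is a sum of minimum-jerk-like velocity pulses (one per movement
phase; manipulation tasks have two or three) with white sensor noise and
lognormal per-trial duration jitter (SD 0.15 — a single trial's pace is a
noisy readout of how impaired the subject is). Two correlated
subject-level factors drive the signal, mirroring the distinct constructs
the two scales measure:

* the pace/compensation trait
  $s_{\mathrm{pace}} = \mathrm{clamp}(s + \mathcal N(0, 0.04))$, where
  $s = (66 - \mathrm{FMA})/66$ is impairment severity, scales trial
  duration ($\times(1 + a_1 s_{\mathrm{pace}})$, $a_1 = 1$) and the
  chest–wrist trunk-compensation coupling ($a_4 = 0.8$) — how slowly and
  how trunk-compensated a person moves correlates with, but is not
  determined by, their impairment;
* movement quality $q = \mathrm{clamp}(1 - s + \mathcal N(0, 0.10))$
  drives tremor amplitude (up to $a_2 = 0.16$ g inside a 4–7 Hz band,
  inside the filter passband) and fragmentation (Poisson-many extra
  corrective sub-movements, mean $a_3 (1-q)$ with $a_3 = 6$), and
  generates the per-task FAS labels
  ($5 q \cdot \mathrm{slope}_t + \mathrm{offset}_t + \mathcal N(0, 0.15)$,
  clipped to $[0,5]$).

The quality deviation of 0.10 makes the cohort-level FMA–FAS correlation
land near $r^2 = 0.75$, the empirical relation between the scales; without
it FAS would be a deterministic function of FMA and the FAS-regression
estimator (Method 1) would be unrealistically strong. The pace-trait
deviation matters for a different reason: without it, movement duration
is a noise-free readout of FMA, every estimator saturates, and no input —
the FAS estimate included — can add anything. With it, the pace channel
and the quality channel are two independently noisy measurements of
impairment, so estimators that fuse them (Method 4) have something real to
gain, as in the study. The coefficients were fixed once so that the
proposed estimator reaches $r^2 \approx 0.8$–0.9 on a 40-subject cohort —
informative but not saturated. Because raw jerk *falls* as movements slow,
smoothness relationships are stated (and tested) in terms of dimensionless
jerk, `dimensionless_jerk()`, the duration- and amplitude-normalized form.

Every subject derives an independent RNG substream from the cohort seed,
so cohorts are bit-reproducible and growing a cohort never changes earlier
subjects.

**What the generator does not emulate:** real task-specific object
interactions (a can vs. a key differ only through pulse-count and
amplitude templates), sensor-axis misalignment and drift, day-to-day
variability, recording artifacts, and any nonmonotone relation between
impairment and kinematics. Passing recovery tests on this generator shows
that the pipeline recovers scores when the assumed monotone
impairment–signal structure holds — not that it attains the published
patient-data accuracies.

## Evaluation protocol and problem sizes

LOSO is the primary protocol: all fitting — feature selection, forests,
the Method-1 regression, and the FAS estimates feeding Method 4 — uses
only the other subjects' data. A record-level k-fold option exists purely
to demonstrate why LOSO is needed: with repetitions of one subject split
across training and test, apparent $r^2$ inflates substantially on
cohorts where LOSO reveals modest accuracy.

Package checks run the full pipeline on 40-subject cohorts over a fixed
five-seed protocol (about a minute per seed on one core): Method 4 and
FAS recovery thresholds ($r^2 \ge 0.75$ and $\ge 0.7$, each in at least 4
of 5 seeds) are set below the published patient-data values to allow for
synthetic–real mismatch; the method ordering is asserted on mean RMSE
across seeds; and the balancing effect is asserted as lower mean
minority-class (most/least impaired) absolute error for the balanced
forest on imbalanced cohorts (weights 2/6/24/6/2), averaged over the same
seeds — single-cohort minority MAE rests on ~4 subjects and is dominated
by sampling noise.

## Cohort comparison statistics

The demographics module reproduces the published between-group analyses
exactly from printed inputs: Pearson chi-square without continuity
correction for categorical variables (with continuity correction the
printed statistics do not reproduce), pooled-variance Student t from group
summary statistics for continuous variables (which reproduces the printed
FMA and baseline-FAS statistics to two decimals; the printed age,
chronicity, and post-FAS values do not reproduce from the printed
summaries under either pooled or Welch t and are excluded from regression
tests), and Holm's step-down adjustment across whichever family of
p-values is passed in — which family the original analysis adjusted across
is not stated.

## Known limitations

* Synthetic validation only: real patient accelerometry is available
  solely on request to the original investigators, so absolute accuracies
  here characterize the generator, not the clinic.
* Whole-trial duration stands in for per-movement-component segment
  durations; no sub-movement segmentation algorithm is provided.
* The exact sensor montage feeding the published models (six units, but
  bilateral arm/wrist sites are also named) is ambiguous; the pipeline
  uses whichever of the seven admissible placements are present.
* FAS estimation quality depends on all eight tasks being present; a
  subject missing a task is excluded (with a warning) rather than imputed,
  because the aggregation equation is calibrated for the eight-task sum.
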