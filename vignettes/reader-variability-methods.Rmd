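---
title: "Observer variability and diagnostic accuracy for multi-reader imaging studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer variability and diagnostic accuracy for multi-reader imaging studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readervar)
library(dplyr)
```

## The problem

Cine-MRI is a dynamic MRI sequence that shows abdominal organs sliding over
one another; restricted sliding is the radiological sign of an adhesion, a
fibrous band that can form after abdominal surgery and cause chronic pain.
The modality is promising but novel, and its reading depends heavily on the
observer. A multi-reader study of this kind has a panel of radiologists
review every sagittal cine slice, place a bounding box wherever they suspect
an adhesion and attach an ordinal confidence from 1 to 5; a separate
consensus panel defines the slice-level reference standard. Three questions
follow:

1. **Inter-observer variability** — how much do readers agree with one
   another, irrespective of the reference standard?
2. **Intra-observer variability** — how consistent is a single reader who
   reads the same slices twice, typically a year apart?
3. **Diagnostic accuracy** — how well does each reader, and each experience
   group, separate positive from negative slices against the reference?

`readervar` implements the complete analysis pipeline for such a study, plus
a seeded generator of synthetic studies with the same structure, so every
stage can be exercised and calibrated without access to patient data (which
such studies generally cannot share).

All analysis is at slice level: positive patients need not show an adhesion
on every slice, and slice-level agreement carries localization information
that patient-level agreement does not. A patient is positive exactly when at
least one of its slices is.

## From annotations to binary calls

Annotations arrive as one row per bounding box (observer, patient, slice,
box corners, confidence 1–5, reading session). `slice_scores()` reduces them
to a slice-by-observer table of ordinal scores 0–5, where 0 means the
observer did not annotate the slice and an annotated slice takes the
*maximum* box confidence. The maximum is the conventional reduction from
free-response marks to a case-level rating: a slice is as suspicious as its
most suspicious finding. Unannotated slices are explicit zeros, not missing
data — every reader submits every slice.

Agreement statistics need binary calls. Each reader states the confidence
threshold they would use in clinical practice, expressed in percent
(a multiple of 20, since confidence c on the 5-point scale is read as 20c%
certainty). `binarize_scores()` marks a cell positive when the slice was
annotated at all *and* `score * 20 >= clinical_threshold_pct`; the
comparison is `>=` ("at least 40% certain"), and a 0% threshold counts any
annotation as positive. A consequence worth noting: a reader's positive-call
count is non-increasing in their threshold.

Readers are grouped on three experience axes — years of general experience
(cutoff 5), cine-MRI cases reviewed of any type (cutoff 30), and adhesion
cine-MRI cases reviewed (cutoff 2) — with `>=` placing a reader in the high
group. The source study's wording ("less/more than") leaves the boundary
open; the cutoffs here are the ones that reproduce its printed grouping
table exactly, including the readers sitting on the boundary values. The
consensus readers form their own group and are excluded from the
experience groups and from all ROC analysis, since they defined the
reference standard.

## Agreement statistics

**Fleiss' kappa** (`fleiss_kappa()`) is chance-corrected multi-rater
agreement over items,

$$\kappa = \frac{\bar P - \bar P_e}{1 - \bar P_e},\qquad
  P_i = \frac{\sum_j n_{ij}^2 - n}{n(n-1)},\qquad
  \bar P_e = \sum_j p_j^2,$$

with $n$ raters per item, $n_{ij}$ raters assigning category $j$ to item
$i$, and $p_j$ the category proportions pooled over all items and raters.
When every rating in the table is the same category, $\bar P_e = 1$ and
kappa is undefined; the package raises an error rather than returning a
number. For two raters Fleiss' kappa equals Scott's pi, which differs from
Cohen's kappa whenever the two raters' marginal rates differ — the package
deliberately does not conflate them, and the test suite pins an example
where they disagree.

**Cohen's kappa** (`cohen_kappa()`) handles the two-rating case (here:
session 1 vs session 2 of the same reader) with chance agreement from the
product of the two marginal distributions.

**Unanimity percentage agreement** (`pct_agreement()`) is the percentage of
slices on which *every* reader in the group gives the same call; any split
vote is disagreement. It is strongly group-size dependent — adding a reader
can only leave it equal or lower — so it is comparable only within groups of
similar size.

Kappa values are interpreted on the conventional bands: poor at or below 0,
then slight, fair, moderate, substantial and almost perfect above 0, 0.2,
0.4, 0.6 and 0.8, with boundary values belonging to the lower band.

## Resampling inference

The sampling distributions of agreement statistics over a fixed reader panel
have no usable parametric form, so all inference is resampling-based and
fully seeded.

* **Confidence intervals** (`bootstrap_ci()`): slices (cases) are resampled
  with replacement while the reader panel stays fixed, and a percentile
  interval is taken (default 2000 resamples, level 0.95). The estimand is a
  property of this panel over the case population, which is why cases and
  not readers are resampled. Resamples on which kappa is undefined are
  dropped and counted — the estimand is conditional on the statistic being
  defined — and a warning is raised when more than 1% are dropped, which in
  practice happens only for small, highly concordant panels.
* **Group differences** (`permutation_test()`): the null hypothesis is that
  group membership is exchangeable, so the pooled readers are randomly
  re-partitioned into groups of the original sizes and the metric difference
  recomputed (default 10,000 re-partitions). Slices are never permuted:
  permuting them would destroy the within-slice correlation that both groups
  share. The two-sided p-value uses the add-one convention
  $p = (1 + \#\{|\Delta^\ast| \ge |\Delta|\})/(1 + n_{perm})$, so the
  smallest attainable p is $1/(n_{perm}+1)$ and p is never zero.

## ROC analysis

`roc_curve()` builds one operating point per distinct score value the
observer used, under the rule "call positive if score ≥ t", plus the (0,0)
origin; score 0 participates as the lowest ordinal level, so the final point
is always (1,1). The number of points therefore varies across observers with
the number of confidence levels they actually used. `auc()` is the
trapezoidal area, which for this construction equals the Mann–Whitney
probability that a random positive slice outscores a random negative one,
ties counted 1/2 — the test suite verifies the identity to 1e-12 against a
pairwise enumeration oracle.

**Diagonal averaging** (`diagonal_average()`) produces a group-average
curve: each line perpendicular to the chance diagonal, $tpr = b - fpr$ for
an offset $b \in [0,2]$, crosses a monotone ROC curve exactly once; the
crossing points are averaged across readers. The offset grid is 201 equally
spaced values *plus every input vertex's own offset*, which makes the
average of piecewise-linear curves exact rather than approximate: averaging
copies of a curve returns that curve to machine precision, and endpoints
(0,0), (1,1) are preserved exactly. The averaged AUC of a set of curves that
dominate the diagonal always lies between the smallest and largest input
AUC; for the perfect curve averaged with the chance diagonal the geometry
gives the curve (0,0)–(¼,¾)–(1,1) with AUC 0.75.

**Group inference** (`group_auc_summary()`, `compare_group_auc()`): the
group summary is the AUC of the diagonally averaged curve, with a two-way
bootstrap interval that resamples readers and cases jointly — readers with
replacement within the group, cases with replacement *within the positive
and negative reference strata*, so every resample retains both classes. The
group difference uses a z statistic whose standard error is the bootstrap
standard deviation of the difference, with cases resampled once per draw and
shared by both groups. This replaces the U-statistic variance machinery of
dedicated MRMC software with the same inferential target but a different
variance estimator; printed p-values from such software are therefore not
exact reproduction targets. With readers that are exchangeable (no true
skill differences) the two-way bootstrap double-counts part of the
reader-by-case interaction, so the z-test errs on the conservative side;
the test suite asserts validity (type I error at or below the nominal level)
and separately verifies that power against a 0.60 vs 0.80 AUC difference at
10 readers and 500 slices exceeds 80%.

`operating_point()` extracts (sensitivity, specificity) pairs from a curve,
either at the first vertex reaching a target sensitivity or interpolated
along the curve, for comparisons with studies that report a single operating
point rather than a full ROC curve.

## The synthetic study generator

The generator (`simulate_study()`) exists because annotation data from real
observer studies are typically private; it produces studies with the
statistical structure the analysis assumes, so that the pipeline can be
tested, calibrated, and demonstrated end to end. The latent model is
equal-variance binormal with a shared case effect. Slice truth
$D_i \sim \mathrm{Bernoulli}(\pi)$ (default $\pi = 19/61$), grouped into
patients with 5–7 slices each. Reader $r$ in session $s$ sees

$$x_{irs} = d_r D_i + \lambda_r \eta_i +
  \frac{u_{ir} + \tau v_{irs}}{\sqrt{1+\tau^2}},$$

* $d_r \ge 0$ — the reader's discrimination (standardized mean shift);
* $\eta_i \sim N(0, \sigma_c^2)$ — a case effect shared by all readers
  (some slices *look* suspicious regardless of truth), with a per-reader
  loading $\lambda_r$: readers with a common training background pick up
  more of this shared perception and therefore agree with one another beyond
  what the truth alone induces;
* $u_{ir} \sim N(0,1)$ — reader-slice noise shared across sessions, and
  $v_{irs} \sim N(0,1)$ session-specific noise mixed in with weight
  $\tau$ (`intra_session_noise`); the normalization keeps the marginal
  noise variance at 1 for every $\tau$, so test–retest consistency can be
  tuned without moving accuracy. At $\tau = 0$ the two sessions see the
  same draw and Cohen's kappa is exactly 1.

The continuous-score AUC has the closed form
`theoretical_auc(d, sigma_c)` $= \Phi\!\left(d/\sqrt{2(1+\sigma_c^2)}\right)$
(with $\sigma_c$ replaced by $\lambda_r\sigma_c$ for a reader with loading
$\lambda_r$), and `discrimination_for_auc()` inverts it; parameter-recovery
tests generate a reader at a target AUC and re-measure it from the simulated
latent scores. The latent signal is cut into the ordinal score 0–5 at five
fixed cutpoints, and every score ≥ 1 emits one bounding box at a random
location — box geometry is cosmetic, since the analysis is slice-level.

### Default parameters and why

`simulate_benchmark_study()` produces the canonical design: 10 patients, 61
sagittal slices (nine patients contribute 6, one contributes 7), exactly 19
positive slices spread over 7 positive patients, and a 15-reader panel with
the experience values, clinical thresholds and 3-reader consensus subset of
the motivating study; five readers (obs02, obs03, obs04, obs07, obs15) read
twice. Its generator defaults were fixed once, by simulation over 40 seeds,
to land the analysis outputs in the regime such studies report:

| parameter | default | rationale |
|---|---|---|
| $d_r$ | 0.85 + 0.4·(high-year) + 0.4·(high-cine) | group AUCs ≈ 0.65 (low) to 0.77 (high), matching reported group AUCs around 0.7 |
| $\lambda_r$ | 0.4 + 0.5·(high-year) + 0.5·(high-cine) | group Fleiss' kappa ≈ 0.05–0.08 (low groups) vs ≈ 0.33–0.40 (high groups and consensus), the reported poor-to-fair band |
| $\sigma_c$ | 1 | one unit of shared "suspicious appearance" per unit of reader noise |
| $\tau$ | 1.2 | between-session noise correlation 0.41, putting intra-observer Cohen's kappa near 0.5 |
| cutpoints | 0.97, 1.60, 2.24, 2.94, 3.85 | an experienced reader annotates ≈ 40% of slices and uses higher confidence progressively more sparingly; the panel-wide annotation rate is ≈ 34% |

Two design choices deserve emphasis. First, the cutpoints deliberately put
the majority of the marginal score mass at 0: cutpoints giving roughly
uniform score frequencies would have every reader annotating over 80% of
slices, which no reader panel does, and which collapses unanimity agreement
far below anything a real study reports. Second, the per-reader loading
$\lambda_r$ is what lets the generator reproduce the reported *agreement*
pattern at realistic accuracy: with a single shared case effect, group
kappa differences are driven by discrimination alone and are too small to
be stable at 61 slices, whereas shared-perception differences make the
high-experience groups' kappa exceed the low-experience groups' in every
simulated replicate.

### What the generator does and does not emulate

It emulates: the design counts (patients, slices, positives, readers,
consensus subset, repeat readers), ordinal scoring through per-reader
thresholds, experience-linked accuracy and agreement, within-slice
correlation across readers, and test–retest variability. It does **not**
emulate: localization (box positions are random, so spatial agreement is
meaningless here), transverse slices, learning effects between sessions,
reader-specific bias in score usage beyond the shared cutpoints, or the
consensus meeting process — the synthetic reference standard is generative
truth, not a panel decision. One known discrepancy: in this model
high-experience readers call more positives and therefore have *lower*
unanimity percentage agreement than low-experience groups, while the
motivating study reported the opposite ordering for that metric (its kappa
ordering, which chance-corrects the call rates, is reproduced). Passing
tests on synthetic data show the machinery is correct and calibrated; they
cannot show that real cine-MRI readers behave like the latent model.

## Numerical and degenerate-input choices

* Cohort percentages round half-up to integer percent (15/64 → 23%); the
  positive and negative percentages can therefore sum to 99 or 101.
* Stratified patient sampling (`stratified_sample()`) draws
  ceiling(fraction·n) per stratum by default; `floor` and `round` are
  available because the rounding rule is genuinely a convention. (At
  fraction 0.2 with strata of 15 and 49, ceiling gives 3 + 10 — there is no
  uniform rounding under which the motivating study's 3 + 7 = 10 sampled
  patients arise from those strata, so the arithmetic is left configurable
  rather than guessed.)
* Undefined kappa (single pooled category, or identical constant ratings for
  Cohen's kappa) is an error, never a silent number; inside the bootstrap it
  is a dropped-and-counted resample.
* Intersections in diagonal averaging are found by linear interpolation on
  the vertex offsets; duplicate vertices are collapsed first, and the grid
  always contains each curve's own vertex offsets, so no root-finding
  tolerance is needed beyond floating point.
* All resampling functions take a mandatory integer seed and are
  reproducible bit for bit; `run_analysis()` derives an independent
  deterministic seed per stage and group from the master seed, so adding or
  removing a group does not shift any other group's resamples.

## Problem sizes used by the test suite

The suite validates the statistics against independent oracles (loop-based
kappa formulas, pairwise AUC enumeration, analytic curve geometry) at
1e-12, and exercises the resampling machinery at the study's own scale:
permutation type-I error over 1000 simulated 61-slice null studies with 16
readers (band 0.03–0.07 at nominal 0.05), bootstrap CI coverage for Fleiss'
kappa over 500 simulated 15-reader studies against the numerically
integrated population kappa (band 90–98%), AUC parameter recovery at 10,000
slices (±0.02), group-difference power at 10 readers and 500 slices
(>80%), and the qualitative experience pattern of the canonical design
across 20 seeds. These sizes keep the full suite within a few minutes on
one CPU while leaving Monte-Carlo error well inside each band.

## Limitations

The package analyzes binary slice-level calls only: no weighted kappa, no
more-than-two categories, no localization or free-response (FROC) scoring,
no partial AUC, and no model-based agreement estimators. The group AUC
variance estimator is a two-way bootstrap, not the U-statistic estimator of
dedicated MRMC software, and is mildly conservative for group comparisons.
The synthetic generator's parameters are calibrated to reproduce reported
summary statistics, not fitted to any real annotation data.
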