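---
title: "Composite weighted degree analysis of functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite weighted degree analysis of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HubDegree)
```

## The model

HubDegree studies hub centrality in resting-state functional connectomes and
its relation to working-memory performance. A cortical parcellation assigns
each of $n$ parcels (graph nodes) to one network community; here the package
emulates a 333-parcel scheme with 12 networks plus an "unassigned" class.
Functional connectivity between parcels $i$ and $j$ is the Pearson correlation
of their cleaned mean signal time courses, Fisher z-transformed; negative
correlations are removed (set to zero) so that edge weights $a_{ij} \ge 0$
admit an unambiguous "connection strength" reading.

Hub centrality is *weighted degree*,

$$k_i = \sum_{j=1}^{n} a_{ij},$$

computed not on the full matrix but on graphs thresholded to a fixed edge
density. Because any single density is arbitrary, the matrix is thresholded at
2–10% density in 1% steps and the nine degree vectors are summed into a
*composite* weighted degree. Equivalently, each edge contributes its weight
once per density at which it survives, so edges in the top 2% count nine times
and edges between the 9% and 10% cut count once. Thresholds are proportional:
at density $d$ the $m = \max(1, \lfloor d\,n(n-1)/2 \rfloor)$ strongest edges
are retained with their weights. The floor-with-minimum-one rule keeps tiny
densities from producing empty graphs, and ties are broken by ascending
$(i,j)$ index so the operation is deterministic on synthetic data where exact
ties occur.

Composite degree decomposes exactly into a within-network and a
between-network part: the *same* thresholded graphs are reused and each
surviving edge is classed by whether its endpoints share a network label, so
`within + between = total` holds to machine precision at every density
(`partitionDegree()` returns all three).

## Preprocessing and quality control

Head motion is summarized per volume by framewise displacement. The six
rigid-body realignment parameters give

$$\mathrm{FD}_t = \sum_{\text{translations}} |\Delta x| \;+\; 50\,\mathrm{mm}
\sum_{\text{rotations}} |\Delta \theta|,$$

the sum-of-absolute-backward-differences convention with rotations converted
to arc length on a 50 mm sphere; the first volume's FD is defined as 0.
Subjects with mean FD above 0.25 mm are excluded; volumes with FD above
0.5 mm are scrubbed — dropped from the correlation computation only, not from
the filtering, because scrubbing targets the connectivity estimate rather
than the signal model.

Cleaning regresses an intercept plus the supplied confound columns (the
pipeline uses the six motion parameters plus the global signal; tissue-based
regressors enter as additional generic columns) out of every parcel series by
ordinary least squares, then band-pass filters the residuals to 0.01–0.08 Hz
with a zero-phase (forward–backward) Butterworth filter. Order 2 is the
default: applied twice, it gives gain 0.98 at 0.05 Hz and 0.04 at 0.005 Hz
for TR = 3 s, and avoids the numerical fragility of high-order IIR designs at
very low normalized frequencies. Filtering runs forwards and backwards so no
phase distortion enters the correlations; outputs are re-centered because the
filter's edge transients leave a small residual mean. Fisher's z is applied
with $r$ clipped to $\pm(1 - 10^{-7})$ so degenerate (perfectly correlated)
synthetic inputs stay finite; since $\mathrm{atanh}$ preserves sign, removing
negative correlations after the transform is equivalent to removing them
before.

## Inference

**Group differences.** Per parcel, the statistic is the difference of group
means of composite degree. The null is built from 5000 random reassignments
of the group labels; one shared label shuffle per iteration is reused across
all parcels, preserving the cross-parcel dependence of the null. The p value
is the plain proportion of permuted |differences| at least as large as the
observed one (two-sided via absolute values; the underlying report's wording
reads one-sided, but effects in both directions are reported, so two-sided is
the default with a `alternative` switch). p = 0 is possible by this
definition; an optional (b+1)/(m+1) correction is available but off by
default. Benjamini–Hochberg adjustment across parcels controls FDR at 5%,
and Cohen's d (pooled SD, $n_a + n_b - 2$ denominator) is attached as the
effect size.

**Brain–behavior correlations.** Per parcel, Pearson r between composite
degree and the behavioral outcome. 5000 reshuffles of the behavior vector
estimate the standard error of r at each node; $z = r/\mathrm{SE}$ gives a
two-tailed normal p, again BH-adjusted. Because two outcomes form the family
(combined accuracy and combined reaction time), the significance flag uses
q < 0.025, a Bonferroni-corrected family threshold.

**Behavioral comparisons.** The classical pooled-variance two-sample t test
is the default (`tTestSummary()` also accepts published group summaries
directly); Welch is a flag. Per-load p values are reported uncorrected across
loads. Combined accuracy is the unweighted mean over loads 1/3/5/7; combined
reaction time is trial-count-weighted when counts are supplied, since RT is
averaged over trials rather than load cells.

**Post-hoc decomposition.** For parcels whose degree correlates with behavior
exclusively in one group — significant (q below the family threshold) in that
group and not even nominally significant (p ≥ 0.05) in the other; the
"exclusive" rule is configurable since only its first half is forced — the
within- and between-network degree components are correlated with the outcome
separately at an uncorrected 0.05 level.

## Prediction

Degree-based connectome predictive modeling under leave-one-out
cross-validation: in each fold, parcels whose training-set correlation with
behavior has parametric p < 0.01 enter the positive (r > 0) or negative
(r < 0) feature set; the combined summary score is the positive-set degree
sum minus the negative-set sum (a two-predictor positive/negative variant is
deliberately out of the default path — the combined score is the reported
protocol); a one-variable least-squares line from score to behavior, fitted
on the training subjects only, predicts the held-out subject. Predictive
power is the Pearson correlation of predicted and observed behavior over all
N folds, and significance reruns the entire LOOCV on each of 1000 behavior
reshuffles (p = proportion of null r at least the observed r). Folds that
select no features predict the training mean — across a whole null run this
yields r = −1 (the training mean is affine-decreasing in the held-out value),
a conservative convention that lets null simulations complete without
special-casing. Per-parcel *prevalence*, the fraction of folds selecting the
parcel, summarizes feature stability.

The permutation null here has a noticeably heavy right tail: a spurious
feature with a large full-sample correlation is selected in almost every fold
and survives cross-validation, so null prediction r values of 0.2–0.3 occur
regularly at N = 60. Rerunning the full selection inside every permutation is
what keeps the test honest about this.

## The synthetic cohort generator

The generator exists so every stage is testable without imaging data. It
emulates exactly the second-order structure the analysis consumes:

- **Time series**: zero-mean multivariate normal draws with a block
  correlation matrix — `rhoWithin` (default 0.30) inside a network,
  `rhoBetween` (0.05) across networks, and designated hub parcels whose
  rows/columns are raised to `rhoHub` (0.25). Patients receive an additive
  `groupDelta` (−0.06) on hub correlations, planting a group difference in
  hub degree of moderate effect size. Naive block-plus-hub constructions can
  be indefinite, so the matrix is repaired by clipping eigenvalues below
  1e-8 and re-symmetrizing before sampling.
- **Motion**: rotations follow a smooth bounded random walk, translations a
  bounded random walk plus Bernoulli spike volumes (rate 0.01) whose jumps
  exceed the 0.5 mm scrub threshold. Spikes are translation-only — the
  simplest construction that exercises both QC rules. Step sizes give a
  typical mean FD near 0.11 mm and roughly 1–3% scrubbed volumes, ordinary
  values for a compliant resting-state cohort.
- **Behavior**: combined accuracy is `intercept + group offset + beta ×
  (mean composite degree over the coupling nodes, centered at the cohort
  mean) + N(0, sigmaY)`; per-load values sit around the combined value with
  fixed load offsets and small noise, clipped to [0, 100]. Centering makes
  the intercepts meaningful at any parcel count. Defaults (intercept 91.5%,
  patient offset −7.0, sigmaY 8; RT 879.5 ms, +70.1 ms, SD 130) emulate the
  published cohort's performance table; beta defaults to 0.1 accuracy points
  per degree unit, about a 4-point accuracy SD from degree at the default
  scale — a moderate, realistic coupling chosen once from a pilot run of the
  generator, not fitted to any test.
- **Defaults are the study conditions**: 333 parcels in 12 networks plus an
  unassigned class (block sizes mirroring the emulated parcellation), 29
  patients and 29 controls, 120 volumes at TR = 3 s (a 6-minute run).

All randomness flows from one top-level integer seed: stream $i$ uses
`childSeed(seed, i)` = `(seed + 104729 i) mod (2^31 - 2)`, so a cohort is a
pure function of its seed and identical configurations are byte-identical on
disk.

What the generator does *not* emulate: hemodynamics, autocorrelated BOLD
noise, physiological rhythms, spatial smoothness, scanner drift, or any
anatomical meaning for specific parcels. Passing tests therefore demonstrate
that the machinery is correct and calibrated under the assumed second-order
structure, not that the published dataset's specific regional findings would
reproduce.

## Problem sizes used in the test suite

The statistical checks run at deliberately chosen scales: calibration pools
60 null cohorts of 58 subjects × 30 parcels (≈1800 permutation p values) for
the uniformity and FDR checks; group-difference power plants a d = 1.5 shift
at one of 200 parcels (29 + 29 subjects, 100 replicates); CPM recovery uses
generator degrees at 60 parcels for N = 60 with noise calibrated to true
R² = 0.25 against a 150-subject pilot estimate of the coupled-degree
variance; the null-optimism check uses the full 58 × 333 layout. These sizes
make the Monte-Carlo error small relative to each acceptance band while the
suite stays conveniently rerunnable.

## Numerical choices and edge cases

- Fisher z clipping at $|r| = 1 - 10^{-7}$; zero-variance parcels get zero
  edges with a warning rather than NA propagation.
- Rank-deficient confound matrices drop collinear columns with a warning.
- The all-zero connectivity matrix thresholds to itself with a warning.
- Permutation p values use plain proportions (anti-conservative at p = 0) to
  match the stated definition; the (b+1)/(m+1) variant is one flag away.
- Degree ties at a threshold boundary resolve by index order, making every
  result reproducible bit-for-bit for a given seed.

## Known limitations

Voxel-level preprocessing (registration, segmentation, smoothing, CompCor's
eigen-decomposition of tissue voxels) is out of scope: the package starts
from parcel × time tables, and tissue confounds enter as plain columns.
Binary degree, other graph metrics (efficiency, clustering, betweenness) and
k-fold variants beyond LOOCV are deliberately not provided. Group sizes,
effect magnitudes and coupling strengths in the generator are free,
documented parameters — the package makes no calibrated claim about
schizophrenia effect sizes beyond the structure described above.
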