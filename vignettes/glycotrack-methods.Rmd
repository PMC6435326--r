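---
title: "Methods: differential O-glycoproteomics, track metrics and image quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential O-glycoproteomics, track metrics and image quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotrack)
```

This vignette documents the statistical model behind each quantification in
glycotrack, the parameters a user may want to change, the numerical
conventions at boundaries and degenerate inputs, and what the synthetic-data
generators do and do not emulate.

## 1. The differential glycoproteomics model

### Ratios and their orientation

Dimethyl isotope labelling yields, per identified glycopeptide
spectrum (PSM), a light-channel intensity (mutant genotype, CH2O label) and
a medium-channel intensity (control genotype, CD2O label). The quantity of
interest is

\[ r = \log_{10}\frac{I_\text{light}}{I_\text{medium}}, \]

so $r < 0$ means less of that glycopeptide in the mutant. Some precursors
appear without an isotope partner ("singletons"); they carry no ratio.
`compute_log_ratio()` returns `NA` for these — an explicit *unquantifiable*
signal, never zero — and every downstream stage excludes them from ratio
statistics while still counting them as evidence that a glycoform occupies
a site. No pseudo-count imputation is performed for missing or zero
intensities; such records are simply treated as unpaired.

### The empirical null and the candidate cutoff

Peptides in the lectin-column flow-through are not glycosylated, so their
ratios reflect only labelling and measurement noise. `fit_null_model()`
assumes this null is normal, estimates $\hat\mu$ and $\hat\sigma$ by sample
moments, and sets the candidate cutoff to the half-width of the central
`coverage` interval, $z\,\hat\sigma$ with $z = \Phi^{-1}((1+\text{coverage})/2)$.

The default `coverage = 0.9973` is chosen to be exactly the two-sided
3-sigma mass of a normal ($2\Phi(3)-1$), so the default cutoff is
$3\hat\sigma$; on flow-through data with $\sigma \approx 0.183$ that is the
familiar working cutoff of ±0.55 log10 units (≈ 3.6-fold). Writing the
coverage as "99.7%" and using $z = 3$ are the same convention; we prefer the
exact 3-sigma formulation because it makes the false-positive rate of
candidate selection ($1 - \text{coverage} = 0.27\%$) analytic.

`select_candidates()` uses a *strict* inequality: a ratio exactly on the
cutoff is not a candidate. Fitting requires at least 30 finite ratios and
non-zero variance; anything less raises a degenerate-input error rather
than returning a silently useless model.

### Fold-change tiers

Classification (`classify_fold_change()`) is deliberately separate from
candidate selection and uses the literal fold thresholds: `t3 = log10(3)`
(≈ 0.477) and `t10 = 1`. Boundaries are inclusive towards the stronger
category (`|r| = t3` is a three-fold change; `|r| = t10` is ten-fold),
whereas candidate selection is exclusive at its cutoff; both conventions
are configurable. Because the fitted null cutoff (≈ 0.55) and the 3x bound
(0.477) differ, the report echoes both, including the fold-change
equivalent of the null cutoff, so the discrepancy is visible rather than
hidden. The tiers nest by construction: every ten-fold site is also beyond
the three-fold bound.

### Aggregation and summaries

A glycosite is keyed by (protein accession, 1-based residue position in the
protein, residue letter); `site_position_in_protein()` converts
peptide-relative modification positions given the peptide start. Two
records agreeing on protein and position but not on residue are a
data-integrity error, not a fourth key.

Within a site, each glycoform's ratio is the **median** of its paired PSM
ratios. The choice is ours (nothing in the upstream search pipeline dictates
an aggregation); the median is robust to a single aberrant spectrum, and
with the typical 1–3 PSMs per site it coincides with the mean under
symmetric noise. A site's glycoform class is the union of observed
glycoforms — `Tn-only`, `T-only` or `both` — where singleton records count
as observations.

At the protein level, `summarize_proteins()` reports the site count, the
class (`both` as soon as glycoforms mix anywhere on the protein), the
strongest signed site change, and the *direct-target* flag: some site
decreased at least three-fold while another quantified site on the same
protein did not decrease. The rationale: if every site drops together, a
lower protein level explains the data; a site-specific drop implicates
glycosylation itself. Sites quantified by no paired PSM contribute no
evidence either way, and single-site proteins can never be flagged.

`compare_multiplicity()` is a two-sided Mann–Whitney U test
(`stats::wilcox.test`, normal approximation with tie and continuity
correction) on per-protein glycosite counts. Multiplicity counts are small
integers with heavy ties, which rules out the exact U distribution; the
tie-corrected normal approximation agrees with a brute-force permutation
null to within 0.02 on 10-vs-10 inputs (tested).

### Report percentages

Percentages within one classification axis are rounded by largest
remainder so each axis sums to exactly 100 — naive per-entry rounding can
drift by a full percentage point. Class and multiplicity axes are reported
at integer precision, the S/T/Y residue split at 0.1%.

## 2. Track metrics

Tracks are ordered 3D nucleus positions in micrometres with strictly
increasing, uniformly spaced timestamps (non-uniform spacing is rejected:
the metrics below assume a constant frame interval, 40 s in the default
configuration).

* **Instantaneous speed**: step displacement over step duration, reported
  in um/min regardless of the time unit of `dt`.
* **Condition mean speed**: each track's steps are averaged first, then
  tracks are averaged with one vote each, so long tracks do not dominate;
  the SE is across tracks. A single-track condition returns `se = NA` with
  a flag rather than a fabricated zero.
* **Directionality**: per 10-frame segment, net displacement divided by
  summed path length (1 = straight; a segment returning to its start
  scores 0; a perfectly stationary segment is defined as 0 and flagged,
  since 0/0 has no physical meaning here). Segment values are averaged per
  track, then across tracks. Two windowings are offered because "fixed
  segments" and "sliding window" describe different estimators: the
  default tiles consecutive segments that share their boundary frame
  (every step enters exactly one segment); `overlapping = TRUE` slides by
  one frame. The choice is recorded in the result's `windowing` attribute.
  Trailing frames short of a window are dropped from directionality but
  still contribute to speed; tracks shorter than one window are excluded
  from condition averages and counted.
* **Entry time**: the boundary is supplied externally (a per-axis planar
  threshold or arbitrary predicates), never inferred from images. T0 is
  the earliest time *any* track satisfies the edge predicate, T1 the
  earliest time any track is inside; the two may come from different
  cells. No crossing raises a classed no-entry condition, distinct from
  invalid input.
* **Percent reduction**: `round((control - test)/control * 100)` to the
  nearest integer, the form in which condition comparisons are quoted.

## 3. Image quantifications

* **Pearson colocalization** is the plain sample correlation over unmasked
  pixels. No automatic thresholding (Costes-style) is applied; results are
  therefore invariant under positive affine rescaling of either channel,
  and a constant channel raises an undefined-correlation error.
* **Arbitrary units**: per measurement, background ROI mean is subtracted
  from signal ROI mean individually; each difference is divided by the mean
  difference of that imaging day's controls. A day-specific multiplicative
  gain (laser power, staining strength) cancels exactly, and each day's
  control group averages to 1 by construction. ROI geometry is the caller's
  concern — this module consumes ROI means. A day without controls
  requires an explicit reference divisor; otherwise it is an error.
* **Line profiles** sample `n_samples` equidistant points between two
  micrometre endpoints with bilinear interpolation between pixel centres.
  Pixels are 0-based with origin top-left; pixel (i, j) has its centre at
  (j·px, i·px), so sampling at centres reproduces raw values exactly.
  Endpoints outside the raster are an error rather than clamped.
* **Border-cell migration** is the scalar projection of the observed
  displacement onto the origin→target axis as a percentage of the full
  distance. Values outside [0, 100] are reported raw alongside a clamped
  value and a flag, so overshoot is visible.

## 4. What the generators emulate

`simulate_glyco_dataset()` draws, per protein, a glycosite count (default:
44% single-site, 20% two-site, geometric tail), per site a residue
(S/T/Y at 21.2/78.5/0.3%), a glycoform class and a true log10 effect
(0 for unchanged sites). PSM intensities are log-normal — the standard
rough model for MS intensities, and immaterial downstream since only
ratios are used — with the light channel set to medium × 10^(effect +
N(0, null_sigma)). Default class probabilities are 0.77/0.04/0.19 for
Tn-only/T-only/both: wild-type embryonic glycoproteomes are dominated by
Tn-only sites with a small solely-T fraction, and the three probabilities
must sum to 1, which fixes the mixed class at 0.19 once the two
better-determined ones are set. Ground truth is returned as a separate
table, never embedded in the record table.

The generator does **not** emulate spectra, retention time, charge states,
protein-level abundance correlation between sites, or any structure in
*which* sites change; passing tests therefore demonstrate the estimators'
correctness and calibration, not robustness to identification errors or
interference, which real data can add.

`simulate_tracks()` is a fixed-step-length persistent random walk: each
step has length `speed · dt / 60` and the new heading is the normalized
mix `persistence · previous + (1 − persistence) · random unit vector`.
This is the simplest model exposing both speed and directionality ground
truth: instantaneous speed is exact by construction, the persistence → 1
limit is a straight line, persistence = 0 is an isotropic walk. It does
not model speed fluctuations, confinement by tissue geometry, or
cell–cell interactions. `simulate_image_pair()` constructs two Gaussian
rasters with exact target correlation in expectation
(`b = ρ·a + sqrt(1−ρ²)·noise`); it contains no spatial structure, so it
validates the correlation estimator, not segmentation or ROI placement.

All generators take an explicit seed and run on a private RNG stream,
restoring the caller's `.Random.seed`; fixed seed implies bit-identical
output.

## 5. Problem sizes and tolerances in the test suite

The suite runs at desk scale: null-calibration checks use 2×10^5 simulated
flow-through ratios (Monte-Carlo SE of the coverage ≈ 0.01 percentage
points), candidate false-positive rates use 4×10^4 null ratios against a
3·binomial-SE band, spiked-recovery checks use ~120 proteins with ±1 log10
effects at null sigma 0.1 (≥ 10σ separation, so sensitivity and sign
accuracy are exactly 1), and the random-walk directionality estimate from
~1,500 ten-frame segments is compared to an independent 3–4×10^4-sample
Monte-Carlo oracle within 2%. These sizes keep every stochastic assertion
at ≥ 3 standard errors from its pass boundary.

## 6. Known limitations

* The null model is moment-based; heavy-tailed flow-through distributions
  would widen σ and make the cutoff conservative. A robust (quantile-based)
  fit would be a natural extension.
* Glycoform classes stop at the Tn/T (HexNAc/HexHexNAc) dichotomy; no
  glycan structures beyond it.
* The entry-time boundary is planar or user-supplied; curved, moving
  tissue boundaries must be encoded by the caller as per-frame predicates.
* Pearson colocalization is whole-mask; objects of interest occupying a
  small fraction of the mask dilute the coefficient.
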