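---
title: "Methods: AUROC discrimination of posterior-pole thickness grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AUROC discrimination of posterior-pole thickness grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppoleauc)
```

## The problem and the data

Neurodegenerative diseases thin specific layers of the retina, and OCT
posterior-pole scans quantify that thinning as an 8×8 grid of mean
thicknesses (µm) per retinal layer, each cell covering 3°×3° of a macular
cube centred on the fovea. This package analyses four layers — RNFL, GCL,
IPL and ONL — and asks, for each layer and each of nine anatomical
regions, how well the per-eye regional mean thickness discriminates two
cohorts (healthy controls, MS, AD, or the pooled patients).

Two geometric conventions anchor everything:

* **Coordinates.** Rows and columns are 1-based; after normalization cell
  (1,1) is the infero-temporal corner and (8,8) the supero-nasal corner.
  Rows run inferior → superior and columns temporal → nasal; the optic
  disc lies off the nasal edge.
* **Laterality.** Left-eye grids are mirrored about the vertical axis
  (column *c* → 9 − *c*) so nasal/temporal anatomy lines up across eyes.
  The mirror is an involution and `normalize_laterality()` is idempotent;
  an analysis of pre-mirrored grids is identical to one that normalizes on
  the way in (this equivariance is tested).

Scan quality uses the device's 0–40 score; only grids scoring **strictly
above 25** are analysed. Individual cells may be missing: regional means
skip missing cells, and a region with no present cells yields a missing
observation that is excluded pairwise from the AUROC samples. By default
each eye is one analysis unit (matching a design that counts eyes per
group); `one_eye_per_subject()` provides the conservative alternative when
within-subject correlation between fellow eyes is a concern.

## Parcellation

The nine regions come in two families: concentric rings (FOVEAL,
PARAFOVEAL, PERIFOVEAL) and zones (PMB, PARAMACULAR, SN, IN, IT, ST).
Regions are disjoint *within* a family only — a cell can lie in one ring
and one zone. Exact cell memberships are a configurable JSON input because
region definitions in this literature are typically given pictorially; the
packaged default is an explicit, validated approximation:

* FOVEAL: central 2×2 block {(4,4),(4,5),(5,4),(5,5)};
* PARAFOVEAL: the 12-cell ring around it (rows/cols 3–6 minus the fovea);
* PERIFOVEAL: the 20-cell ring around that (rows/cols 2–7 minus the inner
  4×4);
* PMB: rows 4–5 × columns 6–8, the nasal band between fovea and disc
  carrying the papillomacular bundle;
* PARAMACULAR: the parafoveal ring minus its two PMB cells;
* SN/IN/IT/ST: the remaining cells split by quadrant about the grid
  centre, so the six zones partition all 64 cells.

`parcellation()` validates bounds, non-emptiness, within-family
disjointness and structural concentricity (each ring is 8-adjacent to the
ring it encloses), and every comparison table records the parcellation
name in its provenance. Cells are equal-area, so regional means are
unweighted.

## The discrimination statistic

For measurement sets X and Y, `auroc()` computes
AUROC = Prob(X > Y) = U/(n_X·n_Y) with the tie-aware U (half credit per
tied pair, via midranks). Reported values are folded to
max(A, 1 − A) ∈ [0.5, 1], because the direction of a difference is
captured separately by which group is thicker; folding makes every result
invariant to the orientation of the comparison. A folded AUROC **strictly
greater than 0.75** is flagged significant — a fixed effect-size
threshold, deliberately not a p-value, and no multiplicity adjustment is
applied across the 36 layer×region cells (the report states this).

### Confidence intervals

The CI method is configurable and logged:

* `bootstrap` (default): percentile bootstrap on the folded AUROC,
  resampling the two groups independently with replacement, n_boot = 2000,
  seeded and deterministic. Chosen as the default because it respects the
  folded [0.5, 1] scale without normality assumptions.
* `hanley`: normal interval with the Hanley–McNeil variance.
* `delong`: normal interval with the DeLong placement-value variance
  (cross-checked against `pROC` in the tests).

Intervals are clipped below at 0.5 to match the folded reporting scale;
the unclipped bounds are kept in the result so the raw interval remains
recoverable. Two numerical choices keep results reproducible and
orientation-invariant: resampling happens in a deterministic canonical
ordering of the two samples (by size, then sum, then sum of squares), so
swapping the groups cannot change the interval; and each layer×region cell
derives its own seed from the base seed and the cell's indices, so tables
are reproducible cell by cell. Degenerate inputs (fewer than 2 values in a
group) are an error rather than a silent wide interval.

### Sample size

`sample_size_two_means()` implements the normal-approximation two-sample
formula n = (1 + 1/r)·σ²·(z₁₋α/₂ + z_power)²/Δ² per group, rounded up. With
Δ = 6 µm, α = 5% two-sided, 90% power and an assumed σ = 4.5 µm it gives
12 eyes per group; the tests verify the formula against a brute-force
power search over n. σ is a required input: it must come from pilot data
for the instrument and layer, and the package asserts no particular value.

## The synthetic-cohort generator

Real posterior-pole cohorts are rarely shareable, so the generator is a
first-class module. Its model is the simplest one consistent with the
eyes-as-units analysis: for subject *i* of cohort *g*, layer *L*, cell
(r,c),

thickness = baseline_L(r,c) − effect_{g,L}(r,c) + b_i + ε,

with subject effect b_i ~ N(0, σ_subject²) shared across the subject's
cells and iid cell noise ε ~ N(0, σ_cell²), floored at 0. A k-cell
regional mean then has SD σ_total = √(σ_subject² + σ_cell²/k), so a target
folded AUROC for a region is achieved exactly in expectation by the
binormal inversion δ = σ_total·√2·Φ⁻¹(target); outside the targeted region
the effect tapers linearly to zero over one cell.

Default conditions: cohorts of 19 HC / 33 MS / 21 AD subjects, ages
N(69.5, 7²) years, σ_subject = 4 µm and σ_cell = 3 µm — values chosen once
as plausible between-eye biological variation and within-grid measurement
noise for this instrument class; with them, the MS ONL effect implied by
the 0.85 parafoveal target is ≈ 6 µm, the same order as the design's
minimum detectable difference. Calibration targets: HC-vs-MS GCL and IPL
at the PMB 0.95; HC-vs-AD GCL PMB 0.93 and IPL PMB 0.88; AD ONL effect
identically zero; MS ONL parafoveal 0.85 (which drives MS-vs-AD in the
outer retina); RNFL targets 0.62 (MS) and 0.60 (AD), keeping every RNFL
expectation below 0.7. Baseline fields are smooth illustrative templates
(foveal depression with a parafoveal peak for GCL/IPL, foveal ONL peak,
RNFL thickening toward the disc); they are *not* fitted to any published
thickness map, and no test compares absolute thickness to external values.

Quality scores are drawn on [26, 40] so generated grids pass the filter by
construction (`low_quality_fraction` injects sub-threshold grids to
exercise it); laterality alternates OD/OS (or both eyes per subject); left
eyes are emitted mirrored into native orientation so the pipeline's
normalization is exercised for real. Generation is fully deterministic
given the scenario seed and restores the caller's RNG state.

What passing tests on these cohorts do **not** show: Gaussian noise has no
heavy tails or spatial artefact structure; there is no segmentation error,
no floor effects from advanced atrophy, no age/sex confounding, and
fellow-eye correlation beyond the shared subject effect is absent. Results
on real cohorts depend on those features; the synthetic fingerprint checks
the pipeline's statistical machinery, not clinical effect sizes.

## Verification strategy and problem sizes

The test suite pins the statistic to independent oracles: an explicit
pairwise-count loop (1000 random small instances, exact equality including
ties), the binormal closed form at n = 2000 per group, a brute-force power
search for the sample-size formula, and `pROC`'s DeLong interval. Interval
behaviour is checked by simulation: 500 replicates at n = 30 per group
with 2000 bootstrap resamples give ~95% coverage of the true binormal
AUROC (the check accepts 90–99%). Fingerprint recovery runs the full
pipeline at 200 subjects per group, where Monte-Carlo error on an AUROC is
about ±0.03 — small enough to separate the calibrated targets from the
0.75 and 0.7 boundaries. These sizes were chosen so each property is
decisively powered while the whole suite stays quick to run.

## Known limitations

* The default parcellation is an approximation; analyses of real data
  should supply the parcellation matching their device's region
  definitions and will find it recorded in every output's provenance.
* The 0.75 rule is a fixed threshold, not an error-rate guarantee; with 36
  cells per comparison some cells will cross it by chance at small n.
* Folded reporting discards the direction of a difference; thinning versus
  thickening must be read from the group summaries
  (`summarize_regions()`, which uses Tukey median-of-halves quartiles).
* The bootstrap CI is percentile-based; at very small n (< ~10 per group)
  its coverage degrades and the closed-form alternatives are no better —
  interpret such intervals cautiously.
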