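# ppoleauc

Discrimination analysis of posterior-pole OCT retinal-layer thickness
grids.

Multiple sclerosis (MS) and Alzheimer's disease (AD) both thin the
neuroretina, and optical coherence tomography (OCT) measures that thinning
in vivo. The Spectralis Posterior Pole protocol reports each retinal layer
as an 8×8 grid of mean thicknesses (64 cells of 3°×3° each) centred on the
fovea. `ppoleauc` is for researchers who want to ask, from such grids,
*which layers and which retinal regions separate two cohorts* — patients
from controls, or one disease from the other — using a simple,
assumption-light discrimination statistic.

## The statistic

For two sets of measurements X and Y (per-eye mean thickness of one layer
in one region), the package computes the area under the ROC curve via the
Mann–Whitney U statistic:

    AUROC = Prob(X > Y) = U / (n_X · n_Y),
    U = Σ_{i,j} [ 1·(x_i > y_j) + ½·(x_i = y_j) ]

Reporting is direction-agnostic: the *folded* AUROC `max(A, 1−A) ∈ [0.5, 1]`
is given a 95% confidence interval (percentile bootstrap by default;
Hanley–McNeil and DeLong closed forms as alternatives) and a folded AUROC
strictly greater than **0.75** is flagged as a significant difference. No
multiplicity adjustment is applied across the 4 layers × 9 regions.

The pipeline around the statistic handles the geometry: left eyes are
mirrored to the right-eye convention (cell (1,1) infero-temporal, (8,8)
supero-nasal), scans with quality score ≤ 25 are excluded, and the grid is
parcellated into three concentric rings (foveal, parafoveal, perifoveal)
and six zones (papillomacular bundle, paramacular, and the four
quadrants SN/IN/IT/ST). The parcellation is a configurable JSON input; the
packaged default is a documented approximation.

Because clinical grids are rarely shareable, the package includes a
synthetic-cohort generator whose layer×region thinning effects are
calibrated through the binormal model (`AUROC = Φ(δ/(σ√2))`) to reproduce
the qualitative diagnostic fingerprint: ganglion-cell and inner-plexiform
thinning separates patients from controls, outer-nuclear thinning
separates MS from AD, and the nerve-fibre layer separates almost nothing.

## Worked example

```r
library(ppoleauc)

parc <- default_parcellation()
scenario <- default_scenario(parc)          # 19 HC / 33 MS / 21 AD subjects
subjects <- generate_cohorts(scenario, eyes_per_subject = 1)
subjects <- normalize_subjects(quality_filter_subjects(subjects))

tab <- run_comparison(subjects,
                      comparison_spec("MS_vs_AD", "MS", "AD",
                                      n_boot = 2000, ci_seed = 20231L),
                      parc)
tab
```

```
<comparison_table> MS_vs_AD (MS vs AD), parcellation 'ppole-default'
 layer FOVEAL PARAFOVEAL PERIFOVEAL  PMB PARAMACULAR   SN   IN   IT   ST
  RNFL   0.50       0.56       0.56 0.51        0.57 0.54 0.57 0.59 0.58
   GCL   0.54       0.53       0.56 0.57        0.53 0.57 0.56 0.55 0.57
   IPL   0.53       0.53       0.56 0.57        0.54 0.53 0.54 0.55 0.53
   ONL   0.70       0.84       0.66 0.68        0.83 0.54 0.51 0.53 0.56
```

Each cell is the folded AUROC for one layer × region. Here the outer
nuclear layer (ONL) separates MS from AD in the parafoveal ring (0.84) and
paramacular zone (0.83) — both above the 0.75 threshold — while the RNFL,
GCL and IPL stay near 0.5: between the two diseases, the discriminating
signal sits in the outer retina. `tab$results` holds the full rows
(AUROC, 95% CI, group sizes, significance flags) and
`render_outputs(tab, "results/tables", c("csv", "json", "heatmap"))`
serializes them.

The full analysis is scripted:

```sh
Rscript analysis/01_simulate.R      # scenario + cohort CSV -> results/
Rscript analysis/02_comparisons.R   # four preset comparisons -> results/tables/
Rscript analysis/03_summaries.R     # ONL box-plot summaries, sample sizes
```

Also included: `sample_size_two_means(delta = 6, sigma = 4.5)` returns the
per-group size (12 eyes) needed to detect a 6 μm difference at two-sided
α = 5% and 90% power under the normal approximation.

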