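---
title: "Identifying CAF subsets: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying CAF subsets: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cafsubtypes)
```

`cafsubtypes` identifies five cancer-associated fibroblast (CAF) subsets —
CAF-S1 to CAF-S5 — from four data modalities and quantifies their spatial
and prognostic behaviour. This vignette explains each stage's model and
assumptions, the parameters that matter, the synthetic-data design that
stands in for patient material, and the numerical conventions adopted where
a choice had to be made.

## The subset model

Each subset is an ordinal marker profile over seven activation markers
(FAP, CD29, αSMA, PDPN, CD90, FSP1, PDGFRβ), with six ordered levels from
`Neg` to `High`. `caf_marker_profiles()` ships the five reference profiles;
CAF-S1 is the FAP-high myofibroblast-like subset, CAF-S2/S3 are
quiescent-like low-marker populations, CAF-S4 is FAP-negative but
contractile (αSMA+), and CAF-S5 expresses FAP and PDPN without αSMA.

For profile matching, levels are scored on a midpoint scale: `Neg` = 0,
`Neg-Low` = 0.5, `Low` = 1, `Med` = 2, `Med-High` = 2.5, `High` = 3, so the
hyphenated levels sit exactly halfway between their parents. Only relative
distances matter to the L1 matching, so any affine rescaling of this scale
yields identical assignments.

## Intensity model

Fluorescence has no canonical numeric scale, so `intensity_model()` maps
each ordinal level to a log-normal distribution: log-means 3.0, 3.65, 4.3,
5.6, 6.25, 6.9 (arbitrary log-intensity units) with common log-SD 0.3.
Adjacent levels then have a Bayes error of at most ≈ 0.14, enough overlap
to be realistic but separable enough that clustering can succeed — this
bound is asserted in the tests. The positivity threshold (`exp(3.65)`) sits
at the `Neg`/`Low` midpoint and the high threshold (`exp(6.25)`) at the
`Med`/`High` midpoint; the viability gate is `exp(4)` on the viability dye,
whose live and dead populations have log-means 2 and 6. Per-marker log
offsets support rescaled acquisition channels: multiplying one channel by a
constant and shifting its offset identically leaves every downstream
assignment unchanged (tested).

## Synthetic data: what it emulates and what it does not

The generators reproduce the statistical structure each analysis stage
assumes, with planted ground truth:

* **Flow** (`generate_flow_sample()`, `generate_flow_cohort()`): events are
  mixtures of subset populations plus lineage-positive contaminants
  (EpCAM+/CD45+/CD31+) and dead cells. Cohorts draw per-sample mixtures
  from a Dirichlet around tissue-specific base compositions (concentration
  60, a moderate inter-sample variability chosen once; no published
  quantification of inter-patient heterogeneity exists to calibrate
  against). Defaults enrich CAF-S1/S4/S5 in tumour and CAF-S3 in adjacent
  lung, with CAF-S2 shared.
* **Tissue cores** (`generate_mif_core()`): tumour regions are polygons
  (default two 150 µm discs in a 1 mm² frame); stromal subsets are placed
  by rejection sampling with exponential distance kernels of scale 15, 40
  and 90 µm for CAF-S4, CAF-S1 and CAF-S5, implementing the near-to-far
  ordering S4 < S1 < S5 stochastically. Binary staining truth sets ON
  markers to the `High` level and OFF markers to `Neg`.
* **scRNA** (`generate_scrna_counts()`): negative-binomial counts
  (size 2) with baseline means Gamma(2, 1.5). Marker construction is exact:
  every cell expresses ITGB1/PDGFRB/PDPN/FAP, none expresses S100A4, and
  ACTA2 is positive in CAF-S1 cells only. Planted log2 effects default to
  −2 for the contractility genes TAGLN, TPM2, SPARC, MYL9 and +2 for the
  inflammatory/complement genes C3, SEPP1, C7, CLU (down/up in CAF-S5
  respectively). The gene universe is fixed (markers + these eight + numbered
  fillers); planting a gene outside it is a schema error.
* **Survival** (`generate_survival_cohort()`): exponential event times with
  the hazard multiplied by the planted ratio for the high-risk group;
  censoring times are independent exponentials with the per-subject rate
  chosen so the censoring probability equals `censoring_rate` exactly. The
  bulk design models a latent CAF-S5-dominant subgroup (prevalence 0.15)
  whose FAP/PDPN scores are shifted up and αSMA down by 1.3 log units
  (2.6 SD), so marker-wise cutpoints are recoverable from the data — with
  independent marker scores no faithful per-marker analysis could recover
  the planted phenotype.

Not emulated, deliberately: pixel-level imaging (no PSF, spectral
unmixing, or segmentation noise beyond intensity overlap), spillover and
batch effects, doublets, cell-cycle or patient-level transcriptional
covariates, and non-proportional hazards. Passing tests therefore show the
analysis logic is correct under the assumed structure, not that real data
meet those assumptions.

## Flow gating

Fibroblasts are viable events below the positivity threshold on each of
CD45, EpCAM and CD31. Ties at any threshold count as positive (`>=`)
throughout the package. Gated samples are downsampled uniformly without
replacement to 300 events; a sample with fewer than 300 fibroblasts raises
a `caf_sample_excluded` condition that callers treat as "drop this sample".
Thresholds default to the analytic model values; alternatively
`gate_config_from_controls()` uses the 99th percentile of a designated
negative-control population per marker, the standard isotype-control
surrogate. Group comparisons are unpaired Welch t-tests.

## SOM subtyping

`caf_flowsom()` log-transforms the seven phenotype markers (lineage
markers are never clustered on), z-scales each, and batch-trains a 10×10
rectangular SOM for 20 epochs with a neighbourhood radius shrinking
linearly from half the grid edge to 0.5. Events map to their nearest
codebook node. Occupied nodes are Ward-clustered (`ward.D2`), and the
cluster count is selected automatically as the maximiser of the mean
silhouette width over k = 2…15 — no user-supplied k. A degenerate codebook
(all occupied nodes identical) yields k = 1 with a warning.

Each metacluster is summarised by its per-marker geometric MFI (the
geometric mean is the standard cytometry summary for log-normal
intensities), discretised to the nearest ordinal level by log-mean, and
matched to the reference profiles by minimal L1 score distance; an exact
tie leaves the cluster `unassigned`. The per-marker min-max normalised MFI
matrix (values in [0, 1] per marker) is what `plot()` draws.

Note one scaling consequence: z-scaling stretches whatever variation the
input has to unit variance, so a single-population input yields a codebook
tiling the ±2 scaled-unit cloud rather than collapsing to a point; the
meaningful degenerate-input invariant (and the one tested) is that the
occupancy-weighted codebook centroid matches the population mean.

## MIF classification

Cells are called per channel against one global threshold each (a single
threshold across the whole collection, never per core); the default is
Otsu's criterion computed on log-intensities, where the two-component
mixture is near-symmetric. Otsu requires the channel to actually show both
populations somewhere in the collection: for data in which a marker is OFF
in every cell there is no valley to find, and `mif_thresholds_from_model()`
(or any explicit vector) should be supplied instead.

The default ruleset omits CD90 (CAF-S1: FAP⁺ αSMA⁺ FSP1⁻ PDPN⁺; CAF-S4:
FAP⁻ αSMA⁺ FSP1⁻ PDPN⁻; CAF-S5: FAP⁺ αSMA⁻ FSP1⁻ PDPN⁺), because CD90
staining is typically too sparse to classify on; the CD90-bearing variant
is available as `caf_binary_ruleset("with_CD90")`. Mutual exclusivity of
every ruleset is proven at construction by enumerating all ON/OFF call
vectors. Subset percentages are taken over "total CAFs" — stromal cells ON
for at least one CAF marker — with non-matching CAFs reported as `other`;
percentages plus `other` sum to 100 per core.

## Spatial analysis

Distance is Euclidean point-to-boundary (0 inside a region), minimised over
regions, computed exactly from the polygon segments; containment uses a
ray-crossing test. Accuracy is verified against a dense boundary
discretisation oracle to well under 0.5 µm, and rigid-motion invariance to
1e-9 µm. Cells inside tumour regions are non-stromal by construction and
excluded upstream; 0 is the safe convention if one slips through. Pairwise
subset comparisons use Welch tests with Benjamini–Hochberg correction — the
same control intent as classical multiple-comparison procedures but
simpler to verify.

## scRNA differential expression

"Expressed" means count > 0 exactly; the filter and the αSMA split are
deterministic and idempotent. Differential expression uses a two-sided
Wilcoxon rank-sum test per gene on log1p counts-per-million, an
assumption-light engine whose acceptance surface is effect *direction*, not
exact p-values; genes expressed in fewer than 3 cells are not tested, and a
gene with no variation after normalisation gets p = 1. BH correction runs
over tested genes only. `top_genes()` orders by q, then |log2 FC|
descending, then symbol. The log2 fold-change is the difference of group
means of log2(CPM + 1) (CAF-S5 minus CAF-S1), which makes the label-swap
antisymmetry exact.

## Survival analysis

Kaplan–Meier estimation and the log-rank test delegate to the `survival`
package (product-limit estimator; observed-minus-expected with
hypergeometric variance). `median_split()` puts covariate values strictly
above the median in the high group; ties go low. The maximally selected
cutpoint search scans midpoints between adjacent unique covariate values,
keeps splits leaving both groups at least `minprop` (default 0.1) of the
cohort, and maximises the absolute standardized log-rank statistic
(score / √variance), ties resolving to the smallest cutpoint; the search is
verified to match an exhaustive `survdiff`-based brute force on every
tested cohort. No selection-bias correction of the maximal statistic's
p-value is applied: downstream reporting uses the log-rank p of the chosen
split, and the cutpoint's own significance should not be over-read. One
caution from the underlying mathematics: the maximal standardized
statistic tends to prefer unbalanced splits, which is exactly why
`minprop` exists. The composite bulk phenotype is FAP > cut ∧ PDPN > cut ∧
αSMA ≤ cut, compared against all other patients. `restrict_followup()`
(default 1826 days) implements five-year horizons; truncation can only
censor, never add events.

## Problem sizes and runtime

The test-suite and acceptance-script sizes are the package's reference
conditions: flow cohorts of 14 + 14 samples at 2000 events gated and
downsampled to 300 (4200–8400 pooled events), 10×10 SOM; tissue cores of
1000–3000 stromal cells; scRNA matrices of 300 genes × 300 cells over 20
seeds; survival cohorts of 60–300 patients with 50–200 replicate seeds for
power and calibration. At these sizes the full pipeline runs in seconds
and the complete validation in well under a minute on one CPU; all sizes
scale up linearly through the exported generator arguments.

## Known limitations

* The ordinal profiles and binary rulesets are fixed vocabularies; novel
  subsets require supplying new profiles.
* Automatic k selection by silhouette favours well-separated, roughly
  convex metaclusters; heavily overlapping subsets may merge (consensus
  clustering would be a more expensive alternative).
* The rank-sum DE engine does not model library-size-dependent dispersion;
  for real single-cell data a count-model engine is preferable when exact
  inference matters.
* Compartment labels (tumour/stroma) are consumed, not computed; tissue
  segmentation is upstream of this package.
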