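---
title: "Methods: invasive-front quantification and prognostic modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: invasive-front quantification and prognostic modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invasivefront)
```

This vignette is the package's own account of its methods: the models and
procedures, the assumptions behind them, the tunable parameters with their
defaults and rationale, the design choices made where the design was
genuinely open, and the known limitations.  It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The analysis model

The unit of measurement is a *field of view*: three co-registered
greyscale rasters (DAPI for nuclei, pan-cytokeratin/Cy3 for epithelium,
D2-40/Cy5 for lymphatic endothelium), with a physical pixel size in µm.
A *section* (one patient) is a set of fields — 15 by default, matching the
practice of capturing evenly spaced high-resolution fields along the
invasive front of a resection specimen.

Analysis is hierarchical, and the hierarchy is the package's central
contract:

1. **Region level.** Every pixel receives exactly one of four labels:
   `tumor`, `stroma`, `lumen_necrosis`, `no_tissue`.  The tumor region is
   the union of pan-CK connected components whose area reaches the
   "main mass" threshold (default 10,000 µm²); pan-CK-negative holes
   enclosed by tumor become lumen/necrosis; remaining tissue is stroma.
2. **Object level.** Connected components of thresholded pan-CK signal
   *inside stroma* are detached epithelial objects (candidate buds, PDCs,
   intravascular clusters); D2-40 components are lymphatic vessels,
   reconstructed as ring-plus-lumen regions so that "inside the vessel"
   is well defined.
3. **Nucleus level.** DAPI blobs declumped by a distance-transform
   watershed.  Each nucleus is assigned to exactly one parent — the
   epithelial object containing its centroid, else the vessel region,
   else its centroid's region class.  Centroid containment was chosen
   over pixel-majority because it is cheap and cannot tie.

Classification then applies the conventional numeric definitions, all
exposed in `feature_class_config()`: a detached stromal object with 1–4
assigned nuclei is a **tumor bud**, one with ≥ 5 a **poorly differentiated
cluster**; an epithelial object with at least half of its pixels inside a
vessel region is intravascular — **minimal LVI** below 5 nuclei, **LVI**
at 5 or more.  The overlap rule (default fraction 0.5, not any-pixel
contact) avoids counting a vessel that merely brushes a gland.  Objects
with zero assigned nuclei (cytokeratin debris) are excluded as
`unresolved` rather than inflating bud counts.  Two scalar summaries
complete the candidate set: lymphatic vessel density (vessels per mm² of
analyzed tissue — the whole tissue area, not stroma only) and the
tumor:stroma ratio (tumor area as % of total tissue).

## The 123-parameter manifest

Per field, the package extracts a declared manifest of exactly 123
parameters (`manifest_default()`), built from the hierarchy levels crossed
with measurement families: counts and areas per class, shape descriptors
(roundness $4\pi A/P^2$, elongation = major/minor axis), distances from
detached clusters to the tumor margin, nearest-neighbour distances,
per-region and per-nucleus channel intensities, and grey-level
co-occurrence texture (contrast, entropy, correlation; 32 grey levels,
distance 1, direction-averaged — a standard, declared parameterization).
The exact composition of the historical 123-parameter set is not
recoverable, so the manifest is versioned package data: the *number* and
the family structure are fixed, the names are the package's own.

Collation to one data point per parameter per patient follows the nature
of each parameter: extensive quantities (counts, summed areas) are summed
over fields, intensive ones (means, ratios, intensities, texture)
averaged.  Intensive features of a class absent from a field are missing
for that field and skipped by the average; a feature missing in every
field collates to 0 and is flagged in a QC attribute, keeping patient
vectors rectangular for the models downstream.

## Distillation

`rf_iterative_reduce()` implements iterative random-forest elimination:
fit a forest (default 5000 trees; probability forests via `ranger`), read
the out-of-bag predictive value, drop the feature with the lowest Gini
(impurity-decrease) importance, and refit — the forest is refit every
iteration rather than ranked once.  "Predictive value" is the OOB AUC and
the stopping tolerance is 0.005: elimination stops once the OOB AUC falls
more than the tolerance below the best value observed, and the function
returns the smallest surviving set still within tolerance of that best.
Both choices are package decisions; no canonical metric or tolerance
exists for this procedure.  When the classes are separable the OOB AUC
saturates and its fold-to-fold jitter can exceed the tolerance at any
iteration, so the retained set size is itself stochastic — the planted
driver, however, must survive, and the acceptance suite checks exactly
that.

`cart_fit()` grows a Gini-impurity classification tree (`rpart`) with
`cp = 0` and a minimum leaf of 5, then prunes by cost-complexity with the
pruning level chosen by k-fold (default 10) cross-validated risk under the
1-SE rule.  One refinement matters on null data: the resampled risk of
the root row of `rpart`'s CP table is itself noisy and can drift above 1,
so the trivial single-leaf tree — whose relative cross-validated risk is
1 by definition — is always included as a candidate; without this, pure
noise can escape pruning.  Split thresholds follow `rpart`'s convention of
midpoints between adjacent sorted values, which the tests assert.  The
root split is exported as the headline parameter and cut-off.  The
"self-test" metrics (specificity, sensitivity, AUC) come from held-out
fold predictions at the chosen complexity, refit per fold.

`pca_overview()` gives the customary overview: z-scored features, top two
principal components, a 2-means partition of the scores mapped to outcome
by majority.  How to turn a cluster plot into an ROC is underdetermined;
the package's declared choice is the continuous projection of each
patient onto the axis joining the two cluster centroids, oriented toward
the poor-outcome cluster.

## Survival statistics

`optimal_cutpoint()` replaces interactive cut-point software with an
explicit maximally selected log-rank statistic: candidates are the
midpoints between adjacent sorted unique values, restricted to the
10th–90th percentile band to avoid degenerate tail splits; the selected
threshold maximizes the two-group log-rank chi-square (computed by a
vectorized scan verified against `survival::survdiff` to machine
precision).  Because maximizing over candidates inflates the naive p, the
corrected p is the Monte-Carlo permutation tail probability of the maximal
chi-square under feature permutation (default 1000 permutations, with the
standard $(x+1)/(n+1)$ estimator, floored at the naive p).  The
acceptance suite verifies the corrected test holds its nominal type-I
error.

Dichotomization at validated cut-offs uses a strict tie rule: group 2
("high") strictly above the threshold, the boundary value itself staying
in group 1.  The shipped thresholds are 287 buds, 16 minimal-LVI events,
35 PDCs, 21% tumor:stroma and 35,647 µm² AreaPDC; for tumor:stroma the
*low* group carries the risk, recorded in the config's `high_is_risk`
column.

Kaplan-Meier estimation and the log-rank test delegate to the `survival`
package; p values across the feature family are Benjamini-Hochberg
adjusted (`stats::p.adjust`; an independent hand-coded step-up oracle
lives in the test suite).  Cox models use Efron tie handling.  Backward
elimination removes, at each step, the covariate whose removal most
decreases AIC, stopping when no removal decreases it (via
`MASS::stepAIC`); collinear covariates are dropped with a warning before
fitting.  Ordinal covariates are entered as 0/1/2 codes
(well/moderate/poor differentiation), binary ones as 0/1.

The composite prognostic index counts three flags — AreaPDC above its
cut-off, stage pT4, poor differentiation — and calls patients with ≥ 2
flags high-risk.  The clinical components' binarization is a package
decision: pT4 vs pT3 is unambiguous, and differentiation is taken as poor
vs {well, moderate}; the plausible alternative ({moderate, poor} vs well)
would flag nearly every patient in a cohort where well-differentiated
tumors are rare, so the stricter reading was adopted.

## The synthetic-data model

`generate_field()` renders the simplest geometry that exercises every
segmentation contract: a tumor mass with a sinuous margin occupying a
configurable fraction of the field (default 0.4) with elliptical
lumen/necrosis holes; nuclei as discs of radius 6 px; detached clusters as
unions of nucleus-centred discs plus a 3 px cytoplasmic margin; vessels as
elliptical D2-40 rings with dark lumens, invaded vessels carrying planted
intravascular clusters.  Channels are composited at plateau intensities
(≈ 0.72–0.78 against 0.03 background, with 0.12 diffuse stromal signal
standing in for autofluorescence), blurred with a σ = 1 px Gaussian as an
optics stand-in, and degraded with Gaussian read noise (default SD 0.02).
Fields are 512 × 512 px at 0.5 µm/px — the physical pixel size of the
historical imaging platform is not published, so it is a free parameter,
and all areas scale with its square.  Object footprints are placed
non-overlapping with margins; a field that cannot host its requested
objects fails with an explicit "too crowded" error rather than silently
truncating.  Ground truth (label rasters, per-object records, planted
summaries) is emitted alongside, and generation is bit-reproducible from
the field specification's seed without disturbing the caller's RNG.

Two geometry choices are load-bearing.  Within clusters, nucleus centres
are packed at 2·r + 2.5 px; background nuclei at least 2·r + 2 px apart.
The nucleus radius default of 6 px makes the watershed declumping contract
hold comfortably: under the σ = 1 blur, touching nuclei of this size are
split reliably from about 1.5 radii of centre separation (the tests probe
1.6 radii), whereas 4 px nuclei would merge below ~1.75 radii because
blurring fills the concave waist between overlapping discs.  Second, the
segmentation channel thresholds default to the half-amplitude points
between background and plateau (pan-CK 0.375, DAPI 0.40, D2-40 0.39),
which keeps blurred object boundaries unbiased — recovered object areas
land within ~1.5% of planted areas, versus a systematic +3% at a 0.35
threshold.

`generate_cohort()` draws exponential event times with hazard
$\lambda_0 \prod_j \mathrm{HR}_j^{x_j}$ over binary covariates, censored
administratively — the minimal model satisfying the proportional-hazards
assumption used downstream.  Defaults emulate a 134-patient stage II
validation-style cohort: pT4 prevalence 32/134, poor differentiation
22/134, elevated AreaPDC 65/134, baseline hazard 0.0012/month with a
138-month horizon (≈ 15% disease-specific death).  Continuous features are
drawn around covariate-dependent group means (AreaPDC: 15,000 vs 65,000
µm², SD 9,000), so dichotomization at 35,647 µm² recovers the planted
flag with ~95% fidelity.

What the generator does *not* emulate — and therefore what passing tests
do not show about real tissue: stain variability and bleed-through,
autofluorescence structure, out-of-focus fields, touching or overlapping
objects, irregular nuclear morphology, 3D sectioning effects, and any
correlation structure among the 123 parameters beyond what geometry
induces.  Exact-recovery results on synthetic fields certify the
*bookkeeping* (no object lost, merged or double-counted under the modelled
contrast), not segmentation accuracy on clinical material, which would
need retuning of every threshold in `seg_config()`.

## Numerical and scale choices

* Raster convention: matrices indexed [row, col], 1-based, centroids in
  pixel units; areas in µm² via `pixel_size_um^2`.
* Minimum object size 20 px² (keeps single-cell buds); minimum nucleus
  12 px; minimum lumen hole 60 px; watershed tolerance 1.
* TIFFs are written 16-bit; round-tripping is exact to 1/65535.
* The permutation-corrected p is floored at the naive p, making the
  invariant `p_corrected >= p_naive` hold by construction.
* Degenerate inputs fail loudly: all-background fields log and return
  `no_tissue`; constant features, single-class outcomes and cohorts with
  fewer than two events are errors, not NaNs.
* Test and acceptance problem sizes are the package's declared choices:
  forests of 200–300 trees for the elimination studies (the 5000-tree
  default is an API default, not a test requirement), 20-seed
  exact-recovery studies, 200 null replicates × 200 permutations for the
  type-I study, 50 cohorts of n = 500 for Cox coverage.  At these sizes
  the planted effects are far from the detection boundary, so the checks
  are insensitive to the exact scales.

## Known limitations

* The region segmentation substitutes threshold-and-morphology rules for
  the trained, proprietary region classifier of the historical workflow;
  the four-class partition contract is preserved, the decision surface is
  not.
* The PDC definition is purely nucleus-count based; the conventional
  requirement of absent gland formation has no analogue in the synthetic
  geometry (a config hook is the natural extension point).
* The manifest's parameter names are package-defined; only the count
  (123) and family structure are anchored.
* Backward elimination by AIC and the OOB-AUC stopping rule are
  reasonable but not unique readings of "stopping rule based on AIC" and
  "predictive value"; both are isolated behind their function interfaces.
* The cut-point permutation correction treats the whole scan as the unit
  of inference; it does not implement training/validation splitting
  within the correction.
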