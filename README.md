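# invasivefront

Quantitative histopathology of the colorectal cancer invasive front from
multiplexed immunofluorescence, with feature distillation and prognostic
modelling for stage II disease.

## The problem

Roughly one in five stage II colorectal cancer (CRC) patients dies of
disease despite nominally curative surgery, and classical TNM staging does
a poor job of identifying them.  A family of invasive-front features is
known to carry prognostic signal — tumor budding (detached clusters of ≤ 4
tumor cells), poorly differentiated clusters (PDCs, detached clusters of
≥ 5 cells), lymphatic vessel invasion (LVI), lymphatic vessel density
(LVD), and the tumor:stroma ratio — but visual scoring of these features
is poorly reproducible.  `invasivefront` implements an automated pipeline
for researchers in digital pathology:

1. **Segmentation** of three-channel immunofluorescence fields (DAPI =
   nuclei, pan-cytokeratin = epithelium/tumor, D2-40 = lymphatic
   endothelium) into a three-level hierarchy: tissue regions (tumor /
   stroma / lumen-necrosis / no tissue), stromal objects (pan-CK clusters,
   vessels), and nuclei, each nucleus assigned to exactly one parent.
2. **Classification** of the objects into the candidate features and the
   per-field scalars: bud / PDC / LVI / minimal-LVI / vessel counts,
   summed PDC area (**AreaPDC**, µm²), LVD (vessels/mm²), tumor:stroma %.
3. **Feature extraction**: a declared manifest of 123 morphometric,
   density, spatial, intensity and texture parameters per field, collated
   (sum or mean, per parameter) over the 15 fields of a patient section.
4. **Distillation**: PCA overview; iterative random-forest elimination
   (refit, rank by Gini importance, drop the weakest, stop when the
   out-of-bag AUC degrades); CART with cost-complexity pruning, exporting
   the root split as the headline parameter and cut-off.
5. **Survival statistics**: maximally selected log-rank cut-points with
   Monte-Carlo permutation correction, Kaplan-Meier + log-rank with
   Benjamini-Hochberg FDR control, univariate Cox, backward elimination by
   AIC, and a composite prognostic index (high risk when ≥ 2 of {AreaPDC
   above cut-off, pT4, poor differentiation}).

Validated dichotomization cut-offs ship as defaults: 287 buds, 16
minimal-LVI events, 35 PDCs, 21% tumor:stroma, 35,647 µm² AreaPDC
(strictly-above ⇒ high group).

Because no public cohort of this design exists, the package includes a
first-class **synthetic-data module**: seeded immunofluorescence fields
with exact ground truth (planted buds, PDCs, vessels with or without
intravascular tumor cells, tumor mass with lumen holes) and survival
cohorts with planted proportional-hazards structure.  Every stage of the
pipeline is tested against these ground truths.

## Worked example

Simulate one field with 3 buds, 2 PDCs and 2 vessels (one invaded by 6
tumor cells, one by 2), then segment and classify it:

```r
library(invasivefront)

spec <- field_spec(n_buds = 3, n_pdc = 2, n_vessels = 2,
                   lvi_events = list(c(1, 6), c(2, 2)), seed = 42)
field <- generate_field(spec)
hier  <- segment_field(field$image)
cf    <- classify_objects(hier)
```

This prints (counts recovered exactly; planted AreaPDC was 638.0 µm²):

```
buds 3 | PDCs 2 | LVI 1 | minimal LVI 1 | vessels 2
AreaPDC 641.8 um^2 (planted 638.0) | tumor:stroma 38.9% | LVD 30.5 /mm^2
```

Distill a 123-parameter table with one planted step driver (outcome = 1
iff `area_pdc_um2` > 35,647 µm²) down to the driving parameter and its
cut-off:

```r
rk <- rf_iterative_reduce(X, y, cfg = list(n_trees = 300, seed = 1))
ct <- cart_fit(X[, rk$selected, drop = FALSE], y, cfg = list(seed = 1))
print(ct)
```

```
features surviving elimination: 1 | retained: area_pdc_um2 | best OOB AUC: 1
CART model (10-fold self-test)
  root split: area_pdc_um2 > 35581.3
  self-test specificity 100.0%, sensitivity 100.0%, AUC 1.000
```

The recovered cut-off (35,581 µm²) falls inside the empirical gap around
the planted boundary.  The composite index combines AreaPDC with the two
clinical parameters:

```r
build_npi(list(area_pdc_um2 = 41000, pt_stage = "pT4",
               differentiation = "moderate"))
#> NPI score 2 -> high risk
```

A command-line wrapper over the same functions lives at
`inst/cli/invasivefront.R` (subcommands `simulate`, `extract`, `distill`,
`survive`, `all`).

## Layout

- `R/` — synthetic data (`field_spec`, `generate_field`, `generate_section`,
  `cohort_spec`, `generate_cohort`), segmentation (`segment_rois`,
  `detect_objects`, `segment_nuclei`, `assign_hierarchy`), classification
  (`classify_objects`, `area_pdc`, `compute_lvd`, `tumor_stroma_ratio`),
  features (`manifest_default`, `extract_field_features`,
  `collate_patient`), distillation (`pca_overview`, `rf_iterative_reduce`,
  `cart_fit`), survival (`optimal_cutpoint`, `dichotomize`, `km_logrank`,
  `bh_adjust`, `cox_univariate`, `cox_backward_aic`, `build_npi`), and the
  pipeline (`run_config`, `run_extract`, `run_distill`, `run_survival`).
- `vignettes/invasivefront-methods.Rmd` — the methods account: models,
  assumptions, parameter choices, limitations.
- `tests/testthat/` — unit, property and end-to-end acceptance suites.
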