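# cavquant

Seizures are the most common presentation of cerebral cavernous
malformations (CCMs), and the strongest known anatomical driver is how much
cortical gray matter (GM) the lesion involves. `cavquant` quantifies that
involvement: given a binary lesion label and a population GM density
template on one common (MNI-like) grid, it measures the **volume** and
**proportion** of gray matter displaced by the lesion, attributes the
lesion to one of eight merged anatomical lobes, and computes the
cohort-level seizure-risk statistics used to evaluate displaced GM as a
predictor. It is aimed at neuroimaging researchers studying
lesion–symptom relationships who already have co-registered NIfTI-1
volumes (spatial normalization itself is out of scope).

## The core quantities

With a lesion mask of `N_ccm` voxels (voxel volume `Vs` mm³) and template
GM densities `D_k ∈ [0, 1]` at the in-lesion voxels:

- **Displaced GM volume (mL)** = `Nd_ccm × Vs / 1000`, where `Nd_ccm` is
  the number of in-lesion voxels with density strictly above 0.5 (the
  GM / non-GM cut);
- **Displaced GM proportion (%)** = `100 × Σ D_k / N_ccm`, the mean GM
  density inside the lesion.

Cohort evaluation treats the proportion as a diagnostic score for seizure
status: odds ratios with Woolf confidence intervals from 2×2 lobe tables,
Wilcoxon rank-sum group comparisons, logistic regression with
Hosmer–Lemeshow fit and calibration slope, ROC/AUC with Youden threshold
selection, the full metric battery (Se, Sp, PPV, NPV, F1, DOR, MCC,
kappa) with stratified bootstrap CIs, and the prevalence-adjusted
predicted PPV

```
predicted PPV = Se·P / (Se·P + (1 − Sp)(1 − P))
```

at a target population prevalence `P`.

A seeded synthetic-cohort generator (`synth_config()`, `make_cohort()`)
produces a spherical-shell GM phantom, an 8-lobe parcellation, lesion
masks with exact ground-truth bookkeeping, and outcome labels drawn from
a stated logistic model, so the whole pipeline can be exercised and
tested without patient data.

## Worked example

```r
library(cavquant)

cfg <- synth_config(grid_shape = c(64, 64, 64), voxel_size_mm = c(2, 2, 2),
                    shell_outer_mm = 52, shell_inner_mm = 43,
                    n_per_group = c(seizure_like = 12, nonseizure_like = 99),
                    seed = 17)
co <- make_cohort(cfg, keep_masks = TRUE)

quantify_displacement(co$masks[[3]], co$template)
#> <displacement_result> 342/554 voxels GM; displaced 2.736 mL, 62.4%

ev <- evaluate_cohort(co$cohort$proportion_pct, co$cohort$label,
                      prevalence = 0.37, B = 1000, seed = 17)
#> threshold = 60.3% (Youden), AUC = 0.782
round(unlist(ev$metrics), 3)
#> sensitivity specificity         ppv         npv          f1         dor
#>       0.711       0.849       0.711       0.849       0.711      13.835
#>         mcc       kappa
#>       0.560       0.560
ev$predicted_ppv
#> 0.735

odds_ratio(contingency_2x2(2, 1, 10, 98))
#> OR = 19.6 (95% CI 1.63-236) [woolf]
```

The displacement result says lesion 3 occupies 554 voxels, 342 of which
sit in template GM (> 0.5 density): 2.736 mL of displaced gray matter,
with a mean in-lesion GM density of 62.4%. The evaluation block scores
the simulated cohort's displaced-GM proportion as a seizure classifier;
the predicted PPV projects the operating point onto a 37% population
prevalence. The odds ratio call reproduces a 2×2 lobe-exposure table
analysis (2 exposed cases, 1 exposed control, 10/98 unexposed).

A thin command-line front end with `simulate`, `build-template`,
`quantify`, `locate`, `cohort-stats`, `evaluate` and `run` subcommands
lives at `inst/cli/cavquant.R`; `run_pipeline()` drives the whole chain
from a YAML/JSON config and writes a JSON/CSV report bundle.

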