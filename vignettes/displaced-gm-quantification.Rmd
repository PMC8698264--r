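---
title: "Quantifying gray matter displaced by cavernous malformations"
author: "cavquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gray matter displaced by cavernous malformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavquant)
```

## The problem and the model

Cerebral cavernous malformations (CCMs) are vascular brain lesions whose
most common clinical presentation is seizures, and cortical gray matter
(GM) involvement is the leading anatomical risk factor. `cavquant`
operationalizes "involvement" on a voxel lattice. All volumes — a
population GM density template, binary lesion labels, and an optional
lobe parcellation — are assumed co-registered upstream to one
axis-aligned common grid (an MNI-like space); this package verifies only
lattice agreement (`assert_same_grid()`), never anatomical alignment.

The template is the voxel-wise arithmetic mean of control-subject GM
density maps (`build_template()`), each voxel holding a value in [0, 1]
interpretable as the population probability that the voxel is gray
matter. A voxel is *designated* GM when its template density exceeds 0.5
strictly; below, it is white matter or CSF. For a lesion mask with
`N_ccm` voxels of volume `Vs` mm³ and in-lesion template densities `D_k`:

- displaced GM **volume** (mL) `= Nd_ccm × Vs / 1000`, with `Nd_ccm` the
  count of in-lesion voxels with `D_k > 0.5` — a hard, thresholded count;
- displaced GM **proportion** (%) `= 100 × Σ D_k / N_ccm` — a soft
  average over *all* in-lesion voxels.

The asymmetry is deliberate and preserved as defined: the volume asks
"how much tissue that is probably GM does the lesion occupy", the
proportion asks "how GM-like is the lesion's neighbourhood on average".
Because the density sum is not thresholded, a lesion sitting entirely in
tissue of density 0.4 has zero displaced volume but a 40% proportion.
Users who want the thresholded sum instead can set
`proportion_mode = "hard"` in `quantify_displacement()`; the default is
`"soft"`.

Two boundary conventions are fixed here because the defining texts leave
them open:

- **density exactly 0.5** is non-GM (strict `>`), consistent with the
  definition of `Nd_ccm`; the threshold is a `gm_threshold` argument for
  sensitivity analyses;
- **scores exactly at the classifier cutoff** are predicted negative
  (strict `>`), matching the phrasing "risk increased when the proportion
  *exceeded* the cutoff".

## Lobe attribution

Atlas lobes are merged to eight: frontal (incl. the frontal–temporal
space), temporal, parietal, occipital, limbic, sublobar (deep
structures), cerebellum (anterior + posterior), and brainstem (medulla +
midbrain + pons). `lobe_proportions()` reports, for each merged lobe,
the fraction of lesion voxels inside it; fractions sum to the atlas
coverage (out-of-atlas voxels carry no lobe), and the identity
`Σ proportions + out-of-atlas fraction = 1` holds exactly.

A lesion's single *location* is its arg-max lobe. No published rule
exists for assigning one location to a lesion spanning several lobes, so
the package makes its own: ties are broken by a fixed lobe order
(frontal, temporal, parietal, occipital, limbic, sublobar, cerebellum,
brainstem) with a warning. Location classes follow the lobe unions:
supratentorial = the six cortical/deep lobes, infratentorial =
cerebellum + brainstem; within supratentorial lesions, temporal =
temporal + limbic, everything else extratemporal. The temporal class is
undefined (NA) for infratentorial lesions, and a zero-coverage profile is
"unclassified".

## Cohort statistics

- **Odds ratios** on 2×2 exposure tables use the cross-product with a
  Woolf (log-normal) 95% CI, `z = 1.96`. This choice is verifiable:
  back-calculating published lobe-exposure CIs from their integer counts
  reproduces them to the printed digit. Tables with an infinite OR
  (`b·c = 0`) report `+Inf` with an exact conditional one-sided lower
  bound; a Haldane 0.5 correction is available behind a flag but off by
  default.
- **Fisher's exact test** and the **Wilcoxon rank-sum test** wrap the
  standard `stats` implementations behind the package surface; the
  Wilcoxon p-value is exact for small untied samples (both routes are
  verified in the test suite against full enumeration oracles).
- **Logistic regression** is the standard IRLS fit with Wald CIs on
  `exp(β)`; separation is detected and flagged, never silently dropped.
- **Hosmer–Lemeshow**: equal-count groups by fitted risk (deciles for
  `g = 10`), ties kept together, `χ² = Σ (O−E)²/(E(1−E/n_g))`,
  `df = g − 2`. Groups lost to ties are merged with a warning; a
  constant-risk model collapses to one group and the statistic is
  reported as undefined rather than fabricated.
- **Calibration slope**: slope of outcome on the logit of fitted
  probability (1 = perfect; 0.5 under twofold logit inflation, which the
  suite checks analytically).
- **Pseudo-R²**: which flavour a given report means is often unstated,
  so McFadden, Cox–Snell and Nagelkerke are all returned and none is
  privileged.

## Classifier evaluation

The displaced-GM proportion is scored as a diagnostic test for seizure
status. `roc_auc()` computes the AUC as the normalized Mann–Whitney
U-statistic (ties ½), which equals the trapezoidal area under the
empirical curve; `select_threshold()` maximizes Youden's J with
lowest-threshold tie-breaking. The metric battery (Se, Sp, PPV, NPV, F1,
DOR, MCC, kappa) reports undefined ratios as NA with a reason, except
the DOR, which is `+Inf` when only its denominator vanishes.

Confidence intervals use a stratified percentile bootstrap: cases and
controls are resampled within class, so no resample is degenerate, and
the whole procedure is bit-reproducible given a seed. Percentile
bootstrap coverage is a first-order asymptotic property: with only a
dozen positives and sensitivity near 1 the bootstrap distribution
collapses onto the point estimate and no interval of any method is
trustworthy — the suite therefore checks near-nominal coverage at 100
cases / 100 controls with continuous scores, a regime where the claim
applies. Published interval widths from very small cohorts are not
reproduced, and no attempt is made to match them.

The prevalence-adjusted predicted PPV re-projects a sample operating
point `(Se, Sp)` onto a target prevalence `P` by Bayes' rule:

```{r}
predicted_ppv(se = 0.917, sp = 0.838, prevalence = 0.37)
```

It is strictly increasing in each argument on the open domain and equals
`P` exactly for an uninformative test (`Se = Sp = 0.5`).

One genuine inconsistency is worth documenting: a published DOR of 0.570
alongside Se 0.917 / Sp 0.838 on 12/99 group sizes contradicts the
standard definition `(TP/FN)/(FP/TN)`, which gives ≈ 57.1 for that
confusion matrix. The package computes the standard DOR.

## The synthetic cohort generator

`synth_config()` fixes the simulated study conditions; all randomness
flows through its mandatory seed, and reruns are identical at the level
of drawn masks, labels and counts.

- **Grid**: 181 × 217 × 181 voxels at 1 mm isotropic — the normalized
  grid of the motivating study, with voxel size 1 mm adopted from its
  control acquisitions (the normalized voxel size is not stated
  anywhere, so file headers are authoritative for real data).
- **Template**: a spherical GM shell (outer 75 mm, inner 62 mm, peak
  density 0.95) over a WM core (0.25) and CSF exterior (0.02). Density
  is a pure function of radius when smoothing is off (the default), so
  shell volumes are analytic — the suite checks the > 0.5 voxel count
  against `4π(R³ − r³)/3` within 5%. Optional Gaussian smoothing softens
  the tissue interfaces at the cost of that closed form.
- **Lesions**: spheres with radii uniform on 3–12 mm (≈ 0.1–7 mL,
  bracketing reported CCM volumes), centred uniformly in the brain;
  placement can be biased toward GM-rich or GM-poor tissue per group,
  but the default is unbiased so that the outcome model alone drives the
  label–score association. Ground-truth `Nd_ccm`, `Σ D_k`, `N_ccm` are
  recorded at rasterization time, independently of
  `quantify_displacement()`, and the two routes must agree exactly — the
  central cross-module integration test.
- **Cohort**: 12 + 99 patients by default, mirroring the motivating
  cohort's size. Labels are drawn
  `Bernoulli(plogis(β₀ + β₁ · proportion_pct))` with defaults
  `β₀ = −4`, `β₁ = 0.06` per percentage point: risk is low (< 5%) below
  ~20% displaced GM and rises through the 30–50% range, the qualitative
  structure reported for real cohorts. A run in which every drawn label
  is identical is refused with advice rather than passed downstream.
- **Parcellation**: the brain sphere split into octants, one raw region
  per merged lobe (cortical lobes on top, cerebellum/brainstem below).
  It is a geometric fixture: it exercises counting, merging and
  tie-breaking, not anatomy.

What the generator does *not* emulate: realistic MRI contrast,
hemosiderin rims, registration error, non-spherical lesion shapes, or
anatomically shaped lobes. Passing tests therefore demonstrate
correctness of the arithmetic and the statistical machinery on data with
known truth — not segmentation or registration quality on clinical
images.

## Problem sizes used by the test suite

Unit and property tests run on small grids chosen for tight feedback:
48³–64³ voxels at 2–3 mm (the phantom keeps its shell proportions),
brute-force voxel-loop oracles at 64³ over 100 random instances,
exhaustive Fisher enumeration over all 2×2 tables with `n ≤ 40`,
logistic-recovery cohorts of n = 1000, and bootstrap coverage over 500
simulated cohorts at B = 500. The generator's defaults stay at the
study-scale grid; tests override them explicitly, and
`make_cohort(keep_masks = FALSE)` streams per-patient masks so the
default grid never requires holding 111 full volumes in memory.

## Numerical conventions and degenerate inputs

- Grids are axis-aligned with a shared origin; world coordinate =
  0-based voxel index × voxel size. Affines with rotation or shear are
  rejected outright rather than silently mis-applied.
- Nearest-neighbour resampling is mandatory for masks and labels (and
  enforced); trilinear interpolation is available for densities and
  cannot leave the source value range.
- Densities are written as 32-bit float; masks and labels as integers.
  Sub-float-precision excursions on read (±1e-6) are clamped.
- Non-binary "mask" files are binarized at > 0.5 with a warning, the
  same cut as the GM designation.
- Empty lesion masks are errors (the proportion would divide by zero);
  in cohort mode the failure is recorded per patient and the run
  continues.
- All bootstrap and simulation randomness is funnelled through explicit
  seeds; `bootstrap_ci()` restores the caller's RNG state.

## Known limitations

Lesion masks are inputs: manual delineation and spatial normalization
happen upstream, and errors there propagate here unexamined. The
location rule (arg-max lobe) is this package's reconstruction, not a
published convention. The per-patient results of the motivating study
are not reproducible without its raw images, so the suite validates the
machinery on synthetic ground truth plus the published aggregate tables
whose inputs (integer 2×2 counts, the reconstructed confusion matrix,
Se/Sp/prevalence) are printed in full.
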