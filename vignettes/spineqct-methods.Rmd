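---
title: "Opportunistic QCT spine densitometry: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opportunistic QCT spine densitometry: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineqct)
```

## The problem

Routine contrast-enhanced multi-detector CT (MDCT) of the thorax and
abdomen — acquired for oncologic staging and follow-up, not for
densitometry — images every vertebral body from the mid-thoracic spine to
the sacrum. With a density reference phantom lying in the scanner table
mat, each scan can be converted into a quantitative CT (QCT) exam at no
extra dose: the two phantom phases of known hydroxyapatite-equivalent
density anchor a per-scan linear map from Hounsfield units (HU) to
volumetric bone mineral density (BMD, mg/cm³). This *synchronous
calibration* absorbs scan-to-scan drift, including the scan-wide HU shift
produced by intravenous contrast, because the phantom sits outside the
vascular compartment.

`spineqct` implements that opportunistic workflow end to end —
per-scan calibration, standardized trabecular ROI densitometry at every
level Th5–L5, subcutaneous/visceral fat (SAT/VAT) quantification at the
L4/5 disc, and the matched case-control statistics used to ask which
measurement best separates patients who go on to an incident vertebral
fracture from matched controls. Because clinical CT of this kind cannot be
redistributed, the package ships a synthetic-CT and synthetic-cohort
generator with voxel-level ground truth; every stage is validated against
that ground truth.

## The measurement model

**Calibration.** For phantom phases with known densities $\rho_1 < \rho_2$
and sampled mean attenuations $\bar H_1, \bar H_2$, the conversion is the
least-squares line $\hat\rho(H) = a + b H$; with exactly two phases it
interpolates both pairs. Phase ROIs emulate central manual placement: a
cylinder at 80 % of the phase radius, eroded one voxel from the
partial-volume rim and trimmed one voxel at each axial end.

**Vertebral ROI rule.** In the most central sagittal slice through the
vertebral body (ties toward the lower index), a circular ROI with diameter
two-thirds of the vertebral height is placed in the anterior half of the
trabecular compartment, equidistant to both endplates, excluding the
cortical shell, the endplates, and the contrast-filled basivertebral
venous channel. HU is averaged over a 3 mm sagittal reformation —
implemented as the largest odd number of contiguous native slices covering
3 mm, centered on the mid-sagittal slice — and converted with the per-scan
line. A voxel belongs to the ROI iff its center lies inside the circle, so
voxel counts are reproducible. Vertebrae with a prevalent fracture are not
measured; the QCT-standard summary is the arithmetic mean over L1–L3, and
when a member of L1–L3 is skipped the mean of the remaining levels is
reported with a `partial` flag (a choice this package makes explicitly;
skipping the whole summary would discard usable levels).

**Fat compartments.** At the axial slice of the L4/5 intervertebral disc
plus two slices cranial and caudal, fat-range voxels (default −190 to
−30 HU, configurable) are partitioned by connectivity relative to the
muscle wall: the abdominal cutis is the outer border and the abdominal /
paravertebral musculature the inner border. A seeded 4-connected region
grown from the body centroid, with the muscle/cutis attenuation band
(0–100 HU) as barrier, defines the visceral side; fat inside it is VAT,
fat between it and the cutis is SAT. Volumes are voxel counts × voxel
volume (cm³); the VAT/SAT ratio is per subject. The five window slices are
segmented independently and summed, since the quantity of interest is the
windowed volume, not a whole-abdomen segmentation. A grown region that
reaches the subcutaneous rim indicates an open muscle wall and raises a
leak error with the breach location — replacing the "manual assistance"
of an interactive workflow with an explicit failure mode.

**Statistics.** Matched pairs justify the Wilcoxon signed-rank test
(exact by sign enumeration up to 25 untied non-zero differences, normal
approximation with tie/continuity correction beyond; zeros dropped).
Correlations are Spearman mid-rank correlations with t-approximation
p-values. Discrimination uses the nonparametric (Mann–Whitney) AUC with
ties counting one half, its Hanley–McNeil standard error, and a normal
test against 0.5. Odds ratios are per one-SD *decrease* of the predictor
(logistic fit on $(\bar x - x)/s$), with Wald 95 % intervals. The
multivariate model is forward stepwise logistic regression: Rao score
test for entry at $p < 0.05$ (ties in candidate p-values broken by listed
order), Wald statistics for the final report. No multiplicity correction
is applied — each test is two-sided at 0.05, as is conventional for
exploratory case-control imaging analyses.

Orientation matters for AUC and is always recorded: BMD (and the L1–L3
mean) is oriented lower-indicates-case; SAT and the VAT/SAT ratio
higher-indicates-case. VAT is oriented lower-indicates-case, matching the
direction of its group means in the cohort structure the generator
encodes. The per-SD odds-ratio scaling uses the pooled whole-sample SD
(configurable); the score-test entry criterion and the entry threshold
are likewise configurable.

## What the synthetic data emulate — and what they do not

**Scans.** The voxel renderer builds, from continuous geometry in mm: a
13-level spine of elliptic-cylinder vertebral bodies (heights growing
22→27 mm caudally) with flat endplates (1.5 mm), a lateral cortical shell
(2.5 mm), and a posterior midline venous channel (radius 2 mm,
penetrating 30 % of the AP diameter); concentric abdominal compartments —
cutis (2 mm, 20 HU), subcutaneous fat ring (25 mm, −100 HU), muscle wall
(12 mm, 50 HU), visceral space (−100 HU with 240 HU contrast-filled bowel
disks); and a two-phase phantom (0 and 200 mg/cm³, 9 mm radius cylinders)
in the table mat. Trabecular and phantom attenuations come from an
internal density→HU line (default HU = 5 + 1.05·ρ); a scan-level additive
offset emulating intravenous contrast applies to anatomy but not the
phantom; i.i.d. Gaussian HU noise (default SD 15 HU, typical of routine
120 kVp abdominal MDCT) applies everywhere. Labels and intensities are
rendered from the same continuous geometry at voxel centers, so the
ground-truth masks are exact by construction. Default spacing is
2 × 2 × 3 mm (sagittal, coronal, axial), with 1-based voxel indices as is
idiomatic in R; coarser grids are used in tests where sub-millimetre
detail is irrelevant.

Not emulated: CT physics (partial volume, beam hardening, scatter,
correlated noise), anatomical variation (scoliosis, osteophytes, marrow
fat heterogeneity), fracture morphology (fracture status is a label), and
automatic vertebra labeling (scans carry their geometry as metadata).
Passing the recovery tests therefore demonstrates the correctness of the
measurement logic under the stated model, not robustness to real
anatomy.

**Cohorts.** Within each group, the 13 level BMDs are multivariate
Gaussian with the published group means/SDs and an exchangeable
inter-level correlation (default ρ = 0.7, inside the printed 0.445–0.855
range of observed pairwise correlations; the full matrix was never
published). Gaussianity is a modeling choice — the source study reported
only means and SDs and noted non-normality for most parameters — so the
Gaussian is the minimal stand-in consistent with the published summaries.
SAT and VAT are zero-truncated Gaussians (their SDs approach their means,
so an untruncated normal would produce negative volumes), drawn
independently of BMD; the VAT/SAT ratio and the L1–L3 mean are recomputed
per subject rather than drawn, which keeps them consistent with their
components at the cost of not exactly matching their own published
summary rows. Pairs are matched on age and follow-up through shared
pair-level values with a 1-year/1-month jitter SD. Prevalent-fracture
missingness is injectable (`n_prevalent`) but defaults to zero.

## Numerical choices and degenerate inputs

* Mid-sagittal tie-break: lower index. ROI shrink-to-fit: if the
  2/3-height circle cannot fit the anterior trabecular half (checked
  against the continuous geometry across the whole reformation slab), it
  is shrunk to the largest fitting diameter and flagged; if no usable ROI
  remains (e.g. the venous channel crosses the anterior compartment) a
  placement error is raised.
* Calibration demands two phases with distinct HU; identical phase HU is
  a degenerate-fit error. Negative BMD is permitted (the affine map is
  order-preserving), left to downstream flagging.
* Wilcoxon on all-zero differences returns p = 1 with a `degenerate`
  flag; Spearman on constant input returns an undefined-flag; complete
  separation in a logistic fit is flagged with an infinite-CI marker.
* `segment_fat` with no fat-range voxels returns two empty masks; a SAT
  volume of zero leaves VAT/SAT undefined rather than infinite.
* Leak detection uses a rim of 3 voxels inside the body outline; with the
  default 2 mm cutis this covers the cutis plus two subcutaneous layers,
  so an intact wall can never trigger it while any breach floods the
  subcutaneous ring and must touch the rim.

## Problem sizes used in the validation suite

The test suite regenerates everything from code: 50 default-resolution
scans for the bias/reproducibility study (per-level bias bound 1 mg/cm³;
percent CV checked against a 0.5–10 % plausibility band that contains the
2.09–7.70 % long-term reproducibility reported for this ROI technique),
200 coarse-grid scans for the central-limit noise property, 1000 random
small inputs for the exhaustive AUC oracle, full sign enumeration for the
signed-rank test up to n = 12, 2000 replicate 17 + 17 cohorts per variable
for the AUC coverage checks, and 300 replicate cohorts for the null
behavior of the adiposity measures. These sizes were chosen so the whole
suite completes in a few minutes while keeping every Monte-Carlo bound at
least three standard errors wide.

## Known limitations

The renderer's abdomen is convex and concentric; real subcutaneous fat is
not a perfect ring, and paravertebral muscle is not a closed ellipse, so
the segmentation's leak detection is exercised only by constructed
fixtures. The exchangeable BMD correlation understates the distance decay
visible in the published extremes. AUC standard errors use the
Hanley–McNeil formula, which differs slightly from the binormal/exact
variants other software reports; they are reported, not gated. And with
17 pairs per group, any single published AUC carries a sampling SE near
0.1 — which is exactly why the package validates discrimination results
as coverage points of simulated sampling distributions rather than as
point equalities.
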