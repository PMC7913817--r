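# spineqct

Opportunistic osteoporosis assessment from routine contrast-enhanced
multi-detector CT (MDCT), implemented as a fully testable R pipeline.

Routine thoraco-abdominal CT — acquired for oncologic staging, not for bone
densitometry — images every vertebral body from Th5 to L5. With a two-phase
density reference phantom lying in the scanner table mat, each scan becomes a
quantitative CT (QCT) exam: the phantom phases of known density `ρ₁ < ρ₂`
anchor a per-scan linear conversion `ρ̂(H) = a + b·H` from Hounsfield units to
volumetric bone mineral density (BMD, mg/cm³). This *synchronous calibration*
absorbs scan-level drift, including the HU shift from intravenous contrast.
The package implements:

* **Calibration** — phantom-phase sampling and the two-point (or
  least-squares) HU→BMD line, per scan.
* **Vertebral densitometry** — the standardized ROI rule at every level
  Th5–L5: a circle of diameter ⅔ of the vertebral height in the anterior
  trabecular compartment of the mid-sagittal 3 mm reformation, equidistant
  to both endplates, excluding cortex, endplates and the basivertebral
  venous channel; vertebrae with prevalent fractures are skipped; the
  QCT-standard mean over L1–L3 is reported alongside.
* **Fat quantification** — SAT/VAT volumes (cm³) over five axial slices at
  the L4/5 disc by threshold + seeded 4-connected region growing, with the
  cutis as outer and the muscle wall as inner border.
* **Case-control statistics** — paired Wilcoxon signed-rank comparisons,
  Spearman correlations, nonparametric (Mann–Whitney) AUC with
  Hanley–McNeil SE and a test against 0.5, odds ratios per SD decrease
  with Wald 95% CI, and forward stepwise logistic regression (score-test
  entry at p < 0.05), asking which measurement best identifies patients
  with incident vertebral fractures.
* **Synthetic data** — a voxel renderer producing spine + abdomen + phantom
  CT volumes with exact voxel-level ground truth, and a matched-cohort
  generator with published group means/SDs, so the whole pipeline is
  validated without any patient data.

## Worked example

```r
library(spineqct)

x   <- generate_scan(seed = 1)                     # synthetic contrast-enhanced MDCT
cal <- calibrate_scan(x$scan, phantom_spec(), scan_id = "demo")
cal
#> Synchronous HU-to-BMD calibration (scan demo)
#>   BMD = -4.65035 + 0.953497 * HU  [mg/cm^3]
#>   phases: (4.9 HU, 0 mg/cm^3), (214.6 HU, 200 mg/cm^3)

measure_spine(x$scan, cal, prevalent_fractures = "Th12")
#> Vertebral trabecular BMD (mg/cm^3)
#>  level mean_hu   bmd n_vox diameter_mm slice shrunk                     status
#>    Th5   185.3 172.0    27    14.66667    78  FALSE                   measured
#>    Th6   177.2 164.3    30    15.00000    78  FALSE                   measured
#>    Th7   177.1 164.2    32    15.33333    78  FALSE                   measured
#>    ...
#>   Th12      NA    NA    NA          NA    NA     NA skipped-prevalent-fracture
#>    ...
#>     L5   134.4 123.5    39    17.33333    78  FALSE                   measured
#> Mean L1-L3: 132.5 mg/cm^3 (complete)

measure_fat(x$scan)
#> L4/5 fat compartments: SAT 267.4 cm^3, VAT 279.4 cm^3, VAT/SAT 1.04
```

The fitted line inverts the generator's internal density→HU map (slope
`1/1.05 ≈ 0.952`), the skipped Th12 carries no BMD value, and on noise-free
scans the measured BMD equals the rendered trabecular density exactly — those
are the properties the test suite asserts.

The statistical battery runs on a matched cohort (here simulated with the
published group parameters; 17 pairs):

```r
co  <- generate_cohort(cohort_params(), seed = 1)
rep <- build_report(co)
rep$discrimination[c(3, 14, 15, 16), c("variable", "auc", "auc_se", "auc_p")]
#>  variable   auc auc_se    auc_p
#>       Th7 0.865 0.0646 1.58e-08
#>      L1L3 0.747 0.0850 3.62e-03
#>       VAT 0.471 0.1003 7.69e-01
#>       SAT 0.329 0.0932 6.62e-02
```

Mid-thoracic BMD separates the groups sharply (AUC near 0.87 at Th7), the
lumbar standard L1–L3 less so, and the adiposity measures hover at chance —
the qualitative pattern the cohort parameters encode. `stepwise_logistic()`
then selects the multivariate predictors, and `run_pipeline(run_config())`
(or the CLI in `inst/cli/spineqct`) executes every stage end to end with a
provenance manifest.

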