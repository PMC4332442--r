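# lavvflow

Direct quantification of left atrioventricular valve (LAVV) regurgitation
from whole-heart 4D flow cardiovascular MR, with retrospective valve
tracking.

After correction of an atrioventricular septal defect, the left-sided
valve often leaks through jets that defeat echocardiographic grading:
several jets at once, directions that swing through systole, and
non-circular cross-sections. 4D flow CMR stores the full velocity vector
per voxel and cardiac phase, so the measurement plane can be placed
*retrospectively* — per phase, perpendicular to each jet, 1–2 cm into the
receiving chamber — and the regurgitant volume integrated directly,
without geometric assumptions. `lavvflow` implements that pipeline:
velocity-volume I/O (NIfTI + JSON sidecar), Venc phase unwrapping,
multiplanar reformatting of vector fields, jet tracking, myocardial
background correction, flow-rate and cycle integration, jet–annulus angle
dynamics and circularity, planimetric volumetry, and Bland–Altman /
correlation method comparison. A parametric digital flow phantom with an
exact analytic ground truth stands in for patient data.

The central quantities, from per-phase flow rate
`Q(t) = Σ v⊥·a × 10⁻²` (cm/s × mm² → mL/s) integrated over the tracked
interval:

* total regurgitant volume `R = Σⱼ Rⱼ` (one tracked plane series per jet),
* effective forward volume `E = F − R` (diastolic inflow `F`),
* regurgitant fraction `RF = R / F × 100 %`,
* internal validation `Δ = E − aortic volume` (≈ 0 without shunts).

## Worked example

Simulate the canonical phantom — an 11 mL regurgitant jet whose
jet–annulus angle sweeps 50°→86° across systole in the 2-chamber view,
core circularity 0.61, 78 mL inflow, aortic outflow equal to the
effective forward volume, 3 cm/s velocity noise, at 2.3 × 2.3 × 3.0 mm /
30 phases / Venc 150 cm/s — then track, quantify and characterize it:

```r
library(lavvflow)
report <- run_pipeline(pipeline_config(seed = 101))
print(report$flow)
#> <flow_result>
#>   forward (inflow) volume: 78.21 mL
#>   regurgitant volume(s): lavv_jet = 11.06 mL
#>   total regurgitant: 11.06 mL
#>   effective forward: 67.15 mL
#>   regurgitant fraction: 14.1 %
#>   aortic volume: 66.59 mL;  internal validation diff: 0.56 mL
print(report$jets[[1]])
#> <jet_characterization> 10 systolic phases
#>   2ch: min 49.0, max 87.2, difference 38.2 deg
#>   4ch: min 88.4, max 90.4, difference 2.0 deg
#>   circularity index: 0.64 (peak phase 5)
```

The phantom's true values are 11 mL, fraction 14.10 %, internal
validation 0, sweep difference 36°, circularity 0.61: the pipeline
recovers the regurgitant volume to 0.5 %, the fraction to 0.05
percentage points, and the angle sweep and circularity within the
reading precision of the streamline/segmentation steps. `report$deltas`
lists measured-minus-truth for every quantity.

The numbered scripts under `analysis/` run the full study narrative —
`01_simulate_phantom.R` (write the dataset + manifest),
`02_quantify_regurgitation.R`, `03_characterize_jets.R`,
`04_cohort_validation.R` (20-subject synthetic cohort: Bland–Altman of
effective forward vs aortic flow), `05_volumetry_comparison.R` (direct vs
indirect regurgitant volume) — writing tables under `results/`.

## Learning more

The package vignette (`vignettes/lavv-flow-quantification.Rmd`) documents
the phantom model, the tracking and integration choices, parameter
defaults with units, the unwrapping algorithm and its validity limits,
and what phantom-based validation does and does not demonstrate.
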