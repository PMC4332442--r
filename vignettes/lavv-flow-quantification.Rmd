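---
title: "Quantifying atrioventricular valve regurgitation from 4D flow CMR: models, parameters and validation phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying atrioventricular valve regurgitation from 4D flow CMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

After surgical correction of an atrioventricular septal defect (AVSD), the
left atrioventricular valve (LAVV) frequently leaks. The regurgitant jets
in these patients are hard to grade with echocardiography because they
violate its geometric assumptions: there are often several jets at once,
their direction changes through systole, and their cross-sections are far
from circular. Whole-heart 4D flow CMR measures the full velocity vector
in every voxel over the cardiac cycle, so the measurement plane can be
placed retrospectively, per cardiac phase, perpendicular to each jet —
*retrospective valve tracking* — and the regurgitant volume can be
integrated directly, without geometric assumptions.

`lavvflow` implements that analysis chain end to end:

1. a data model and NIfTI I/O for three-directional velocity volumes
   (`flow_dataset`, `write_flow_dataset`, `load_flow_dataset`);
2. velocity-aliasing correction when speeds exceed the encoding limit
   (`apply_aliasing`, `unwrap_velocity`);
3. multiplanar reformatting of the vector field onto oblique planes and
   through-plane velocity maps (`plane`, `reformat_plane`,
   `make_mpr_stack`);
4. jet tracking and direct flow quantification (`estimate_jet_direction`,
   `build_tracked_planes`, `background_correct`, `flow_rate`,
   `integrate_volume`, `quantify_lavv`);
5. jet characterization: streamlines, per-phase jet–annulus angles in the
   2- and 4-chamber projections, and the cross-sectional circularity index
   (`trace_streamline`, `jet_angle`, `angle_dynamics`,
   `circularity_index`);
6. planimetric volumetry and indirect regurgitation (`simpson_volume`,
   `ejection_fraction`, `la_biplane_volume`, `bsa_du_bois`,
   `indirect_regurgitant_volume`);
7. method-comparison statistics (`correlation`, `bland_altman`);
8. orchestration and cohort summaries (`run_pipeline`,
   `cohort_summarize`).

No patient datasets accompany this package. All validation runs on a
parametric digital flow phantom (`generate_phantom`) with an exact,
analytic ground-truth manifest, generated at the clinical acquisition
geometry.

## Core quantities

With per-phase flow rate $Q(t)$ (mL/s) obtained by integrating the
through-plane velocity $v_\perp$ over the jet region of interest $A$,

$$Q(t) = \sum_{p \in A} v_\perp(p, t)\, a_p \times 10^{-2},$$

($v_\perp$ in cm/s, pixel area $a_p$ in mm²), the volumes follow by
integrating $Q$ over the tracked interval. The derived quantities obey

* total regurgitant volume $R = \sum_j R_j$ over jets,
* effective forward volume $E = F - R$ (forward inflow $F$),
* regurgitant fraction $\mathrm{RF} = R / F \times 100\,\%$,
* internal validation $\Delta = E - Q_{\text{aortic}}$, which should be
  zero in the absence of shunts.

The denominator of the regurgitant fraction is the total diastolic inflow
volume: in steady state the inflow is exactly the effective forward volume
plus the regurgitant volume, which matches the conventional definition.

The jet–annulus angle is measured between the jet direction projected into
a view plane (2-chamber: x–z; 4-chamber: y–z in phantom coordinates) and
the annulus line of that view, in $[0°, 180°)$; a jet entering the atrium
along the annulus normal reads 90°, and angles are deliberately not folded
at 90° because eccentric jets exceed it. The circularity index is the
ratio of minimum to maximum Feret diameter of the jet core (pixels at or
above half the peak through-plane speed, largest 8-connected component,
convex hull, 1° rotation granularity).

## The digital phantom

Each transvalvular flow is an elliptical-cylinder jet: a plug velocity
profile with a cosine-tapered rim (default rim 2 mm, expressed in the
normalized elliptical coordinate via the geometric-mean radius), directed
along a unit vector that may change per phase, modulated by a half-sine
waveform over its active interval. Because the profile and waveform are
closed-form, the peak speed is scaled exactly so that the time-integrated
flux equals the prescribed volume, and the manifest (volumes, per-phase
rates, directions, angles, circularity, peak phase) is analytic.

Defaults reproduce the whole-heart acquisition this analysis targets:
2.3 × 2.3 × 3.0 mm³ voxels, 30 reconstructed phases at 31 ms (RR 930 ms),
Venc 150 cm/s. The canonical scenario programs the clinically typical
magnitudes: 11 mL regurgitation over a 300 ms systole with the
jet–annulus angle sweeping linearly from 50° to 86° across the systolic
phases (difference 36°), core circularity $b/a = 0.61$, 78 mL inflow
(fraction ≈ 14 %), and aortic outflow equal to the effective forward
volume so the true internal-validation difference is zero. Velocity noise
defaults to 3 cm/s SD per component (a realistic velocity-to-noise level
at this Venc), fully determined by the mandatory seed. The sweep is linear
across the *active phases*, so the programmed endpoint angles are exact at
the first and last tracked phase.

Rasterization models partial-volume averaging: every voxel stores the
profile averaged over its extent (2-point Gauss quadrature per axis), as
MR voxels do. Center-point sampling would leave a ~2 % flux bias on jets
only four voxels across.

What the phantom does **not** emulate: it is not divergence-free outside
the jet cylinders (conservation checks therefore compare parallel planes
cutting the same jet segment), there is no turbulence, no intravoxel
dephasing, no eddy-current spatial structure (the baseline offset is
uniform per component), and no magnitude image. Passing tests demonstrate
correct geometry, integration and bookkeeping of the pipeline — not
robustness to everything clinical data can contain.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `offset_mm` | 15 | mm | tracked plane distance from the annulus along the jet, into the receiving chamber (clinical practice: 10–20 mm, to avoid phase dispersion at the orifice); a warning is issued outside that range |
| `roi_frac` | 0.1 | – | jet-ROI threshold as a fraction of the local peak through-plane speed |
| `core_threshold` | 0.5 | – | circularity segmentation threshold (half-max, stable for plug-like cores) |
| `jet_speed_threshold` | 0.5 | – | voxel speed cutoff (fraction of in-sphere peak) for direction estimation |
| `smooth_radius_vox` | 1 | voxels | box pre-smoothing for direction/streamline estimation only |
| plane raster | 64 × 64 @ 1 mm | px, mm | finer than the voxel grid; trilinear interpolation supplies sub-voxel sampling |
| `edge_width` | 2 | mm | cosine rim of phantom jets |
| `noise_sd` | 3 | cm/s | velocity noise per component |

## Numerical and design choices

**Interpolation and geometry.** Velocity sampling is trilinear in voxel
space; points outside the grid return zero and are masked (planes may
overhang the volume, as clinical reformats do). In-plane axes are chosen
deterministically (world x-axis projected into the plane, falling back to
y), so repeated runs build identical planes; all measured quantities are
invariant to that choice. Polygon ROIs select pixels by center
containment with the even–odd rule.

**Default jet ROI.** The automatic contour takes pixels with
$|v_\perp| \ge 0.1 \times$ the local peak (searched within 10 mm of the
plane center, where the tracked jet lies by construction), keeps the
8-connected component containing that peak, and dilates by one pixel. The
connectivity step mirrors what a human tracer does — contour *this* jet —
and keeps other flows that clip the raster (the aortic jet on a
left-ventricular plane) out of the ROI. The threshold is additionally
floored at 1.5 × the background velocity SD estimated from a quiet tissue
patch, so the contour cannot flood into noise at slow phases. Explicit
contours always override the automatic ROI.

**Background correction.** Phase-contrast maps carry a residual baseline
offset; the mean through-plane velocity over a static-myocardium patch is
subtracted per phase. The automatic patch is the fully in-bounds raster
quadrant square (centers ±20 mm, 8 mm wide) with the lowest through-plane
variance — static tissue carries only offset plus noise, flowing blood has
structure.

**Cycle integration.** Rates are measured at the tracked phases, anchored
with zero rate at the tracked-interval endpoints (the valve is closed
outside the interval), and integrated via a natural cubic spline through
the samples. A plain trapezoid at 31 ms sampling underestimates a 300 ms
systolic half-sine by ~0.9 % but the 450 ms diastolic inflow by only
~0.4 %; that asymmetry alone would dominate the internal-validation
difference. The generic `integrate_volume` utility keeps the standard
trapezoidal rule.

**Direction estimation under noise.** At the half-sine endpoints the jet
core moves at ~3 cm/s — the same magnitude as the velocity noise — so a
single-phase direction estimate is information-limited. Two physically
motivated steps recover the trajectory: (i) a 3³-voxel box smoothing of
the field used *only* for direction estimation and streamline tracing
(flux quantification and the circularity cross-section always use raw
data, because box smoothing is anisotropic in millimetres on anisotropic
voxels and would bias the half-max contour); (ii) a weighted quadratic
fit of the per-phase direction vectors over the tracked interval, with
weights proportional to voxel count × squared jet speed — the temporal
coherence of valve and jet motion is precisely the prior that
retrospective tracking exploits.

**Phase unwrapping.** Velocities beyond ±Venc wrap by multiples of
2·Venc. Correction is continuity-guided region growing: trusted seeds
(voxels outside the correction region, or the grid faces) are taken as
unwrapped, and a breadth-first front assigns each voxel the 2·Venc
multiple closest to the mean of its already-unwrapped 6-neighbors,
followed by consistency sweeps against the 26-neighborhood mean. Validity
requires the *true* field to be continuous at the voxel scale and wrapped
regions not to touch the seeds. Marginal aliasing — true peaks only a few
cm/s above Venc — is intrinsically ambiguous for any local method (the
wrapped plateau is then numerically consistent with the static
background) and is outside the method's scope; jets that alias in
practice exceed Venc substantially.

**Degenerate inputs.** Zero-velocity fields raise "no jet detected";
directions perpendicular to a view plane raise a degenerate-projection
error rather than returning an arbitrary angle; empty segmentations and
ROIs error out; ties in the largest-projection slice selection go to the
lowest index.

## Problem sizes

The phantom grid is 42 × 42 × 40 voxels × 3 components × 30 phases
(≈ 6.3 M velocity samples, ~100 × 100 × 120 mm field of view), which keeps
a full simulate–track–quantify–characterize run at a few seconds and the
20-phantom cohort analysis at ~2 minutes on one core. The unit-test
phantoms use 26³ grids.

## Known limitations

* The jet model is kinematic, not fluid-dynamic; there is no Coandă
  adhesion, turbulence or orifice phase dispersion, so the 10–20 mm
  plane offset matters less here than clinically.
* View planes (2-/4-chamber) are declared inputs; no anatomical view
  planning is attempted, and clinical data would need explicit plane and
  contour inputs (`quantify_lavv` accepts them).
* The angle convention (against the annulus line, not its normal) is
  fixed by the reading that a jet entering the atrium perpendicular to
  the annulus measures 90°.
* Circularity is measured on pixel centers of the segmented core; for
  very small jets (core < 3 voxels across) rasterization dominates the
  index.
* Bland–Altman limits use the fixed 1.96 multiplier without small-sample
  correction; Spearman p-values use the t approximation with average
  ranks for ties.
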