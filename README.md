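# ctmotion

Implant migration measurement from paired clinical CT scans, in the manner
of CT-based radiostereometric analysis (CT-RSA), for tibial components in
total knee arthroplasty.

Early and continuous migration of a tibial tray relative to the tibia
predicts later aseptic loosening, and migration of fractions of a
millimetre is clinically meaningful. The gold-standard measurement, RSA,
needs stereo radiographs, implanted markers and dedicated equipment; CT-RSA
measures the same quantities from two ordinary CT scans. `ctmotion`
implements the full volumetric-matching workflow:

1. **Segmentation** of bone and implant masks in the baseline scan:
   HU thresholding, seeded 26-connectivity region growing, ball-element
   erosion/dilation, removal of the scatter-degraded bone directly under
   the metal baseplate, and subtraction of the (dilated) implant mask from
   the bone mask.
2. **Masked rigid registration** of each structure from baseline to
   follow-up by voxel intensities: normalized cross-correlation over the
   mask, multi-resolution schedule, deterministic Nelder-Mead optimization.
3. **Migration parameters** from the relative transform
   `T_bone^-1 ∘ T_implant`, reported in the implant-centred anatomical
   frame (+x medial, +y proximal, +z anterior, right-knee convention):
   translations `Tx, Ty, Tz` of the implant centre of gravity (mm), Cardan
   rotations `Rx, Ry, Rz` (degrees, fixed-axes x→y→z), their vector norms
   `TT = ||T||` and `TR = ||R||`, and the main outcome

   `MTPM = max_p ||M(p) − p||`

   the maximum total point motion over the implant surface points.
4. **Agreement statistics** for method and observer comparisons:
   Bland-Altman mean difference with limits of agreement
   `mean ± 1.96·SD`, t-based 95% CIs (`t·SD/√n` for the mean,
   `t·SD·√(3/n)` for each limit), ICC(2,1) with its F-based 95% CI, and a
   Shapiro-Wilk normality check.
5. A **digital phantom**: an analytically voxelized tibia (tapered, lobed
   cortical shell) carrying a metal tray (elliptical plate, stem, fins) at
   clinically realistic Hounsfield plateaus, spacing, noise and metal
   scatter, with a *known* rigid micromotion between time points — so
   every stage is testable against ground truth without clinical data.

## Worked example

```r
library(ctmotion)

# a baseline/follow-up pair whose implant truly moved 0.5/-0.3/0.2 mm
spec <- phantom_spec(implant_motion = rt_from_params(t = c(0.5, -0.3, 0.2)))
pair <- generate_pair(spec)
pair$ground_truth$reference$MTPM   # 0.6164414 (= sqrt(0.38) mm)

out <- run_pipeline(pair$baseline, pair$followup, study_config())
out$result
```

The pipeline prints, for this pair (numbers from an actual run):

```
<migration_result> (reported for a right-sided knee)
  MTPM 0.6210 mm | TT 0.6205 mm | TR 0.0015 deg
  T (mm):  x +0.4997  y -0.3096  z +0.1985
  R (deg): x +0.0013  y +0.0004  z -0.0006
```

i.e. the measured maximum total point motion is within 0.005 mm of the
ground truth and each translation axis is recovered to about a hundredth
of a millimetre at clinical noise and voxel sizes. `out$diagnostics`
carries the segmentation report (thresholds in HU, mask volumes in cm³),
the bone length used for matching (warned below 7 cm), per-structure
similarity scores and convergence flags.

Observer and method comparisons use the agreement module:

```r
rep <- agreement_suite(results_obs1, results_obs2)  # 9 parameters
rep$summary[, c("parameter", "mean_diff", "loa_lower", "loa_upper", "icc")]
```

A thin command-line interface is installed with the package
(`exec/ctmotion`): subcommands `simulate`, `segment`, `register`,
`migrate`, `check`, `run` and `agree` over NIfTI volumes, JSON transforms
and CSV reports.

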