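---
title: "Measuring implant micromotion from paired CT scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring implant micromotion from paired CT scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ctmotion` measures the rigid micromotion of a metal tibial tray relative
to the tibia between two CT scans of the same knee. This vignette explains
the measurement model, the choices behind each stage, what the synthetic
phantom does and does not emulate, and the numerical decisions that matter
for sub-voxel accuracy.

## The measurement model

Both the bone and the implant are treated as rigid bodies. Each is
registered independently from the baseline scan to the follow-up scan by
maximizing a masked intensity similarity, yielding two world-space rigid
transforms $T_b$ and $T_i$. Patient repositioning between scans affects
both equally, so the clinically meaningful quantity is the *relative*
motion expressed in the baseline bone frame,

$$M = T_b^{-1} \circ T_i,$$

which is the identity for a perfectly stable implant regardless of how the
limb was repositioned. From $M$ the package reports, in an anatomical frame
(+x medial, +y proximal, +z anterior, right-knee convention):

* translations $T_x, T_y, T_z$ — displacement of the implant centre of
  gravity (mm); the CoG is the unweighted centroid of the implant-mask
  voxel centres (metal HU values are scanner-saturated, so intensity
  weighting would add noise, not information);
* rotations $R_x, R_y, R_z$ — Cardan angles of the rotation part, in
  degrees, extracted with the fixed-axes sequence x→y→z
  ($R = R_z R_y R_x$). At the sub-2° magnitudes of implant migration the
  sequence choice is second order, but it is fixed and recorded in every
  output;
* the vector norms $TT$ (mm) and $TR$ (degrees);
* $\mathrm{MTPM} = \max_p \lVert M(p) - p\rVert$ over the implant surface
  points — the 6-connectivity boundary voxel centres of the implant mask.
  For a rigid motion the maximum displacement is attained on the convex
  hull, so surface points suffice; using mask-derived rather than
  CAD-derived points matches how the measurement is defined when no CAD
  model is available.

Left knees are reported in the right-knee convention by reflecting the
motion about the sagittal plane through the implant CoG and
re-decomposing. For this Cardan sequence the reflection is *exactly* a
sign flip of $T_x$, $R_y$ and $R_z$ (conjugating $R = R_z(c)R_y(b)R_x(a)$
by $\mathrm{diag}(-1,1,1)$ gives angles $(a,-b,-c)$), and MTPM, TT and TR
are unchanged.

## Segmentation

Masks are built on the baseline scan only:

* **Thresholding.** The bone mask takes $[\theta_\text{bone},
  \theta_\text{implant})$ HU, the implant mask $[\theta_\text{implant},
  \infty)$. Clinically used values centre around 430 HU (range roughly
  220–770) for bone and 2200 HU (1900–3100) for metal; the upper cap on
  the bone window keeps metal voxels out of the bone mask by
  construction. Thresholds are observer choices; the whole point of the
  interobserver analysis is that the downstream result barely depends on
  them.
* **Region growing** retains the 26-connected components containing a
  seed (26-connectivity is the most permissive standard choice). Automatic
  seeding picks the largest component for bone — a centroid-based seed can
  land in the thin partial-volume halo around the metal — and the
  brightest voxel for the implant.
* **Morphology** uses a discrete Euclidean ball in voxel units (erode 1,
  dilate 1 by default — an opening). Anisotropic spacing is deliberately
  ignored, matching how interactive segmentation tools behave. The radii
  are a convention, not a measured quantity.
* **Proximal cut.** The few millimetres of bone directly distal to the
  baseplate are corrupted by metal scatter and are removed below the tray
  plane. The tray plane is derived automatically as the most distal face
  of the tray slab (the contiguous run of widest implant slices), normal
  +y. The default cut is 8 mm: the scatter band itself (modelled at 5 mm)
  plus a margin for implant/limb motion between scans and for the reach of
  the registration's Gaussian smoothing. A cut equal to the band width
  exactly leaves a corrupted sliver in the mask whenever the implant has
  moved.
* **Implant subtraction.** The implant mask, dilated by 4 voxels
  (≈ 2 mm), is subtracted from the bone mask. The dilation matters: the
  metal's partial-volume halo — voxels on the 2500→300 HU ramp that fall
  inside the bone window — moves with the *implant*, and leaving it in
  the bone mask measurably biases the bone registration toward the
  implant's motion (we observed bone-transform errors of several tenths
  of a millimetre without the margin, and ≤ 0.02 mm with it).
* **Bone length** is the extent of the final bone mask projected on the
  proximal axis; below 7 cm a quality warning is raised, reflecting the
  practical recommendation for reliable matching.

## Registration

The similarity is normalized cross-correlation (NCC) between the fixed
volume's masked intensities and the moving volume's intensities sampled at
the transformed positions with trilinear interpolation. NCC is invariant
to positive affine intensity changes, which is the robustness needed
against interval bone remodeling and calibration drift; a 32-bin
histogram mutual information metric is available as an option. The
optimizer is Nelder-Mead over 6 parameters (degrees and mm — at these
scales 1° and 1 mm move the metric comparably) with rotations pivoted at
the mask centroid, a 3-level schedule (point stride 4/2/2, Gaussian
smoothing 2/1.2/1.2 voxels), translation initialization from intensity
centroids, and a convergence requirement of a parameter step below 1e-4.
There are no random restarts; identical inputs give identical output. The
sample positions carry a fixed sub-voxel jitter (deterministic, seeded
internally) so that the moving-volume interpolation behaves uniformly over
candidate transforms instead of favouring grid-aligned ones.

Two numerical effects dominate sub-voxel accuracy, and both informed the
defaults:

* **Noise-interpolation bias.** With independent noise in the two scans,
  trilinear interpolation *averages* noise at off-grid positions, so NCC
  is inflated away from grid-aligned truth. Keeping Gaussian smoothing of
  1.2 voxels at the finest level (rather than none) suppresses this; we
  measured ~0.1 mm bias without smoothing and ~0.01 mm with it.
* **Interpolation bias on under-resolved edges.** If edges are sharper
  than the sampling grid supports, the interpolated moving image is a
  pose-dependent distortion of the fixed one, displacing the NCC optimum.
  This constrains the *phantom* (below) to band-limited edges, and on
  real scans it is mitigated by the same smoothing.

The registration result records initial and final similarity, the
evaluation count, the masked voxel count, and an explicit convergence
flag; non-convergence aborts the pipeline unless forced. Inverse
consistency (registering A→B and B→A and composing) holds at the level of
the noise-limited single-registration accuracy (~0.05 mm/°), not at the
optimizer's parameter tolerance — the tolerance controls termination, not
statistical accuracy.

## The digital phantom

The phantom exists so that every stage can be validated against known
ground truth: no clinical CT pairs with independently known micromotion
are publicly available. It voxelizes, by supersampled analytic evaluation
(3×3×3 midpoint rule per voxel):

* a **tibia** as a tapered cylinder (outer radius 28 mm proximally,
  tapering to 75%, length 80 mm) with a 4 mm cortical shell at 600 HU
  around trabecular bone at 300 HU, and a tri-lobed angular modulation
  (amplitude 0.12) of the outer radius. The lobes make the cross-section
  tibia-like rather than circular; without them rotation about the bone
  axis would be unobservable by any intensity metric;
* a **tibial tray** at 2500 HU: an *elliptical* plate (semi-axes
  32 × 22 mm — trays are wider medial-lateral than anterior-posterior,
  which likewise makes axial rotation observable), 4 mm thick, with a
  40 mm stem and four 3 mm fins welded underneath (the stem and fins
  extend into the plate interior so the shared faces are not spurious
  metal-air edges);
* **background** at −50 HU, additive Gaussian noise of 20 HU drawn
  independently per volume from the spec seed, voxel spacing 0.5 mm
  in-plane and 0.4 mm between slices (clinically typical values for this
  application), and a **scatter band**: a multiplicative radial streak
  pattern (amplitude 25% of local HU, ≈150 HU on cortical bone) confined
  to 5 mm directly distal to the tray plate, rigidly attached to the
  implant. The streak model is a stand-in for the real, spatially complex
  scatter; its role is to justify and exercise the proximal-cut step, not
  to claim physical fidelity.

Edges use a logistic profile of 0.8 mm 10–90% width attached to each
structure's local frame, emulating a clinical reconstruction's ~1 lp/mm
resolution. This choice is load-bearing twice over: it is what makes
sub-voxel motion recoverable from partial-volume intensities (hard-edged
voxelization quantizes edge occupancy and produced orientation-dependent
biases up to 0.1°), and it keeps the images approximately band-limited so
trilinear interpolation is trustworthy.

The follow-up volume is *always* re-voxelized analytically in the moved
pose (limb repositioning applied to everything; the ground-truth migration
additionally applied to the implant in the bone frame) — never resampled
from the baseline grid, which would correlate the two volumes' sampling
artifacts and flatter the registration.

What the phantom does **not** emulate: beam hardening and streak artifacts
away from the baseplate, spatially varying noise, the polyethylene insert
and femoral component, cement, real trabecular texture, and anatomically
realistic bone shape. Passing the phantom suite therefore demonstrates the
*numerical* fidelity of the chain (segmentation → registration →
decomposition → statistics) under controlled, clinically plausible imaging
conditions; it does not by itself establish clinical accuracy on real
scans.

## Validation statistics

For paired migration series (two methods or two observers, n subjects):

* **Bland-Altman**: differences $d = a - b$; limits of agreement
  $\bar d \pm 1.96\,s_d$ with the multiplier fixed at exactly 1.96; the
  95% CI of the mean difference uses the t distribution with $n-1$ df
  ($t_{0.975}\,s_d/\sqrt n$) — with $n = 24$ this is the only choice
  consistent with published half-widths when back-computed from their
  printed limits; each limit's CI uses the standard
  $t_{0.975}\,s_d\sqrt{3/n}$ approximation. Shapiro-Wilk (Royston's
  approximation, implemented in the package and cross-checked against the
  reference implementation in tests) accompanies every report.
* **ICC**: the default form is ICC(2,1) — two-way random effects,
  absolute agreement, single measurement — because the validation question
  is whether observers produce the *same* numbers, not merely correlated
  ones. The 95% CI follows the F-based method of McGraw and Wong. ICC(3,1)
  is exposed for sensitivity. No multiple-testing adjustment is applied
  across the nine parameters.

## Problem sizes and determinism

The test suite and the acceptance script run study-condition phantoms
(145 × 241 × 145 voxels at 0.5/0.4/0.5 mm) for end-to-end checks, a
27-point motion grid (|t| ≤ 0.8 mm, |θ| ≤ 1° per axis combined) for
parameter recovery, and a scaled-down phantom for unit tests; the MTPM
oracle is exercised on hundreds of random rigid motions against an
explicit per-point maximum. The motion grid shares one baseline volume
(the baseline does not depend on the motion), which makes the sweep
affordable while still varying the follow-up pose per case. All phantom
randomness flows from the spec seed; registration and the pipeline are
deterministic, so repeated runs produce byte-identical outputs.

## Known limitations

* The similarity metric, optimizer and interpolation are this package's
  own contracts, validated by phantom recovery — commercial CT-RSA tools
  do not disclose theirs, and no claim of equivalence is made.
* MetaImage and DICOM-series input are not supported; volumes travel as
  NIfTI with the world geometry in the sform.
* Registration accuracy on real scans will additionally depend on metal
  artifacts, reconstruction kernel and dose — factors outside the
  phantom's scope.
* The eligibility rule (slice thickness strictly below 1.0 mm) and the
  7 cm bone-length warning are quality gates, not guarantees.
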