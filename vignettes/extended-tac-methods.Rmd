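---
title: "Extended thoracic-aorta calcium scoring: models, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended thoracic-aorta calcium scoring: models, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Thoracic aorta calcium (TAC) is usually quantified opportunistically on the
same non-contrast CT acquisition used for coronary artery calcium (CAC)
screening. A routine cardiac scan, however, covers only the ascending aorta
near the root and the distal descending aorta; the aortic arch — the
curvilinear portion between the subclavian branches — is outside the scan
range and is systematically excluded from TAC scores. `aortacalc`
implements the full analysis chain needed to study what that exclusion
hides: centerline-based segmentation of the whole thoracic aorta on an
extended scan, per-lesion Agatston scoring with anatomical segment
assignment, and cohort-level statistics contrasting the *standard*
(segments 1 and 5 only) with the *extended* (all five segments) TAC
measurement, including the stratification of subjects into three groups —
free of calcium, detected by the standard method, and detected exclusively
by the extended method (the reclassification candidates).

Because no patient volumes can be redistributed, the package is organised
around synthetic data with analytic ground truth: every image-analysis
stage is exercised against phantoms whose centerline, diameters, segment
boundaries and lesion scores are known in closed form, and the cohort
statistics are exercised against generated cohorts whose marginal counts
are controlled exactly.

## The segmentation model

### Circle inscription

The vessel cross-section on a 2D plane is located by dynamically expanding
and re-centring a circle inside the lumen-like region
(`inscribe_circle()`). A pixel is *lumen-like* when its (3×3
box-smoothed) HU value lies within `hu_tol` of a local reference — the
median HU of the 5×5 patch around the seed. The radius grows in
`growth_mm` = 0.25 mm steps while at least 95% of 72 perimeter samples
remain lumen-like; the centre then moves to the centroid of the per-ray
lumen boundary (the first non-member sample along each of the 72 radial
rays), and growth and centring alternate until the centre moves less than
0.05 mm or 50 iterations elapse. A final refinement moves the centre to
the Chebyshev centre of the ray-boundary polygon (the point maximizing the
inscribed radius): on asymmetric sections — a curved tube bulges toward its
inner curvature — the boundary centroid alone is biased by up to half the
bulge, and the refinement removes that bias. On a convex section the
centroid step halves the centre offset per iteration, so convergence is
geometric.

Two guards make the tracker fail loudly instead of drifting: a seed whose
patch reference differs from the expected lumen HU (`lumen_hu`, default
40 HU — unenhanced blood) by more than `hu_tol` raises a seed error, as
does a region that stays lumen-like out to `r_max_mm` (a seed in a uniform
background); and a cross-section whose diameter jumps by more than 30%
between consecutive planes truncates the track (the sweep has left the
vessel). The 30% jump bound is deliberately loose so that genuine wall
calcifications — which locally indent the inscribed circle — never truncate
a track.

`hu_tol` defaults to 25 HU. It must stay below the lumen-to-background
contrast (40 HU here: lumen 40, mediastinal background 0) or circle growth
would never stop at the wall, and comfortably above the residual noise of
the smoothed image (a 3×3 box filter reduces 20 HU of white noise to about
7 HU), so that the 95% perimeter-coverage test is stable. Both bounds are
checked by the test suite (noise robustness at sd = 20 HU; wall stopping
on every phantom).

### Axial and semitoroidal tracking

The user supplies two seed points at the level of the pulmonary artery
bifurcation: `C_A` in the ascending and `C_D` in the descending aorta.
Below the seeds the vessel is near-vertical and is tracked slice by slice
on axial planes (`track_descending()`), each slice's circle centre seeding
the next slice — down to the diaphragm end of the volume on the descending
side, and down to the left main coronary (LMCA) level on the ascending
side. The curvilinear portion is tracked on oblique planes
(`track_arch()`): planes contain the rotation axis through the midpoint of
the `C_A`–`C_D` chord (perpendicular to the chord and to the axial
direction) and rotate in 2° steps up to 240°, endpoint-inclusive — 121
planes at the defaults. Each plane is resliced from the volume by
trilinear interpolation (`reslice_oblique()`); an axis-aligned plane
reproduces the corresponding axial slice bit-exactly because the
interpolation weights collapse to 0/1.

The three tracks are merged proximal-to-distal. The oblique sweep beyond
the seed-chord plane re-covers the limbs below the seed level, territory
the axial tracks own with exactly perpendicular planes, so arch points
below the seed level are clipped; remaining near-duplicates at the
junctions (closer than a quarter of the axial spacing) are resolved by
keeping the point whose plane is more perpendicular to the local travel
direction. Finally `perpendicular_correction()` re-estimates tangents from
the smoothed polyline (running mean, window 5), reslices each
cross-section in the plane orthogonal to its tangent and re-inscribes the
circle; two passes are run because the first pass's tangents are estimated
from the raw track, and re-centred positions improve them materially at
the limb–arch transitions. On the default phantom the full extraction
yields about 150 centerline points over a ~28 cm vessel.

### Segment partition

Four landmarks — LMCA, right and left subclavian arteries (RSA, LSA), and
the coronary sinus (CS) — bound five segments. Boundaries
proximal-to-distal: the LMCA projection starts segment 1; the seed-pair
axial level on the ascending limb separates 1|2; the RSA and LSA
projections separate 2|3 and 3|4; the CS axial level projected onto the
descending limb separates 4|5; the distal terminus ends segment 5. This
rule makes segments 1 and 5 coincide with the coverage of a standard
cardiac scan, which is the operative definition of *standard TAC*.
Landmark projection takes the nearest centerline point (ties to the
proximal one, and a landmark farther than 5 cm from the line warns);
boundary hits belong to the distal segment (half-open intervals). The five
intervals tile the centerline exactly — the partition identity
`sum(lengths) == total length` is asserted to a relative 10⁻⁶ in the
tests.

## Calcium scoring

Candidates are the 26-connected 3D components of voxels at or above
130 HU (`detect_candidates()`); components whose largest single-slice area
falls below 1 mm² are discarded (the classical operational minimum). A 3D
component definition was chosen over per-slice objects so that a lesion
spanning several slices counts once in the spatial distribution; the
convention is recorded in the output metadata. The Agatston score of a
lesion is the per-slice sum of (area in mm²) × (weight 1/2/3/4 for a
slice-peak HU of 130–199/200–299/300–399/≥400), computed on the native
2.5 mm slices with no slice-thickness rescaling. An independent per-voxel
oracle (`analytic_agatston()`) computes the same quantity directly from
the lesion's analytic geometry, bypassing component labelling entirely;
pipeline and oracle must agree exactly on every synthetic lesion, and do —
this is one of the acceptance properties.

The interactive validation step of the original workflow (the reader
clicks each highlighted candidate) is replaced by a geometric surrogate:
a candidate is accepted when its centroid lies within 1.5× the local
lumen radius of the nearest centerline point (`validate_lesions()`).
The margin is configurable; acceptance is monotone non-decreasing in it.
Accepted lesions are orthogonally projected onto the centerline and
assigned to the segment containing the projection's arc length
(`assign_segment()`), and per-segment scores and counts are accumulated
with exact conservation (`accumulate_scores()`).

## The synthetic phantom

`phantom_spec()` describes an aorta as an ascending cylinder, a torus-arc
arch and a descending cylinder, tangent-continuous, with a configurable
lumen diameter profile; reduced variants (`tube_phantom_spec()`,
`torus_phantom_spec()`) isolate single stages. Default geometry emulates a
250 mm field of view at 0.5 × 0.5 × 2.5 mm voxels: lumen 28 mm across,
arch radius 30 mm, and an inter-subclavian arch segment of 30 mm (RSA and
LSA half a radian either side of the apex) — a typical adult arch, which
also puts segment 3 at 3 cm, the scale on which per-cm lesion densities
are computed. Lumen HU is 40 and background 0, with Gaussian noise applied
to the background only (lumen and lesions are uniform, matching the
stated phantom contract); HU are rounded to integers as on a real scanner,
which also makes the int16 NIfTI round trip lossless. Tube ends are flat
(no spherical caps): the thoracic aorta leaves the scan through its end
faces, and a rounded cap inside the volume would be an artifact with no
anatomical counterpart. Lesions are cuboids or ellipsoids placed tangent
to the lumen surface (`wall_lesion()`), half in and half out — the
intimal/medial wall location of aortic calcification.

What the phantom deliberately does not model: scanner physics (beam
hardening, gating artifacts, dose), the aortic wall as a distinct layer
(non-contrast CT cannot separate wall from lumen, so the phantom models
lumen only, with calcifications on its surface), anatomical variability
(no taper, no arch asymmetry beyond what the spec parameters express), and
the aortic valve (excluded from scoring by construction, since tracking
starts at the LMCA). Passing the phantom suites therefore demonstrates
algorithmic correctness — geometry recovery, scoring identities, segment
logic — not clinical performance on patient data.

One measurement property is worth stating plainly: across the arch apex
the vessel runs horizontally, so the perpendicular cross-section spans the
2.5 mm axial axis and the rasterized tube surface is a 2.5 mm staircase.
The largest inscribed circle of that staircased section is genuinely up to
~1 mm smaller than the analytic diameter. Centerline positions are
unaffected (sub-half-voxel everywhere); diameters are exact along the
limbs (in-plane sampling) and carry the axial quantization at the apex.
The acceptance thresholds reflect this anisotropy: centre errors are held
to the in-plane voxel, apex diameters to the axial voxel.

## The synthetic cohort

`cohort_spec()` describes a screening cohort of 970 subjects (77% men,
age 57 ± 9, hypertension 49%, hypercholesterolemia 82%, current-or-past
smoking 54%, diabetes 9%) with per-segment TAC, CAC, and per-segment
lesion counts. Two modes:

* **Stochastic** — every subject sampled independently from the prevalence
  targets, with an optional log-odds age slope on segment positivity
  (default 0). Used for calibration checks: recovered prevalences must sit
  within three binomial standard errors at n = 970, and the three-group
  ANOVA must hold its nominal type-I error (checked over 1000 null
  simulations).
* **Exact-marginal** — a deterministic construction whose marginal counts
  equal the requested integers exactly, then shuffled by the seed. The
  default counts are: 618 extended-TAC positives, 296 standard-TAC
  positives, 598 CAC positives, 457 positive on both, 211 free of any
  calcium; groups of 211/648/111; per-segment positives
  (39, 116, 407, 534, 296); per-age-tertile positives (122, 209, 287); and
  10831 lesions split (412, 371, 2803, 3824, 3421) across the segments.

Two of those integer choices deserve their derivations. First, the
standard-positive set is the union of the segment-1 and segment-5
positives, so its size caps the segment-5 count: with 296
standard-positives, the segment-5 count must be ≤ 296 (and 296/970 =
30.5% still rounds to the 31% headline), with the 39 segment-1 positives
nested inside. Second, per-tertile positive counts that each round to
(38, 65, 89)% would naively be (123, 210, 287) — but those sum to 620,
not 618; the adjusted (122, 209, 287) is the count vector that both sums
to the extended-positive total and rounds to the printed percentages
under the package's nearest-integer convention. Ages are drawn per group
(normal quantiles at means 50/59/55, sd 8) and then repaired to hit the
tertile counts exactly by swapping ages between a positive subject in a
surplus tertile and a negative subject in the deficit tertile — the age
multiset, and hence the tertile boundaries, is invariant under the swaps.

Positive segment scores are log-normal (meanlog log 140, sdlog 1.6; CAC
meanlog log 65), chosen once to put the all-subject medians in the tens,
the scale typical of screening populations; score magnitudes are not
parity-tested. Percentages are reported to the nearest integer, halves
away from zero, and every parity test works on that convention.

## Framingham risk

The 10-year risk (`framingham_risk()`) uses the published
continuous-variable Framingham general cardiovascular model: sex-specific
Cox regressions on ln(age), ln(total cholesterol), ln(HDL), ln(SBP), with
smoking and diabetes as indicator terms, `risk = 1 − s0^exp(lp − mean_lp)`.
The coefficient table is embedded verbatim (`framingham_coefficients()`)
and guarded by a frozen regression fixture computed with an independent
hand implementation. Cholesterol enters in mg/dl (the package converts
from mmol/l, × 38.67). Two modelling caveats are intentional: treatment
status for hypertension is not modelled (the untreated-SBP coefficient is
used throughout), and the cohort's smoking flag is *current or past*
while the model expects current smoking — both noted limitations of the
tabular inputs rather than of the model code. Because this is a
general-CVD model, absolute risks in the simulated cohort run higher than
a coronary-only risk equation would give; the group comparisons (ANOVA +
Tukey HSD on age and risk, chi-square with pairwise Bonferroni-corrected
tests on categorical factors) depend only on the ordering and spread,
which match the expected pattern: the reclassification group sits between
the calcium-free and standard-detected groups in age, resembles the
calcium-free group in risk, and carries a markedly higher proportion of
women.

## Problem sizes and runtime

The oracle-equivalence acceptance checks run at clinical resolution
(512 × 512 × 80 voxels at 0.5/0.5/2.5 mm; generation plus full extraction
is under half a minute per volume on one CPU). Unit tests use reduced
grids (roughly 200³ mm at 1 mm in-plane) that preserve every geometric
relation at about a tenth of the cost; the bundled demo pipeline runs ten
subjects on a coarse 96 × 96 × 40 grid in a few minutes. The
exact-marginal cohort is instantaneous, and the 1000-replicate ANOVA
calibration takes a few seconds.

## Degenerate inputs and tie-breaks

* A zero-span sweep returns the single seed-level plane; a seed on the
  bottom slice returns a single-point track.
* An empty candidate set accumulates to an all-zero score table; a
  zero-lesion distribution reports zero shares with an explicit
  `undefined_shares` flag.
* Landmark projection ties break proximal; segment-boundary hits go
  distal; tertile ties break by subject order.
* Missing covariates or segment scores raise errors naming the column —
  the cohort analysis is complete-case by design, mirroring a cohort with
  no missing data.
* Exact-marginal count sets are validated up front; every violated
  inequality is reported in the error message.
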