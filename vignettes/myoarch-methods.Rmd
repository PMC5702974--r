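---
title: "Mapping ventricular myocardial architecture from diffusion tensor CMR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping ventricular myocardial architecture from diffusion tensor CMR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The ventricular walls are built from helically wound aggregations of
cardiomyocytes. Their orientation is commonly summarized by three angles
measured against a local wall-attached coordinate frame: the **helical
angle** (the inclination of the fibre direction within the epicardial
tangential plane, positive when sub-endocardial fibres wind
counterclockwise towards the base as seen from the base), the **intrusion
angle** (the tilt of the fibre out of the tangential plane), and the
**E3 angle** (the tilt of the tertiary eigenvector — the normal of the
flattened cardiomyocyte aggregates, often called sheetlets — against a
reference plane). Chronic right-ventricular volume overload, e.g. from
pulmonary valve regurgitation, remodels this architecture; the
quantitative signature is a shift of right-ventricular midwall helical
angles towards a more circumferential (flatter) orientation.

Ex-vivo diffusion tensor cardiovascular magnetic resonance (DT-CMR)
measures these orientations indirectly: the primary eigenvector of the
per-voxel diffusion tensor follows the mean long axis of the aggregated
cardiomyocytes, and the tertiary eigenvector follows the aggregate
normal. `myoarch` implements the full analysis chain and a synthetic
biventricular phantom that generates DT-CMR data with *known* fibre and
sheet-normal fields, so that every stage of the chain can be validated by
parameter recovery.

## Signal model and tensor estimation

Diffusion-weighted signals follow the single-tensor Stejskal-Tanner
model,

$$S(\mathbf g, b) = S_0 \exp(-b\, \mathbf g^\top D\, \mathbf g),$$

with $D$ symmetric positive definite (units mm²/s). The acquisition
emulated by the phantom uses 30 isotropically distributed directions at
b = 1000 s/mm² plus one b = 0 image, at 0.4 × 0.4 mm in-plane resolution
and 0.8 mm slice thickness. The direction table ships with the package as
a fixed electrostatic-repulsion layout (minimal antipodal Coulomb
energy); any user scheme with at least one b = 0 measurement and six
non-collinear directions is accepted.

`fit_tensor()` solves the log-linearized system per voxel by ordinary
least squares for the six tensor components and $\log S_0$. OLS is the
transparent baseline estimator: it is exact on noiseless data, which is
what the recovery experiments require, and unbiased enough at the noise
levels studied here. Non-positive signals are dropped per voxel; voxels
with fewer than 7 usable measurements or a rank-deficient design are
flagged invalid rather than filled. Negative eigenvalues are clamped to
zero and flagged; near-equal leading eigenvalues
($(\lambda_1-\lambda_2)/\lambda_1 < 10^{-6}$) set a `degenerate` flag.
Flagged voxels never enter angle statistics. Eigenvector signs are left
unconstrained; every angle computation folds antipodally, so no global
orientation convention is needed.

## Local frames

Analysis proceeds on three short-axis slices of interest — the middles of
the basal, equatorial and apical thirds of the apex-to-base extent —
after verifying long-axis alignment (the principal inertia axis of the LV
wall mask; the apex is recognized as the end with the smaller radial
spread). Each slice is divided into 64 equal-angle sectors about the LV
cavity centroid; right-ventricular free-wall voxels are binned with the
same angular width, so the number of RV sectors scales with the size of
the ventricle.

Per sector, the epicardial tangential plane is estimated from the
epicardial boundary in the slice of interest and the slices nominally
2 mm above and below (snapped to whole slices; ±2 slices at 0.8 mm,
i.e. 1.6 mm). Two numerical details matter here, both found by
validating against the phantom:

* **Point placement.** A plane fitted through three epicardial points at
  a single azimuth is degenerate — the points are coplanar with the
  meridian plane and the fitted "normal" is tangential. Even symmetric
  three-point placements leak meridional curvature into the normal's
  azimuth (about 10° at the apical slice, where the wall surface is
  tilted ~35° from vertical). `build_frames()` therefore uses the
  unbiased discrete surface normal: the cross product of the
  circumferential chord across the sector (within the slice of interest)
  and the meridional chord between the epicardial points of the slices
  above and below at the sector-centre azimuth. Both chords are centred
  on the sector centre, so neither curvature biases the normal. The
  classical three-point construction remains available as
  `epicardial_tangent_plane()` and is exact on a cylinder.
* **Boundary radii.** Taking the innermost/outermost voxel-centre radius
  of a sector wedge quantizes the boundary by up to a voxel and biases
  transmural depth by 1–3% of wall thickness. The wedge's endo- and
  epicardial radii are instead solved from its voxel count (area) and
  mean radius under an annular-sector model, which is sub-voxel accurate;
  sparse or partially covered wedges (e.g. crescent ends) fall back to
  half-voxel-padded extremes.

The local frame sets `radial_outward` to the plane normal,
`longitudinal` to the normalized projection of the long axis onto the
tangential plane, and `circumferential` to their cross product
(counterclockwise viewed from the base, making the triple right-handed).
Frames whose normal lies within 5° of the long axis (apex cap) are
undefined and their voxels excluded.

**Transmural depth** is the linear fraction along the in-slice radial ray
between the endocardial and epicardial boundary of the voxel's sector,
0% at the sub-endocardium and 100% at the sub-epicardium; for the septum
the 100% boundary is the right-ventricular sub-endocardium. The phantom
prescribes its ground-truth profiles against exactly this in-slice
definition (not the 3-D ray fraction): on a truncated ellipsoid the two
differ by several percent away from the equator, which would otherwise
contaminate ramp-profile recovery. Ex-vivo **wall thickness** per zone is
the distance between the most epicardial and the most endocardial voxel
along the zone-centre ray, plus one in-plane voxel for the footprint of
the boundary voxels themselves.

## Angle conventions

With frame $(\mathbf c, \mathbf l, \mathbf r)$ and primary eigenvector
$\mathbf e_1$:

* helical: project $\mathbf e_1$ onto the tangential plane, take
  `atan2` of longitudinal versus circumferential components, fold into
  (−90°, 90°]. Projections within 2° of radial are undefined (`NA`).
* intrusion: $\arcsin(\mathbf e_1 \cdot \mathbf r)$ after folding
  $\mathbf e_1$ so the sum of its in-plane components is non-negative
  (ties broken on the longitudinal, then circumferential component; a
  purely radial vector folds to +90°). The magnitude is the
  out-of-plane tilt; the sign is a deterministic convention, since no
  anatomical sign convention for intrusion is standard.
* E3: with the default tangential reference,
  $\arcsin(\mathbf e_3 \cdot \mathbf r)$ after folding the longitudinal
  component non-negative. An alternative radial-longitudinal (plane-B)
  reference — angle $\arcsin(\mathbf e_3 \cdot \mathbf c)$ after folding
  the radial component non-negative — is selectable via
  `e3_reference = "radial_longitudinal"`, since both references are in
  use in the field. Both paths are tested; the tangential reference is
  the default.

All three angles are invariant under $\mathbf e \mapsto -\mathbf e$
(property-tested on 10⁴ random vectors).

## The 23-zone map

The ventricular mass is divided into 23 zones over three short-axis
levels: basal 1–8 (1 and 4 are the interventricular hinge zones, 2–3
septal, 5–6 LV free wall, 7–8 RV), equatorial 9–16 (10 and 12 are the LV
papillary zones, 9/13 septal, 11/14 LV, 15/16 RV), apical 17–23 (17 is
the apical vortex, 18–19 septal, 20–21 LV, 22–23 RV). Zones
{1, 4, 10, 12, 17} — hinge points, papillary muscles and the vortex — are
excluded from all angle statistics. The exact numbering is a documented
package convention (`zone_definitions()`); only the region (LV free wall
/ septum / RV free wall) and level aggregation feed the headline
outputs, so the convention is configurable without affecting results.

## Tractography

`fact_track()` implements FACT (fibre assignment by continuous tracking):
from a seed-voxel centre, the path follows the current voxel's primary
eigenvector — sign chosen to continue the previous direction — to the
voxel boundary, without interpolation; trilinear-interpolated tracking is
deliberately out of scope. Tracking runs bidirectionally and each end
terminates on: FA below 0.15, absolute inner product of successive step
directions below 0.75, mask exit, or the 40 mm (4 cm) total length cap.
Each end records exactly one termination reason. `seed_regions()`
returns the four deterministic seed sets used for RV visualization: the
rightmost, anterior and posterior aspects of the RV free wall and the
septal myocardium, all at the equatorial level.

## Statistics

Group comparisons mirror the study design: two-sample Kolmogorov-Smirnov
tests on pooled per-region angle distributions; Mann-Whitney U per 10%
transmural-depth bin on per-subject bin medians (helical and intrusion
only — E3 angles are heterogeneously distributed through the wall, and
transmural testing of them is refused by design); Wilcoxon rank-sum on
morphometrics; Shapiro-Wilk as the normality screen. Exact p-values are
used for small groups (n ≤ 8 per group for Mann-Whitney, n ≤ 10 for KS,
without ties) and tie-corrected asymptotics otherwise; the test suite
cross-checks both engines against brute-force enumeration over all group
assignments. Tests are two-sided at a 5% level with no multiple-testing
correction, matching the per-bin post-hoc design this package mirrors; a
Holm correction could be applied downstream but is deliberately not the
default. In the pooled KS test each subject is subsampled to the common
minimum voxel count so subjects carry equal weight (`subject_weight =
FALSE` pools raw voxels); whether the original analyses pooled voxels or
weighted subjects is not documentable, so both paths exist. The
transmural-thirds summary reports, per region and for the entire heart,
the group medians with interquartile ranges, their difference
(first group minus second), and the Mann-Whitney p-value.

## The phantom

The phantom stands in for excised porcine hearts: an idealized geometry
is adequate because all downstream mathematics is local. The left
ventricle is a truncated-ellipsoid shell (default outer semi-axes
12.5 × 12.5 × 22 mm, 8 mm wall, 4 mm apical cap, top quarter of the
ellipsoid height removed at the base); the right ventricle is a thinner
crescent shell (3.4 mm wall — a typical ex-vivo RV thickness — across
150° of circumference, separated by a 2.5 mm cavity). The shared sector
is the septum. Defaults are piglet-scale so that the mask, including ±3%
inter-subject size jitter, fits a reduced 96 × 96 × 48 matrix at the
acquisition voxel size; full 125-slice emulation is a `dims` option.

Ground truth: at every myocardial voxel the fibre lies in the epicardial
tangential plane of its transmural ray, rotated from circumferential by
`helix_profile(depth)` and tilted out of plane by `intrusion_offset`; the
sheet normal is placed orthogonal to the fibre so the E3 angle equals
`e3_profile(depth)`. Profiles are per region (LV free wall, septum, RV)
and the default is the control-group reference medians, piecewise
constant over transmural thirds (`reference_helix_medians()`): for
parameter-recovery studies the prescribed plateau value is exactly what
the pipeline's binned medians must return. Piecewise-constant profiles
make the recovery robust to sub-voxel depth error at the third
boundaries; linear ramps probe depth accuracy itself.

Tensors use eigenvalues (1.7, 0.7, 0.3) × 10⁻³ mm²/s (FA ≈ 0.67, typical
of fixed myocardium), and noise, when requested, is Rician — magnitude MR
noise — applied channel-wise under a stated seed: `sqrt((S + n₁)² + n₂²)`
with `n₁, n₂ ~ N(0, σ)`.

What the phantom does **not** emulate: trabeculations and papillary
muscles (the exclusion zones exist, but the idealized wall has no such
structures), partial-volume mixtures at the endocardium, motion,
eddy-current or susceptibility artefacts, multi-compartment diffusion,
and realistic regional voxel proportions. The last point has one concrete
consequence: pooled "entire heart" medians are emergent properties of how
many voxels each region contributes, so they are *not* prescribable in
the phantom, and the entire-heart midwall group difference recovers only
approximately (the per-region differences recover exactly). Passing
recovery tests therefore validate the measurement chain, not the
biological realism of the geometry.

## Problem sizes and reproducibility

The recovery experiments run at the reduced 96 × 96 × 48 matrix
(~113 000 myocardial voxels, ~2 s per subject for synthesis plus
analysis); the test suite additionally uses a coarser 64 × 64 × 40 grid
at 0.6 × 0.6 × 1.0 mm for unit-level checks. A study run is fully
determined by its configuration and master seed: per-subject seeds are
derived deterministically, geometry jitter is the only randomized input
for noiseless subjects, and `run_study()` writes a manifest with the
parameters, seeds and md5 checksums of every artefact. Stages communicate
through files on disk (angle tables, profiles, thickness tables,
comparison tables), so each stage is independently inspectable and
resumable.

## Known limitations

* The frame construction assumes a roughly convex, closed LV contour per
  analysed slice; strongly trabeculated or disrupted masks would need
  preprocessing.
* Intrusion-angle signs follow a package convention (see above);
  magnitudes are the comparable quantity across conventions.
* The sub-voxel boundary estimator assumes each sector wedge is an
  annular sector; it falls back to voxel extremes where coverage is
  partial, with a corresponding local loss of depth precision.
* OLS tensor fitting has no outlier rejection (RESTORE-style) or
  positivity constraint; heavily corrupted data would need a robust
  estimator upstream.
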