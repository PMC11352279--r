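---
title: "Quantifying bacterial storage granules from segmented cryo-electron tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bacterial storage granules from segmented cryo-electron tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Many bacteria store carbon as polyhydroxybutyrate (PHB) and phosphate as
polyphosphate (PP), both in cytoplasmic granules. Cryo-electron
tomography resolves these granules in intact cells, and semi-automated
segmentation turns each tomogram into a *label volume*: an integer voxel
array marking cell body, PHB and PP. This package converts such label
volumes into the quantities a storage-granule study reports:

* per-granule volume, surface area, volume-equivalent spherical
  diameter, and centroid;
* per-cell aggregates — granule counts, class volume and surface
  totals, cell length, and PHB mass via the polymer density
  (1.170 g/cm^3, so 1 nm^3 is 1.17e-6 fg);
* surface-to-surface nearest-neighbor distances between granule
  classes and the fraction of PP granules within a threshold (default
  25 nm) of a PHB surface;
* LC-MS PHB quantification from peak-area tables (internal-standard
  normalization, calibration curve, percent of dry biomass, fg per
  cell);
* demographs of fluorescent foci along normalized cell length.

Because raw tomograms for such studies are rarely deposited, the
package ships a synthetic phantom generator that produces label
volumes, fluorescence images and LC-MS tables with known ground truth.
Every downstream stage is validated against that ground truth, and the
phantom defaults encode the published cohort statistics for
*Rhodobacter sphaeroides* under growth arrest (see below).

## Morphometry

Granules are extracted as 26-connected components of their class label.
Compact blobs rasterized on a grid have staircase boundaries;
26-connectivity keeps those staircases whole where 6-connectivity would
fragment them. Components under 8 voxels (below meshing resolution) are
discarded as segmentation noise and logged.

**Volume** is voxel count times voxel volume; on rasterized spheres of
diameter at least 20 voxels it is within 2% of the analytic volume, and
the *equivalent spherical diameter* `(6V/pi)^(1/3)` is within 1%.
Reported diameters are volume-equivalent because published granule
"diameters" rarely state their estimator; the volume-equivalent
definition is orientation-free and far less noise-sensitive than Feret
widths.

**Surface area** needs more care. Counting exposed voxel faces
overestimates a sphere's area by roughly 1.5x (the staircase artifact),
and a triangle mesh taken directly from the binary mask still carries
about +9% of staircase excess. The package therefore meshes the exposed
voxel faces into a watertight triangle surface and relaxes the
staircase with Taubin smoothing — alternating shrink
(lambda = 0.5) and inflate (mu = -0.53) Laplacian steps, 20
iterations — before summing triangle areas. The two-step scheme
relaxes the single-voxel staircase wavelength without the systematic
shrinkage of plain Laplacian smoothing, and the iteration count is
scale-free because the staircase wavelength is always one voxel.
Accuracy on rasterized spheres of 20-220 voxel diameter is within
~2.5%; sharp edges are chamfered, so a 10-voxel cube measures ~6%
under its exact area. These bands are asserted in the test suite.

**Cell length** is the extent of the cell mask's voxel centers
projected on the mask's first principal axis, plus one voxel. The
definition is orientation-invariant (tested under 30-degree rotations)
and reproduces tip-to-tip capsule length on phantoms within two voxels.

**Distances.** The minimum surface-to-surface distance between two
granules is the minimum distance between their boundary-mesh vertex
sets after a deliberately light relaxation (two Taubin iterations):
unrelaxed staircase vertices sit up to ~0.9 voxel outside the smooth
surface and bias gaps low, while the full 20-iteration relaxation used
for areas drifts up to ~1.1 voxels from the voxelized-solid distance.
Two iterations keep the measured gap within one voxel of both the true
smooth-surface gap and the exact voxelized-solid distance. That exact
solid-to-solid distance (minimum cube-to-cube distance over boundary
voxels) is retained as the brute-force oracle; objects that share or
6-adjoin voxels are at distance 0 by definition (no negative
penetration depths). For
each PP granule the nearest PHB granule in the same cell defines its
association distance; published practice restricts pairs to "the same
pole", but since no pole-assignment rule is ever stated the package
measures cell-wide nearest neighbors and flags records whose partners
lie in opposite cell halves (fractional axial position on either side
of 0.5), letting the analyst filter either way.

## The phantom generator

Phantom cells are sphero-cylinders (capsules): rod-shaped bacteria with
no published shape model are well approximated by a cylinder with
hemispherical caps. Granules are spheres; a voxel belongs to a granule
iff its center lies inside the sphere (center-in-sphere rasterization,
whose volume bias vanishes for diameters above ~20 voxels). Diameters
are drawn from a normal law truncated above two voxel widths by
rejection — the published statistics give only mean and SD, and the
generator treats them as population SDs (whether they include
measurement error is unknowable from the text). Granules of one class
never overlap (a two-voxel surface gap keeps their rasterizations
26-disconnected); across classes surface contact is the closest
allowed approach.

Three placement rules cover the observed arrangements:

* `polar_cluster` — all granules of the population inside a ball of
  cell radius around one randomly chosen pole, every pairwise surface
  gap capped (default 400 nm, the observed group spacing in growing
  cells);
* `dispersed_polar` — granules alternate between the two polar balls,
  uncapped, as in growth-arrested cells;
* `near_other_class` — with probability `coloc_prob` the granule's
  surface is placed exactly `coloc_gap_nm` from a random granule of
  the other class, otherwise at least `noncoloc_min_gap_nm` (default
  100 nm) from every one of them. The default target gap is 10 nm:
  safely inside the 25 nm association threshold, so rasterization
  jitter (about one voxel) cannot flip the colocalization label of a
  generated granule. The default `coloc_prob` of 0.55 matches the
  observed associated fractions (7/12 and 11/20).

`phantom_cohort()` fixes the two study conditions: untreated cells
carry 7 PHB granules per cell with diameters N(179, 55.6) nm clustered
at one pole plus one PP granule N(106, 34) nm; chloramphenicol-treated
cells carry 1-3 PHB granules N(383, 86.5) nm dispersed to the poles
plus one PP granule N(202, 34) nm. Cell lengths are uniform on
1.8-3.6 um with radius 450 nm (a ~0.9 um-wide rod, matching the
published 1-4 um length axis). Each spec carries a single integer seed
that drives all of its sampling; identical seed and spec give
byte-identical volumes and ground truth.

What the phantoms do *not* emulate: electron-optical contrast, noise,
the missing wedge, or segmentation errors of the upstream CNN. Passing
recovery tests therefore demonstrates that the measurement stages are
unbiased on clean labels — not that segmentation of real tomograms is
accurate. Voxel sizes are configurable because whole-cell phantoms at
the published 0.9202 nm tomogram voxel would be billions of voxels;
module tests use 6-10 nm voxels for whole cells (keeping granules
comfortably above the 20-voxel accuracy regime at 2 nm for diameter
cohorts), while the acceptance script measures per-granule cohorts at
0.9202 nm exactly.

## LC-MS quantification

The quantification arithmetic mirrors standard practice: analyte peak
areas are normalized to the co-injected internal standard
(`area * is_ref / is_area`, with the reference fixed as the mean IS
area over the calibration standards — the normalization constant is
never stated in print, and any constant cancels in the calibrated
result), an ordinary least-squares line is fitted to normalized area
versus concentration over 10-750 ug/mL (unweighted by default; 1/x
weighting is available), and samples convert as concentration times
extract volume to mass, mass over dry biomass to percent, and mass
over CFU-derived cell count to fg per cell. The methyl
3-hydroxybutyrate standard is treated as 1:1 with PHB monomer at the
concentration level; the calibration curve absorbs response factors.
The simulated response model is linear with a per-injection
multiplicative drift shared by analyte and IS (so IS normalization
cancels it exactly) plus independent measurement noise; at zero noise
quantification is exact to rounding, and at 5% CV the mean of 50
replicates is unbiased within 2%.

## Demographs

Cell masks come either from the user or from the membrane channel by
Otsu thresholding, hole filling and connected-component labeling. Each
cell's axis is the principal axis of its mask pixels; fluorescence is
averaged per axial bin (mean rather than sum, so a uniformly lit cell
profiles flat despite the capsule's tapering caps) and the profile is
oriented so the brighter half sits at fractional position 1, the
published heatmap convention. Foci are local maxima of the
Gaussian-smoothed image (sigma 1 px) inside the mask exceeding the
in-mask median by 3 MADs, with a 3 px minimum separation (the brighter
peak wins); maxima are evaluated on the mask-restricted image so a
spot at the very pole is still detected. The demograph stacks per-cell
profiles normalized to unit maximum, rows sorted by cell length. Bin
count (default 50) and normalization are deliberate defaults, exposed
as arguments, since the published figures state neither.

## Cohort statistics and deliberate non-claims

`summarize_condition()` computes cohort means per cell first, then
averages (granule-basis columns are labeled separately), and
`compare_conditions()` forms treated-over-untreated fold changes. Two
published figures are deliberately not reproduced as single numbers:

* the volume-to-surface ratios (20.6 and 90.3 nm^3/nm^2) depend on an
  unidentifiable surface-area estimator — the printed ratios are
  inconsistent with d/6 of the printed mean diameters, so the package
  reports both per-cell-averaged and pooled ratios under its own
  documented estimator instead of matching either figure;
* the "~9-fold" spherical-model volume increase is ambiguous
  (cube-of-mean versus mean-of-cubes, per-granule versus per-cell);
  both variants are computable from the emitted tables.

A related internal tension in the published numbers is worth noting:
7 granules per cell with mean diameter 179 nm imply ~27 fg of PHB per
cell at 1.170 g/cm^3, yet the printed per-cell mass is 7.8 fg. The
phantom cohorts therefore validate diameter and volume recovery
(which are self-consistent) rather than asserting the printed per-cell
mass, and the mass arithmetic is validated on the printed values
directly (103.3/7.8 gives the reported ~13-fold).

## Numerical choices and limitations

* Rasterization is center-in-sphere; partial-volume weighting is not
  modeled. Sub-voxel center jitter in `rasterize_sphere()` keeps grid
  alignment from biasing cohort statistics.
* Taubin parameters (0.5/-0.53, 20 iterations) are fixed package
  constants; they are scale-free and were chosen for sphere accuracy
  with bounded cube chamfer, not tuned per dataset.
* Mesh-vertex distances use a sorted-axis pruned search; worst case is
  quadratic but granule meshes are small at test scales.
* Cells must be cropped to single connected masks before length
  measurement; multi-cell volumes are an error by design.
* The label-volume reader accepts isotropic MRC files only, converts
  Angstrom to nm exactly once (x 0.1), and requires an explicit
  override when the header voxel size is zero.
* Statistical hypothesis testing between conditions is out of scope;
  the published study reports none.

## Problem sizes used by the shipped checks

Module tests run whole-cell phantoms at 6-10 nm voxels with up to a
few cells per test and diameter cohorts at 2 nm voxels; the acceptance
script rasterizes the three published diameter cohorts (158, 36 and 23
granules) at the full 0.9202 nm tomogram voxel size, the largest
single volumes being ~400 voxels across. These sizes reproduce the
published statistics while keeping the whole suite runnable on a
single CPU in minutes.
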