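---
title: "Mesh-based 3D morphometry of snow-alga cysts: models and methods"
author: "cystmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesh-based 3D morphometry of snow-alga cysts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystmorph)
```

## Scope

`cystmorph` quantifies the 3D subcellular architecture of *Sanguina
nivaloides* cysts (and structurally similar single cells) from segmented
volume-electron-microscopy reconstructions. The inputs are either triangle
meshes of organelle surfaces (STL/PLY/OBJ, nanometre coordinates) or
integer-labelled voxel volumes (TIFF stacks or NRRD, isotropic voxel size);
the outputs are surface areas, enclosed volumes, cell-volume occupancies,
pairwise volume/area ratios, inter-organelle proximity maps, and membrane
wrinkle statistics. A separate module computes standard PAM
chlorophyll-fluorescence parameters and the liquid-phase renormalisation of
snow ionomics data.

Everything is exercised end-to-end on synthetic organelle scenes, so the
whole pipeline is testable without any microscopy download.

## Metric geometry on meshes

Surface area is the sum of triangle areas. Enclosed volume is the sum of
signed tetrahedron volumes, one tetrahedron per face spanned against a fixed
reference point; the implementation uses the vertex centroid as reference,
which makes the result numerically stable and translation-invariant to
machine precision. Both quantities assume a *watertight* (every edge shared
by exactly two faces), consistently outward-oriented mesh; `validateMesh()`
checks exactly these properties (plus duplicate vertices, degenerate faces
with area below $10^{-6}\,\mathrm{nm}^2$, and the Euler characteristic), and
the metric operations refuse non-watertight input unless `force = TRUE`, in
which case the value is returned as approximate. A negative signed volume
indicates inward orientation and is an error unless `fixOrientation = TRUE`.

Label volumes are converted to meshes by marching tetrahedra on the binary
mask of each label at iso-level 0.5, with the mask padded by one background
voxel so that labels touching the volume boundary still close. Marching
tetrahedra (six-fold Kuhn decomposition of each grid cell) was chosen over
marching cubes because it is unambiguous — no case table, no cracks — and
always yields watertight, orientable surfaces. Voxel-corner convention is
used throughout: the sample at 0-based index $(z, y, x)$ sits at coordinate
$(x, y, z)\cdot h$ for voxel size $h$. The voxel-count volume
(`voxelLabelVolume()`, count $\times h^3$) serves as an independent oracle:
on rasterized shapes a few tens of voxels across, extracted-mesh volumes
agree with it to well under 5% (under 2% for spheres of radius
$\geq 20$ voxels). Surface *areas* of marching-tetrahedra meshes carry a
staircase bias of order +25% and are not used as references anywhere;
areas should be measured on native (segmentation-tool) meshes or after
smoothing.

## Proximity mapping

For organelle pair (A, B), the per-vertex distance field is the exact
minimum point-to-triangle distance from each vertex of A to the full surface
of B, computed with an axis-aligned-bounding-box tree over B's triangles.
Point-to-triangle (rather than point-to-vertex) matters because it is exact
for any target tessellation; the accelerated query is tested for equality
(within $10^{-6}$ nm) against an exhaustive brute-force implementation kept
in the package (`bruteForceDistances()`) purely as a test oracle.

A face of A is *proximal* at threshold $t$ when the minimum of its three
vertex distances is $\leq t$ (inclusive); the proximity area fraction is the
proximal area divided by A's total area. The defaults $t = 100$ nm
(organelle vicinity) and $t = 24$ nm (putative membrane contact sites)
follow the thresholds used for cyst reconstructions. Fractions are reported
inclusively (the 24 nm set is a subset of the 100 nm set) and the exclusive
band fractions are emitted alongside, since either reading of a two-threshold
table can be wanted downstream. The map is asymmetric in (A, B) by
construction — chloroplast-to-mitochondria and mitochondria-to-chloroplast
fractions differ because the two surfaces have different areas.

Distances are unsigned; there is no interior-negative convention. If source
vertices fall *inside* the target volume (overlapping segmentations), they
are in contact: their distances clamp to zero and a warning is logged.

The analytic test case is a pair of spheres: for radii $r_A, r_B$ at centre
distance $d > r_A + r_B$, the fraction of A within $t$ of B is the
normalised spherical cap $(1 - \cos\theta^*)/2$ with
$\cos\theta^* = (r_A^2 + d^2 - (r_B + t)^2)/(2 r_A d)$. At icosphere
subdivision 5 the pipeline reproduces this within 0.01 absolute for moderate
cap sizes; the residual is the half-edge-wide band of faces straddling the
cap boundary, which the inclusive min-vertex rule counts fully.

## HC Laplacian smoothing and wrinkle area gain

The plasma membrane of a cyst is covered in ridge-like wrinkles; comparing
the native membrane area with a smoothed counterpart quantifies the area the
wrinkles add (`wrinkleAreaGain()`, $100\,(A_\mathrm{native} -
A_\mathrm{smooth})/A_\mathrm{smooth}$). Smoothing uses the HC variant of
Laplacian smoothing: each iteration replaces every vertex by the uniform
average of its 1-ring neighbours, then pushes it back by a blend of its own
and its neighbours' displacement, which suppresses the volume shrinkage that
makes plain Laplacian smoothing unusable for metric work. The original
algorithm's weights $\alpha = 0$, $\beta = 0.5$ are the defaults; the source
describing the cyst membranes cites the algorithm and an iteration count of
three but no weights, so the defaults here are the published ones, not
fitted values. On an icosphere (already smooth), three HC iterations change
the area by under 0.01% and the volume loss is two orders of magnitude
below plain Laplacian smoothing with the same iteration count.

## Curvature-based wrinkle detection

The wrinkle *dimensions* reported for cysts (length $406 \pm 90.9$ nm,
width $140.6 \pm 44.2$ nm) come without a stated measurement protocol, so
the detector here is the package's own construction, designed to be
validated against the synthetic generator:

1. discrete mean curvature per vertex via the cotangent Laplace–Beltrami
   operator with Meyer mixed-Voronoi areas (sign: convex bumps positive; a
   sphere of radius $r$ yields $+1/r$ within 5% at subdivision 4);
2. vertices with curvature above `mean + curvatureSdFactor * sd` (default
   factor 1.0) are selected and grouped into connected components over the
   mesh edge graph;
3. per component, length and width are the extents of the member vertices
   along the first two principal axes (ambient-frame PCA, acceptable because
   ridges are short relative to the cell curvature radius — roughly 400 nm
   against 9400 nm);
4. a sampling-bias correction of one mean incident edge length is added to
   each extent, because the outermost selected vertices sit on average half
   an edge inside the true ridge boundary at either end;
5. components spanning fewer than `minComponentFaces` (default 10) fully
   selected faces are dropped.

The synthetic generator (`makeWrinkledSphere()`) stamps non-intersecting
elliptic-paraboloid ridges, radial displacement $h(1 - q^2)$ inside an
elliptical footprint, onto an icosphere; lengths and widths are drawn from
the Gaussians above truncated at $\pm 2$ SD, placement is by rejection
sampling with a conservative disc-separation criterion (honouring the
observation that the wrinkles do not intersect), and the ground-truth table
is attached to the mesh. The paraboloid profile was chosen deliberately: its
transverse curvature is constant over the footprint interior and two orders
of magnitude above the sphere background, so the curvature threshold
recovers the footprint itself rather than an arbitrary crest subset, and the
measured extents are comparable with the stamped dimensions. Ridge relief
height is not a reported quantity; the default is 80 nm.

Resolution matters: the narrow ridge dimension must span several mesh
edges. When no subdivision level is given, the generator picks the smallest
level whose mean edge length is at most a quarter of the mean ridge width
(4 edges across a ridge). At full cyst scale (radius 9.4 µm, width
140.6 nm) this selects subdivision 9 ($2.6\times10^6$ vertices), where the
detector recovers all 60 stamped ridges and both mean dimensions within a
few percent; one level coarser (subdivision 8, ~3 edges per width) already
loses 10–25% of the components to fragmentation and biases the width up by
5–10%. Problem sizes in the test-suite recovery checks use radius 3 µm
(auto-selected subdivision 7, ~160k vertices), which preserves the
edges-per-width ratio at a fraction of the cost.

## The synthetic cyst scene

`makeToyCyst()` builds a deterministic, seeded scene reproducing the
qualitative architecture of a reconstructed cyst: a spherical plasma
membrane of radius 9400 nm (the mean reported cyst diameter is 18.8 µm); a
central chloroplast at 29% of the cell volume with six radial protrusions
(smooth cosine-squared bumps on octahedral axes) each tipped internally by
a starch grain; a central pyrenoid at 5% of the chloroplast volume; a
peripheral flattened (oblate) nucleus at 2.3% in the direction clearest of
the protrusions; 36 prolate mitochondria at 2% in total, the first six
parked at a 50 nm surface gap from the protrusion tips (so that
mitochondrion-to-starch minimum distances equal the configured offset) and
the rest scattered in the cytosolic shell; and 400 lipid droplets at 8% of
the cell volume, packed by random sequential addition. Chloroplast,
nucleus and lipid-droplet occupancies sit at or near the reported ranges
(28.6–31%, 2.3–3.6%, 13.5–35.5%); the droplet fraction is the one
deliberate departure, because a sphere-packed spherical shell saturates
(random sequential addition jams near 38% locally) well before the real,
highly non-convex cytosol does, and 8% over 400 droplets keeps packing
reliable at every seed.

Every organelle's reference volume and area are recorded in a ground-truth
table: exact formulas for spheres and ellipsoids, adaptive quadrature of the
radial bump profile for the protruded chloroplast (the mesh itself is never
the reference). Each placement stage draws from its own seeded substream,
so adding droplets does not move mitochondria. The generator emulates
*segmentations*, not micrographs: no imaging noise, no curtaining, no
anisotropy, perfectly closed surfaces. Passing tests therefore demonstrate
the correctness of the geometry pipeline, not robustness to segmentation
error.

`rasterizeScene()` closes the loop for label-volume inputs: point-in-mesh
labelling (parity ray casting) on a regular grid, with nested organelles
resolved by priority (smallest bounding box first by default, so a pyrenoid
keeps its label inside its chloroplast). Rasterize-then-remesh round trips
preserve volumes within 5% at default resolutions.

## Photophysiology and snow chemistry

The PAM module implements the standard pulse formulas,
$Y(II) = (F_m' - F)/F_m'$, $\mathrm{NPQ} = (F_m - F_m')/F_m'$,
$\mathrm{rETR} = Y(II) \cdot I$, $F_v/F_m = (F_m - F_0)/F_m$, against the
dark-adapted reference, and a per-phase summary for the
dark / 22 / 337 µmol photons m⁻² s⁻¹ / dark-relaxation protocol. The dark
$F_m$ is used as the NPQ reference throughout, the conventional reading when
no per-phase reference is restated. $F > F_m'$ clamps $Y(II)$ to zero with a
warning; $F_m' > F_m$ yields a negative NPQ that is reported as computed
with a data-quality warning rather than hidden. The synthetic trace
generator gives $Y(II)$ a saturating irradiance response and NPQ a Hill-type
rise, so light-saturation ordering ($Y(II)$ lower and NPQ higher at 337 than
at 22) is a generator contract the tests can rely on.

Ionomic meltwater concentrations are renormalised to the snow liquid phase
by `c_liquid = (c_melt / concentrationFactor) / lwc`, on the assumption that
solutes are excluded from ice crystals; the default liquid water content is
0.15 (15 mass%), and freeze-drying pre-concentration factors (10–12.5 in
the reference protocol) are divided out first.

## Numerical choices and degenerate inputs

* Canonical unit: nanometres. Loaders take a `unitScale` for meshes
  exported in µm or voxel units (different segmentation tools disagree, and
  deposited meshes do not always record units).
* Degenerate faces (area $< 10^{-6}\,\mathrm{nm}^2$) are removed during
  validation with a warning; isolated vertices make smoothing fail loudly.
* Ties in the rasterizer (rays through mesh edges) are measure-zero for
  generic meshes; coincident intersections are deduplicated at
  $10^{-9}$ nm.
* Thresholds are inclusive ($\leq t$), and threshold lists are sorted
  decreasing internally so fraction vectors are always monotone.
* Reports serialize numbers at full precision and carry a config hash that
  excludes run-local keys (output directory, log level), so identical
  analyses produce byte-identical JSON.
* Truncating ridge Gaussians at $\pm2$ SD keeps widths positive and the
  sample mean an unbiased estimate of the configured mean.

## Known limitations

* Areas of meshes extracted from label volumes are staircase-biased; only
  volumes are quantitative after marching tetrahedra without smoothing.
* The wrinkle detector assumes ridges are convex reliefs separable by a
  global curvature threshold; it has no notion of ridge *orientation*
  statistics, and merged or intersecting ridges would be undercounted (the
  generator never produces them, matching the observation it emulates).
* Geodesic distances and signed (inside/outside) distances are out of
  scope; proximity is Euclidean and unsigned.
* The toy cyst is a geometric idealisation for pipeline validation —
  concentric spheres and ellipsoids, not reconstructed shapes; its
  plastid/mitochondria *area* ratio in particular is far below reconstructed
  values because the synthetic chloroplast envelope is smooth rather than
  highly convoluted.
* Only two cells were reconstructed in the source study; nothing here does
  cross-cell statistics.
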