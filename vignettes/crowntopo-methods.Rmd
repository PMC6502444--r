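---
title: "Methods: dental topography and preparation sensitivity in crowntopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dental topography and preparation sensitivity in crowntopo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowntopo)
```

crowntopo quantifies occlusal tooth shape from triangular surface meshes and
measures how sensitive those quantities are to the way a mesh was prepared.
This vignette is the package's account of its models, conventions and
numerical choices.

## The six measurements

Meshes are assumed to be in millimetres with the occlusal surface toward +z
(`orient_occlusal()` asserts or restores this convention).

**Surface area (SA)** is the sum of triangle areas. **Tooth size** is the
area of the union of all triangles projected onto the xy-plane, overlaps
counted once: the occlusal outline area.

**Relief index (RFI)** is `ln(sqrt(SA / size))`, the log square-root ratio of
3D to projected area. It is zero for a flat surface, `ln(sqrt(2)) ~ 0.347`
for a hemisphere, and grows with relative crown or cusp height. It is
undefined when the outline area is zero (a surface destroyed by aggressive
preparation); such values are reported as missing, never imputed.

**Dirichlet normal energy (DNE)** measures how fast the surface normal
rotates across the surface — curvature, and hence sharpness. Vertex normals
are area-weighted averages of incident face normals. For each face with edge
vectors $u, v$ and vertex-normal differences $n_u, n_v$, the energy density
is $e = \operatorname{tr}(G^{-1}H)$ with
$G = \begin{pmatrix} u\cdot u & u\cdot v \\ u\cdot v & v\cdot v\end{pmatrix}$,
$H = \begin{pmatrix} n_u\cdot n_u & n_u\cdot n_v \\ n_u\cdot n_v & n_v\cdot n_v\end{pmatrix}$,
and DNE is $\sum e \cdot A$ over included faces. The sum converges to
$\int (\kappa_1^2 + \kappa_2^2)\,dA$ — $4\pi$ for a hemisphere of any radius
(DNE is scale invariant). Two inclusion rules, both on by default in the
conventional configuration: faces touching an open boundary are excluded
(their vertex normals are one-sided), and the top 1% of faces ranked by
energy-times-area are discarded as outliers (ties broken by face index).
No implicit fair smoothing is applied inside the measurement; smoothing is a
preparation step, applied explicitly or not at all.

**Orientation patch count (OPC / OPCR)** measures complexity. Each face whose
normal is neither vertical nor downward-pointing is assigned to one of 8
equal azimuth sectors, sector 0 centred on +x; a bin-boundary azimuth belongs
to the lower-index bin. Edge-connected runs of same-bin faces form patches
and patches with at least 3 faces count. OPCR is the mean of OPC over 8
rotations of the mesh about z in steps of 5.625 degrees, so the rotations
tile exactly one 45-degree bin and the orientation dependence of OPC
averages out. Face normals (not vertex normals) are binned, matching the
original formulation in which polygons were binned by the direction their
normal pointed. A horizontal plane scores 0; an axis-aligned square pyramid
with subdivided slant faces scores exactly 4.

**Ambient occlusion (PCV, portion de ciel visible)** is, per vertex, the
fraction of a fixed direction set on the upper unit hemisphere along which a
ray from just above the vertex (offset $10^{-4}$ mm along the vertex normal)
escapes the mesh. The direction set is a deterministic Fibonacci spiral, so
PCV needs no random seed; the upper hemisphere is the "visible sky" of an
occlusal-up crown. The surface summary is the unweighted vertex mean, which
tracks the area-weighted mean closely on near-uniform triangulations. Rays
are cast through a bounding-volume hierarchy; tests compare it against a
naive all-faces oracle and against the analytic solid angle of a square
aperture.

## Preparation operators

The canonical pipeline order is **crop, then decimate, then smooth**.
Smoothing must come last: decimation leaves an irregular surface that would
otherwise stay rough.

*Cropping.* `crop_bco()` keeps the surface at or above a horizontal plane,
splitting crossing triangles exactly at the plane (basin cut-off, BCO);
leaving the mesh untouched is the entire-enamel-cap (EEC) treatment.
`estimate_basin_plane()` stands in for the manual landmark "lowest point of
the central basin": the minimum z among vertices whose projection falls in
the projected convex hull shrunk 25% toward its centroid. It is explicitly a
heuristic; batch studies can supply per-specimen plane heights instead.

*Decimation.* `decimate_to_count()` is quadric edge-collapse simplification
with boundary preservation: boundary edges contribute strong perpendicular
constraint planes, a collapse between a boundary and an interior vertex may
only land on the boundary vertex, and chords between two boundary vertices
are refused. Collapses are ordered by quadric cost with ties broken on the
lowest vertex-index pair, so results are deterministic. The result has
between `n - 2` and `n` faces. Ladders always decimate the original surface,
never a previously decimated level. `decimate_to_resolution()` converts a
target in triangles/mm^2 to a count using the surface area of the input
(already-cropped) mesh: `round(r * SA)`.

*Smoothing.* `smooth_mesh()` is plain iterative Laplacian smoothing: each of
`iterations` passes moves every vertex by `lambda_step` times the vector to
the unweighted centroid of its edge neighbours. The defaults
(`lambda_step = 0.6`, `iterations = 100`) are the settings conventionally
used on prepared crowns. A pure positive step shrinks noisy surfaces — the
systematic area loss that preparation-sensitivity studies observe — which is
why no shrink-compensating (Taubin-style) negative step is used. Vertices on
an open boundary average only over boundary neighbours, so a cropped rim
cannot drift inward and artificially change the outline. Smoothing that
collapses a surface to zero projected extent is flagged, and downstream
metric failures are recorded as missing values with reasons.

## Numerical choices

- **Projected area** is computed by scanline integration that is exact in x:
  the y-axis is cut into slabs at every projected vertex, the union of the
  per-triangle x-intervals is computed exactly at two Gauss points per slab,
  and the slab contributions are summed. No polygon-clipping library for R
  is available in this toolchain, and rasterization was rejected as
  resolution-dependent; the scanline is exact for rectilinear unions (the
  unit square comes out at exactly 1) and converges quadratically for curved
  outlines (the hemisphere disk is recovered to well under 0.1% at the face
  counts used in studies). An opt-in flag quantizes the result to 0.0005 mm^2
  steps to emulate tools that report at that accuracy.
- **Welding** (`validate_mesh()`) snaps vertices to a grid of pitch equal to
  the weld tolerance, default 1e-6 mm — far below the 10–100 micrometre
  resolution of the scanners these meshes come from — then drops zero-area,
  repeated-vertex and duplicate faces and unreferenced vertices. Validation
  is idempotent and never moves surviving geometry.
- **Quantiles** in distribution summaries use linear interpolation between
  order statistics (R's default type 7); the choice is documented because
  percent-difference confidence bands depend on it.
- **`prob_gt_zero`** is the empirical fraction of percent differences above
  zero. It is reported as such — an empirical fraction, not a frequentist
  p-value, although sensitivity studies conventionally read it as the
  strength of evidence for a directional effect.
- **Factorial ANOVA** uses sequential (type I) sums of squares; the
  synthetic designs the package generates are balanced, where the types
  coincide. The term table covers all interactions up to the full order.
- **Infinite percent differences** (zero denominators) are flagged and
  excluded listwise per analysis, with exclusion counts logged in study
  reports.
- PLY I/O supports the ASCII and binary little-endian dialects only;
  big-endian files are rejected with a clear message. The writer stores
  doubles, so binary round-trips are bit-exact and byte-stable. Normals in
  input files are ignored: the package always recomputes them from geometry.

## The synthetic-data generator

Real specimen scans are not redistributable, so fixtures and cohorts are
generated. Analytic shapes (plane, hemisphere, cone, pyramid) have
closed-form metric values and anchor the test suite. Crowns are height
fields over a disk: a base dome, Gaussian cusps, an optional central fossa,
and seeded vertical noise.

Two dome profiles exist. The default (`wall_exponent = 2`) is the exact
spherical cap through the rim, whose DNE has a closed form. Cohorts instead
use `wall_exponent = 8` with a central fossa (`basin_depth = base_height/2`):
a flat occlusal table on steep cervical walls. The steep-wall-plus-fossa
anatomy matters for cropping realism — on real molars the basin cut-off
removes a great deal of enamel wall area while barely shrinking the occlusal
outline, and only this geometry reproduces that asymmetry.

Noise is a seeded band-limited random field (a sum of 48 random plane waves
with wavelengths 0.2–0.6 mm, pointwise sd `noise_sd = 0.02` mm) evaluated at
each vertex. Scanner noise has a physical spatial scale; white per-vertex
noise would make roughness — and therefore area and DNE — grow without bound
as the mesh is refined, a coastline-paradox artefact that real converged
scans do not show. With band-limited noise, RFI converges once the noise
wavelength is resolved (around 10 000 triangles at molar scale), while
smoothing still produces its characteristic area shrinkage.

Dietary presets encode ordinal contrasts only: relative cusp height and
sharpness decrease from insectivore through folivore, omnivore and frugivore
to hard-object feeder. The ranges are not calibrated to any real taxon;
consequently, cohort tests demonstrate that the pipeline recovers *designed*
orderings and directions, not that it would classify real primates. Features
of real data the generator does not emulate: wear facets, enamel-dentine
structure, asymmetric crown outlines, scan holes, and phylogenetic
covariance between specimens.

## Study harness and problem sizes

`run_study()` executes the factorial experiment (cropping x smoothing x
ladder) per specimen, records failures as missing rows with reason codes and
writes deterministic CSVs; `study_report()` assembles percent-difference
summaries by triangle-count class (low < 210, medium-low 210–1799,
medium-high 1800–9999, high 10000+), ln–ln scaling fits of DNE and OPCR over
the 7 highest levels, convergence curves against the highest level, and
per-level diet group tests.

The package's own test studies use cohorts of 3 crowns per diet at 24 000
base triangles with a seven-step count ladder (200–20 000), sizes chosen so
the full suite exercises every preparation effect at the scale where the
effects are unambiguous while remaining quick to run on one CPU. Statistical
calibration uses 1000 null one-way ANOVA simulations and a 200-observation
uninformative discriminant analysis; Tukey HSD is compared against a
single-step max-statistic permutation reference on n = 30 fixtures.

## Known limitations

- The decimation and smoothing operators are deterministic reimplementations
  of standard algorithms, not of any specific commercial tool; numerical
  agreement with surfaces prepared elsewhere is not attempted, only
  directional agreement of the preparation effects.
- `estimate_basin_plane()` can misplace the basin on crowns whose lowest
  interior point is not in the central fossa (e.g. deeply notched margins).
- PCV ray origins are offset along the vertex normal; pathological
  self-intersecting meshes can occlude their own origin vertex.
- Only horizontal cropping planes are supported.
- OPC bins face normals by azimuth with a fixed +x-centred sector 0; the
  anatomical (buccal/lingual) alignment of that axis is the user's
  responsibility.
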