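---
title: "Mitochondrial morphometrics: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitochondrial morphometrics: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomorph)
```

## The measurement model

`mitomorph` quantifies organelle morphology at three scales.

**Per-object 3D shape.** Every labeled object gets a volume, a surface area
and two derived dimensionless shape indices. Volume is computed two ways:
the exact voxel form $V = N_{vox} \cdot (x \cdot y \cdot z)$, and the mesh
form $V = \sum_i v_i$, the total signed-tetrahedron volume enclosed by a
closed triangulated surface. Surface area is $A = \sum_i A_i$ over the
mesh's triangle faces. From $(V, A)$:

$$\Phi = \frac{\pi^{1/3}(6V)^{2/3}}{A}, \qquad
  \mathrm{MCI}_{root} = \frac{A^{3/2}}{4\pi V}, \qquad
  \mathrm{MCI}_{sq} = \frac{A^3}{16\pi^2 V^2}.$$

$\Phi = 1$ for a perfect sphere and decreases with elongation or branching;
the complexity index is its size-invariant inverse view, with the squared
form preferred for dynamic range. Both forms carry the same information:
$\mathrm{MCI}_{sq} = \mathrm{MCI}_{root}^2$ and, algebraically for any
$(V, A)$, $\mathrm{MCI}_{sq}\,\Phi^3 = 9/(4\pi)$ — the package asserts this
identity on every measured object, which pins any implementation error in
either index immediately.

By default the shape indices use the **mesh** volume; `volume_source =
"voxel"` switches to the voxel convention. Both volumes are always reported
so either convention can be reproduced downstream.

**2D cross-sections.** Perimeter $P = \sum_j l_j$ from sub-pixel
marching-squares contours; length as the maximum Feret diameter; area as
pixel count times squared spacing; cristae density as segmented cristae
area over cross-section area.

**Cell-scale distribution.** A per-pixel normalized radius $\rho$ (0 deep
inside the cell, 1 at its boundary) partitions each cell into concentric
perinuclear / radial / distal zones, and the fraction of total
mitochondrial signal per zone is the reported statistic. Peripheral
redistribution of mitochondria shows up as a rising distal fraction.

## Segmentation parameters

The preprocessing stage mirrors a published commercial-software workflow
with each step made explicit:

| parameter | default | units | meaning |
|---|---|---|---|
| `background_radius` | 37.1 | µm | rolling-ball (grayscale opening) radius |
| `smoothing_width` | 0.129 | µm | Gaussian σ, applied per axis as σ/spacing voxels |
| `threshold` | `"otsu"` | — | or `fixed(value)` |
| `connectivity` | 26 | — | 3D neighborhood (6 = faces only) |
| `min_voxels` | 121 | voxels | strict "smaller than" exclusion |

Three of these required interpretation, resolved as follows and kept
configurable:

- the published "width" of the Gaussian filter is read as **σ**, not FWHM —
  the original software's parameter semantics are not documented in the
  source description; at the typical 0.0645 µm isotropic spacing the
  default gives σ = 2.0 voxels;
- the length-valued background parameter is read as a **rolling-ball
  radius**, the standard meaning of a µm-valued background-subtraction
  setting;
- the original **trained pixel classifier is not reproducible** from any
  published description, so segmentation uses Otsu (or fixed) thresholding;
  every pipeline provenance record names this substitution. Transparency
  was preferred over fidelity to an unavailable model.

The 121-voxel filter is applied after smoothing and thresholding, to
labeled objects, matching the order in which the original workflow lists
its steps; "smaller than 121" is strict, so a 121-voxel object survives.
26-connectivity is the default so diagonally touching network branches
count as one object, consistent with treating interconnected networks as
single surfaces.

## Mesh extraction: why surface nets

The mesh stage must deliver closed, consistently oriented surfaces whose
area and volume are accurate on *binary* masks — there is no grayscale
iso-surface to exploit after segmentation. Classic marching cubes was
evaluated first and rejected on measurement: on a digitized radius-12
sphere its triangle soup overestimates surface area by 7–9% (an effect
inherent to binary input, reproducible with any standard implementation),
which is outside this package's own 3% accuracy contract. Naive surface
nets — one vertex per boundary cell at the centroid of its edge crossings,
two triangles per sign-changing grid edge — is watertight by construction,
needs no case table, and on the same binary sphere gives SA within +1.4%
and V within −1.9% at r = 12 voxels, improving with resolution. The object
mask is zero-padded by one voxel so surfaces always close; vertex
coordinates are scaled per axis into µm, and global orientation is fixed by
the sign of the enclosed volume.

No mesh smoothing or decimation is applied: the estimator stays
deterministic, at the cost of a small, documented, resolution-dependent
bias relative to commercial smoothed surfaces. Mesh volume uses signed
tetrahedra referenced to the mesh centroid — mathematically
origin-independent, numerically better conditioned than the raw origin.

## 2D perimeter: known estimator bias

Perimeters use marching squares at level 0.5 with linear interpolation (on
binary masks: edge midpoints), per object, counting only the outer contour
(holes are reported separately). This is the same algorithm as
`skimage.measure.find_contours`, and the two implementations agree to six
decimals on identical inputs. Two properties follow from the estimator and
are deliberately documented rather than hidden: a single pixel yields the
diamond contour with $P = 2\sqrt{2}\times$ spacing, and digitized smooth
convex boundaries are overestimated by ~6–9% (the polygon is exact for
axis-aligned and 45° straight edges but zigzags across intermediate
orientations). Crack-boundary counting would be ~27% high on circles.
Because the bias is resolution- and shape-stable, *comparisons between
conditions imaged at one resolution are unaffected*; absolute perimeters
of near-circular profiles carry the stated bias.

"Length" follows the most common FIJI convention: the maximum Feret
diameter, computed over boundary-pixel centers (a 1×50 px strip at
0.1 µm/px measures 4.9 µm — 49 inter-center units). A brute-force pairwise
oracle over the same vertex set reproduces it exactly in the tests.

## Concentric zones

The normalized radius is built from the exact Euclidean distance transform
$d$ to the nearest background pixel:
$\rho = (d_{max} - d)/(d_{max} - d_{min})$, so the deepest interior pixel
has $\rho = 0$ and boundary pixels exactly $\rho = 1$. For a disc this is
$r/R$ up to one-pixel quantization; unlike a centroid ray-cast it remains
well defined for non-convex or crescent-shaped cells, which is why the
EDT construction is the default (a nucleus-offset ray-cast variant was
considered and left out of scope). Zone $k$ is the half-open band
$b_{k-1} \le \rho < b_k$ with the outermost band closed, so a pixel at
exactly 1/3 belongs to zone 2.

The original assay names its zones but never publishes their radii or even
their number; the default here — three equal thirds of $\rho$ — is a
declared convention, configurable via `boundaries`. Under it, a uniformly
filled disc has zone fractions (1/9, 3/9, 5/9), which the tests assert at
a 0.02 pixelation tolerance (at R = 80 px the realized fractions differ
from the continuum values by < 0.01).

## The synthetic world

Phantoms state the world the pipeline is validated in; their defaults are
fixed once and not tuned against test outcomes.

**3D fields.** Spheres, axis-aligned ellipsoids and capsules
(sphero-cylinders — the idealized elongated mitochondrion) are rasterized
by voxel-center inclusion: a voxel belongs to an object iff its center is
inside. No partial-volume antialiasing — the voxel-count oracle stays
unambiguous — and overlapping primitives are rejected rather than merged so
ground truth stays closed-form. Ground-truth V and SA are exact for spheres
($\tfrac{4}{3}\pi r^3$, $4\pi r^2$) and capsules
($\pi r^2 L + \tfrac{4}{3}\pi r^3$, $2\pi r L + 4\pi r^2$); ellipsoid SA
uses the Thomsen approximation ($p = 1.6075$, max error ≈ 1.06%), since no
elementary closed form exists — ellipsoid tolerances are widened
accordingly. `random_phantom()` defaults emulate an SBF-SEM-like field:
spacing (0.08, 0.065, 0.065) µm, organelle radii 0.3–0.8 µm, capsule
lengths 0.8–2 µm, with rejection sampling keeping bounding spheres two
voxels apart. `voxel_count_phantom()` builds connected objects with *exact*
voxel counts for size-filter tests, where geometric primitives cannot hit a
target count. Acquisition noise is additive Gaussian plus a flat offset,
seeded and reproducible.

**2D cell scenes.** A star-convex cell boundary
$R(\theta) = R\,(1 + \sum_{k=2}^{5} a_k \cos(k\theta + \varphi_k))$ with
total modulation amplitude `irregularity` (default 0.1, range [0, 0.3)),
default radius 15 µm at 0.2 µm/px — a typical cultured-cell scale. Signal
is `n_puncta` (default 2000) unit point masses dropped into zones drawn
from the target fractions, uniformly within each zone. The recorded ground
truth is the *realized* multinomial fraction, which matches the target to
$\sim 1/\sqrt{n}$ and is recovered to 1e−9 by the zones module under the
same partition — a closed-loop identity the tests assert. The
`"knockdown-like"` preset fixes target fractions (0.10, 0.15, 0.75): only
the 75% distal value is anchored to a reported measurement; the
`"control-like"` preset (0.35, 0.27, 0.38) is a convention consistent with
the qualitative description ("nearly double" in knockdown), documented as
such and not a reproduction target.

**What a green test does not establish.** Phantoms are geometric ground
truth, not realistic micrographs: no electron-microscopy contrast, cristae
texture, point-spread function, anisotropic noise, or touching/overlapping
organelles. Passing tests certify the *measurement* chain (given a
segmentation, the numbers are right, and a threshold-separable scene is
segmented correctly), not classifier-grade segmentation of hard real data.

## Statistics

Group comparisons follow the source assays exactly: unpaired two-tailed
Student's t (pooled variance, so $t^2 = F$ against the two-group one-way
ANOVA), one-way ANOVA followed by Fisher's *protected* LSD — pairwise t on
the pooled MSE with $N - k$ degrees of freedom, computed only when the
omnibus p < 0.05 — and the two-sample Kolmogorov–Smirnov test for
distributional shifts. Protected LSD has weaker family-wise control than
Tukey; it is implemented as stated for fidelity, not preference. Zero
pooled variance yields a flagged degenerate result rather than an error.
Stars follow the `*` < 0.05 … `****` < 0.0001 convention, with raw
p-values always emitted. The units-of-analysis question (per-object vs
per-cell pooling) is left to the caller: the long-format `group_table()`
accepts either.

## Numerical choices and edge cases

- All randomness flows through explicit integer seeds; generator functions
  save and restore the caller's RNG state.
- Relabeling is deterministic: descending voxel count, ties broken by
  original label id.
- Otsu maximizes between-class variance over a 256-bin linear histogram,
  with double-precision accumulators (integer accumulation overflows on
  multi-megavoxel volumes).
- An all-background segmentation returns an empty label volume, not an
  error; empty metrics tables have the full column schema.
- Background subtraction short-circuits to a global-minimum opening when
  the ball covers the whole grid (radius ≥ grid diagonal), and warns +
  no-ops when the radius is below one voxel.
- Gaussian smoothing mirrors the boundary and normalizes the kernel, so
  constants are preserved exactly and interior impulses conserve total
  intensity to 1e−6.
- Mesh integrity (every edge shared by exactly two opposite-winding faces)
  is checked before measurement; violations report the offending edges.
- CSV metrics are written at 17 significant digits so read→write→read
  round trips are lossless; volumes use a plain-text header + column-major
  values format chosen for offline reproducibility (no binary image
  dependency exists in the supported stack).

## Known limitations

- Surface-area estimates on raw binary masks are accurate to ~2–3% at
  r ≥ 10 voxels and degrade below that; sub-resolution objects (allowed
  through by a small `min_voxels`) carry large relative mesh errors.
- The 2D perimeter bias discussed above.
- No skeleton/graph topology metrics (branch counts, nanotunnels): the
  complexity index is the package's complexity measure.
- The concentric-zone defaults (three equal-ρ bands) are a convention; the
  distal-fraction statistic is comparable across conditions analyzed with
  the same partition, not an absolute anatomical quantity.
- `crista_metrics()` measures supplied masks; it does not segment cristae
  from raw TEM texture, and "cristae volume" is only reported when a
  section thickness is given (area × thickness).
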