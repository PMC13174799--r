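# mitomorph

Quantitative mitochondrial morphometrics from 3D microscopy volumes and 2D
cross-sections, in R.

Mitochondria remodel constantly — fusing into elongated networks, fragmenting
into spheres, redistributing within the cell — and these changes are an early,
measurable signature of metabolic and cardiac disease models. `mitomorph`
turns segmented (or raw, threshold-segmentable) image volumes into the
standard per-organelle shape statistics used in that literature, and ships a
synthetic phantom generator with closed-form ground truth so the whole
pipeline is testable without any external imaging data.

## What it computes

For each labeled 3D object (voxel spacing in µm, axis order z, y, x):

- **Volume**, two ways: voxel-based `V = N_vox · (x·y·z)` and mesh-based
  `V = Σ vᵢ` (signed tetrahedra of a closed triangulated surface);
- **Surface area** `A = Σ Aᵢ` over the triangle faces of a watertight
  surface-nets mesh extracted at iso-level 0.5;
- **Sphericity** `Φ = π^{1/3} (6V)^{2/3} / A` — 1.0 for a perfect sphere,
  lower for elongated or branched shapes;
- **Mitochondrial Complexity Index**, root form `MCI = A^{3/2} / (4πV)` and
  squared form `MCI = A³ / (16π²V²)`; the squared form expands dynamic range
  and satisfies `MCI_sq · Φ³ = 9/(4π)` identically.

Preprocessing reproduces a published surface-generation workflow with
transparent parts: rolling-ball background subtraction (default 37.1 µm),
Gaussian smoothing (default σ = 0.129 µm), Otsu or fixed thresholding in
place of the original proprietary pixel classifier, 26-connected component
labeling, and strict exclusion of objects smaller than 121 voxels.

2D cross-sections (TEM-style): sub-pixel marching-squares perimeter
`P = Σ lⱼ`, max-Feret length, cross-sectional area, object count / total
area, and cristae area + density from paired masks.

Cell-scale distribution: a boundary-EDT normalized radius ρ ∈ [0, 1]
partitions each cell into perinuclear / radial / distal zones (equal thirds
of ρ by default) and reports the fraction of mitochondrial signal per zone.

Group statistics follow the conventions of the source assays: unpaired
Student's t, one-way ANOVA with Fisher's protected LSD, and two-sample
Kolmogorov–Smirnov, with `*`…`****` star annotation.

## Worked example

```r
library(mitomorph)

# A phantom field with analytic ground truth: one sphere (r = 1 µm) and one
# capsule (r = 0.5 µm, L = 2.5 µm) at SBF-SEM-like anisotropic spacing.
specs <- list(
  sphere_spec(center = c(3, 3, 3), r = 1.0),
  capsule_spec(center = c(3, 3, 7.5), r = 0.5, L = 2.5, axis = c(0, 0, 1))
)
ph  <- rasterize(specs, spacing = c(0.08, 0.065, 0.065), shape = c(80, 100, 160))
raw <- add_noise(ph$intensity, background_offset = 0.08, gaussian_sd = 0.05, seed = 1)

labels <- preprocess_and_segment(raw, segmentation_params(min_voxels = 121))
#> background subtracted (radius 37.1 um)
#> smoothed (sigma 0.129 um)
#> segmented: 2 object(s) [otsu threshold, connectivity 26]
#> size filter (>= 121 voxels): 2 object(s) retained

measure_objects(labels)
#>   id n_vox v_voxel_um3 v_mesh_um3 sa_um2 sphericity mci_root mci_sq
#> 1  1 12948       4.376      4.355  13.31     0.9692    0.887 0.7867
#> 2  2  7765       2.625      2.601  11.48     0.7969    1.190 1.4151

ph$truth   # analytic ground truth for comparison
#>   id     V    SA sphericity mci_sq
#> 1  1 4.189 12.57     1.0000 0.7162
#> 2  2 2.487 11.00     0.8073 1.3610
```

The recovered sphere scores Φ ≈ 0.97 (ideal 1.0) and the capsule Φ ≈ 0.80
(analytic 0.81) with MCI_sq raised accordingly — noise, smoothing and
thresholding account for the few-percent volume inflation relative to truth.

Concentric-zone analysis of a synthetic "knockdown-like" cell whose signal
mass targets 75% in the distal zone:

```r
kd <- make_cell_scene(scene_preset("knockdown-like", seed = 7))
analyze_zones(kd$scene)
#> <zone_profile> 3 zones; fractions: perinuclear=0.0975, radial=0.1575, distal=0.7450
```

## Command line

```sh
Rscript inst/cli/mitomorph.R phantom   --kind volume --n 10 --seed 1 --out ph/
Rscript inst/cli/mitomorph.R segment   --in vol.tsv --background 37.1 --smooth 0.129 \
                                       --min-voxels 121 --connectivity 26 --out labels.tsv
Rscript inst/cli/mitomorph.R measure3d --labels labels.tsv --out metrics.csv
Rscript inst/cli/mitomorph.R zones     --mask cells.csv --signal mito.csv --out zones.csv
Rscript inst/cli/mitomorph.R run       --config run.json --out out/
```

Volumes use a plain-text format (`write_volume_tsv()`); no binary image
libraries are required. See `vignettes/mitomorph-methods.Rmd` for the model,
parameter and validation details.
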