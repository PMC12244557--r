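# mcsquant

Quantification of ER–membrane contact sites (MCSs) in light-microscopy and
volume-EM images.

Membrane contact sites are regions of close apposition (~10–50 nm) between
the endoplasmic reticulum and a partner organelle. Inducible labelling
methods relocalize a fluorescently tagged ER protein to the contact sites,
where it accumulates as diffraction-limited clusters; serial block-face SEM
provides label maps of ER and mitochondria from which contacts can be
measured directly. `mcsquant` implements the downstream quantification for
both regimes, for cell biologists analysing such experiments:

* **3D cluster analysis** — segment labelled clusters in confocal z-stacks
  (global threshold, 26-connected components), measure each cluster's
  surface area *S* on a triangulated isosurface in physical units and its
  **contact area** *A = S / 2* (one face of the thin double-membrane
  apposition touches the partner organelle); summarize per cell by the
  median contact area.
* **Cell-surface density** — approximate the cell surface from the cluster
  centroids with a 3D alpha shape (Delaunay tetrahedra with circumradius
  ≤ α; α = ∞ gives the convex hull) and report the density
  *n* / area(α-shape) and the coverage Σ*A* / area.
* **Two-channel colocalization** — matched cluster fractions by voxel
  overlap (or centroid distance), with paired *t* tests under
  Holm–Bonferroni correction, one-way ANOVA + Tukey HSD, and Welch/Student
  *t* for group comparisons.
* **Perimeter profiles** — normalized intensity profiles along closed
  organelle outlines; the **MCS fraction** is the run-length-encoded
  fraction of samples above a threshold, with wrap-around runs merged;
  pixelwise Pearson correlation for signal colocalization.
* **Spot tracking** — per-frame detection, greedy nearest-neighbour
  linking, the track filters (≥ 4 frames and end time ≥ 100 s, inclusive)
  and mobility as the median of per-track median step speeds.
* **EM contacts** — exact anisotropic Euclidean distance transform (EDT)
  seeded from the mitochondria labels; ER voxels with distance ≤ *d* for
  *d* = 10…50 nm form contact patches (3D segmented), each assigned to its
  nearest mitochondrion by majority vote; tables report per-patch and
  per-mitochondrion contact area against the mitochondrion surface area,
  and per-cell means across the distance sweep.

Raw imaging data for the published measurements are not deposited, so the
package ships seeded synthetic-scene generators (`gen_clusters_on_cell()`,
`gen_two_channel_clusters()`, `gen_em_scene()`, `gen_profile()`,
`gen_tracks()`) whose analytic ground truth makes every stage testable:
puncta on a spherical cell at a controlled density, sphere–plane EM
geometries with the closed-form contact area π((R+d)² − (R+g)²), profiles
with an exactly realized above-threshold fraction, and spots moving at a
controlled speed.

## Worked example

```r
library(mcsquant)

# a synthetic interphase cell: 150 label clusters on a ~6.8 um cell surface
cfg <- scene_config(seed = 42, spacing = c(0.1, 0.1, 0.15), noise_sd = 0.2)
sim <- gen_clusters_on_cell(cfg, cell_radius = 6.78, n_clusters = 150,
                            cluster_radius = 0.28, psf_sigma = 0.05)
seg <- segment_clusters(sim$stack, threshold = 0.5, min_size = 10)
seg$clusters
#> <cluster_set> cell 'cell' (interphase): 128 clusters
#>   median contact area 0.478 um^2, median size 59 voxels

surf <- alpha_shape_surface(as.matrix(seg$clusters$clusters[, c("x", "y", "z")]))
surf
#> <cell_surface> 128 vertices, 252 boundary triangles, area 554 (alpha = Inf)
cluster_density(seg$clusters, surf)   # 0.231 clusters/um^2 (truth 0.260)
coverage_fraction(seg$clusters, surf) # 0.124 of the cell surface
```

The median contact area (0.478 µm²) recovers the 0.28 µm puncta
(2π·0.28² = 0.49 µm²); the density under-reads the true 0.26 µm⁻² by ~11%
because at this realistic crowding some sub-resolution cluster pairs merge
— the vignette quantifies this behaviour.

```r
# EM pipeline on a sphere-plane scene (R = 200 nm, gap 20 nm)
ecfg <- scene_config(seed = 1, spacing = c(10, 10, 10), shape = c(60, 60, 80))
scn <- gen_em_scene(ecfg, mito_spec = list(list(center = NULL, radius = 200)),
                    er_spec = list(list(gap = 20, thickness = 100)))
mito <- segment_labels_3d(scn$mito$labels > 0, scn$mito$spacing)
build_contact_table(scn$er, mito, cell_id = "cell_1")
#> <contact_table> 1 mitochondria, distances 10/20/30/40/50 nm
#>  cell_id search_distance mean_contact_area n_mito n_patches
#>   cell_1              10              0.00      1         0
#>   cell_1              20            300.00      1         1
#>   cell_1              30          13247.34      1         1
#>   cell_1              40          27082.07      1         1
#>   cell_1              50          47631.21      1         1
```

At *d* = 30 nm the analytic truth is π·(230² − 220²) ≈ 14 137 nm²; the
pipeline measures 13 247 nm² (−6%). Below the 20 nm gap there is no
contact; at *d* = *g* exactly only a measure-zero ring survives (one voxel,
300 nm²).

A thin CLI wraps the same functions (`exec/mcsquant`):

```sh
mcsquant simulate em --seed 1 --out scenes/
mcsquant run --config run.yaml --seed 4
```

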