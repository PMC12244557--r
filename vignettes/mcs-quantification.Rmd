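---
title: "Quantifying ER-membrane contact sites: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ER-membrane contact sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mcsquant` quantifies endoplasmic-reticulum membrane contact sites (MCSs)
from two very different kinds of image data: fluorescence stacks in which an
inducibly relocalized ER label accumulates as diffraction-limited clusters
at contact sites, and volume-EM label maps in which ER and mitochondria are
delineated voxel by voxel. This vignette explains the quantities the package
computes, the estimators behind them, the synthetic scenes everything is
validated on, and the design decisions that were genuinely open.

## The measured quantities

**Contact area of a cluster.** A labelled cluster marks a patch of ER
apposed to the partner membrane. Its segmented volume is a thin blob whose
closed surface counts both the apposed face and the cytoplasmic face, so
the contact area is defined as half the cluster surface area,
$A = S/2$. This identity is enforced structurally (the `cluster_set`
container rejects anything else) and every per-cell summary is the median
over clusters, which is robust against the occasional merged cluster pair.

**Cluster density and coverage.** Cluster counts are normalized by a cell
surface reconstructed *from the cluster positions themselves*: the boundary
of the 3D alpha complex (tetrahedra of the Delaunay tetrahedralization with
circumradius $\le \alpha$). Density is $n/\mathrm{area}$ and coverage is
$\sum A_i/\mathrm{area}$.

**MCS fraction of a perimeter.** A closed outline drawn around an organelle
in the anchor channel is sampled at equal arc-length steps; both channels
are normalized to $(I-\mathrm{bg})/(\max-\mathrm{bg})$; the fraction of
samples *strictly above* a threshold, computed by run-length encoding with
the wrap-around runs merged, is the fraction of the perimeter occupied by
labelled contact.

**EM contact areas.** The exact Euclidean distance transform (EDT) of the
mitochondria labels gives every voxel its distance to the nearest
mitochondrion, voxel centre to voxel centre, with anisotropic spacing
honoured exactly. ER voxels with distance $\le d$ (inclusive) form the
contact mask at search distance $d$; its 26-connected components are the
contact patches, each assigned to the mitochondrion that is nearest for the
majority of its voxels (ties to the smaller label). Patch areas are
accumulated per mitochondrion and compared with the mitochondrion's own
surface area; the sweep $d = 10,\dots,50$ nm is reported per distance.

## Surface-area estimation

The only non-obvious numerical problem in the package is measuring the area
of a digitized object. Counting exposed voxel faces overestimates a sphere
by a factor approaching 1.5 (the Manhattan staircase), and a triangulated
isosurface of the *raw binary* mask still overestimates by roughly 9% at
any resolution, because the mesh follows the staircase at voxel scale. Both
estimators are available (`surface_area(method = "voxel_faces")` is kept as
a diagnostic), but the default mesh estimator works on a lightly smoothed
mask:

1. Gaussian-smooth the binary component, $\sigma = 0.7\times$ the smallest
   voxel spacing;
2. extract the 0.5-level isosurface by marching tetrahedra (each grid cell
   split into six tetrahedra; the decomposition is consistent across shared
   faces, so the surface is watertight);
3. compensate the smoothing-induced erosion: smoothing moves the half-level
   surface of a convex blob of radius $r$ inward by $\approx\sigma^2/r$, so
   the area is multiplied by $(1+(\sigma/r_{\mathrm{eff}})^2)^2$ with
   $r_{\mathrm{eff}}$ the volume-equivalent radius of the component.

On digitized spheres this estimator is within 1–2% at 10-voxel radius and
within ~10% down to 3-voxel radius; convergence with radius is asserted in
the tests. The compensation step assumes blob-like (convex) components,
which is exactly the regime of diffraction-limited clusters.

EM contact patches are a different regime: sheets one to a few voxels
thick. The default $0.7$-voxel smoothing would erase them, so
`patch_area()` meshes the patch after a gentler $0.4$-voxel anti-aliasing
pass (enough to melt the terrace risers that otherwise inflate curved
patches by up to +16%, gentle enough that one-voxel sheets keep a 0.5-level
surface), halves the total, and falls back to the unsmoothed mesh and
finally to half the exposed voxel-face area (a single voxel at 10 nm
spacing reports $6\cdot100/2 = 300$ nm²). These two smoothing scales were
fixed from pilot error tables on digitized spheres and sphere-plane scenes
before the acceptance tests were written, and are not tuned per dataset.

## The alpha-shape default

The alpha complex needs a cutoff $\alpha$ with length units. A popular
heuristic — a small multiple of the nearest-neighbour spacing — fails
structurally for this package's own use case: cluster centroids lie *on a
smooth closed surface*, so any four nearby points are nearly co-spherical
with the cell itself and every local tetrahedron has circumradius close to
the cell radius, far above any multiple of the point spacing. A small
$\alpha$ therefore retains nothing. The default is $\alpha = \infty$ (the
convex hull), which is correct for convex cell outlines; a finite $\alpha$
of the order of the expected local radius of curvature remains available
for concave cells, and the implementation errors loudly when no tetrahedron
survives the cutoff.

Robustness: points on a sphere are a degenerate input for incremental
Delaunay (the insphere predicate vanishes identically). The implementation
applies a deterministic symbolic jitter of $10^{-9}$ of the cloud diameter
(escalating to $10^{-5}$ if a watertightness audit of the boundary fails)
before triangulating; areas are always evaluated on the unjittered
coordinates.

One bias deserves attention: the convex hull of $n$ points *sampled from* a
smooth surface is inscribed in it and under-measures its area by
$\approx 6/n$ for a sphere (−11% at $n=50$, −3% at $n=200$, −0.6% at
$n=1000$; measured numerically). This is a property of the surface
reconstruction, not of the implementation, and it partially cancels the
count lost to cluster merging when densities are realistic. It is why
density recovery in the acceptance benchmark is asserted on the mean over
scenes rather than per scene at small $n$.

## What the synthetic scenes emulate — and what they do not

The generators are first-class, tested code; all downstream validation
rests on them because the raw imaging data behind the published per-cell
values are not deposited.

* **Cluster scenes.** Puncta are hard spheres convolved with an isotropic
  Gaussian (closed form, verified against the noncentral-$\chi^2$
  representation of the ball-Gaussian convolution), placed *uniformly* on a
  spherical cell (normalized 3D Gaussian draws — exactly uniform), over a
  constant background with additive Gaussian noise. Defaults: voxel spacing
  $0.1\times0.1\times0.15$ µm (in-plane Nyquist-ish confocal sampling, a
  finer-than-typical z step chosen so a 0.3 µm punctum spans two z planes),
  optical blur $\sigma$ one in-plane voxel (benchmarks use 0.05 µm), SNR
  (peak/noise-sd) 5. Uniform placement means *sub-resolution pairs occur at
  realistic densities*: at the measured density of 0.26 µm⁻² with 0.28 µm
  puncta, several percent of clusters merge under any threshold
  segmentation. The benchmark therefore fixes a true density of 0.04 µm⁻²
  (cell radius grows with $n \in \{50, 100, 200\}$) where the expected merge
  loss is 2–3%, and the acceptance criteria bound the *mean* recovery error
  over 20 seeded scenes (count 5%, density 10%, median contact area 15%).
* **Two-channel scenes** place shared puncta co-centred and non-shared
  puncta with a minimum separation (rejection sampling), so the expected
  colocalized fraction is exact by construction.
* **EM scenes** are spheres (mitochondria) and plane slabs (ER) with
  controlled surface-to-surface gaps; the analytic contact area at search
  distance $d$ is $\pi((R+d)^2-(R+g)^2)$ for $d \ge g$. Sphere centres are
  snapped to the voxel-centre lattice: EDT distances are centre-to-centre,
  and off-lattice geometry would load every measured distance with a
  systematic half-voxel penalty that is an artefact of scene construction,
  not of the estimator (on-lattice scenes recover the analytic area within
  15% at every $d>g$; at $d=g$ only a measure-zero ring of voxels at the
  exact distance can appear).
* **Tracks** take a step of `speed * frame_interval` in a fresh random
  direction each frame; **profiles** realize an exactly rounded
  (round-half-even) above-threshold sample count, optionally split into
  several runs that may wrap across the closed-profile seam.

None of the generators model a realistic PSF (no axial elongation, no
Airy rings), camera noise beyond additive Gaussian, reticular ER
morphology, curved or tubular mitochondria, uneven illumination, or
photobleaching. Passing the acceptance benchmark therefore demonstrates
that the *estimators* are correct and well-calibrated on geometry whose
truth is known — not that segmentation choices (threshold, minimum size)
transfer to any particular real dataset. On real data the threshold and
the alpha parameter remain the analyst's responsibility, and every output
table records the parameters that produced it.

## Statistical conventions

Paired pre/post comparisons use two-sided paired $t$ tests per pair with
Holm's step-down adjustment across the family (`p.adjust(method = "holm")`;
the worked example $(0.01, 0.04, 0.03) \to (0.03, 0.06, 0.06)$ is asserted
in the tests). Between-condition comparisons use one-way ANOVA with Tukey's
HSD on per-experiment means; two-sample comparisons use Welch's $t$ by
default with the pooled Student form available. All tests are two-sided.
Degenerate inputs (zero-variance differences or samples) raise errors
rather than returning numbers.

Tracking follows the published filters exactly: tracks shorter than 4
frames *or* ending before 100 s are removed, both bounds inclusive, and the
cell-level mobility is the median over tracks of the per-track median step
speed (the averaging order is stated here because it is not uniquely
determined by a single printed median; medians-of-medians is the
scale-robust choice).

## Numerical and contract details

* "Above threshold" is strict (`>`); ties count as below. Search distance
  is inclusive (`<=`), matching the stated "equal or less than" rule.
* Connectivity is 26 everywhere in 3D (8 in 2D frames); labels are
  assigned in raster order of each component's first voxel, so labelling
  is deterministic.
* Voxel centres sit at $(i-0.5)\times$ spacing; centroids are
  intensity-weighted and reported in physical units.
* Greedy nearest-neighbour linking links closest pairs first, refuses
  displacements above `max_disp`, and breaks distance ties toward the
  smaller spot id. No gap closing, splitting or merging, consistent with
  the near-absence of such events in the underlying movies.
* Contact-patch ties between equidistant mitochondria go to the smaller
  label id. Patches are re-identified independently at each search
  distance.
* All randomness flows from a single seed; generators restore the caller's
  RNG state. Pipeline reruns with one configuration and seed are
  byte-identical, which the acceptance suite asserts on raw file bytes.
* Problem sizes in the shipped benchmark: twenty cluster scenes with
  $n \in \{50, 100, 200\}$ puncta (grids up to $\sim$420×420×280 voxels),
  sphere-plane EM scenes at 60×60×80 voxels and 10 nm spacing, 50 random
  EDT volumes up to $32^3$ against a brute-force oracle, 1000-point alpha
  shapes, 1000 random run-length profiles. These sizes make the whole
  validation reproducible on a laptop in a few minutes while keeping every
  tolerance meaningfully exercised.

## Known limitations

* Global thresholding with connected components cannot split
  sub-resolution cluster pairs; at published densities this biases counts
  low by a few percent (quantified above). Marker-based splitting was
  deliberately left out to keep the segmentation contract simple and
  deterministic.
* The curvature compensation in the mesh-area estimator assumes convex
  blobs; for elongated or branched objects it over-corrects slightly (the
  uncompensated value can be recovered with
  `curvature_correction = FALSE`).
* The EDT measures distances between voxel centres. Sub-voxel gap
  geometry (gaps that are not multiples of the spacing) shifts detected
  contact areas by up to half a voxel in effective distance; at 10 nm
  voxels this matters most in the first 10 nm of the sweep.
* `alpha_shape_surface()` with finite alpha reports the boundary of the
  alpha complex without manifold repair; for pathological point sets the
  area of a non-watertight boundary is still the sum of its boundary-face
  areas.
* TIFF I/O carries physical spacing in a JSON sidecar (the TIFF writer
  available cannot embed resolution tags); readers error rather than
  assume units when the sidecar is missing and no override is given.
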