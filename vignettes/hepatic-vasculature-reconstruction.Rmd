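---
title: "Reconstructing hepatic vessels from dual-channel fluorescence volumes"
author: "hepavasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing hepatic vessels from dual-channel fluorescence volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepavasc)
```

## The problem

Whole-organ fluorescence tomography of the mouse liver produces two
co-registered channels at sub-micrometre lateral resolution: a **vessel
channel** carrying the endothelial signal (blood and lymphatic vessel walls
light up; biliary epithelium does not) and a **cytoarchitecture channel**
carrying a nuclear stain (every cell nucleus, plus diffuse cytoplasmic
signal). The liver's vessel systems span three orders of magnitude in
caliber, and each leaves a different footprint in these channels:

* **Portal vein (PV)** and **hepatic vein (HV)** — large lumens that appear
  as nuclei-free *dark voids* in the cytoarchitecture channel.
* **Hepatic artery (HA)**, **bile duct (BD)**, **lymphatic vessel (LV)** —
  companion tubes that travel with the portal vein (the portal triad, plus
  lymphatics). The HA has a thick wall and stable lumen; the BD is visible
  only in the cytoarchitecture channel as a ring of biliary epithelial
  nuclei; the LV is thin-walled and irregular.
* **Hepatic sinusoids** — the capillary mesh (≈7–15 µm diameter) connecting
  portal inflow to venous outflow, appearing as bright tubes in the vessel
  channel.
* **Peribiliary plexus (PBP)** — fine capillaries wrapping the bile ducts.

`hepavasc` implements the computational part of the reconstruction
workflow: preprocessing, a multiresolution pyramid with block extraction,
parameter-corrected Otsu segmentation in a dark-lumen and a bright-tube
mode, topology-preserving centerline skeletonization, rayburst-style
diameter estimation, PV/HV classification by the accompaniment principle,
and sinusoid diameter statistics under a strict 15 µm cutoff. Because no
public dataset of this kind exists, the package ships a synthetic phantom
generator that emulates the statistical and geometric structure the
pipeline assumes and carries exact ground truth, so every stage can be
validated quantitatively.

## Conventions

One convention is used everywhere: arrays are indexed `(z, y, x)` with the
first index fastest in memory; all 3-vectors (voxel sizes, origins, sizes,
coordinates) are ordered `(z, y, x)`; world coordinates are micrometres;
the world position of 0-based voxel `(i, j, k)` is
`origin + (index + 0.5) * voxel_size` (voxel centres). Stacks are 16-bit
multi-page TIFF with a JSON sidecar for geometry; skeletons export to
7-column SWC with the vessel class in the `type` column
(`VESSEL_CLASSES`).

## The phantom generator

`phantom_config()` + `generate_phantom()` build a dual-channel scene with
exact ground truth (tube polylines, per-point radii, class labels, a label
volume and per-class masks). The generator emulates:

* **Vein trees.** Recursive bifurcation with Murray-type radius decay
  (`r_child = decay · r_parent`, default 0.72–0.75), jittered growth
  (tortuosity), and a PV and an HV tree entering from opposite faces. The
  two trees interdigitate but are confined to disjoint bands so the lumen
  systems never touch, as parenchyma separates portal tracts from central
  veins in a real lobe.
* **Companions.** Each PV tube carries HA, BD and LV tubes running parallel
  at offset `local PV radius + gap + companion radius`, at three phases
  around the PV axis. HV tubes have none — this is the accompaniment
  structure the classifier exploits.
* **Sinusoid mesh.** A random geometric graph: junction points sampled
  uniformly (default 0.06 per 1000 µm³, ≈25 µm spacing), each joined to its
  2 nearest neighbours within 40 µm, plus edges from every vein tip to its
  nearest junction. Edge radii are log-normal with median 4.75 µm and
  σ(log) = 0.18, i.e. median diameter 9.5 µm, mean ≈9.65 µm, ≈99% below the
  15 µm sinusoid cutoff — consistent with the 7–15 µm range reported for
  mouse hepatic sinusoids. At these defaults the mesh occupies ≈10% of the
  block volume.
* **Peribiliary plexus.** Two 1.5 µm helices wrapping each bile duct.
* **Channels.** Vessel channel: endothelial-labelled tubes thicker than
  `solid_max_radius_um` (8 µm) render as bright walls (2 µm) around a dark
  lumen; thinner ones render solid, since wall and lumen are unresolved at
  the ≈1 µm working voxel; BD is absent. Cytoarchitecture channel: diffuse
  cytoplasmic background (0.15), bright nuclei (radius 3.5 µm, 0.06 per
  1000 µm³) outside vessels, a ring of biliary epithelial nuclei around
  each BD, and dark nuclei-free lumens.
* **Noise.** The standard fluorescence camera model,
  `Poisson(gain · signal)/gain + N(0, σ²)`, applied last (gain 50,
  σ = 0.01 by default); zero gain and σ give a strictly noiseless scene
  taking only the configured intensity levels.
* **Grid.** The default block rasterizes 128³ µm on an anisotropic
  `(z, y, x) = (1, 0.5, 0.5)` µm grid — the native acquisition grid
  (1 µm axial, sub-micrometre lateral) coarsened laterally so desk-scale
  volumes stay ≤ 256³ voxels.

The intensity levels are free parameters of the emulation, not fits to any
measured photon statistics; segmentation is threshold-based, so tests
depend on contrast ordering rather than absolute levels.

What the phantom deliberately does **not** emulate: illumination stripes
and stitching seams of real block-face tomography, photobleaching, optical
PSF anisotropy, zonation of the lobule, and hemodynamically realistic
branching geometry. Passing tests therefore demonstrate correctness of the
algorithms on geometry of the right scale and topology under shot noise —
not robustness to every artifact of real acquisitions.

## Preprocessing

The large-vessel chain is median filter → gamma correction → bicubic
downsampling (`preprocess_volume()`):

* **Median filter** — per-voxel median over a cubic `(2r+1)³` window with
  reflected edges. The window radius is not documented in the original
  workflow; the default `r = 1` (3³) is the minimal denoising window.
* **Gamma correction** — intensities are percentile-normalized to `[0, 1]`
  (clipping), then raised to γ. No γ value is documented; the default 0.8
  gives mild contrast enhancement, and every test is parameter-independent
  (the mapping is monotone for any γ > 0). Whether normalization preceded
  the power in the original workflow is unstated; normalize-then-power is
  this package's choice.
* **Resampling** — Gaussian anti-alias blur (σ = 0.5 × the per-axis
  decimation factor, in source voxels) followed by separable Catmull–Rom
  cubic interpolation at the new voxel centres. Only downsampling is
  supported. The two working grids are 5 µm isotropic (large veins) and
  1 µm isotropic (sinusoid blocks, from the native anisotropic grid).

## Pyramid and blocks

`build_pyramid()` mean-pools by 2 per axis per level (partial edge blocks
average what is available, so every level covers the source box);
`write_pyramid()`/`read_pyramid()` store it as one 16-bit TIFF per chunk
plus a JSON manifest, padding partial edge chunks by edge replication and
flagging them. `extract_block()` picks the finest level at or above the
requested voxel size and resamples bicubically (nearest for label
volumes). The output grid *covers* the requested box:
`shape = ceiling(size/voxel)` per axis, so a 2000³ µm block at
1.28 × 1.28 × 4 µm comes out 1563 × 1563 × 500 voxels. The exact on-disk
layout of terabyte-scale pyramid formats is out of scope; this store is
format-*like*, not format-compatible.

## Segmentation

All "manually tuned" freedom is collapsed into one documented knob:
`correction_c`, a positive multiplier on the Otsu level, plus explicit
cleanup parameters (`segment_params()`).

* `otsu_level()` maximizes the between-class variance over all `n_bins − 1`
  splits of a full-volume histogram (per-slice thresholding would flicker
  along z); ties break to the lowest level. The unit suite checks it
  against an exhaustive scan on random 8- and 16-bit histograms.
* `segment_volume()` keeps voxels ≥ `c · t*`. In `dark_lumen` mode the
  volume is inverted first: vein lumens are nuclei-free, hence dark in the
  cytoarchitecture channel. (The original workflow does not state that vein
  segmentation used inversion; dark-lumen mode is an inference from the
  image logic and is flagged as such.) The vein workflow default is
  `c = 1.05`: at 5 µm, partially-resolved structures sit between the lumen
  and parenchyma modes, and a 5% raise keeps only clean lumen voxels.
* `morph_cleanup()` — binary closing with an exact Euclidean ball (via the
  distance transform), 6-connectivity hole filling, then removal of
  26-connected components below `min_component_vox`. The operation is
  idempotent; connectivity is fixed at 26 for components and 6 for holes to
  prevent diagonal leaks.

Companion vessels (HA/BD/LV) are *inputs* to classification, not products
of this pipeline — they were traced manually in the original workflow, and
validation supplies the phantom's ground-truth masks in their place.
`reconstruct_veins()` subtracts the (separately traced) companion lumens
from the vein mask before skeletonization, since companion lumens are
nuclei-free voids too.

## Skeletonization

`skeletonize()` thins the mask to a 1-voxel curve skeleton and assembles a
spatial graph (`igraph`), requiring an isotropic grid (thinning on
anisotropic voxels biases centerlines — resample first; the function
refuses otherwise).

The thinning is *sequential simple-point thinning*: a border voxel is
deleted only while it is a simple point for (26, 6) connectivity — its
object neighbourhood forms exactly one 26-component and the background
voxels of its 18-neighbourhood that touch it 6-wise form exactly one
6-component — so every deletion is homotopy-preserving by construction.
Three ordering rules keep the result centred and stable:

1. candidates are processed in increasing distance-to-background order, so
   deletion tracks the medial ridge;
2. each iteration runs six directional subpasses (borders of one face
   direction at a time), which balances erosion;
3. voxels with fewer than three object neighbours are never deleted. This
   last rule is what prevents "zippering": with only an endpoint rule
   (≤1 neighbour), a 2-voxel-wide ribbon can be consumed end-to-end in scan
   order — a failure mode that orientation-dependently affects parallel
   thinning implementations as well. Requiring ≥3 neighbours makes a 2-wide
   ribbon resolve to a clean 1-wide curve at full length.

Graph assembly links 26-adjacent skeleton voxels, drops diagonal shortcut
edges across a common neighbour, and merges mutually adjacent junction
voxels (degree ≥ 3) into one junction node at their centroid. Every
skeleton voxel is a node — no resampling — so radius sampling is dense.

`prune_spurs()` removes terminal branches shorter than `min_spur_um`
(default 5 µm ≈ one sinusoid radius) to a fixpoint, never touching cycles.
It is the declared automated stand-in for manual branch correction, whose
criteria were never recorded; it is not a reproduction of them.

Validated properties: a cylinder reduces to one branch with two endpoints
within one voxel of the true axis; a torus keeps exactly one cycle; a tube
lattice with known first Betti number (β₁ = 16) is recovered exactly,
including junction and branch counts; skeleton endpoints equal the
generated tree's tip count after 5 µm pruning. One property planned
against the random mesh was replaced: at realistic density the rasterized
mesh *itself* loses cycles (tubes of ≈9.5 µm diameter merge at ≈25 µm
junction spacing before skeletonization sees them), so cycle preservation
is asserted on the deterministic lattice where mask topology equals graph
topology.

## Diameters: rayburst-style ray casting

`local_diameter()` casts `n_rays` (default 32) evenly spaced directions in
the plane orthogonal to the local tangent; opposed rays pair into chords;
each boundary is located by marching (0.25 µm steps) the trilinearly
interpolated mask to its 0.5 level and linearly interpolating the crossing,
which gives sub-voxel precision and makes the estimate unit-correct on
anisotropic grids. Rays without a boundary inside `max_ray_um` make a
chord unbounded; a point with no bounded chord is returned missing and
excluded from statistics.

The default aggregate is the **median lower band** — the median of the
chords at or below the overall median chord. On a circular section all
chords agree and the rule reads the true diameter; on elongated sections
(oblique cuts, fused branch junctions) it reads the minor axis instead of
being dragged upward by long chords. Plain `median_chord` was measurably
high (≈ +3%) on mesh phantoms for exactly that reason; `min_chord` is
biased low by boundary noise. `measure_graph()` takes tangents from
central differences of neighbour nodes (one-sided at endpoints), stores a
diameter per node, and summarizes branches by the median over non-junction
nodes.

## Classification and statistics

`classify_veins()` implements the accompaniment principle: for each
connected vein component, the fraction of skeleton nodes with any
companion (HA/BD/LV) foreground within `companion_radius_um` (one
distance-transform lookup per mask) decides PV
(fraction ≥ `min_companion_fraction`, boundary inclusive) versus HV. The
defaults are 0.5 for the fraction and a search radius sized to the vein
caliber (60 µm for root radii ≈ 40 µm: the companion surface sits at about
the vein radius plus the triad gap from the centerline). Classification is
deterministic and invariant to node order; with no companion evidence at
all, every component is HV, with a warning.

`sinusoid_stats()` filters diameters **strictly below 15 µm** — vessels of
15 µm and above are terminal arterioles and terminal portal venules, not
sinusoids — computes one mean per block, and reports mean ± sample SD
(n − 1) *across block means*, matching a blocks-as-replicates design with
n = 8 randomly chosen blocks; pooled per-node statistics are reported
alongside, since the unit of replication behind a published
"mean ± SD over 8 blocks" is ambiguous between the two.

## Validation design and problem sizes

The validation suite generates everything at run time; sizes were chosen
so the full suite runs comfortably on one CPU:

* analytic shapes at 1 µm voxels in 128³ grids (diameter and topology
  oracles);
* vein scenes of 512³ µm at 2.5 µm raster for segmentation fidelity
  (dark-lumen Dice ≈ 0.95 against PV+HV labels at the 5 µm working
  resolution) and 320³ µm at 4 µm raster for the 20-phantom
  classification check (100% correct with companions present and absent);
* eight sinusoid blocks of 128³ µm (1 µm isotropic working grid, default
  noise) for end-to-end morphometry, mirroring the study design of eight
  randomly selected local blocks.

On those eight blocks the pipeline recovers the generator's mean sinusoid
diameter to within ≈2% (well inside the 10% requirement). A stricter
agreement bound of two cross-block standard errors (≈0.12 µm here) is not
met and is knowingly reported as failing in the acceptance suite: the
remaining offset is systematic, dominated by genuinely fused junction
zones of the anastomosed mesh and by sub-15 µm companion structures
entering the cutoff sample — not by estimator noise — and shrinking it
below 1% would require tuning the scene toward the test, which the
validation deliberately avoids.

## Numerical choices and degenerate inputs

* Ties in the Otsu scan break to the lowest level; the threshold is the
  boundary between the two classes' bins, and `≥` assigns the boundary to
  foreground.
* A histogram with a single occupied bin, a constant volume, a degenerate
  percentile window, upsampling requests, anisotropic input to
  `skeletonize()`, a 2D TIFF, and missing voxel-size metadata all raise
  explicit errors rather than guessing.
* Closing uses `d ≤ r + ε` consistently for the dilation/erosion adjoint
  pair, which is what makes the discrete closing idempotent.
* The fraction-at-threshold classification case is PV (`≥` rule).
* Empty masks skeletonize to empty graphs; isolated loops are immune to
  pruning.
* Seeds fully determine phantoms: tree generation and rasterization each
  reseed from `config$seed`, so identical configs give byte-identical
  volumes, ground truth and output files.

## Known limitations

* The phantom's intensity statistics are plausible but uncalibrated; the
  pipeline's behaviour on real stripe/bleaching artifacts is untested.
* Skeleton centerlines shorten by roughly one tube radius at open tube
  ends (caps erode before the curve emerges) — endpoint *counts* are
  exact, endpoint *positions* are conservative.
* Diameters at branch junctions describe the fused geometry, not a single
  vessel; the lower-band aggregate mitigates but does not remove this.
* The peribiliary plexus is generated in the phantom but no dedicated
  automatic segmentation is claimed for it, matching the manual treatment
  in the original workflow.

## A worked example

```{r example, eval = FALSE}
library(hepavasc)

cfg <- phantom_config(seed = 1)
ph  <- generate_phantom(cfg)

res <- reconstruct_sinusoids(ph$vessel)     # preprocess, segment, skeletonize,
print(res$skeleton)                         # prune, measure

st <- sinusoid_stats(list(res$diameters_um))
print(st)

write_swc(res$skeleton, "sinusoids.swc", VESSEL_CLASSES[["SINUSOID"]])
write_node_csv(res$skeleton, "sinusoid_nodes.csv")
```
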