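---
title: "Methods: models, parameters and numerical choices in emsegkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices in emsegkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

emsegkit is a headless, scriptable toolkit for segmenting neuronal structures
(mitochondria, neurites, synapses) in serial-section electron microscopy
volumes. It covers the full desk-scale workflow: reading and writing image and
label stacks, classic preprocessing, 2D CNN semantic segmentation, 3D
flood-filling instance segmentation, postprocessing into labeled objects,
quantitative evaluation, and mesh/annotation export. This vignette documents
the models, the parameters that matter, and the numerical decisions, in the
package's own words.

## Data model

Volumes are dense 3D arrays in `(z, y, x)` order — the slice index is `z`.
`image_stack` holds 8- or 16-bit grayscale (or 8-bit RGB) intensities with a
physical voxel spacing, default `(30, 6, 6)` nm `(z, y, x)`: 30 nm serial
sections at 6 nm in-plane sampling, a common ATUM-SEM geometry. The spacing
is configurable everywhere; anisotropy matters for the distance transform and
for mesh coordinates. `label_volume` holds nonnegative integer object ids,
background strictly 0, ids not necessarily contiguous.

Label stacks written as PNG encode ids above 255 as RGB with
`id = R + 256·G + 65536·B` (little-endian, the Dojo/VAST convention), which
caps PNG-representable ids at $2^{24}-1$; 32-bit TIFF or HDF5 carry larger
ids. All round trips are bit-exact, enforced by tests.

## Classic filters

Filters (`gaussian`, `median`, `clahe`, `invert`, `threshold`) are described
by a small registry and applied slice-wise unless declared `3d` (then a true
volumetric kernel). A chain of filters is always bit-identical to applying
the filters one at a time, so the chain runner is purely a convenience.
Gaussian and median smoothing delegate to EBImage.

### CLAHE

Contrast-limited adaptive histogram equalization is parameterized by block
size (default 127 px, odd, smaller than the slice), histogram bins (256) and
*max slope* (1.50). The max-slope parameterization is common in EM practice
but its conversion to a clip limit is rarely written down; ours is:

* each tile's histogram is clipped at `max_slope / bins` of the tile's pixel
  mass — a uniform histogram holds `1/bins` per bin, so the transfer
  function's slope is limited to roughly `max_slope` times the identity
  slope;
* the clipped histogram is renormalized (no redistribution of the excess; the
  monotone mapping is what matters, and renormalization keeps the full output
  range available);
* the mapping is the equalization CDF anchored at the lowest occupied gray
  level, `(cdf(v) − cdf_min) / (1 − cdf_min)`, scaled to the dtype range;
* a tile with a single gray level carries no contrast information and maps
  identity — hence constant slices are exact fixed points;
* pixels are transformed by bilinear interpolation between the four
  surrounding tile mappings (clamped at borders), the standard CLAHE
  blending.

Two consequences the tests rely on: a constant slice is returned unchanged,
and a two-level image (e.g., a checkerboard) is always stretched to the full
dtype range regardless of the slope, because a two-bin histogram clips to
equal masses. We do not claim this mapping is numerically identical to any
other CLAHE implementation; it is documented and tested on its own terms.

## The 2D CNN engine

No deep-learning framework is assumed: the engine is a compact computation
graph over im2col/col2im convolution kernels (C++ via Rcpp; the matrix
products go through BLAS), with hand-derived backward rules verified against
numerical differentiation in the test suite, and Adam as the optimizer
(learning rate $10^{-3}$ by default).

Four topologies are provided, all mapping an `(h, w, c)` patch to raw
per-pixel scores at full resolution:

* **resnet** — a stem convolution, `(n_layers − 2) / 2` two-convolution
  residual blocks, and a 1×1 head; `n_layers` counts convolution layers.
* **highway** — as resnet but each block computes a sigmoid gate `T` and a
  candidate `H`, returning `T·H + (1 − T)·x`.
* **dense** — each layer convolves the concatenation of all previous feature
  maps (growth 16) and the head sees the full concatenation.
* **unet** — the classic 4-level contracting/expansive architecture with skip
  connections, 2×2 max pooling and nearest-neighbour upsampling; input sides
  must be divisible by 16. `n_layers` is ignored for unet.

Five losses: `square` (MSE on sigmoid outputs), `softmax` (per-pixel
cross-entropy across ≥ 2 channels), `entropy` (per-channel sigmoid
cross-entropy, multi-label), `dice` (1 − soft Dice, smoothing 1), `logistic`
(single-channel sigmoid cross-entropy). The names `entropy` and `logistic`
appear in EM tooling without printed formulas; we fix them as multi-channel
vs single-channel sigmoid cross-entropy and document that choice rather than
claim equivalence to any particular implementation.

**Epochs are gradient steps.** Training samples one random patch per step
(uniform random crop of a random slice, one augmentation drawn uniformly from
the configured dihedral set), so a "pass over the dataset" is not a
meaningful unit when a single annotated slice is a legitimate training set.
Patch sampling is uniform; class balancing is deliberately not applied.
Training is bit-reproducible from the config seed: initialization, sampling
and augmentation all flow from it, and the engine is single-threaded
deterministic.

### Tiled inference

`infer2d` covers each slice with `tile`-sized windows whose central cores
(the window minus an `overlap`-wide margin) tile the slice exactly; only core
predictions are kept. The margin supplies true image context, so any output
pixel farther than `overlap` + receptive-field radius from the slice border
is *identical* to a whole-slice forward pass — stitching introduces no seams
by construction, rather than hiding them by averaging. The receptive-field
radius of the full-resolution topologies is `n_layers` pixels (3×3 kernels),
so the default `overlap = 16` is seamless for the 9-layer default. Windows
extending past the slice are reflect-padded. Scores pass through the loss's
link (sigmoid, or per-pixel softmax for multi-class models).

## The flood-filling network

The 3D instance segmenter follows the flood-filling idea: a recurrent 3D CNN
sees a small field of view (FOV) of normalized intensity plus its own current
soft object mask, and predicts a residual update to the mask logits for the
object at the FOV center. Desk-scale defaults: FOV 17³ voxels (9³ in the
bundled fixtures), 2 residual conv blocks of width 12, 2 refinement
iterations, 500 training steps — sized so the full pipeline trains in minutes
on one CPU core. Gradients do not flow across refinement iterations (the fed
back mask is treated as data), which keeps memory flat and training stable at
these scales.

**Training coordinates.** For every voxel whose FOV fits inside the volume,
the fraction of the FOV occupied by that voxel's object is computed with a
summed-area table and bucketed into equal-width classes on (0, 1]; the
returned set is balanced to the smallest occupied class and shuffled. This
biases training toward both easy (object-filled) and hard (boundary) FOVs.
Coordinates travel as HDF5 (`centers`, `ids`, `classes`).

**Seeds.** The seed policy thresholds the intensity volume (Otsu; the darker
side is foreground for EM organelles), removes already-claimed voxels, and
ranks local maxima of the Euclidean distance transform in decreasing height
with `(z, y, x)` ascending tie-break — deterministic and biased toward object
centers.

**Flood filling.** Per seed: the object's probability canvas starts at the
background level (0.05) with the seed at 0.95; the model runs at the seed,
writes its refreshed mask back, and enqueues moves of `delta` voxels toward
each FOV face whose center-face probability reaches `move_threshold` (0.9),
never revisiting a move location for the same object (this plus the finite
seed list bounds termination even for adversarial constant-probability
models). When the queue drains, voxels at or above `segment_threshold` (0.6)
and not yet claimed become the object — first-come priority, no voxel ever
carries two ids — and objects below `min_segment_size` (27 voxels) are
discarded. No agglomeration of oversegmentation and no 2D watershed
refinement are applied afterwards; those are deliberately out of scope.

With a perfect membership oracle in place of the network, flood filling
provably reduces to connected-component labeling on convex-ish objects, and
the acceptance suite verifies exact equality (Rand score 1) on random
multi-ellipsoid volumes — separating the correctness of the flood-fill
machinery from the quality of any trained model.

## Postprocessing

* `binarize` uses the `>=` convention at the threshold (0.5 for probability
  maps, 128 for 8-bit images).
* `label3d` is BFS component labeling; connectivity 6 by default (26
  optional) — conservative for thin EM structures, since corner-touching
  voxels are almost always distinct processes at EM resolution. Ids are
  assigned in scan order of each component's first voxel.
* `distance_transform` is the exact separable lower-envelope squared EDT,
  anisotropic by default (z counts 5× at 30/6 nm spacing), toggleable.
* `watershed3d` floods the mask from markers in order of decreasing distance
  (equivalently ascending on the negative distance). When markers are absent
  they are the *h-maxima* of the EDT (h = one voxel step in the finest axis):
  grayscale reconstruction suppresses shallow plateaus — ripples from
  digitization and the flat crests of thin necks — so a dumbbell mask yields
  exactly two markers. Flood order is a priority queue keyed by (distance
  desc, discovery order asc, marker id asc): equal-distance fronts grow in
  lock step, so a uniform bar with markers at both ends splits exactly in
  half, and any remaining tie is broken by marker id. We considered breaking
  all ties purely by marker id, but that lets the lowest id flood an entire
  plateau before its competitor starts, which contradicts the balanced split
  one expects on symmetric fixtures.

## Evaluation

The central score is the foreground-restricted Rand score
$$V_\alpha = \frac{\sum_{ij} p_{ij}^2}{\alpha \sum_k s_k^2 + (1-\alpha)\sum_k t_k^2},$$
where $p_{ij}$ is the joint probability that a voxel lies in predicted object
$i$ and ground-truth object $j$, and $s_i$, $t_j$ are the marginals. It is 1
exactly when the segmentation matches up to relabeling. The $\alpha \to 0$
limit ($\sum p^2 / \sum t^2$, the split score) decreases when objects are
shattered; the $\alpha \to 1$ limit ($\sum p^2 / \sum s^2$, the merge score)
decreases when objects are fused; $\alpha = 0.5$ is their harmonic-type
combination and the conventional single number.

"Foreground-restricted" means voxels whose *ground-truth* id is 0 are dropped
before counting (the evaluation convention of the public EM segmentation
challenges); the toggle applies in both instance and semantic modes, and
semantic mode first collapses both volumes to binary. Predicted background
over ground-truth foreground is kept as an ordinary "object 0" row, so missed
voxels are penalized. Semantic overlap adds Jaccard, Dice and conformity
$(3D - 2)/D$; conformity is reported as $-\infty$ when Dice is 0.

## Meshes and annotations

Per-object surfaces are extracted as the 0.5 iso-surface of the object's
indicator under nearest-neighbour interpolation — a cuberille surface: one
quad (two triangles) per exposed voxel face, vertices on voxel corners scaled
to nanometres, outward winding. We chose this over classic marching cubes
deliberately: the 256-case triangle table has ambiguous configurations that
can produce non-watertight output, while the cuberille surface is watertight
by construction, encloses exactly the voxel volume, and gives Euler
characteristic 2 for genus-0 objects — the properties downstream morphometry
actually needs. The cost is a blocky appearance at voxel scale. Volumes are
padded by one background voxel so border-touching objects still close.

Annotation tables carry one row per object (default name `obj_<id>`,
deterministic golden-angle palette, voxel count) plus marker points in
physical nanometres (mesh space). Export produces `objects.csv`,
`markers.csv` and one ASCII STL or OBJ file per object; CSV round trips are
lossless.

## Synthetic volumes

Two generators make every stage testable without external data. The
*mitochondria* mode places non-overlapping random ellipsoids (in-plane
rotation only, so each slice cuts an oval; semi-axes 4–10 voxels in-plane,
1.5–3.5 in z; 2-voxel separation so components are unambiguous at either
connectivity) rendered dark (mean gray 80) with brighter internal stripes on
bright textured cytosol (mean 180), plus Gaussian noise (sd 10). The *mosaic*
mode partitions space into columnar cells by nearest-generator tessellation
with a per-slice random-walk drift (sd 0.75 voxels), separated by dark
membranes wherever the two nearest generators are within `membrane_width` of
equidistant. Placement uses rejection sampling capped at 100 retries per
object; an impossible request errors with the achieved count rather than
silently under-delivering.

The intensity model mimics SEM contrast only qualitatively: dark organelles
and membranes on bright cytosol with stationary Gaussian noise. It does not
simulate section artifacts, alignment jitter, charging, or texture inside
neurites — so green tests demonstrate that the algorithms are implemented
correctly and that the pipelines converge on easy, well-posed geometry, not
that any particular accuracy transfers to real EM data.

## Validation scales and expectations

The acceptance pipelines are sized for a single CPU core, and those sizes are
the package's documented study conditions:

* 2D workflow: 20 slices of 256², 15 ovals; 9-layer resnet, square loss, 300
  steps, patch 64, 32 base filters; evaluation on 5 held-out slices expects
  foreground-restricted semantic Rand ≥ 0.8 (measured ≈ 0.99).
* 3D workflow: two spheres in 32³, FOV 9³, 500 steps; flood-fill inference
  expects ≥ 2 recovered objects and instance Rand ≥ 0.7 (measured ≈ 0.85).
* Oracle-level properties (Rand equation vs voxel iteration, labeling vs BFS,
  flood fill vs components, watershed partition, mesh integrity, I/O round
  trips) are exact or near machine precision.

These desk-scale numbers make no claim about benchmark accuracy on real
connectomics datasets, which requires orders of magnitude more training on
GPUs; the point is that every moving part is individually and jointly
verified.

## Known limitations

* The CNN engine is single-threaded, single-sample (batch 1), CPU-only; it is
  a faithful small-scale engine, not a performance framework.
* `logistic`/`entropy` loss definitions are fixed by this package's
  documentation, not by an external reference implementation.
* Flood filling assumes reasonably convex objects for exact component
  recovery; long thin processes may need smaller move steps than the default.
* The mesh generator trades smoothness for guaranteed watertightness; apply
  external smoothing/decimation if visual quality matters.
* PNG I/O is limited to 8-bit grayscale and 24-bit RGB; use TIFF or HDF5 for
  16-bit data and ids ≥ 2²⁴.
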