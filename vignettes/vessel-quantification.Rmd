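---
title: "Measuring microvessel length density from detection boxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring microvessel length density from detection boxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesseltrace)
```

## The measurement problem

Angiogenesis assays seed intact microvessel fragments in a 3D gel and
let new vessels sprout. The readout that matters is **vessel length
density**: total vessel centerline length per unit field area, in µm/mm².
The imaging substrate is a 2D maximum-intensity projection of a confocal
stack (lectin-stained, bright vessels on dark background) or a
phase-contrast frame (dark, low-contrast vessels on gray). Both carry
structured nuisance: debris clumps and elongated single cells that
resemble vessels, out-of-focus objects, and strong vessel-to-vessel
brightness variation.

Manual tracing of each vessel with a polyline is the accepted reference
but does not scale. Pixel-based morphometry (threshold, filter by object
size, skeletonize, sum skeleton length) is fast but label-blind: any
elongated bright object of vessel-like width contributes length, so it
systematically overestimates density on noisy scenes.

`vesseltrace` implements the alternative this package is built around:
an object detector proposes many small overlapping boxes along vessels
(with class labels that *can* distinguish vessels from debris), and
vessel centerlines are reconstructed from the surviving vessel-class
boxes. The package deliberately contains no trained detector — the
detector is a pluggable contract, and a ground-truth-driven oracle plus
a classical intensity-based backend make the whole chain testable.

## From annotation to training regions

An annotation is a polyline: an ordered point chain in pixel units with
a label (`vessel`, `out_of_plane`, `debris`). Training regions are
square boxes of side `box_size` centered at points sampled along the
polyline's arc length every `stride` pixels, endpoints always included.
Requiring `stride < box_size` guarantees consecutive regions overlap, so
the union of boxes covers the whole trace; one traced vessel yields many
detector training regions, which is what makes small image sets
sufficient for detector training in this domain.

Defaults are `box_size = 32` px and `stride = 16` px (50% overlap): the
smallest standard overlap that keeps box counts in the hundreds per
image without redundancy. Both are configuration knobs; squares are used
because mainstream detectors consume axis-aligned boxes. Boxes near the
border keep their nominal centers so arc sampling stays regular;
clipping is purely a rendering concern. Out-of-plane and debris
polylines generate regions of their own class, so a detector can learn
to recognize — and the pipeline to discard — them.

## Reconstruction: boxes to polylines

Reconstruction runs three stages, in this order, then decomposes the
result:

1. **Neighbor graph** (`build_neighbor_graph`). Nodes are centers of
   vessel-class boxes with confidence at least `min_confidence`
   (default 0.25). Two nodes join when their center distance is at most
   `radius_factor` times the mean of the two box diagonals. The rule is
   scale-free in box size; the default `radius_factor = 1.25` connects
   consecutive boxes of one vessel at 50% overlap stride with slack for
   jitter and the occasional missed box (at the defaults the connection
   radius is about 57 px, 3.5 strides), while bounding long-range false
   links. Edge weight is the Euclidean center distance.

2. **False-connection removal** (`filter_false_connections`). Proximity
   links distinct vessels that pass close to each other. Each edge's
   straight segment is sampled at 1 px arc steps against a foreground
   mask — pixels above the `support_quantile` (default 0.8) intensity
   quantile of the histogram-equalized image — and kept only if at least
   `min_support` (default 0.7) of samples land on foreground. An edge
   crossing a dark gap dies; an edge inside a vessel survives. This
   straight-segment support test is this package's concrete reading of
   "contour-based" false-connection removal: the original criterion is
   not recoverable in detail, so the mask-support rule is declared as a
   substitute and kept pluggable (the mask source and both thresholds
   are parameters).

3. **Cycle removal** (`remove_cycles`). Box proximity plus image support
   can still close cycles (parallel box chains along one thick vessel,
   braided crossings). Per connected component the minimum-weight
   spanning tree is kept. The implementation is Kruskal's algorithm with
   ties broken by lexicographic node-id order, so output is fully
   deterministic; weight is center distance, the only geometrically
   meaningful choice available from boxes alone.

4. **Decomposition** (`graph_to_polylines`). The forest is split into
   maximal simple paths at nodes of degree ≥ 3. Total length — the
   quantity of interest — is invariant to where trees are split; the sum
   of polyline lengths equals the total forest edge weight exactly (to
   1e-9 relative, asserted in tests), and splitting at branch points
   yields a branch count for free. Isolated nodes produce nothing: a
   single box has no linear extent.

Filtering precedes the spanning tree because support is a property of
individual candidate edges while cycles are a property of the surviving
topology; running the MST first would let an unsupported cross-vessel
link displace a genuine along-vessel edge.

## Metrics

`total_vessel_length` sums vessel-labeled polylines only and converts to
µm; `length_density` divides by field area in mm². Aggregation follows
assay convention: image → sample (mean over the sample's images, 4 by
convention — a warning flags other counts) → group (mean over samples,
n−1 standard deviation). Accuracy is computed **on group-mean
densities**, not per image: `percent_error = |ref − measured| / ref ×
100`, `percent_accuracy = 100 − percent_error`, and an error above 100
reports accuracy `NA` rather than a negative number; `NA` propagates
through aggregation together with a count of excluded groups. A
per-image error helper exists for diagnostics only and is named
accordingly.

## The pixel-based comparison method

`pixel_based_length` reproduces the classical protocol: equalize,
threshold at an intensity quantile (quantiles rather than absolute
intensities, since equalized images make them modality-portable),
remove connected components smaller than `min_object_px` (isolated
cells) or larger than `max_object_px` (tissue clumps), skeletonize by
Zhang–Suen thinning, and sum the skeleton length. Length is a weighted
pixel count: an orthogonal step counts 1, a diagonal step √2 (raw pixel
counts understate diagonal runs by up to 41%), corner-redundant
diagonals are skipped, and each connected piece contributes its first
pixel, so a straight k-pixel run measures exactly k. Defaults
`threshold_quantile = 0.9`, `min_object_px = 50`, `max_object_px =
50000` are exposed, not hard-coded: the historical protocol's exact
values are not published, and they are data-dependent.

## Cross-validation partitioning

`make_partitions` assigns **samples**, never individual images, to
train/validation/holdout — all images of a biological replicate share a
partition, which is what prevents leakage between near-identical fields
of one construct. The default scheme draws one global holdout
(`holdout_fraction`, default 0.2) that is identical in every fold —
the strict reading of a holdout "entirely segregated" from training —
with per-fold validation draws from the remainder; a `rotating` scheme
cycles holdout blocks fold-by-fold for users who want conventional
k-fold coverage. Plans are deterministic in the seed;
`check_partition_plan` asserts disjointness, coverage and holdout
fixedness, and `partition_error` averages per-sample percent errors
within one fold/partition. At least `fold_count` samples are required,
and each partition must be non-empty.

## The synthetic scene generator

`grow_network` grows each vessel as a branching correlated random walk:
per step of `step_px` (4 px) the heading is perturbed by
`Normal(0, tortuosity_sd)` (0.15 rad), a branch spawns with
`branch_prob` (0.02) at a 30–60° divergence angle, and growth clips at
the field border. `render_scene` draws vessels as ridges of Gaussian
cross-section (sd = `vessel_width_px`/2, default width 3 px), scales
each vessel's brightness by a lognormal with CV `intensity_cv` (0.3,
emulating uneven lectin labeling), adds debris as compact bright blobs
(3–10 px), blurs out-of-plane objects with a 4 px Gaussian, and adds
read noise (sd 0.02); phase mode renders dark ridges on mid-gray with a
faint halo at lower contrast. The default field is 384×384 px at
1.3 µm/px (a 0.5 mm field, typical of a 10× objective) with 6 seeded
fragments — a medium-density scene; `generate_benchmark` crosses a
low/medium/high density grid (3/6/10 seeds) for group-structured
experiments. Every scene derives its RNG stream from (master seed,
scene index), so collections are reproducible and order-independent.

The generator is measurement scaffolding, not a biophysical model: it
produces the features that matter to the measurement chain — variable
density, tortuosity, branching, brightness variation, vessel-like
debris, out-of-plane haze — and nothing else. Real images additionally
have uneven illumination, touching vessels of varying width, and
annotation ambiguity; passing tests on synthetic scenes demonstrates
the correctness of the reconstruction and metric chain under known
ground truth, not detector performance on real data.

## Numerical choices and degenerate inputs

* Coordinates are zero-based pixel centers, x along columns, y along
  rows; all geometry stays in pixel units, and unit conversion happens
  once, in the metrics layer.
* Histogram equalization is global (the minimal reading of
  "histogram equalization"), maps through the empirical CDF of the
  image's own values — so 16-bit exports with low occupancy are
  equalized over their observed range — and never reorders
  intensities. A constant image is returned unchanged with a warning.
* Edge support sampling uses nearest-pixel lookup at 1 px arc steps,
  endpoints included; samples outside the image count as background.
* MST ties break on (weight, node id, node id); graph edges store
  `i < j`, so results are independent of box order.
* Degenerate inputs are contracts, not crashes: empty detection sets
  reconstruct to empty polyline lists, a blank image yields pixel-based
  length 0 and removes all graph edges, a single box yields no length,
  and cyclic input to the decomposition step is rejected with advice to
  run cycle removal first.

## Problem sizes

The test suite and the acceptance script run entirely on generated
data: 20-scene recovery experiments at the default 384×384 px field,
100-seed jitter sweeps on a single 300 px vessel, 200-seed partition
sweeps over 20 samples, and exhaustive spanning-tree enumeration on
graphs of at most 8 nodes. These sizes exercise every code path with
comfortable statistical margins while keeping a full run in the
minutes range on one CPU.

## Known limitations

* **Overlapping vessels are under-counted.** When distinct vessels run
  within the connection radius of each other, their boxes merge into
  one component and the spanning tree counts the shared corridor once,
  while an annotator counts both vessels. On dense synthetic scenes
  this biases total length low (up to ≈ −20% at the highest default
  density); per-vessel, reconstruction recovers length to well under
  1%. This mirrors the known behavior of the method on dense,
  highly-overlapping projections; magnification or 3D analysis, not
  post-processing, is the real remedy.
* Center jitter produces zigzag "kinks" that slightly lengthen each
  link while chord sampling of tortuous vessels slightly shortens
  paths; the two effects largely offset (tested: median recovery
  within 10% at 2 px jitter, within one stride noise-free).
* The image-support filter assumes bright-on-dark (or equalized
  phase) foreground statistics; masks from other segmentation sources
  can be substituted through the quantile parameter but no learned
  contour model is provided.
* No 3D reconstruction: z-collapsed crossings that are separate in
  depth are merged by design.
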