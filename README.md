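# vesseltrace

Vessel length density is the primary readout of in vitro angiogenesis
assays: the total centerline length of microvessels in a field, divided by
the field area (µm/mm²). Measuring it by hand — tracing every vessel in
every image — is accurate but slow, and classical pixel-based pipelines
(threshold → size filter → skeletonize) cannot tell vessels apart from
debris and elongated cells, so they overestimate density on real images.

`vesseltrace` implements the measurement pipeline of a detection-based
alternative: an object detector proposes many small overlapping boxes
along vessels, and the package reconstructs vessel centerlines from those
boxes and measures their length. It is aimed at scientists quantifying
angiogenesis in fluorescent (lectin-stained confocal projections) or
phase-contrast images, and at developers of detection backends who need a
reference implementation of the box-to-length chain.

## The method

Given a set of detection boxes with centers $c_i$ and diagonals $d_i$:

1. **Neighbor graph.** Vessel-class boxes above a confidence floor become
   nodes; nodes $i, j$ are linked when
   $\lVert c_i - c_j \rVert \le \rho \cdot (d_i + d_j)/2$
   (default $\rho = 1.25$), with edge weight the center distance.
2. **False-connection removal.** Each edge's straight segment is sampled
   at 1 px steps against a foreground mask (pixels above an intensity
   quantile of the histogram-equalized image); edges with support below a
   minimum fraction — links that proximity suggests but the image does not
   — are deleted.
3. **Cycle removal.** Per connected component, the minimum-weight spanning
   tree is kept (Kruskal, deterministic tie-break), since cycles produced
   by box proximity do not represent vessel topology.
4. **Polylines and density.** Each tree is split into maximal paths at
   branch points (degree ≥ 3); total polyline length $L$ (px) is converted
   with the pixel scale $s$ (µm/px) and the field area $A$ (mm²) to the
   density $L \cdot s / A$.

Accuracy against a reference (manual annotation) is reported per
experimental group as

$$\text{percent error} = \frac{|L_\text{ref} - L_\text{measured}|}{L_\text{ref}} \times 100,
\qquad \text{percent accuracy} = 100 - \text{percent error},$$

with accuracy `NA` whenever the percent error exceeds 100. Group values
are means over samples; sample values are means over (conventionally 4)
images.

The package ships the full surrounding toolchain: maximum z-projection
and global histogram equalization; the polyline annotation model and its
overlapping-rectangle training regions; a ground-truth-driven *oracle
detector* with controllable jitter / missed boxes / false positives and a
classical intensity-based detector, so the pipeline runs without trained
weights; the pixel-based skeleton-length protocol for comparison; grouped
k-fold cross-validation partitioning with leakage checks; and a synthetic
generator of branching vessel scenes with debris, out-of-plane blur and
noise.

## Worked example

Generate a synthetic scene, detect with the noisy oracle backend,
reconstruct, and compare densities:

```r
library(vesseltrace)

p  <- scene_params(seed = 7)               # 384x384 px field, 1.3 um/px
sc <- generate_scene(p, "demo")            # image + ground-truth polylines

truth_um <- total_vessel_length(sc$truth$polylines, p$scale_um_per_px)
dets  <- oracle_detect(sc$truth, box_size = 32, stride = 16,
                       jitter_sd = 2, miss_rate = 0.1, seed = 1)
polys <- reconstruct(dets, sc$image)
meas_um <- total_vessel_length(polys, p$scale_um_per_px)

ref <- length_density(truth_um, sc$image, "annotated")
mea <- length_density(meas_um,  sc$image, "reconstructed")
accuracy_report("demo", ref$density_um_per_mm2, mea$density_um_per_mm2)
```

This prints (106 boxes in, 27 reconstructed polylines):

```
truth:     2064.4 um   ->  density 8284.1 um/mm2   (annotated)
measured:  2076.4 um   ->  density 8332.4 um/mm2   (reconstructed)
percent_error     0.58
percent_accuracy  99.42
```

so on this scene the reconstruction recovers the annotated density to
within 0.6% despite 2 px center jitter and 10% missed boxes. The same
workflow is scriptable from a shell via `inst/cli/vesseltrace`
(`simulate`, `preprocess`, `measure`, `compare`, `crossval` subcommands).

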