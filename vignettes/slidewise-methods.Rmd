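---
title: "Methods: chunked whole-slide analysis in slidewise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chunked whole-slide analysis in slidewise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidewise)
```

## The problem

Whole-slide spatial proteomics produces multi-channel rasters -- one channel
per protein marker -- that routinely reach the gigapixel scale. Instance
segmentation, per-cell feature extraction and pixel/cell clustering on such
rasters cannot assume the image fits in memory, so every stage in slidewise
is formulated over rectangular *chunks*: core tiles that partition the image
exactly, each surrounded by a halo of overlap pixels that gives the chunk
enough context around its core. The scientific difficulty is not the tiling
itself but proving that the tiled computation equals the whole-image one:
naive stitching of per-chunk segmentation masks either fragments cells at
tile borders or glues distinct touching cells together, and both artifacts
occur silently in dense tissue.

## Chunk geometry

`plan_chunks()` lays out `ceiling(extent / chunk_size)` cores per axis,
row-major, full-size cores first and the remainder on the last core of each
axis; a 512 x 512 image at chunk size 212 gives the 3 x 3 grid with core
lengths 212, 212, 88 used throughout the documentation. Intervals are
0-based and half-open, the convention of chunked array stores (OME-NGFF),
so geometry arithmetic has no off-by-one ambiguity. Halos that extend past
the image boundary are filled by mirror reflection *excluding* the boundary
pixel (index -1 copies index 1). One convention had to be fixed; this one
keeps the padded image free of doubled boundary pixels and is pinned by a
property test against an independent pad-then-crop oracle.

Chunked segmentation is only exact when no cell outgrows the halo.
`check_overlap_sufficiency()` condenses a dataset's largest cell area `A`
into the equivalent circle radius `round(sqrt(A / pi))` and requires the
overlap to exceed it strictly (a 3044 px² cell gives radius 31 px, so the
default 50 px overlap is sufficient). The check warns rather than errors:
an insufficient overlap degrades accuracy but does not invalidate the run.

## Border merging

Each chunk is segmented independently and its labels are renumbered to
globally unique ids. Stitching then assembles every output pixel from the
chunk whose core contains it, and decides what to do with objects crossing
core boundaries (`merge_config()`):

* `iou_merge` (the method): for each pair of adjacent chunks, candidate
  object pairs are those whose masks both intersect a band of
  `edge_band = 2` pixels on either side of the shared core boundary.
  For each candidate pair the IoU is computed over the objects' full
  footprints within the shared overlap region -- the band only *selects*
  candidates, keeping the IoU well defined for cells much larger than the
  band. Pairs at or above `iou_threshold = 0.7` are united transitively by
  union-find; the surviving object is the pixel union of its fragments
  restricted to cores, and the surviving id is the smallest in the
  component, which makes the result independent of chunk processing order.
  Pairs below the threshold keep their core-cropped fragments: conservative,
  never deleting a cell silently.
* `no_merge`: cores are cropped and nothing is united. Border-crossing
  cells fragment; kept as the diagnostic baseline for that artifact.
* `touch_merge`: any two cross-border masks that overlap or touch anywhere
  in the shared overlap region are united. This reproduces the over-merge
  artifact of connectivity-based stitching: distinct touching cells near a
  border collapse into one.

On scenes whose cells all fit the overlap, the suite verifies
`AJI(chunked, whole-image) = 1.0` exactly over 20 seeds, and on dense
touching scenes the ordering `count(touch_merge) < count(iou_merge) <=
count(no_merge)` with `iou_merge` scoring the best Aggregated Jaccard Index
against ground truth.

A subtlety the equivalence tests surfaced: a *size-filtered* segmenter
interacts with reflection padding at the global image boundary. A noise
blob touching the boundary is doubled by its mirror image in an edge
chunk's halo and can pass a `min_size` filter that the unpadded whole-image
run rejects. The comparisons therefore give the whole-image reference run
the same boundary convention (a single-chunk plan with the same overlap,
hence the same reflection), which is also how a practitioner should compare
chunked against unchunked output.

## The reference segmenter

Stitching must be testable without deep-learning weights, so the package
ships a deterministic, translation-invariant segmenter
(`reference_segmentation()`): sum the declared channels, binarize at a
threshold, label 8-connected components, optionally split components that
contain two or more nuclear seeds, and drop components below `min_size`
pixels. The split assigns each pixel of a multi-seed component to the
nearest seed centroid (ties to the lexicographically smaller centroid).
A gradient watershed would be the conventional choice, but its tie-breaking
follows pixel scan order and therefore changes with the chunk's local
coordinate frame; the nearest-seed partition depends only on global
geometry, which is what makes the chunked-equals-whole guarantee testable
at equality rather than approximately. Any real segmenter (Cellpose,
InstanSeg, ...) plugs in through the same `segmenter()` contract: raster in,
label matrix out, declared channels, declared determinism.

## Feature extraction as associative aggregation

Per-cell features are computed from *partial statistics*: per label, the
pixel count, per-channel intensity sums and global coordinate sums,
accumulated over chunk cores only (halos are never aggregated, so no pixel
is counted twice) and combined by keyed addition. Because sums over a
partition are exact, the chunked cell table is bit-identical to a
whole-image pass for integer intensities and agrees to summation-reorder
precision (tested at 1e-9 relative) for floats. The feature set is the
associative one: mean intensity per marker (staining-based), area in px²
(mask-based), and the unweighted centroid of pixel-center coordinates
(spatial context). Quantiles and medians are deliberately excluded from the
chunked path -- they are not associative -- and should be computed from the
label image directly when needed.

## Batched SOM and metaclustering

Cell and pixel phenotyping uses a self-organizing map followed by
metaclustering of its codebook, in two training modes:

* **Online**: classical sequential SOM; per presented sample the best
  matching unit is found and all nodes move toward the sample with weight
  `lr(t) * exp(-d_grid^2 / (2 sigma(t)^2))`.
* **Batch**: per epoch the codebook is frozen; every batch independently
  accumulates `num_k = sum_i h(bmu(x_i), k) x_i` and
  `den_k = sum_i h(bmu(x_i), k)`; accumulators are summed across batches
  and each node becomes `num_k / den_k`, nodes with zero mass keeping their
  previous vector. Accumulation is additive, so the trained codebook is
  invariant to the batch partition (tested to 1e-9 across random
  partitions) -- the property that makes the algorithm parallel- and
  out-of-core-safe. With `sigma = 0` the neighbourhood collapses to an
  indicator and one epoch is exactly one k-means Lloyd step, which the
  suite checks against an independent Lloyd-step oracle.

Defaults follow common practice for cytometry-style phenotyping: a 10 x 10
grid, batch size 2048, sigma decaying linearly from `max(grid)/2` to 0.5
over epochs, learning rate (online mode) from 0.05 to 0.01. The codebook is
initialized from data rows sampled under the run seed, making both modes
bit-reproducible. Metaclustering is plain agglomerative average-linkage
clustering of the codebook cut at `n_meta`; a consensus-resampling variant
was considered and rejected for the default because determinism is worth
more here than the modest stability gain.

Pixel clustering normalizes each channel by clipping at its 99.9th
percentile and scaling to [0, 1] -- robust to the hot pixels typical of
multiplexed imaging -- and stores the clip values on the model so training
and prediction share one transform. Pixels with zero total raw intensity
carry no marker signal and receive the reserved label 0. Per-cell
composition features (`cell_composition_features()`) report the fraction of
each cell's pixels per metacluster, with an explicit `unassigned` column so
rows always sum to 1.

Clustering quality is scored with the V-measure, the harmonic mean of
entropy-based homogeneity and completeness, with the conventions
`h = 1` when `H(C) = 0`, `c = 1` when `H(K) = 0`, `v = 0` when `h + c = 0`.
On a 4-component Gaussian mixture with component separation six times the
within-component standard deviation (n = 10 000), the batched SOM plus
4-way metaclustering recovers the components at V >= 0.9.

## Quality control

QC is organized by analysis level. Image level: per-channel
signal-to-noise, defined as `mean(signal) / mean(noise)` after an Otsu
split on the min-max-normalized channel, which makes the metric exactly
invariant to positive intensity rescaling; a constant channel has no
defined SNR and is flagged rather than scored, and a zero noise mean falls
back to a documented `noise_floor` surrogate. Marker-name consistency
across samples is reported as a membership matrix with shared / partial /
unique partitions. Segmentation level: per-cell area distributions, whose
maximum feeds the overlap-sufficiency rule end to end. `qc_report()`
assembles everything into one JSON-serializable report with explicit flags.

## The synthetic generator

`generate_scene()` produces the study conditions all guarantees are tested
under: disk-shaped cells with a bright nuclear core (profile intensity on
an inner disk, dim base over the body) and a membrane rim, type-specific
phenotype markers, Gaussian noise at 5% of the mean profile intensity
(Poisson optional), placed by seeded rejection sampling. With
`allow_touching`, roughly half the cells are packed tangent to a neighbour
with one pixel of claimed overlap -- resolved to the nearer center -- which
guarantees 4-adjacent distinct labels, the precise configuration that
provokes the over-merge artifact. The defaults (256 x 256 canvas, 40
cells, radii 6-12 px, four channels, three cell types) were chosen once as
a realistic miniature of a dense tissue field; `make_fig3_fixture()` scales
the same construction to a 512 x 512, two-channel demonstration scene with
a 212/50 plan of 9 chunks.

What the phantoms do *not* model -- learned cell shapes, optics and
point-spread, cycle-dependent signal decay, segmentation-model errors --
bounds what passing tests show: they validate the *chunking, stitching,
aggregation and clustering machinery* exactly, not the biological accuracy
of any particular segmentation model on real tissue.

## Numerical choices and degenerate inputs

* IoU of two empty masks is an error, not 0; AJI requires a non-empty
  reference; V-measure requires equal-length labelings.
* AJI matching visits reference objects in ascending id and breaks IoU
  ties toward the smaller predicted id -- the definition leaves order
  unspecified, a fixed order makes scores reproducible.
* Union-find roots are the smallest id of each component; relabeled output
  ids are consecutive from 1 in ascending root order.
* SOM BMU ties go to the smallest node index; neighbourhood radii below
  1e-12 are treated as hard assignment; empty SOM nodes keep their vector.
* Label ids are 32-bit; the global relabeler fails loudly, naming the
  required width, before overflow.
* The tests run on deliberately small problem sizes -- 256 x 256 scenes
  with 40-60 cells, 10 000-point mixtures, 20 seeds for the equivalence
  property -- chosen so the full suite documents the guarantees in well
  under a minute while still exercising every border case (multi-chunk
  grids, touching cells, remainder chunks).

## Known limitations

* I/O is scoped to multi-page float TIFF plus a JSON metadata sidecar and
  16-bit TIFF label masks; chunked Zarr stores and HDF5-based AnnData
  export are not available from this R stack, so the cell table ships as
  CSV with a documented schema.
* Chunking is 2-D only: no z-stacks, time series or pyramid levels.
* The reference segmenter is a validation instrument, not a competitive
  cell segmenter; plug real models in through the `segmenter()` contract.
* Merging operates on label rasters, not polygons; sub-pixel boundary
  reconciliation is out of scope.
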