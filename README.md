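# slidewise

Chunk-parallel analysis of whole-slide multiplexed images for R.

Spatial proteomics platforms (IMC, MIBI-TOF, MACSima, CODEX, ...) produce
multi-channel rasters — one channel per protein marker — that reach the
gigapixel scale, far beyond what whole-image processing assumes. slidewise
implements the computational core of a scalable workflow for such data:

* **Chunk geometry** — tile the spatial domain into core regions that
  partition the image exactly, each with a halo of overlap pixels;
  out-of-bounds halos are filled by mirror reflection
  (`plan_chunks()`, `extract_chunk()`).
* **Artifact-free stitched segmentation** — run any instance segmenter per
  chunk and merge masks at chunk borders by intersection-over-union within
  the shared overlap (candidates selected in a 2 px edge band, united at
  IoU ≥ 0.7, transitively via union–find). The naive strategies
  (`no_merge`, `touch_merge`) are kept as diagnostic baselines because they
  reproduce the classical fragmentation and over-merge artifacts
  (`segment_chunked()`, `merge_across_borders()`).
* **Exact chunked feature extraction** — per-cell mean marker intensity,
  area and centroid computed by associative partial aggregation over chunk
  cores, bit-identical to a whole-image pass for integer data
  (`extract_features()`).
* **Batched FlowSOM-style clustering** — online and batch self-organizing
  map training (batch training is invariant to how the data is split into
  batches, the property that makes it parallel-safe), metaclustering of the
  codebook, pixel-level cluster rasters and per-cell composition features
  (`train_som_batch()`, `metacluster()`, `cluster_pixels()`,
  `cluster_cells()`).
* **Evaluation and QC** — Aggregated Jaccard Index, V-measure
  (homogeneity/completeness), per-channel signal-to-noise after Otsu
  thresholding, marker-name consistency across samples, mask-area
  statistics and the overlap-sufficiency rule
  (`aggregated_jaccard_index()`, `v_measure()`, `qc_report()`,
  `check_overlap_sufficiency()`).
* **Synthetic scenes** — a deterministic generator of dense cell fields
  with ground-truth masks and cell-type-specific marker profiles, so every
  guarantee above is testable without external data (`generate_scene()`).

The key quantitative rule of thumb: chunked segmentation is exact when the
overlap exceeds the equivalent circle radius `round(sqrt(area / π))` of the
largest cell — e.g. a 3044 px² cell gives radius 31 px, comfortably inside
the default 50 px overlap.

## Worked example

```r
library(slidewise)

# dense synthetic scene: 60 touching cells, 4 markers, ground truth known
scene <- generate_scene(scene_spec(n_cells = 60, allow_touching = TRUE, seed = 7))
plan  <- plan_chunks(image_shape(scene$image), chunk_size = 96, overlap = 40)
plan
#> <chunk_plan> 256 x 256 image, chunk_size 96, overlap 40: 9 chunks (3 x 3 grid)

seg <- reference_segmenter(threshold = 1.0, min_size = 10,
                           nuclear_channel = 1, nuclear_threshold = 4)
labels <- segment_chunked(scene$image, seg, plan, merge_config())
max(labels)                                    # 61 cells (ground truth: 60)
aggregated_jaccard_index(labels, scene$labels) # 0.9377

tab <- extract_features(scene$image, labels, plan)
head(tab[, c("cell_id", "nuclear", "marker_3", "area_px2",
             "centroid_y", "centroid_x")], 3)
#>   cell_id nuclear marker_3 area_px2 centroid_y centroid_x
#> 1       1   2.508    6.551      136      102.8      16.54
#> 2       2   2.482    6.679      252       85.5      30.23
#> 3       3   2.728    6.911      407      103.7      40.91

# overlap sufficiency from the observed mask areas
st <- mask_area_stats(labels)
check_overlap_sufficiency(st$max, plan$overlap)
#> $equivalent_radius_px [1] 12   $sufficient [1] TRUE

# FlowSOM-style cell phenotyping on the ground-truth masks
truth_tab <- extract_features(scene$image, scene$labels, plan)
res <- cluster_cells(truth_tab, channels = c("marker_3", "marker_4"),
                     n_meta = 3, grid = c(4, 4), seed = 1)
v_measure(scene$cell_types[truth_tab$cell_id], res$meta)$v_measure
#> [1] 1
```

The numbers read as follows: the stitched segmentation recovers the 60
ground-truth cells (plus one noise blob) with an Aggregated Jaccard Index
of 0.94; per-cell mean intensities, areas and centroids come from the
chunked aggregation; the largest mask (429 px², radius 12 px) confirms the
40 px overlap was sufficient; and 3-way metaclustering of a 4×4 SOM on the
two phenotype markers recovers the generator's three cell types perfectly
(V-measure 1.0).

A command-line interface wrapping the same functions is installed as
`exec/slidewise` (subcommands `simulate`, `segment`, `features`,
`cluster-pixels`, `cluster-cells`, `qc`, `run`).

## Documentation

The methods vignette (`vignettes/slidewise-methods.Rmd`) describes the
model and its assumptions, all tunable parameters with defaults and units,
the merge algorithm, the numerical conventions, what the synthetic
generator does and does not emulate, and known limitations.
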