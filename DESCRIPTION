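Package: slidewise
Title: Chunked Analysis of Whole-Slide Multiplexed Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scalable, chunk-parallel analysis of whole-slide spatial
    proteomics images. Tiles gigapixel multi-channel rasters into
    overlapping chunks with reflection padding, runs any instance
    segmenter per chunk and stitches the per-chunk masks into one
    artifact-free label image by intersection-over-union merging at the
    chunk borders. Per-cell staining, mask and spatial-context features
    are computed by associative partial aggregation so the chunked result
    matches a whole-image computation exactly. Includes online and batch
    self-organizing-map training with FlowSOM-style metaclustering for
    pixel and cell phenotyping, V-measure and Aggregated Jaccard Index
    evaluation, multi-level quality-control metrics, and a deterministic
    synthetic-scene generator so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    optparse,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
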