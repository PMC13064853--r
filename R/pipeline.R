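#' Run the full chunked analysis pipeline
#'
#' Executes segment -> features -> pixel clustering -> QC on one image and
#' writes every artifact plus a provenance record to the output directory:
#'
#' * `labels.tif` -- stitched instance mask ([segment_chunked()])
#' * `cells.csv` -- cell-by-feature table ([extract_features()])
#' * `pixel_clusters.tif` + `som_model.json` -- pixel metacluster raster
#'   and its trained model ([cluster_pixels()])
#' * `qc.json` -- multi-level QC report ([qc_report()])
#' * `provenance.json` -- the full configuration, seed and package version
#'
#' Outputs are a pure function of the configuration: re-running with an
#' identical config reproduces identical artifacts. Any stage failure
#' aborts with the stage name in the error.
#'
#' @param config a [pipeline_config()] (validated; invalid configs are
#'   rejected before any stage runs).
#' @param image optionally, an in-memory [multiplex_image()] to process
#'   instead of reading `config$input`.
#' @param verbose emit per-stage progress messages.
#' @return Invisibly, a list with the output paths and the in-memory
#'   results (`labels`, `cell_table`, `pixel_clusters`, `qc`).
#' @export
run_pipeline <- function(config, image = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  if (is.null(image)) {
    if (is.null(config$input)) stop("config$input is required when no image is given")
    image <- read_image(config$input)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    if (verbose) message("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  plan <- plan_chunks(image_shape(image), config$chunk_size, config$overlap)
  nuclear_idx <- if (is.null(config$nuclear_channel)) NULL else {
    ch <- if (is.null(config$channels)) image$channel_names else config$channels
    match(config$nuclear_channel, ch)
  }
  seg <- reference_segmenter(threshold = config$seg_threshold,
                             min_size = config$min_size,
                             channels = config$channels,
                             nuclear_channel = nuclear_idx,
                             nuclear_threshold =
                               if (is.null(config$nuclear_threshold))
                                 config$seg_threshold else config$nuclear_threshold)
  cfg_merge <- merge_config(config$edge_band, config$iou_threshold,
                            config$strategy)

  labels <- stage("segment",
                  segment_chunked(image, seg, plan, cfg_merge, verbose = verbose))
  write_labels(labels, file.path(config$out_dir, "labels.tif"))

  cell_table <- stage("features", extract_features(image, labels, plan))
  write_cell_table(cell_table, file.path(config$out_dir, "cells.csv"))

  clu <- stage("cluster-pixels",
               cluster_pixels(image, channels = config$channels,
                              grid = config$grid, n_meta = config$n_meta,
                              n_epochs = config$n_epochs,
                              batch_size = config$batch_size,
                              seed = config$seed))
  write_labels(clu$clusters, file.path(config$out_dir, "pixel_clusters.tif"))
  write_som_model(clu$model, file.path(config$out_dir, "som_model.json"))

  qc <- stage("qc", qc_report(list(image), labels = list(labels),
                              overlap = config$overlap))
  write_qc_report(qc, file.path(config$out_dir, "qc.json"))

  prov <- list(package = "slidewise",
               version = as.character(utils::packageVersion("slidewise")),
               config = unclass(config))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  invisible(list(out_dir = config$out_dir, labels = labels,
                 cell_table = cell_table, pixel_clusters = clu$clusters,
                 qc = qc))
}
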