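#' Read and write multiplex images as TIFF with a metadata sidecar
#'
#' Images are stored as multi-page 32-bit float TIFF (one page per channel)
#' next to a JSON sidecar `<path>.json` carrying the channel names, the
#' physical pixel size, the sample id and the intensity scale. TIFF float
#' storage is confined to `[0, 1]`, so intensities are divided by a single
#' per-image scale on write and re-multiplied on read; the round trip
#' preserves data to 32-bit float precision (~1e-7 relative). A TIFF
#' without sidecar is read with channels auto-named `channel_0, ...` and a
#' warning.
#'
#' @param image a [multiplex_image()].
#' @param path TIFF file path.
#' @return `write_image()` returns `path` invisibly; `read_image()` returns
#'   a [multiplex_image()].
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "multiplex_image"))
  scale <- max(image$data, 1)
  pages <- lapply(seq_along(image$channel_names), function(k) {
    matrix(image$data[k, , ] / scale, dim(image$data)[2L], dim(image$data)[3L])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "deflate")
  meta <- list(format_version = 1L, channel_names = image$channel_names,
               pixel_size_um = image$pixel_size_um,
               sample_id = image$sample_id, scale = scale)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("no such image file: '%s' (expected a TIFF written by write_image())",
                 path))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    scale <- meta$scale
    ch <- meta$channel_names
    px <- meta$pixel_size_um
    sid <- meta$sample_id
  } else {
    warning(sprintf("no metadata sidecar for '%s'; channels auto-named channel_0...",
                    path))
    scale <- 1
    ch <- paste0("channel_", seq_along(pages) - 1L)
    px <- NULL
    sid <- sub("\\.tiff?$", "", basename(path))
  }
  data <- array(0, c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (k in seq_along(pages)) data[k, , ] <- pages[[k]] * scale
  multiplex_image(data, channel_names = ch, pixel_size_um = px, sample_id = sid)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read and write label images as 16-bit TIFF
#'
#' Instance masks are stored losslessly as single-page 16-bit unsigned
#' TIFF, which bounds label ids at 65535; larger id spaces must be
#' renumbered before writing (stitched outputs are already consecutive).
#'
#' @param labels non-negative integer matrix.
#' @param path TIFF file path.
#' @return `write_labels()` returns `path` invisibly; `read_labels()` the
#'   integer matrix.
#' @export
write_labels <- function(labels, path) {
  validate_labels(labels)
  if (max(labels) > 65535L) {
    stop("label ids exceed 65535, the 16-bit TIFF limit; renumber before writing")
  }
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L, reduce = FALSE,
                  compression = "deflate")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such label file: '%s'", path))
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  storage.mode(m) <- "integer"
  m
}

#' Write / read a cell-by-feature table as CSV
#'
#' Plain-text serialization of the table produced by [extract_features()]:
#' columns `sample_id, cell_id, <channel means...>, area_px2, centroid_y,
#' centroid_x`.
#'
#' @param cell_table data frame.
#' @param path CSV path.
#' @return `write_cell_table()` returns `path` invisibly; `read_cell_table()`
#'   the data frame.
#' @export
write_cell_table <- function(cell_table, path) {
  utils::write.csv(cell_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Serialize a QC report to JSON
#'
#' @param report a [qc_report()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE, pretty = TRUE)
  invisible(path)
}

#' Save / load a SOM model as JSON
#'
#' Versioned plain-text serialization of a trained model: grid, codebook,
#' seed, training mode and (for pixel models) channel set and
#' normalization.
#'
#' @param model a `som_model`.
#' @param path JSON path.
#' @return `write_som_model()` returns `path` invisibly; `read_som_model()`
#'   the `som_model`.
#' @export
write_som_model <- function(model, path) {
  stopifnot(inherits(model, "som_model"))
  payload <- list(format_version = 1L, grid = model$grid,
                  codebook = model$codebook, seed = model$seed,
                  mode = model$mode, channels = model$channels,
                  normalization = if (is.null(model$normalization)) NULL else
                    unclass(model$normalization))
  jsonlite::write_json(payload, path, digits = NA, null = "null",
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_som_model
#' @export
read_som_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format_version) || p$format_version != 1L) {
    stop("unrecognized SOM model schema; expected format_version 1")
  }
  codebook <- matrix(unlist(p$codebook), nrow = prod(p$grid))
  model <- new_som_model(p$grid, codebook, p$seed, p$mode, init_rows = NULL,
                         channels = p$channels)
  if (!is.null(p$normalization)) {
    norm <- p$normalization
    norm$clip <- stats::setNames(unlist(norm$clip), norm$channels)
    model$normalization <- structure(norm, class = "pixel_norm")
  }
  model
}

#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()] and the
#' command line. The processing defaults are the package's standard
#' whole-slide parameters: segmentation chunk size 1000 with overlap 50,
#' IoU merging with a 2-pixel edge band at threshold 0.7, a 10 x 10 SOM
#' grid and SOM batch size 2048.
#'
#' @param input path of the input image (TIFF written by [write_image()]).
#' @param out_dir output directory for all artifacts.
#' @param channels channels used for segmentation/clustering (`NULL` = all).
#' @param chunk_size,overlap chunk geometry (defaults 1000 / 50).
#' @param edge_band,iou_threshold,strategy merge parameters, see
#'   [merge_config()].
#' @param grid,batch_size,n_epochs SOM parameters.
#' @param n_meta number of metaclusters for pixel clustering.
#' @param seg_threshold,min_size,nuclear_channel,nuclear_threshold
#'   reference-segmenter parameters (`nuclear_channel` is a channel *name*;
#'   `nuclear_threshold` defaults to `seg_threshold`).
#' @param seed integer seed for every stochastic step.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, out_dir = "slidewise_out",
                            channels = NULL, chunk_size = 1000L, overlap = 50L,
                            edge_band = 2L, iou_threshold = 0.7,
                            strategy = "iou_merge", grid = c(10L, 10L),
                            batch_size = 2048L, n_epochs = 10L, n_meta = 8L,
                            seg_threshold = 1.5, min_size = 10L,
                            nuclear_channel = NULL, nuclear_threshold = NULL,
                            seed = 1L) {
  cfg <- list(input = input, out_dir = out_dir, channels = channels,
              chunk_size = as.integer(chunk_size), overlap = as.integer(overlap),
              edge_band = as.integer(edge_band),
              iou_threshold = as.numeric(iou_threshold), strategy = strategy,
              grid = as.integer(grid), batch_size = as.integer(batch_size),
              n_epochs = as.integer(n_epochs), n_meta = as.integer(n_meta),
              seg_threshold = as.numeric(seg_threshold),
              min_size = as.integer(min_size),
              nuclear_channel = nuclear_channel,
              nuclear_threshold = if (is.null(nuclear_threshold)) NULL else
                as.numeric(nuclear_threshold),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

# internal: reject invalid configurations before any stage runs
validate_config <- function(cfg) {
  if (cfg$chunk_size < 1L) stop("config: chunk_size must be >= 1")
  if (cfg$overlap < 0L) stop("config: overlap must be >= 0")
  if (cfg$edge_band > cfg$overlap) {
    stop(sprintf("config: edge_band (%d) must not exceed overlap (%d)",
                 cfg$edge_band, cfg$overlap))
  }
  if (cfg$iou_threshold <= 0 || cfg$iou_threshold > 1) {
    stop("config: iou_threshold must lie in (0, 1]")
  }
  if (any(cfg$grid < 1L) || length(cfg$grid) != 2L) {
    stop("config: grid must be two positive integers")
  }
  if (cfg$batch_size < 1L) stop("config: batch_size must be >= 1")
  if (cfg$n_meta < 1L || cfg$n_meta > prod(cfg$grid)) {
    stop("config: n_meta must lie between 1 and the SOM node count")
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; missing keys take the
#' defaults, unknown keys are an error.
#'
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}
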