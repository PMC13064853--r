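#' Per-channel normalization for pixel clustering
#'
#' Fixes the normalization applied before pixel-level clustering: each
#' channel is clipped at its `clip_quantile` quantile (default 99.9th,
#' robust to hot pixels) and scaled to `[0, 1]`. The clip values are
#' estimated once (here) and stored, so training and prediction use the
#' identical transform.
#'
#' @param image a [multiplex_image()].
#' @param channels channel names to normalize (default all).
#' @param clip_quantile upper quantile for clipping, in `(0, 1]`.
#' @return An object of class `pixel_norm`: list of `channels`, `clip`
#'   (named clip values) and `clip_quantile`.
#' @export
pixel_normalization <- function(image, channels = NULL, clip_quantile = 0.999) {
  stopifnot(inherits(image, "multiplex_image"))
  if (is.null(channels)) channels <- image$channel_names
  idx <- match(channels, image$channel_names)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(channels[is.na(idx)], collapse = ", "))
  clip <- vapply(idx, function(i) {
    stats::quantile(image$data[i, , ], clip_quantile, names = FALSE)
  }, numeric(1))
  names(clip) <- channels
  structure(list(channels = channels, clip = clip, clip_quantile = clip_quantile),
            class = "pixel_norm")
}

# internal: pixels x channels matrix of an image, normalized by a pixel_norm
normalized_pixel_matrix <- function(image, norm) {
  idx <- match(norm$channels, image$channel_names)
  shp <- image_shape(image)
  X <- matrix(aperm(image$data[idx, , , drop = FALSE], c(2L, 3L, 1L)),
              ncol = length(idx))
  for (j in seq_along(idx)) {
    cl <- norm$clip[j]
    if (cl > 0) X[, j] <- pmin(X[, j], cl) / cl
  }
  colnames(X) <- norm$channels
  X
}

#' Train a pixel-level SOM on an image
#'
#' Builds the normalized pixel matrix of the selected channels (pixels with
#' zero total raw intensity are excluded: they carry no marker signal) and
#' trains a batched SOM on it. The normalization and channel set are stored
#' on the model so [pixel_cluster_image()] can apply the identical
#' transform.
#'
#' @inheritParams train_som_batch
#' @param image a [multiplex_image()].
#' @param channels channel names to cluster on (default all).
#' @param norm a [pixel_normalization()], or `NULL` to estimate one here.
#' @return A `som_model` with `channels` and `normalization` set.
#' @export
train_pixel_som <- function(image, channels = NULL, grid = c(10L, 10L),
                            n_epochs = 10L, batch_size = 2048L, sigma = NULL,
                            seed = 1L, norm = NULL) {
  stopifnot(inherits(image, "multiplex_image"))
  if (is.null(channels)) channels <- image$channel_names
  if (is.null(norm)) norm <- pixel_normalization(image, channels)
  X <- normalized_pixel_matrix(image, norm)
  idx <- match(channels, image$channel_names)
  raw_tot <- colSums(image$data[idx, , , drop = FALSE], dims = 1L)
  keep <- as.vector(raw_tot) > 0
  if (!any(keep)) stop("image has no pixels with positive total intensity")
  model <- train_som_batch(X[keep, , drop = FALSE], grid = grid,
                           n_epochs = n_epochs, batch_size = batch_size,
                           sigma = sigma, seed = seed)
  model$channels <- channels
  model$normalization <- norm
  model
}

#' Metacluster raster of every pixel of an image
#'
#' Assigns each pixel's normalized channel vector to its best-matching SOM
#' node and maps nodes to metaclusters, summarizing all chosen markers into
#' one overview raster. Pixels whose raw channel total is zero receive the
#' reserved label 0. Assignment is purely per-pixel, so chunked and
#' whole-image execution give identical rasters.
#'
#' @param image a [multiplex_image()].
#' @param model a `som_model` trained with [train_pixel_som()] (carries the
#'   channel set and normalization).
#' @param meta_map node-to-metacluster map from [metacluster()]; `NULL`
#'   labels pixels by SOM node instead.
#' @return Integer matrix `(y, x)` of metacluster labels (0 = background).
#' @export
pixel_cluster_image <- function(image, model, meta_map = NULL) {
  stopifnot(inherits(image, "multiplex_image"), inherits(model, "som_model"))
  if (is.null(model$channels) || is.null(model$normalization)) {
    stop("`model` lacks channel/normalization metadata; train it with train_pixel_som()")
  }
  if (!all(model$channels %in% image$channel_names)) {
    stop("image lacks channel(s) the model was trained on: ",
         paste(setdiff(model$channels, image$channel_names), collapse = ", "))
  }
  shp <- image_shape(image)
  X <- normalized_pixel_matrix(image, model$normalization)
  nodes <- som_assign(X, model)
  lab <- if (is.null(meta_map)) nodes else {
    if (length(meta_map) != nrow(model$codebook)) {
      stop("`meta_map` must map every SOM node")
    }
    meta_map[nodes]
  }
  idx <- match(model$channels, image$channel_names)
  raw_tot <- as.vector(colSums(image$data[idx, , , drop = FALSE], dims = 1L))
  lab[raw_tot == 0] <- 0L
  matrix(as.integer(lab), shp[1L], shp[2L])
}

#' Pixel clustering in one call
#'
#' Convenience wrapper: estimate normalization, train the batched pixel
#' SOM, metacluster the codebook and label every pixel.
#'
#' @inheritParams train_pixel_som
#' @param n_meta number of metaclusters.
#' @return List of class `flowsom_result` with `model`, `meta_map` and
#'   `clusters` (the labeled raster).
#' @export
cluster_pixels <- function(image, channels = NULL, grid = c(10L, 10L),
                           n_meta, n_epochs = 10L, batch_size = 2048L,
                           seed = 1L) {
  model <- train_pixel_som(image, channels = channels, grid = grid,
                           n_epochs = n_epochs, batch_size = batch_size,
                           seed = seed)
  meta_map <- metacluster(model, n_meta)
  clusters <- pixel_cluster_image(image, model, meta_map)
  structure(list(model = model, meta_map = meta_map, clusters = clusters),
            class = "flowsom_result")
}

#' Cluster cells from a feature table
#'
#' FlowSOM-style cell clustering: batched SOM on selected feature columns
#' of a cell table, followed by metaclustering. Columns are scaled to
#' `[0, 1]` by their maximum (consistent with the pixel-path
#' normalization).
#'
#' @param cell_table data frame from [extract_features()].
#' @param channels feature column names to cluster on.
#' @param n_meta number of metaclusters.
#' @inheritParams train_som_batch
#' @return `flowsom_result` list with `model`, `meta_map`, `nodes` (per-cell
#'   BMU) and `meta` (per-cell metacluster label).
#' @export
cluster_cells <- function(cell_table, channels, n_meta, grid = c(10L, 10L),
                          n_epochs = 10L, batch_size = 2048L, seed = 1L) {
  if (!all(channels %in% names(cell_table))) {
    stop("cell table lacks column(s): ",
         paste(setdiff(channels, names(cell_table)), collapse = ", "))
  }
  X <- as.matrix(cell_table[, channels, drop = FALSE])
  for (j in seq_len(ncol(X))) {
    m <- max(X[, j])
    if (m > 0) X[, j] <- X[, j] / m
  }
  model <- train_som_batch(X, grid = grid, n_epochs = n_epochs,
                           batch_size = batch_size, seed = seed)
  model$channels <- channels
  meta_map <- metacluster(model, n_meta)
  nodes <- som_assign(X, model)
  structure(list(model = model, meta_map = meta_map, nodes = nodes,
                 meta = meta_map[nodes]),
            class = "flowsom_result")
}

#' Per-cell metacluster composition
#'
#' For every cell of a label image, the fraction of its pixels falling in
#' each pixel metacluster; a robust, segmentation-aware alternative to raw
#' intensity features for phenotyping. Pixels carrying the reserved
#' background cluster 0 inside a cell are reported in the final
#' `unassigned` column, so rows always sum to 1.
#'
#' @param pixel_clusters integer metacluster raster from
#'   [pixel_cluster_image()].
#' @param labels integer label matrix of the same shape.
#' @param n_meta number of metaclusters (defines the column set).
#' @return Numeric matrix: one row per cell (rownames = cell ids), columns
#'   `meta_1 ... meta_<n_meta>, unassigned`.
#' @export
cell_composition_features <- function(pixel_clusters, labels, n_meta) {
  validate_labels(labels, dim(pixel_clusters))
  idx <- which(labels > 0L)
  if (!length(idx)) stop("label image contains no cells")
  lab <- labels[idx]
  cl <- pixel_clusters[idx]
  if (any(cl > n_meta)) stop("`pixel_clusters` contains labels above `n_meta`")
  ids <- sort(unique(lab))
  counts <- matrix(0, length(ids), n_meta + 1L,
                   dimnames = list(ids, c(paste0("meta_", seq_len(n_meta)),
                                          "unassigned")))
  tab <- table(factor(lab, levels = ids), factor(cl, levels = 0:n_meta))
  counts[, seq_len(n_meta)] <- tab[, -1L, drop = FALSE]
  counts[, n_meta + 1L] <- tab[, 1L]
  counts / rowSums(counts)
}
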