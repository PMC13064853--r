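#' Per-label partial statistics of one chunk core
#'
#' The associative building block of chunked feature extraction: for every
#' positive label in a chunk *core* (halos are never aggregated, so no pixel
#' is counted twice) it accumulates the pixel count, the per-channel
#' intensity sums and the coordinate sums in global pixel coordinates.
#' Accumulators from different chunks combine by keyed addition
#' ([combine_stats()]), so any chunking of the image yields the same totals
#' as a whole-image pass.
#'
#' @param labels_core integer label matrix of the core region.
#' @param image_core numeric `(c, h, w)` array of the same core region.
#' @param origin global 0-based `(y, x)` coordinate of the core's top-left
#'   pixel; coordinates are pixel centers on the integer grid.
#' @param channel_names names for the channel axis.
#' @return An object of class `partial_stats`: list with `ids` (sorted label
#'   ids), `n` (pixel counts), `sums` (labels x channels intensity sums),
#'   `sy`, `sx` (coordinate sums) and `channel_names`.
#' @export
accumulate_chunk <- function(labels_core, image_core, origin = c(0L, 0L),
                             channel_names = NULL) {
  validate_labels(labels_core)
  if (is.matrix(image_core)) {
    image_core <- array(image_core, c(1L, nrow(image_core), ncol(image_core)))
  }
  if (!identical(dim(image_core)[2:3], dim(labels_core))) {
    stop("label and intensity rasters must cover the same core region")
  }
  nc <- dim(image_core)[1L]
  if (is.null(channel_names)) channel_names <- paste0("channel_", seq_len(nc) - 1L)
  idx <- which(labels_core > 0L)
  if (!length(idx)) {
    return(structure(list(ids = integer(0), n = numeric(0),
                          sums = matrix(0, 0L, nc, dimnames = list(NULL, channel_names)),
                          sy = numeric(0), sx = numeric(0),
                          channel_names = channel_names),
                     class = "partial_stats"))
  }
  lab <- labels_core[idx]
  ny <- nrow(labels_core)
  gy <- origin[1L] + (idx - 1L) %% ny
  gx <- origin[2L] + (idx - 1L) %/% ny
  # pixels x channels view of the core intensities at the labeled pixels
  pix <- matrix(aperm(image_core, c(2L, 3L, 1L)), ncol = nc)[idx, , drop = FALSE]
  agg <- rowsum(cbind(1, pix, gy, gx), group = lab) # rows sorted by label id
  ids <- sort(unique(lab))
  structure(list(
    ids = as.integer(ids),
    n = agg[, 1L],
    sums = matrix(agg[, 1L + seq_len(nc), drop = FALSE], ncol = nc,
                  dimnames = list(NULL, channel_names)),
    sy = agg[, nc + 2L],
    sx = agg[, nc + 3L],
    channel_names = channel_names
  ), class = "partial_stats")
}

#' Combine partial statistics by keyed addition
#'
#' Commutative and associative merge of [accumulate_chunk()] accumulators:
#' entries with the same label id are added component-wise, so a cell split
#' across several chunks ends up with exactly its whole-image sums.
#'
#' @param parts list of `partial_stats` objects over a common channel set.
#' @return A single `partial_stats` object.
#' @export
combine_stats <- function(parts) {
  if (inherits(parts, "partial_stats")) parts <- list(parts)
  stopifnot(all(vapply(parts, inherits, logical(1), "partial_stats")))
  parts <- parts[vapply(parts, function(p) length(p$ids) > 0L, logical(1))]
  if (!length(parts)) stop("no labeled pixels in any part")
  cn <- parts[[1L]]$channel_names
  for (p in parts) {
    if (!identical(p$channel_names, cn)) stop("parts disagree on channel names")
  }
  ids <- unlist(lapply(parts, `[[`, "ids"))
  block <- do.call(rbind, lapply(parts, function(p) cbind(p$n, p$sums, p$sy, p$sx)))
  agg <- rowsum(block, group = ids)
  nc <- length(cn)
  structure(list(
    ids = as.integer(sort(unique(ids))),
    n = agg[, 1L],
    sums = matrix(agg[, 1L + seq_len(nc), drop = FALSE], ncol = nc,
                  dimnames = list(NULL, cn)),
    sy = agg[, nc + 2L],
    sx = agg[, nc + 3L],
    channel_names = cn
  ), class = "partial_stats")
}

#' Finalize partial statistics into a cell-by-feature table
#'
#' Turns accumulated sums into the per-cell feature table: staining-based
#' features (mean intensity per channel), the mask-based feature `area_px2`
#' and the spatial-context features `centroid_y` / `centroid_x` (unweighted
#' mean of pixel-center coordinates, global pixel units). Non-associative
#' statistics (quantiles, medians) are deliberately absent from the chunked
#' path; compute them from the label image directly if needed.
#'
#' @param stats a non-empty `partial_stats`.
#' @param sample_id value for the table's `sample_id` column.
#' @return A `data.frame` with one row per cell, columns `sample_id`,
#'   `cell_id`, one mean-intensity column per channel, `area_px2`,
#'   `centroid_y`, `centroid_x`.
#' @export
finalize_features <- function(stats, sample_id = "sample") {
  stopifnot(inherits(stats, "partial_stats"))
  if (!length(stats$ids)) stop("empty accumulator: no cells to finalize")
  if (any(stats$n <= 0)) {
    stop("internal consistency error: zero-count accumulator entry")
  }
  means <- stats$sums / stats$n
  out <- data.frame(sample_id = sample_id, cell_id = stats$ids,
                    stringsAsFactors = FALSE)
  for (j in seq_along(stats$channel_names)) {
    out[[stats$channel_names[j]]] <- means[, j]
  }
  out$area_px2 <- as.numeric(stats$n)
  out$centroid_y <- stats$sy / stats$n
  out$centroid_x <- stats$sx / stats$n
  out
}

#' Per-cell feature extraction over a chunked image
#'
#' Computes the cell-by-feature table of an image/label pair by streaming
#' over the chunk cores of a plan and combining the per-chunk partial sums.
#' For integer intensities the result is bit-identical to a single-chunk
#' computation; for floating-point intensities it agrees to within summation
#' reordering (<= 1e-9 relative).
#'
#' @param image a [multiplex_image()].
#' @param labels integer label matrix aligned with `image`.
#' @param plan a [plan_chunks()] plan, or `NULL` for a single whole-image
#'   chunk. Halos play no role here, so any plan overlap is ignored.
#' @return A `data.frame`, see [finalize_features()]; exactly one row per
#'   positive label, ordered by `cell_id`.
#' @export
extract_features <- function(image, labels, plan = NULL) {
  stopifnot(inherits(image, "multiplex_image"))
  shp <- image_shape(image)
  validate_labels(labels, shp)
  if (is.null(plan)) plan <- plan_chunks(shp, chunk_size = max(shp), overlap = 0L)
  stopifnot(inherits(plan, "chunk_plan"))
  if (!identical(as.integer(plan$image_shape), as.integer(shp))) {
    stop("plan was built for a different image shape")
  }
  parts <- lapply(plan$specs, function(spec) {
    rows <- core_rows(spec)
    cols <- core_cols(spec)
    accumulate_chunk(labels[rows, cols, drop = FALSE],
                     image$data[, rows, cols, drop = FALSE],
                     origin = c(spec$core_y[1L], spec$core_x[1L]),
                     channel_names = image$channel_names)
  })
  finalize_features(combine_stats(parts), sample_id = image$sample_id)
}
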