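#' Multi-channel image container
#'
#' A `multiplex_image` bundles a non-negative intensity raster with axis order
#' `(channel, y, x)`, the ordered channel names, an optional physical pixel
#' size and a sample identifier. It is the container every processing stage
#' consumes: one channel per protein marker, one raster per sample.
#'
#' Instance label masks are *not* wrapped: throughout the package a label
#' image is a plain non-negative integer matrix of shape `(y, x)` with 0 as
#' background, aligned pixel-for-pixel with its companion `multiplex_image`.
#'
#' @param data numeric array with `dim = c(n_channels, y, x)`; all values
#'   must be finite and `>= 0`. A plain `(y, x)` matrix is promoted to a
#'   single-channel array.
#' @param channel_names character vector, one unique name per channel.
#' @param pixel_size_um physical edge length of one pixel in micrometres,
#'   or `NULL` when unknown.
#' @param sample_id identifier of the sample the raster was acquired from.
#'
#' @return An object of class `multiplex_image` with fields `data`,
#'   `channel_names`, `pixel_size_um` and `sample_id`.
#' @examples
#' img <- multiplex_image(array(runif(2 * 8 * 8), c(2, 8, 8)),
#'                        channel_names = c("DNA", "CD45"))
#' dim(img$data)
#' @export
multiplex_image <- function(data, channel_names = NULL, pixel_size_um = NULL,
                            sample_id = "sample") {
  if (is.matrix(data)) {
    data <- array(data, c(1L, nrow(data), ncol(data)))
  }
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a (channel, y, x) array or a (y, x) matrix")
  }
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("intensities must be finite and non-negative")
  }
  if (dim(data)[2L] < 1L || dim(data)[3L] < 1L) {
    stop("spatial dimensions must be >= 1")
  }
  nc <- dim(data)[1L]
  if (is.null(channel_names)) {
    channel_names <- paste0("channel_", seq_len(nc) - 1L)
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nc) {
    stop(sprintf("got %d channel names for %d channels", length(channel_names), nc))
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique within one image")
  }
  if (!is.null(pixel_size_um)) {
    pixel_size_um <- as.numeric(pixel_size_um)
    if (length(pixel_size_um) != 1L || !is.finite(pixel_size_um) || pixel_size_um <= 0) {
      stop("`pixel_size_um` must be a single positive number")
    }
  }
  structure(
    list(data = data, channel_names = channel_names,
         pixel_size_um = pixel_size_um, sample_id = as.character(sample_id)),
    class = "multiplex_image"
  )
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multiplex_image> sample '%s': %d channel(s), %d x %d pixels\n",
              x$sample_id, d[1L], d[2L], d[3L]))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  if (!is.null(x$pixel_size_um)) {
    cat(sprintf("  pixel size: %g um\n", x$pixel_size_um))
  }
  invisible(x)
}

#' Spatial shape of a multiplex image
#'
#' @param image a [multiplex_image()].
#' @return Integer vector `c(y, x)`.
#' @export
image_shape <- function(image) {
  stopifnot(inherits(image, "multiplex_image"))
  dim(image$data)[2:3]
}

#' Total pixel count of a dataset
#'
#' Dataset-size arithmetic used in QC reports to situate a sample on the
#' megapixel-to-gigapixel scale: the product `n_channels * y * x`. A medium
#' 5000 x 5000 region of interest with 4 markers holds 1e8 pixels; a
#' 10-marker 10000 x 10000 sample holds one gigapixel (1e9).
#'
#' @param n_channels,y,x positive integers.
#' @return The pixel count as a double (counts routinely exceed
#'   `.Machine$integer.max`).
#' @examples
#' pixel_count(4, 5000, 5000)   # 1e8
#' pixel_count(10, 10000, 10000) # 1e9
#' @export
pixel_count <- function(n_channels, y, x) {
  for (v in list(n_channels, y, x)) {
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != floor(v)) {
      stop("all arguments must be integers >= 1")
    }
  }
  as.numeric(n_channels) * as.numeric(y) * as.numeric(x)
}

# internal: check a label matrix is a valid instance mask for a given shape
validate_labels <- function(labels, shape = NULL) {
  if (!is.matrix(labels) || any(labels < 0) || any(labels != floor(labels))) {
    stop("labels must be a non-negative integer matrix")
  }
  if (!is.null(shape) && !identical(dim(labels), as.integer(shape))) {
    stop(sprintf("label image shape (%s) does not match image shape (%s)",
                 paste(dim(labels), collapse = "x"),
                 paste(shape, collapse = "x")))
  }
  invisible(labels)
}
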