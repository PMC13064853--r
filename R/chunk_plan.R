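#' Plan the tiling of an image into overlapping chunks
#'
#' Divides the spatial domain into a row-major grid of rectangular *core*
#' regions that partition the image exactly, each carrying a halo of
#' `overlap` extra pixels on every side. Chunks can then be processed
#' independently: the halo gives each chunk enough context around its core
#' that objects crossing a core boundary are seen whole by both neighbours.
#'
#' Per axis the number of cores is `ceiling(extent / chunk_size)`; cores are
#' laid out left-to-right / top-to-bottom at full `chunk_size`, and the last
#' core per axis carries the remainder. Planning a 512 x 512 image with
#' `chunk_size = 212` therefore gives 9 chunks with core lengths
#' 212, 212, 88 per axis.
#'
#' All intervals are 0-based and half-open (the convention of chunked array
#' stores such as OME-NGFF); use the 1-based helpers in [extract_chunk()]
#' when slicing R arrays.
#'
#' @param image_shape integer vector `c(y, x)`, both `>= 1`.
#' @param chunk_size maximum core edge length in pixels, `>= 1`.
#' @param overlap halo width in pixels added on every side of every core,
#'   `>= 0`. The default 50 is suited to cells up to ~50 px radius.
#' @return An object of class `chunk_plan`: list with `image_shape`,
#'   `chunk_size`, `overlap` and `specs`, a row-major list of `chunk_spec`
#'   objects. Each spec holds `core_y` and `core_x` (0-based half-open
#'   `c(start, end)` intervals), `halo` and `grid_index = c(row, col)`.
#' @examples
#' plan <- plan_chunks(c(512, 512), chunk_size = 212, overlap = 50)
#' length(plan$specs) # 9
#' @export
plan_chunks <- function(image_shape, chunk_size, overlap = 50L) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(is.na(image_shape)) || any(image_shape < 1L)) {
    stop("`image_shape` must be two positive integers (y, x)")
  }
  if (length(chunk_size) != 1L || is.na(chunk_size) || chunk_size < 1) {
    stop("`chunk_size` must be a positive integer")
  }
  if (length(overlap) != 1L || is.na(overlap) || overlap < 0) {
    stop("`overlap` must be a non-negative integer")
  }
  chunk_size <- as.integer(chunk_size)
  overlap <- as.integer(overlap)

  axis_starts <- function(extent) seq.int(0L, extent - 1L, by = chunk_size)
  ys <- axis_starts(image_shape[1L])
  xs <- axis_starts(image_shape[2L])

  specs <- vector("list", length(ys) * length(xs))
  k <- 1L
  for (i in seq_along(ys)) {
    y0 <- ys[i]
    y1 <- min(y0 + chunk_size, image_shape[1L])
    for (j in seq_along(xs)) {
      x0 <- xs[j]
      x1 <- min(x0 + chunk_size, image_shape[2L])
      specs[[k]] <- structure(
        list(core_y = c(y0, y1), core_x = c(x0, x1),
             halo = overlap, grid_index = c(i, j)),
        class = "chunk_spec"
      )
      k <- k + 1L
    }
  }
  structure(
    list(image_shape = image_shape, chunk_size = chunk_size,
         overlap = overlap, specs = specs,
         grid_shape = c(length(ys), length(xs))),
    class = "chunk_plan"
  )
}

#' @export
print.chunk_plan <- function(x, ...) {
  cat(sprintf("<chunk_plan> %d x %d image, chunk_size %d, overlap %d: %d chunks (%d x %d grid)\n",
              x$image_shape[1L], x$image_shape[2L], x$chunk_size, x$overlap,
              length(x$specs), x$grid_shape[1L], x$grid_shape[2L]))
  invisible(x)
}

# internal: mirror a vector of 0-based indices into [0, n) by reflection
# about the array edges, excluding the boundary pixel itself: index -1 maps
# to 1, index n maps to n - 2 ("reflect", not "symmetric").
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(0L, length(idx)))
  period <- 2L * (n - 1L)
  idx <- idx %% period
  idx[idx < 0L] <- idx[idx < 0L] + period
  over <- idx > (n - 1L)
  idx[over] <- period - idx[over]
  idx
}

#' Extract one chunk (core plus halo) from an image
#'
#' Returns the intensity raster of shape
#' `(n_channels, core_y + 2 * halo, core_x + 2 * halo)` for one chunk of a
#' plan. Halo pixels inside the image copy the true neighbouring pixels;
#' halo pixels beyond the global image boundary are filled by mirror
#' reflection about the boundary (column -1 copies column 1), so every chunk
#' has the same padded geometry regardless of its position in the grid.
#'
#' @param image a [multiplex_image()].
#' @param spec one `chunk_spec` from [plan_chunks()] built for this image's
#'   shape.
#' @return Numeric array `(c, h, w)`.
#' @export
extract_chunk <- function(image, spec) {
  stopifnot(inherits(image, "multiplex_image"), inherits(spec, "chunk_spec"))
  shp <- image_shape(image)
  if (spec$core_y[1L] < 0 || spec$core_x[1L] < 0 ||
      spec$core_y[2L] > shp[1L] || spec$core_x[2L] > shp[2L] ||
      spec$core_y[1L] >= spec$core_y[2L] || spec$core_x[1L] >= spec$core_x[2L]) {
    stop("chunk spec lies outside the image")
  }
  h <- spec$halo
  yg <- seq.int(spec$core_y[1L] - h, spec$core_y[2L] + h - 1L)
  xg <- seq.int(spec$core_x[1L] - h, spec$core_x[2L] + h - 1L)
  yi <- reflect_index(yg, shp[1L]) + 1L
  xi <- reflect_index(xg, shp[2L]) + 1L
  image$data[, yi, xi, drop = FALSE]
}

# internal: 1-based row/col ranges of a spec's core
core_rows <- function(spec) seq.int(spec$core_y[1L] + 1L, spec$core_y[2L])
core_cols <- function(spec) seq.int(spec$core_x[1L] + 1L, spec$core_x[2L])
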