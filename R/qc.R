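#' Signal-to-noise ratio of one channel
#'
#' Image-level QC metric: pixels are split by an Otsu threshold on the
#' channel into signal (above) and noise (at or below); the SNR is
#' `mean(signal) / mean(noise)`. Because Otsu operates on the min-max
#' normalized raster, the split -- and therefore the SNR -- is invariant to
#' positive rescaling of the intensities. When the noise mean is exactly
#' zero (a fully clean background) the `noise_floor` surrogate is used as
#' denominator.
#'
#' @param x numeric matrix of one channel; must contain at least two
#'   distinct values.
#' @param noise_floor smallest-positive-noise surrogate used when the noise
#'   mean is 0 (default `1e-6`).
#' @param channel optional channel name, used in error messages.
#' @return List with `snr` and `mean_signal`.
#' @export
channel_snr <- function(x, noise_floor = 1e-6, channel = "channel") {
  if (!length(x) || !all(is.finite(x))) stop("`x` must be finite")
  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    stop(sprintf("SNR undefined for channel '%s': constant intensities", channel))
  }
  norm <- (x - rng[1L]) / (rng[2L] - rng[1L])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  signal <- x[norm > thr]
  noise <- x[norm <= thr]
  if (!length(signal) || !length(noise)) {
    stop(sprintf("SNR undefined for channel '%s': thresholding produced an empty class",
                 channel))
  }
  mn <- mean(noise)
  list(snr = mean(signal) / max(mn, noise_floor), mean_signal = mean(signal))
}

#' Marker-name consistency across samples
#'
#' Multi-sample QC of channel naming (the tabular equivalent of a supervenn
#' diagram): a boolean membership matrix of samples against the union of
#' all marker names, plus the partition of markers into those shared by
#' every sample, those unique to one sample, and the partially shared rest.
#'
#' @param samples named list: `sample_id -> character vector` of that
#'   sample's marker names. Duplicate markers within one sample are an
#'   error.
#' @return List with `membership` (samples x markers logical matrix),
#'   `shared`, `partial`, `unique_per_sample` (named list) and `consistent`
#'   (`TRUE` iff all samples carry identical marker sets).
#' @export
marker_set_report <- function(samples) {
  if (!length(samples)) stop("need at least one sample")
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("sample_", seq_along(samples))
  }
  for (s in names(samples)) {
    if (anyDuplicated(samples[[s]])) {
      stop(sprintf("duplicate marker name within sample '%s'", s))
    }
  }
  all_markers <- unique(unlist(samples, use.names = FALSE))
  membership <- t(vapply(samples, function(m) all_markers %in% m,
                         logical(length(all_markers))))
  # vapply over a single marker collapses dims; force matrix shape
  membership <- matrix(membership, nrow = length(samples),
                       dimnames = list(names(samples), all_markers))
  n_with <- colSums(membership)
  shared <- all_markers[n_with == length(samples)]
  uniq <- all_markers[n_with == 1L]
  unique_per_sample <- lapply(samples, function(m) intersect(m, uniq))
  partial <- setdiff(all_markers, c(shared, uniq))
  list(membership = membership, shared = shared, partial = partial,
       unique_per_sample = unique_per_sample,
       consistent = length(shared) == length(all_markers) &&
         all(vapply(samples, length, integer(1)) == length(all_markers)))
}

#' Segmentation-level mask area statistics
#'
#' Per-cell areas of a label image with summary statistics and a histogram;
#' the maximum area is the input to [check_overlap_sufficiency()].
#'
#' @param labels integer label matrix.
#' @param breaks histogram breaks, passed to [graphics::hist()] semantics
#'   via [base::cut()]-free binning (`"Sturges"` by default).
#' @return List with `areas` (named by cell id), `n_cells`, `min`, `median`,
#'   `max` and `histogram` (a `counts`/`breaks` list). With no cells, an
#'   empty report is returned with a warning.
#' @export
mask_area_stats <- function(labels, breaks = "Sturges") {
  validate_labels(labels)
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) {
    warning("label image contains no cells; returning empty area report")
    return(list(areas = numeric(0), n_cells = 0L, min = NA_real_,
                median = NA_real_, max = NA_real_, histogram = NULL))
  }
  areas <- as.numeric(table(labels[labels > 0]))
  names(areas) <- ids
  h <- graphics::hist(areas, breaks = breaks, plot = FALSE)
  list(areas = areas, n_cells = length(ids), min = min(areas),
       median = stats::median(areas), max = max(areas),
       histogram = list(breaks = h$breaks, counts = h$counts))
}

#' Multi-level quality-control report
#'
#' Assembles the image-level and segmentation-level QC metrics of a dataset
#' into one report: per-sample pixel counts and marker sets with a
#' consistency flag, per-channel SNR and mean signal, mask-area summaries,
#' and (when `overlap` is given) the overlap-sufficiency check against the
#' largest observed cell. Channels whose SNR is undefined (constant rasters)
#' are reported with `NA` and flagged rather than failing the report.
#'
#' @param images list of [multiplex_image()] objects (one per sample).
#' @param labels optional list of label matrices parallel to `images`.
#' @param overlap chunk overlap (pixels) to check sufficiency against, or
#'   `NULL` to skip.
#' @return Nested list of class `qc_report`; serialize with
#'   [write_qc_report()].
#' @export
qc_report <- function(images, labels = NULL, overlap = NULL) {
  stopifnot(length(images) >= 1L,
            all(vapply(images, inherits, logical(1), "multiplex_image")))
  sample_ids <- vapply(images, `[[`, character(1), "sample_id")
  marker_sets <- lapply(images, `[[`, "channel_names")
  names(marker_sets) <- sample_ids
  markers <- marker_set_report(marker_sets)

  per_sample <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    shp <- image_shape(img)
    chans <- lapply(seq_along(img$channel_names), function(k) {
      res <- tryCatch(
        channel_snr(matrix(img$data[k, , ], shp[1L], shp[2L]),
                    channel = img$channel_names[k]),
        error = function(e) list(snr = NA_real_, mean_signal = NA_real_))
      c(res, list(channel = img$channel_names[k]))
    })
    out <- list(sample_id = img$sample_id,
                pixel_count = pixel_count(length(img$channel_names),
                                          shp[1L], shp[2L]),
                channels = chans)
    if (!is.null(labels)) {
      out$mask_areas <- mask_area_stats(labels[[i]])
      if (!is.null(overlap) && out$mask_areas$n_cells > 0L) {
        out$overlap_check <- withCallingHandlers(
          check_overlap_sufficiency(out$mask_areas$max, overlap),
          warning = function(w) invokeRestart("muffleWarning"))
      }
    }
    out
  })
  names(per_sample) <- sample_ids

  flags <- list(
    inconsistent_markers = !markers$consistent,
    undefined_snr = unlist(lapply(per_sample, function(s) {
      vapply(s$channels, function(ch) is.na(ch$snr), logical(1))
    })),
    insufficient_overlap = if (!is.null(overlap) && !is.null(labels)) {
      any(vapply(per_sample, function(s) {
        !is.null(s$overlap_check) && !s$overlap_check$sufficient
      }, logical(1)))
    } else NA
  )
  structure(list(samples = per_sample, markers = markers, flags = flags),
            class = "qc_report")
}
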