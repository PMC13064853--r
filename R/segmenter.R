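# Union-find over integer ids 1..n; `pairs` is a 2-column matrix of ids to
# unite. Returns for every id the smallest id in its component, so the
# surviving id of a merged group is deterministic and order-independent.
uf_roots <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]] # path halving
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
      if (a != b) {
        # union by min id keeps the smallest id as the root
        if (a < b) parent[b] <- a else parent[a] <- b
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# internal: densify positive labels to 1..k preserving numeric order of ids
relabel_consecutive <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (!length(u)) return(labels)
  out <- labels
  pos <- labels > 0
  out[pos] <- match(labels[pos], u)
  out
}

#' Label connected components with 8-connectivity
#'
#' Connected-component labeling of a binary mask where diagonal neighbours
#' belong to the same object. Built on [EBImage::bwlabel()] (4-connected)
#' followed by a union-find pass that unites label pairs touching only
#' diagonally. Labels are renumbered 1..k in ascending order of the
#' 4-connected pass, background stays 0.
#'
#' @param mask logical or 0/1 numeric matrix.
#' @return Integer matrix of the same shape.
#' @export
label_components <- function(mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  lab <- EBImage::imageData(EBImage::bwlabel(mask > 0))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n < 2L) return(lab)
  ny <- nrow(lab); nx <- ncol(lab)
  # diagonal neighbour pairs: down-right and down-left
  a1 <- lab[-ny, -nx]; b1 <- lab[-1L, -1L]
  a2 <- lab[-ny, -1L]; b2 <- lab[-1L, -nx]
  pairs <- rbind(
    cbind(as.vector(a1), as.vector(b1)),
    cbind(as.vector(a2), as.vector(b2))
  )
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L & pairs[, 1L] != pairs[, 2L], ,
                 drop = FALSE]
  if (!nrow(pairs)) return(lab)
  pairs <- unique(pairs)
  roots <- uf_roots(n, pairs)
  out <- lab
  pos <- lab > 0L
  out[pos] <- roots[lab[pos]]
  relabel_consecutive(out)
}

#' Declare a segmenter under the chunked-segmentation contract
#'
#' A segmenter is any function mapping an intensity raster `(c, h, w)` to an
#' integer label raster `(h, w)` with 0 as background and the same spatial
#' shape. Wrapping it in this contract records which input channels it
#' expects (by name; [segment_chunked()] subsets and orders them) and
#' whether it is deterministic, which the stitching guarantees rely on.
#' Adapters for external deep-learning models (Cellpose, InstanSeg, ...)
#' plug in here; none are bundled.
#'
#' @param fn function of one argument, the `(c, h, w)` channel-subset array.
#' @param channels character vector of input channel names, or `NULL` to
#'   receive all channels of the image.
#' @param deterministic logical flag declared by the caller.
#' @return An object of class `segmenter`.
#' @export
segmenter <- function(fn, channels = NULL, deterministic = TRUE) {
  stopifnot(is.function(fn))
  structure(list(fn = fn, channels = channels, deterministic = isTRUE(deterministic)),
            class = "segmenter")
}

#' Deterministic reference segmentation of a raster
#'
#' A deterministic, translation-invariant instance segmenter used to
#' exercise and validate the chunked stitching machinery without any
#' learned model: (1) the declared channels are summed and binarized at
#' `threshold` (`>=`), (2) foreground is labeled by 8-connected components,
#' (3) when a nuclear channel is given, components containing two or more
#' nuclear seeds (8-connected components of `nuclear >= nuclear_threshold`)
#' are split by assigning each pixel to the nearest seed centroid -- a
#' marker-based Voronoi split that separates touching cells, (4) components
#' smaller than `min_size` pixels are dropped. Output labels are 1..k.
#'
#' @param raster numeric `(c, h, w)` array.
#' @param threshold binarization threshold on the channel sum.
#' @param min_size minimum object area in pixels; smaller components are
#'   removed (default 10).
#' @param nuclear_channel index (into `raster`'s first axis) of the nuclear
#'   channel used for seed detection, or `NULL` to skip splitting.
#' @param nuclear_threshold threshold on the nuclear channel defining seeds;
#'   defaults to `threshold`.
#' @return Integer label matrix `(h, w)`.
#' @seealso [reference_segmenter()] for the contract-wrapped version.
#' @export
reference_segmentation <- function(raster, threshold, min_size = 10L,
                                   nuclear_channel = NULL,
                                   nuclear_threshold = threshold) {
  if (!is.array(raster) || length(dim(raster)) != 3L) {
    stop("`raster` must be a (c, h, w) array")
  }
  signal <- colSums(raster, dims = 1L)
  lab <- label_components(signal >= threshold)
  if (!is.null(nuclear_channel) && max(lab) > 0L) {
    nuc <- matrix(raster[nuclear_channel, , ], dim(raster)[2L], dim(raster)[3L])
    seeds <- label_components(nuc >= nuclear_threshold)
    lab <- split_by_seeds(lab, seeds)
  }
  if (min_size > 1L && max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(areas < min_size)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  relabel_consecutive(lab)
}

# internal: split multi-seed components by nearest seed centroid.
# Translation-invariant: assignment depends only on distances to seed
# centroids; ties go to the seed with the lexicographically smaller
# (centroid_y, centroid_x).
split_by_seeds <- function(lab, seeds) {
  ns <- max(seeds)
  if (ns < 2L) return(lab)
  ny <- nrow(lab)
  sidx <- which(seeds > 0L)
  sid <- seeds[sidx]
  sy <- (sidx - 1L) %% ny
  sx <- (sidx - 1L) %/% ny
  cy <- rowsum(as.numeric(sy), sid) / tabulate(sid, ns)
  cx <- rowsum(as.numeric(sx), sid) / tabulate(sid, ns)
  # component hosting each seed: majority label under the seed's pixels
  host <- vapply(seq_len(ns), function(s) {
    l <- lab[sidx[sid == s]]
    l <- l[l > 0L]
    if (!length(l)) return(0L)
    as.integer(names(which.max(table(l))))
  }, integer(1))
  out <- lab
  offset <- max(lab)
  for (comp in unique(host[host > 0L])) {
    sset <- which(host == comp)
    if (length(sset) < 2L) next
    # order seeds lexicographically by centroid so argmin ties are stable
    ord <- sset[order(cy[sset], cx[sset])]
    pidx <- which(lab == comp)
    py <- (pidx - 1L) %% ny
    px <- (pidx - 1L) %/% ny
    d2 <- outer(py, cy[ord], function(a, b) (a - b)^2) +
          outer(px, cx[ord], function(a, b) (a - b)^2)
    nearest <- max.col(-d2, ties.method = "first")
    out[pidx] <- offset + nearest
    offset <- offset + length(ord)
  }
  relabel_consecutive(out)
}

#' Contract-wrapped reference segmenter
#'
#' Convenience constructor returning [reference_segmentation()] as a
#' [segmenter()] ready for [segment_chunked()].
#'
#' @inheritParams reference_segmentation
#' @param channels channel names the segmenter consumes (`NULL` = all).
#' @param nuclear_channel index of the nuclear channel *within* `channels`.
#' @return A `segmenter` object.
#' @export
reference_segmenter <- function(threshold, min_size = 10L, channels = NULL,
                                nuclear_channel = NULL,
                                nuclear_threshold = threshold) {
  segmenter(
    function(raster) {
      reference_segmentation(raster, threshold = threshold, min_size = min_size,
                             nuclear_channel = nuclear_channel,
                             nuclear_threshold = nuclear_threshold)
    },
    channels = channels, deterministic = TRUE
  )
}
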