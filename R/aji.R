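#' Aggregated Jaccard Index of an instance segmentation
#'
#' Object-level accuracy of a predicted label image against a reference
#' labeling. Reference objects are visited in ascending label id; each is
#' matched to the not-yet-matched predicted object maximizing IoU (ties
#' broken by the smaller predicted id; objects with no overlapping
#' unmatched prediction stay unmatched). The index is
#' `sum(matched intersections) / (sum(matched unions) + sum(areas of
#' never-matched predicted objects))`, where an unmatched reference object
#' contributes its own area to the denominator. Equal labelings (up to any
#' relabeling bijection) score 1; an empty prediction scores 0.
#'
#' The fixed visiting order and tie-breaks make the score reproducible; the
#' underlying definition leaves them unspecified.
#'
#' @param pred,truth integer label matrices of equal shape, 0 = background.
#'   `truth` must contain at least one object.
#' @return A number in `[0, 1]`.
#' @export
aggregated_jaccard_index <- function(pred, truth) {
  validate_labels(pred)
  validate_labels(truth, dim(pred))
  truth_ids <- sort(unique(truth[truth > 0]))
  if (!length(truth_ids)) stop("`truth` must contain at least one object")
  pred_ids <- sort(unique(pred[pred > 0]))

  area_t <- table(truth[truth > 0])
  area_p <- table(pred[pred > 0])
  sel <- truth > 0 & pred > 0
  inter <- if (any(sel)) table(t = truth[sel], p = pred[sel]) else NULL

  matched <- integer(0)
  num <- 0
  den <- 0
  for (t in truth_ids) {
    at <- area_t[[as.character(t)]]
    best_p <- NA_integer_
    best_iou <- 0
    best_i <- 0
    if (!is.null(inter) && as.character(t) %in% rownames(inter)) {
      row <- setNames(as.vector(inter[as.character(t), , drop = FALSE]),
                      colnames(inter))
      cands <- setdiff(as.integer(names(row)[row > 0]), matched)
      cands <- sort(cands) # ascending id, so a tie keeps the smaller one
      for (p in cands) {
        i <- row[[as.character(p)]]
        iou <- i / (at + area_p[[as.character(p)]] - i)
        if (iou > best_iou) {
          best_p <- p; best_iou <- iou; best_i <- i
        }
      }
    }
    if (!is.na(best_p) && best_iou > 0) {
      matched <- c(matched, best_p)
      num <- num + best_i
      den <- den + at + area_p[[as.character(best_p)]] - best_i
    } else {
      den <- den + at
    }
  }
  unmatched <- setdiff(pred_ids, matched)
  if (length(unmatched)) {
    den <- den + sum(unlist(area_p[as.character(unmatched)]))
  }
  num / den
}
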