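## Multi-annotator bounding-box consensus. Three raters annotate HE
## lesions independently; the ground truth is built pairwise: raters 1 and
## 2 are merged, then the result is merged with rater 3. Within a merge,
## boxes overlapping with IoU > 0.15 are matched one-to-one and the
## larger-area box of each matched pair is kept verbatim; boxes at or
## below the threshold are retained from both sides.

## Optimal one-to-one matching between two box sets restricted to pairs
## with IoU > threshold, maximising total IoU. Exhaustive branch-and-bound
## for small sets; greedy descending-IoU fallback for large ones (the two
## coincide except on contrived many-to-many overlap patterns).
.matchBoxes <- function(iouMat, threshold) {
  n <- nrow(iouMat); m <- ncol(iouMat)
  if (n == 0L || m == 0L) return(matrix(integer(), 0L, 2L))
  cand <- which(iouMat > threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(matrix(integer(), 0L, 2L))
  if (min(n, m) > 9L) return(.matchBoxesGreedy(iouMat, threshold))
  ## candidates per a-box, sorted by decreasing IoU for a deterministic
  ## tie-break (first maximiser found wins)
  candByA <- lapply(seq_len(n), function(i) {
    js <- cand[cand[, 1L] == i, 2L]
    js[order(-iouMat[i, js], js)]
  })
  best <- list(total = -1, pairs = matrix(integer(), 0L, 2L))
  recurse <- function(i, usedB, pairs, total) {
    if (i > n) {
      if (total > best$total + 1e-12) {
        best$total <<- total
        best$pairs <<- pairs
      }
      return(invisible())
    }
    ## upper bound: remaining a-boxes each add at most their best candidate
    ub <- total
    for (k in i:n) {
      js <- candByA[[k]]
      js <- js[!(js %in% usedB)]
      if (length(js)) ub <- ub + iouMat[k, js[1L]]
    }
    if (ub <= best$total + 1e-12) return(invisible())
    for (j in candByA[[i]]) {
      if (!(j %in% usedB))
        recurse(i + 1L, c(usedB, j), rbind(pairs, c(i, j)),
                total + iouMat[i, j])
    }
    recurse(i + 1L, usedB, pairs, total)  # leave a-box i unmatched
  }
  recurse(1L, integer(), matrix(integer(), 0L, 2L), 0)
  best$pairs
}

.matchBoxesGreedy <- function(iouMat, threshold) {
  cand <- which(iouMat > threshold, arr.ind = TRUE)
  ord <- order(-iouMat[cand], cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  usedA <- logical(nrow(iouMat)); usedB <- logical(ncol(iouMat))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <- usedB[j] <- TRUE
      keep[k] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

.sortBoxes <- function(b) {
  if (length(b) < 2L) return(b)
  b[order(b@coords[, 2L], b@coords[, 1L], b@coords[, 4L], b@coords[, 3L])]
}

#' Merge two annotators' HE box sets into a partial ground truth
#'
#' Boxes from the two sets are matched one-to-one among pairs with
#' IoU strictly above `iouThreshold` (matching maximises total IoU). For
#' each matched pair the larger-area box is kept verbatim (ties keep the
#' box from `a`); every unmatched box from either set is retained. The
#' result is sorted by `(ymin, xmin)`.
#'
#' @param a,b [AnnotationSet-class] objects for the same image.
#' @param iouThreshold overlap threshold in `(0, 1)`; default 0.15. A pair
#'   with IoU exactly equal to the threshold is *not* matched (both boxes
#'   are retained).
#' @return An [AnnotationSet-class] with `annotatorId = "consensus"`.
#' @examples
#' a <- annotationSet("img", "r1", boundingBoxes(0, 0, 10, 10))
#' b <- annotationSet("img", "r2", boundingBoxes(2, 2, 14, 14))
#' annotationBoxes(mergePair(a, b))  # the larger box (2,2,14,14)
#' @export
mergePair <- function(a, b, iouThreshold = 0.15) {
  stopifnot(is(a, "AnnotationSet"), is(b, "AnnotationSet"))
  if (a@imageId != b@imageId)
    stop("cannot merge annotation sets for different images: '",
         a@imageId, "' vs '", b@imageId, "'")
  if (!(iouThreshold > 0 && iouThreshold < 1))
    stop("iouThreshold must lie in (0, 1)")
  ba <- a@boxes; bb <- b@boxes
  if (length(ba) == 0L && length(bb) == 0L)
    return(annotationSet(a@imageId, "consensus"))
  iouMat <- boxIoU(ba, bb)
  pairs <- .matchBoxes(iouMat, iouThreshold)
  keepA <- setdiff(seq_len(length(ba)), pairs[, 1L])
  keepB <- setdiff(seq_len(length(bb)), pairs[, 2L])
  kept <- list()
  if (nrow(pairs) > 0L) {
    areaA <- boxArea(ba)[pairs[, 1L]]
    areaB <- boxArea(bb)[pairs[, 2L]]
    fromA <- areaA >= areaB  # equal area keeps the first argument's box
    if (any(fromA)) kept <- c(kept, list(ba[pairs[fromA, 1L]]))
    if (any(!fromA)) kept <- c(kept, list(bb[pairs[!fromA, 2L]]))
  }
  if (length(keepA)) kept <- c(kept, list(ba[keepA]))
  if (length(keepB)) kept <- c(kept, list(bb[keepB]))
  out <- .sortBoxes(do.call(combineBoxes, kept))
  annotationSet(a@imageId, "consensus", out)
}

#' Three-annotator consensus ground truth
#'
#' The first two annotators are merged with [mergePair()], and the result
#' is merged with the third annotator by the same rule. The fixed
#' `((1, 2), 3)` schedule makes the general (many-to-many) case order
#' dependent; with one-to-one overlaps the outcome does not depend on
#' argument order except through equal-area ties.
#'
#' @param sets a list of exactly three [AnnotationSet-class] objects for
#'   the same image.
#' @param iouThreshold overlap threshold; see [mergePair()].
#' @return The final consensus [AnnotationSet-class].
#' @export
consensusGT <- function(sets, iouThreshold = 0.15) {
  if (!is.list(sets) || length(sets) != 3L)
    stop("consensusGT requires exactly three annotation sets")
  mergePair(mergePair(sets[[1L]], sets[[2L]], iouThreshold),
            sets[[3L]], iouThreshold)
}
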