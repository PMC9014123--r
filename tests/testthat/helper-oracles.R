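## Independent oracles used across the suite. These deliberately avoid
## the package's own arithmetic paths.

## Pixel-rasterisation IoU for integer-corner boxes: count covered unit
## cells directly.
rasterIoU <- function(a, b) {
  cellsOf <- function(bx) {
    xs <- seq(bx[1], bx[3] - 1)
    ys <- seq(bx[2], bx[4] - 1)
    outer(xs, ys, function(x, y) paste(x, y))
  }
  ca <- cellsOf(a); cb <- cellsOf(b)
  inter <- length(intersect(ca, cb))
  inter / (length(ca) + length(cb) - inter)
}

rasterArea <- function(a) {
  length(seq(a[1], a[3] - 1)) * length(seq(a[2], a[4] - 1))
}

## Exhaustive-enumeration consensus merge: over all one-to-one matchings
## restricted to pairs with IoU > thr, pick the one maximising total IoU,
## then apply the keep-larger rule and retain unmatched boxes.
bruteMerge <- function(aM, bM, thr = 0.15) {
  n <- nrow(aM); m <- nrow(bM)
  iou <- if (n && m) fundusfusion::boxIoU(aM, bM) else
    matrix(0, max(n, 1), max(m, 1))
  best <- list(total = -1, pairs = NULL)
  rec <- function(i, usedB, pairs, total) {
    if (i > n) {
      if (total > best$total + 1e-12) best <<- list(total = total,
                                                    pairs = pairs)
      return()
    }
    rec(i + 1, usedB, pairs, total)
    if (m) for (j in seq_len(m)) {
      if (!(j %in% usedB) && iou[i, j] > thr)
        rec(i + 1, c(usedB, j), rbind(pairs, c(i, j)), total + iou[i, j])
    }
  }
  rec(1, integer(), NULL, 0)
  keep <- matrix(numeric(), 0, 4)
  pairs <- best$pairs
  mA <- if (is.null(pairs)) integer() else pairs[, 1]
  mB <- if (is.null(pairs)) integer() else pairs[, 2]
  if (!is.null(pairs)) for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    areaA <- (aM[i, 3] - aM[i, 1]) * (aM[i, 4] - aM[i, 2])
    areaB <- (bM[j, 3] - bM[j, 1]) * (bM[j, 4] - bM[j, 2])
    keep <- rbind(keep, if (areaA >= areaB) aM[i, ] else bM[j, ])
  }
  if (n) keep <- rbind(keep, aM[setdiff(seq_len(n), mA), , drop = FALSE])
  if (m) keep <- rbind(keep, bM[setdiff(seq_len(m), mB), , drop = FALSE])
  unname(keep[order(keep[, 2], keep[, 1], keep[, 4], keep[, 3]), ,
              drop = FALSE])
}

## Sorted corner matrix of an AnnotationSet, for geometric comparison.
sortedCoords <- function(aset) {
  co <- unname(fundusfusion::boxCoords(fundusfusion::annotationBoxes(aset)))
  co[order(co[, 2], co[, 1], co[, 4], co[, 3]), , drop = FALSE]
}

randomBoxSet <- function(k, size = 100, minSide = 3, maxSide = 25) {
  if (k == 0) return(matrix(numeric(), 0, 4))
  x0 <- runif(k, 0, size - maxSide)
  y0 <- runif(k, 0, size - maxSide)
  w <- runif(k, minSide, maxSide)
  h <- runif(k, minSide, maxSide)
  unname(cbind(x0, y0, x0 + w, y0 + h))
}

asAnnotation <- function(m, id = "img", rater = "r") {
  b <- if (nrow(m)) fundusfusion::boundingBoxes(m[, 1], m[, 2], m[, 3],
                                                m[, 4])
  else fundusfusion::boundingBoxes()
  fundusfusion::annotationSet(id, rater, b)
}

## O(n^2) concordance-probability AUC oracle.
bruteAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (x in pos) for (y in neg)
    s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

## Tiny scene dataset for training smoke tests.
makeTinyScenes <- function(n, gp, cfg) {
  lapply(seq_len(n), function(i) {
    sc <- fundusfusion::generateScene(gp, imageId = sprintf("s%03d", i))
    ann <- fundusfusion::simulateAnnotators(sc$truth, gp)
    cons <- fundusfusion::consensusGT(ann)
    list(image = sc$image, boxes = fundusfusion::annotationBoxes(cons),
         label = sc$truth@dmeLabel, truth = sc$truth)
  })
}
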