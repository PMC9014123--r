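## Anatomical landmarks and the geometric DME criterion: a fundus image is
## DME iff any hard exudate lies at or within one optic-disc diameter of
## the centre of the macula (ETDRS-derived rule). Distances are measured
## to the nearest point of the HE box, and the boundary is inclusive.

#' Optic-disc diameter from its bounding box
#'
#' Discs are near-circular, so the diameter is taken as the mean of the
#' box width and height.
#'
#' @param discBox a length-1 [BoundingBoxes-class].
#' @return Diameter in pixels.
#' @examples
#' discDiameter(boundingBoxes(0, 0, 30, 50, category = "optic_disc"))  # 40
#' @export
discDiameter <- function(discBox) {
  m <- .coerceBoxMatrix(discBox)
  stopifnot(nrow(m) == 1L)
  unname((m[1L, 3L] - m[1L, 1L] + m[1L, 4L] - m[1L, 2L]) / 2)
}

#' Macula centre from its bounding box
#'
#' @param maculaBox a length-1 [BoundingBoxes-class].
#' @return Numeric `c(x, y)` centroid.
#' @export
maculaCenter <- function(maculaBox) {
  m <- .coerceBoxMatrix(maculaBox)
  stopifnot(nrow(m) == 1L)
  c(x = (m[1L, 1L] + m[1L, 3L]) / 2, y = (m[1L, 2L] + m[1L, 4L]) / 2)
}

#' The 1-disc-diameter DME rule
#'
#' DME (label 1) iff the distance from the macula centre to the nearest
#' point of any HE box is at most one disc diameter; an image without HE
#' is non-DME. Missing landmarks make the image ungradable and raise an
#' error rather than silently returning non-DME.
#'
#' @param heBoxes a [BoundingBoxes-class] of HE lesions (possibly empty).
#' @param discBox,maculaBox length-1 [BoundingBoxes-class] landmarks, or a
#'   length-0 object / `NULL` when the landmark was not found.
#' @return Integer 0 (non-DME) or 1 (DME).
#' @examples
#' disc <- boundingBoxes(0, 0, 40, 40, category = "optic_disc")
#' mac  <- boundingBoxes(80, 80, 120, 120, category = "macula")
#' he   <- boundingBoxes(139, 100, 149, 110)
#' dmeRule(he, disc, mac)  # distance 39 <= diameter 40 -> 1
#' @export
dmeRule <- function(heBoxes, discBox, maculaBox) {
  if (is.null(discBox) || is.null(maculaBox) ||
      (is(discBox, "BoundingBoxes") && length(discBox) == 0L) ||
      (is(maculaBox, "BoundingBoxes") && length(maculaBox) == 0L))
    stop("ungradable image: optic disc or macula landmark is absent")
  if (is(heBoxes, "BoundingBoxes") && length(heBoxes) == 0L) return(0L)
  d <- pointBoxDistance(maculaCenter(maculaBox), heBoxes)
  as.integer(any(d <= discDiameter(discBox)))
}

#' Extract disc and macula from a detector's output
#'
#' Runs the landmark detector and keeps the highest-confidence optic-disc
#' and macula candidates; absence is reported explicitly as an empty slot.
#' Any detector producing a scored, categorised [BoundingBoxes-class]
#' qualifies: a [FusionModel-class] (its detection path is used) or a
#' plain `function(image) -> BoundingBoxes`.
#'
#' @param detector a [FusionModel-class] or a function of the image.
#' @param img a [FundusImage-class].
#' @return A [LandmarkSet-class].
#' @export
detectLandmarks <- function(detector, img) {
  boxes <- if (is.function(detector)) {
    detector(img)
  } else if (is(detector, "FusionModel")) {
    forwardFusion(detector, img)$boxes
  } else stop("detector must be a FusionModel or a function(image)")
  pick <- function(cat) {
    idx <- which(boxes@category == cat)
    if (!length(idx)) return(boundingBoxes())
    sc <- boxes@score[idx]
    sc[is.na(sc)] <- 1
    boxes[idx[which.max(sc)]]
  }
  landmarkSet(discBox = pick("optic_disc"), maculaBox = pick("macula"))
}

## -- overlay rendering ------------------------------------------------------

.drawRect <- function(px, box, col, thickness = 2L) {
  H <- dim(px)[1L]; W <- dim(px)[2L]
  x0 <- max(1L, floor(box[1L]) + 1L); x1 <- min(W, ceiling(box[3L]))
  y0 <- max(1L, floor(box[2L]) + 1L); y1 <- min(H, ceiling(box[4L]))
  if (x0 > x1 || y0 > y1) return(px)
  t <- thickness - 1L
  for (ch in 1:3) {
    px[y0:min(y0 + t, y1), x0:x1, ch] <- col[ch]
    px[max(y1 - t, y0):y1, x0:x1, ch] <- col[ch]
    px[y0:y1, x0:min(x0 + t, x1), ch] <- col[ch]
    px[y0:y1, max(x1 - t, x0):x1, ch] <- col[ch]
  }
  px
}

.drawCircle <- function(px, center, radius, col, thickness = 2L) {
  H <- dim(px)[1L]; W <- dim(px)[2L]
  theta <- seq(0, 2 * pi, length.out = max(64L, ceiling(4 * pi * radius)))
  for (dr in seq(0, thickness - 1L, by = 0.5)) {
    xs <- round(center[1L] + (radius + dr) * cos(theta)) + 1L
    ys <- round(center[2L] + (radius + dr) * sin(theta)) + 1L
    ok <- xs >= 1L & xs <= W & ys >= 1L & ys <= H
    if (!any(ok)) next
    lin <- cbind(ys[ok], xs[ok])
    for (ch in 1:3) px[cbind(lin, ch)] <- col[ch]
  }
  px
}

#' Render the clinical overlay on a fundus image
#'
#' HE boxes are drawn in blue, the optic-disc box in white, and a white
#' circle of radius one disc diameter is drawn around the macula centre,
#' matching the visualisation shown to physicians. With no boxes and no
#' landmarks the pixels are returned unchanged (with a warning when
#' landmarks are absent).
#'
#' @param img a [FundusImage-class].
#' @param heBoxes a [BoundingBoxes-class] of HE lesions (possibly empty).
#' @param landmarks a [LandmarkSet-class].
#' @return A new [FundusImage-class] with the overlay composited.
#' @export
renderOverlay <- function(img, heBoxes = boundingBoxes(),
                          landmarks = landmarkSet()) {
  stopifnot(is(img, "FundusImage"), is(landmarks, "LandmarkSet"))
  px <- img@pixels
  blue <- c(0.1, 0.3, 1); white <- c(1, 1, 1)
  if (length(heBoxes) > 0L) {
    co <- boxCoords(heBoxes)
    for (i in seq_len(nrow(co))) px <- .drawRect(px, co[i, ], blue)
  }
  hasDisc <- length(landmarks@discBox) == 1L
  hasMac <- length(landmarks@maculaBox) == 1L
  if (!hasDisc || !hasMac) {
    if (length(heBoxes) > 0L || hasDisc || hasMac)
      warning("landmarks incomplete: drawing available elements only")
  }
  if (hasDisc)
    px <- .drawRect(px, boxCoords(landmarks@discBox)[1L, ], white)
  if (hasDisc && hasMac)
    px <- .drawCircle(px, maculaCenter(landmarks@maculaBox),
                      discDiameter(landmarks@discBox), white)
  fundusImage(img@imageId, px, img@sourcePath)
}
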