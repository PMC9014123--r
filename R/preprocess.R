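## Preprocessing: crop to the fundus region with minimal black border,
## resize to the network input size (bilinear), transport annotations
## through the same affine map, and flip augmentation.

#' Tight bounding box of the fundus region
#'
#' Finds the tight box around pixels whose grayscale value (channel mean)
#' exceeds `blackThreshold`; if no pixel does, the full-image box is
#' returned as a degenerate fallback.
#'
#' @param img a [FundusImage-class].
#' @param blackThreshold grayscale cut separating the dark border from the
#'   fundus, on the `[0, 1]` intensity scale; default `10/255`.
#' @return A length-1 [BoundingBoxes-class] (category `"region"`).
#' @export
findFundusBbox <- function(img, blackThreshold = 10 / 255) {
  stopifnot(is(img, "FundusImage"))
  px <- img@pixels
  gray <- (px[, , 1L] + px[, , 2L] + px[, , 3L]) / 3
  H <- nrow(gray); W <- ncol(gray)
  rows <- which(apply(gray > blackThreshold, 1L, any))
  cols <- which(apply(gray > blackThreshold, 2L, any))
  if (!length(rows) || !length(cols))
    return(boundingBoxes(0, 0, W, H, category = "region"))
  boundingBoxes(min(cols) - 1, min(rows) - 1, max(cols), max(rows),
                category = "region")
}

.resizeBilinear <- function(px, targetH, targetW) {
  ## EBImage stores images x-major; our arrays are H x W x 3 (row = y)
  ebi <- EBImage::Image(aperm(px, c(2L, 1L, 3L)), colormode = "Color")
  out <- EBImage::resize(ebi, w = targetW, h = targetH)
  res <- aperm(EBImage::imageData(out), c(2L, 1L, 3L))
  res[res < 0] <- 0; res[res > 1] <- 1
  res
}

#' Crop to the fundus region and resize to the model input size
#'
#' The image is cropped to [findFundusBbox()] and resampled (bilinear) to
#' `target x target`; in `"tight"` mode a non-square crop is stretched
#' anisotropically, in `"pad"` mode it is first padded with black to a
#' square so the scale stays isotropic. Boxes are mapped through the same
#' [AffineTransform-class], which is returned so predictions can be mapped
#' back to source coordinates with [invertTransform()].
#'
#' @param img a [FundusImage-class].
#' @param boxes a [BoundingBoxes-class] to transport (possibly empty).
#' @param target output side length in pixels (default 640).
#' @param mode `"tight"` (default) or `"pad"`.
#' @param blackThreshold passed to [findFundusBbox()].
#' @return `list(image, boxes, transform)`. Boxes falling fully outside
#'   the crop are dropped with a warning.
#' @export
cropAndResize <- function(img, boxes = boundingBoxes(), target = 640,
                          mode = c("tight", "pad"),
                          blackThreshold = 10 / 255) {
  stopifnot(is(img, "FundusImage"), target >= 32)
  mode <- match.arg(mode)
  bb <- boxCoords(findFundusBbox(img, blackThreshold))[1L, ]
  px <- img@pixels
  x0 <- bb[1L]; y0 <- bb[2L]; x1 <- bb[3L]; y1 <- bb[4L]
  crop <- px[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  if (mode == "pad") {
    ch <- nrow(crop); cw <- ncol(crop)
    side <- max(ch, cw)
    if (side > ch || side > cw) {
      padded <- array(0, c(side, side, 3L))
      padded[seq_len(ch), seq_len(cw), ] <- crop
      crop <- padded
    }
  }
  cw <- ncol(crop); chh <- nrow(crop)
  tf <- affineTransform(scaleX = target / cw, scaleY = target / chh,
                        offsetX = x0, offsetY = y0)
  out <- if (cw == target && chh == target) crop else
    .resizeBilinear(crop, target, target)
  if (length(boxes) > 0L) {
    co <- boxCoords(boxes)
    inside <- co[, 3L] > x0 & co[, 1L] < x1 & co[, 4L] > y0 & co[, 2L] < y1
    if (any(!inside)) {
      warning(sum(!inside), " box(es) fall outside the fundus crop; dropped")
      boxes <- boxes[inside]
    }
    boxes <- transformBoxes(boxes, tf)
  }
  list(image = fundusImage(img@imageId, out, img@sourcePath),
       boxes = boxes, transform = tf)
}

#' Deterministic horizontal/vertical flip of an image and its boxes
#'
#' @param img a [FundusImage-class].
#' @param boxes a [BoundingBoxes-class].
#' @param horizontal,vertical logical flags.
#' @return `list(image, boxes, horizontal, vertical)`. Applying the same
#'   flip twice restores the input (involution).
#' @export
applyFlip <- function(img, boxes = boundingBoxes(),
                      horizontal = FALSE, vertical = FALSE) {
  stopifnot(is(img, "FundusImage"))
  px <- img@pixels
  H <- dim(px)[1L]; W <- dim(px)[2L]
  co <- if (length(boxes)) boxCoords(boxes) else NULL
  if (horizontal) {
    px <- px[, W:1, , drop = FALSE]
    if (!is.null(co)) {
      nx <- cbind(W - co[, 3L], co[, 2L], W - co[, 1L], co[, 4L])
      co <- nx
    }
  }
  if (vertical) {
    px <- px[H:1, , , drop = FALSE]
    if (!is.null(co)) {
      ny <- cbind(co[, 1L], H - co[, 4L], co[, 3L], H - co[, 2L])
      co <- ny
    }
  }
  if (!is.null(co)) {
    co <- unname(co)
    colnames(co) <- c("xmin", "ymin", "xmax", "ymax")
    boxes <- new("BoundingBoxes", coords = co, score = boxes@score,
                 category = boxes@category)
  }
  list(image = fundusImage(img@imageId, px, img@sourcePath), boxes = boxes,
       horizontal = horizontal, vertical = vertical)
}

#' Random flip augmentation
#'
#' Applies a horizontal flip with probability 0.5 and, independently, a
#' vertical flip with probability 0.5, mirroring box coordinates
#' consistently.
#'
#' @param img a [FundusImage-class].
#' @param boxes a [BoundingBoxes-class].
#' @param rngSeed integer seed; `NULL` uses the current RNG stream.
#' @return As [applyFlip()], with the realised flips recorded.
#' @export
augmentFlip <- function(img, boxes = boundingBoxes(), rngSeed = NULL) {
  if (!is.null(rngSeed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(rngSeed)
  }
  u <- stats::runif(2)
  applyFlip(img, boxes, horizontal = u[1L] < 0.5, vertical = u[2L] < 0.5)
}
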