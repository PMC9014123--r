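## Core box arithmetic. Everything downstream (consensus, the 1DD rule,
## anchor assignment, detection scoring) reduces to these primitives.
## Convention: 0-based continuous coordinates, half-open
## [xmin, xmax) x [ymin, ymax); area = width * height; boxes sharing only
## an edge have IoU 0.

.coerceBoxMatrix <- function(b) {
  if (is(b, "BoundingBoxes")) return(b@coords)
  if (is.numeric(b) && is.null(dim(b)) && length(b) == 4L)
    return(matrix(b, 1L, 4L))
  if (is.matrix(b) && ncol(b) == 4L) return(b)
  stop("expected a BoundingBoxes object, a length-4 vector or an n x 4 matrix")
}

#' Box area
#'
#' @param b a [BoundingBoxes-class] object, a length-4 numeric
#'   `c(xmin, ymin, xmax, ymax)`, or an n x 4 matrix.
#' @return Numeric vector of areas in squared pixels, strictly positive.
#' @examples
#' boxArea(c(0, 0, 10, 10))   # 100
#' boxArea(c(2, 2, 14, 14))   # 144
#' @export
boxArea <- function(b) {
  m <- .coerceBoxMatrix(b)
  w <- m[, 3L] - m[, 1L]
  h <- m[, 4L] - m[, 2L]
  if (any(w <= 0) || any(h <= 0))
    stop("degenerate box: zero or negative width/height")
  unname(as.numeric(w * h))
}

#' Intersection over union of two box sets
#'
#' @param a,b [BoundingBoxes-class] objects (or length-4 vectors /
#'   n x 4 matrices).
#' @return A `length(a) x length(b)` matrix of IoU values in `[0, 1]`.
#'   Disjoint boxes (including boxes sharing only an edge) have IoU 0;
#'   identical boxes have IoU 1.
#' @examples
#' boxIoU(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 50 / 150
#' @export
boxIoU <- function(a, b) {
  A <- .coerceBoxMatrix(a)
  B <- .coerceBoxMatrix(b)
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(numeric(), n, m))
  areaA <- boxArea(A)
  areaB <- boxArea(B)
  ix <- pmax(0, outer(A[, 3L], B[, 3L], pmin) - outer(A[, 1L], B[, 1L], pmax))
  iy <- pmax(0, outer(A[, 4L], B[, 4L], pmin) - outer(A[, 2L], B[, 2L], pmax))
  inter <- ix * iy
  inter / (outer(areaA, areaB, "+") - inter)
}

#' Euclidean distance from a point to the nearest point of a box
#'
#' Distance to the closed rectangle: 0 when the point lies inside or on
#' the boundary.
#'
#' @param p numeric `c(x, y)`.
#' @param b a [BoundingBoxes-class] object (or vector/matrix form).
#' @return Numeric vector, one distance per box, in pixels.
#' @examples
#' pointBoxDistance(c(0, 0), c(3, 4, 5, 6))  # 5 (3-4-5 triangle)
#' @export
pointBoxDistance <- function(p, b) {
  stopifnot(is.numeric(p), length(p) == 2L, all(is.finite(p)))
  m <- .coerceBoxMatrix(b)
  dx <- pmax(m[, 1L] - p[1L], 0, p[1L] - m[, 3L])
  dy <- pmax(m[, 2L] - p[2L], 0, p[2L] - m[, 4L])
  unname(sqrt(dx^2 + dy^2))
}

#' Map boxes through an affine crop/resize transform
#'
#' Corners map as `x -> (x - offsetX) * scaleX`, `y -> (y - offsetY) *
#' scaleY`; score and category are preserved. Orientation-reversing
#' transforms are rejected by the [AffineTransform-class] validity.
#'
#' @param b a [BoundingBoxes-class] object.
#' @param tf an [AffineTransform-class].
#' @return The transformed [BoundingBoxes-class].
#' @export
transformBoxes <- function(b, tf) {
  stopifnot(is(b, "BoundingBoxes"), is(tf, "AffineTransform"))
  if (length(b) == 0L) return(b)
  co <- b@coords
  co[, c(1L, 3L)] <- (co[, c(1L, 3L)] - tf@offsetX) * tf@scaleX
  co[, c(2L, 4L)] <- (co[, c(2L, 4L)] - tf@offsetY) * tf@scaleY
  new("BoundingBoxes", coords = co, score = b@score, category = b@category)
}

#' Invert an affine transform
#'
#' @param tf an [AffineTransform-class].
#' @return The inverse transform, such that mapping a box forward and then
#'   through the inverse recovers the original corners.
#' @export
invertTransform <- function(tf) {
  stopifnot(is(tf, "AffineTransform"))
  affineTransform(scaleX = 1 / tf@scaleX, scaleY = 1 / tf@scaleY,
                  offsetX = -tf@offsetX * tf@scaleX,
                  offsetY = -tf@offsetY * tf@scaleY)
}
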