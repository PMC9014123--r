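#' @import methods
NULL

## Canonical box categories. "region" is reserved for plumbing boxes
## (e.g. the fundus crop rectangle) that never enter annotation files.
.BOX_CATEGORIES <- c("HE", "optic_disc", "macula", "region")

#' Axis-aligned bounding boxes
#'
#' A set of axis-aligned rectangles in continuous pixel coordinates with an
#' optional detection score and a category per box. Coordinates are 0-based
#' with origin at the top-left corner and half-open extents
#' `[xMin, xMax) x [yMin, yMax)`, so a box with integer corners covers
#' exactly `(xMax - xMin) * (yMax - yMin)` unit pixels. Width/height
#' representations used in annotation files are converted at I/O boundaries.
#'
#' @slot coords numeric matrix with columns `xmin`, `ymin`, `xmax`, `ymax`.
#' @slot score numeric vector of per-box scores in `[0, 1]`, `NA` if absent.
#' @slot category character vector; one of `"HE"`, `"optic_disc"`,
#'   `"macula"` (or `"region"` for internal plumbing boxes).
#'
#' @seealso [boundingBoxes()], [boxArea()], [boxIoU()]
#' @export
setClass("BoundingBoxes",
  representation(coords = "matrix", score = "numeric", category = "character"),
  validity = function(object) {
    co <- object@coords
    msg <- character()
    if (ncol(co) != 4L)
      return("coords must have 4 columns (xmin, ymin, xmax, ymax)")
    n <- nrow(co)
    if (length(object@score) != n || length(object@category) != n)
      msg <- c(msg, "score and category must match the number of boxes")
    if (n > 0L) {
      if (!all(is.finite(co)))
        msg <- c(msg, "box coordinates must be finite")
      else {
        if (any(co[, 1L] >= co[, 3L]) || any(co[, 2L] >= co[, 4L]))
          msg <- c(msg, "degenerate box: require xmin < xmax and ymin < ymax")
      }
      sc <- object@score
      bad <- !is.na(sc) & (sc < 0 | sc > 1)
      if (any(bad)) msg <- c(msg, "scores must be in [0, 1] or NA")
      if (!all(object@category %in% .BOX_CATEGORIES))
        msg <- c(msg, sprintf("category must be one of: %s",
                              paste(.BOX_CATEGORIES, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a BoundingBoxes object
#'
#' @param xmin,ymin,xmax,ymax numeric vectors of box corners (0-based,
#'   half-open; see [BoundingBoxes-class]).
#' @param score per-box score in `[0, 1]`, or `NA` (default) when absent.
#' @param category per-box category, one of `"HE"`, `"optic_disc"`,
#'   `"macula"`.
#' @return A [BoundingBoxes-class] object.
#' @examples
#' b <- boundingBoxes(0, 0, 10, 10)
#' boxArea(b)
#' @export
boundingBoxes <- function(xmin = numeric(), ymin = numeric(),
                          xmax = numeric(), ymax = numeric(),
                          score = NA_real_, category = "HE") {
  n <- length(xmin)
  stopifnot(length(ymin) == n, length(xmax) == n, length(ymax) == n)
  co <- cbind(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
              xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  rownames(co) <- NULL
  new("BoundingBoxes", coords = co,
      score = rep_len(as.numeric(score), n),
      category = rep_len(as.character(category), n))
}

#' @rdname boundingBoxes
#' @export
emptyBoxes <- function(category = character(0)) {
  boundingBoxes()
}

#' Affine crop/resize transform for box coordinates
#'
#' Maps `x -> (x - offsetX) * scaleX`, `y -> (y - offsetY) * scaleY`.
#' Orientation-reversing transforms (non-positive scales) are rejected.
#'
#' @slot scaleX,scaleY positive scale ratios.
#' @slot offsetX,offsetY offsets in source pixels, applied before scaling.
#' @export
setClass("AffineTransform",
  representation(scaleX = "numeric", scaleY = "numeric",
                 offsetX = "numeric", offsetY = "numeric"),
  validity = function(object) {
    if (length(object@scaleX) != 1L || length(object@scaleY) != 1L ||
        length(object@offsetX) != 1L || length(object@offsetY) != 1L)
      return("all slots must be scalars")
    if (!is.finite(object@scaleX) || !is.finite(object@scaleY) ||
        object@scaleX <= 0 || object@scaleY <= 0)
      return("scales must be finite and > 0 (orientation-preserving)")
    TRUE
  })

#' @param scaleX,scaleY,offsetX,offsetY see [AffineTransform-class].
#' @rdname AffineTransform-class
#' @export
affineTransform <- function(scaleX = 1, scaleY = 1, offsetX = 0, offsetY = 0) {
  new("AffineTransform", scaleX = as.numeric(scaleX),
      scaleY = as.numeric(scaleY), offsetX = as.numeric(offsetX),
      offsetY = as.numeric(offsetY))
}

#' One annotator's HE boxes for one image
#'
#' @slot imageId image identifier.
#' @slot annotatorId annotator identifier (`"consensus"` for merged sets).
#' @slot boxes a [BoundingBoxes-class] object, all with category `"HE"`;
#'   may be empty for an image without lesions.
#' @export
setClass("AnnotationSet",
  representation(imageId = "character", annotatorId = "character",
                 boxes = "BoundingBoxes"),
  validity = function(object) {
    if (length(object@imageId) != 1L || length(object@annotatorId) != 1L)
      return("imageId and annotatorId must be scalars")
    if (length(object@boxes) > 0L && !all(object@boxes@category == "HE"))
      return("annotation boxes must have category 'HE'")
    TRUE
  })

#' @param imageId,annotatorId identifiers.
#' @param boxes a [BoundingBoxes-class] object (category `"HE"`).
#' @rdname AnnotationSet-class
#' @export
annotationSet <- function(imageId, annotatorId, boxes = boundingBoxes()) {
  new("AnnotationSet", imageId = as.character(imageId),
      annotatorId = as.character(annotatorId), boxes = boxes)
}

#' A fundus photograph in memory
#'
#' Pixels are stored as an `H x W x 3` numeric array in `[0, 1]`
#' (8-bit files are rescaled on read and written back as 8-bit).
#'
#' @slot imageId image identifier.
#' @slot pixels `H x W x 3` array, values in `[0, 1]`, `H, W >= 32`.
#' @slot sourcePath originating file path, or `NA`.
#' @export
setClass("FundusImage",
  representation(imageId = "character", pixels = "array",
                 sourcePath = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3L] != 3L)
      return("pixels must be an H x W x 3 array")
    if (d[1L] < 32L || d[2L] < 32L)
      return("image must be at least 32 x 32")
    rng <- range(object@pixels)
    if (!all(is.finite(rng)) || rng[1L] < 0 || rng[2L] > 1)
      return("pixel intensities must lie in [0, 1]")
    TRUE
  })

#' @param imageId identifier.
#' @param pixels `H x W x 3` array in `[0, 1]`.
#' @param sourcePath optional originating path.
#' @rdname FundusImage-class
#' @export
fundusImage <- function(imageId, pixels, sourcePath = NA_character_) {
  new("FundusImage", imageId = as.character(imageId), pixels = pixels,
      sourcePath = as.character(sourcePath))
}

#' Ground truth of one synthetic fundus scene
#'
#' The DME label is not free: validity enforces that it equals the
#' 1-disc-diameter rule ([dmeRule()]) applied to the scene's own geometry.
#'
#' @slot imageId image identifier.
#' @slot discBox optic-disc box (length-1 [BoundingBoxes-class]).
#' @slot maculaBox macula box (length-1 [BoundingBoxes-class]).
#' @slot heBoxes HE lesion boxes (possibly empty).
#' @slot dmeLabel integer 0/1.
#' @slot patientId synthetic patient identifier (`NA` when standalone).
#' @export
setClass("SceneTruth",
  representation(imageId = "character", discBox = "BoundingBoxes",
                 maculaBox = "BoundingBoxes", heBoxes = "BoundingBoxes",
                 dmeLabel = "integer", patientId = "character"),
  validity = function(object) {
    if (length(object@discBox) != 1L || length(object@maculaBox) != 1L)
      return("exactly one disc box and one macula box are required")
    if (object@discBox@category != "optic_disc" ||
        object@maculaBox@category != "macula")
      return("disc/macula boxes must carry their landmark categories")
    if (as.vector(boxIoU(object@discBox, object@maculaBox)) > 0)
      return("disc and macula boxes must be disjoint")
    if (!(object@dmeLabel %in% c(0L, 1L)))
      return("dmeLabel must be 0 or 1")
    lab <- dmeRule(object@heBoxes, object@discBox, object@maculaBox)
    if (lab != object@dmeLabel)
      return("dmeLabel inconsistent with the 1DD rule on the scene geometry")
    TRUE
  })

#' @param imageId identifier.
#' @param discBox,maculaBox,heBoxes see [SceneTruth-class].
#' @param dmeLabel integer 0/1; must satisfy [dmeRule()].
#' @param patientId synthetic patient identifier.
#' @rdname SceneTruth-class
#' @export
sceneTruth <- function(imageId, discBox, maculaBox, heBoxes,
                       dmeLabel, patientId = NA_character_) {
  new("SceneTruth", imageId = as.character(imageId), discBox = discBox,
      maculaBox = maculaBox, heBoxes = heBoxes,
      dmeLabel = as.integer(dmeLabel), patientId = as.character(patientId))
}

#' Detected anatomical landmarks for one image
#'
#' At most one optic disc and one macula; absence is explicit (length-0
#' slot), never silently coerced to a default. Confidences ride on the box
#' scores.
#'
#' @slot discBox length-0 or length-1 [BoundingBoxes-class] (optic_disc).
#' @slot maculaBox length-0 or length-1 [BoundingBoxes-class] (macula).
#' @export
setClass("LandmarkSet",
  representation(discBox = "BoundingBoxes", maculaBox = "BoundingBoxes"),
  validity = function(object) {
    if (length(object@discBox) > 1L || length(object@maculaBox) > 1L)
      return("at most one disc and one macula per image")
    if (length(object@discBox) == 1L &&
        object@discBox@category != "optic_disc")
      return("discBox must have category 'optic_disc'")
    if (length(object@maculaBox) == 1L &&
        object@maculaBox@category != "macula")
      return("maculaBox must have category 'macula'")
    TRUE
  })

#' @param discBox,maculaBox length-0 or length-1 [BoundingBoxes-class].
#' @rdname LandmarkSet-class
#' @export
landmarkSet <- function(discBox = boundingBoxes(),
                        maculaBox = boundingBoxes()) {
  new("LandmarkSet", discBox = discBox, maculaBox = maculaBox)
}

#' Synthetic fundus-scene generator parameters
#'
#' Defaults emulate a 45-degree-FOV fundus photograph at 256 x 256 with a
#' DME prevalence mirroring a training population of roughly 42% DME, and
#' annotator noise levels representative of careful human raters.
#'
#' @slot imageSize image side length in pixels.
#' @slot dmePrevalence probability that a scene is DME.
#' @slot heCountRange integer interval for the number of HE lesions.
#' @slot heSizeRange pixel interval for HE box side lengths.
#' @slot annotatorJitterSd corner jitter SD in pixels for simulated raters.
#' @slot annotatorMissRate probability a rater misses a true lesion.
#' @slot annotatorSpuriousRate probability a rater adds a spurious box.
#' @slot backgroundNoiseSd additive Gaussian pixel noise SD (on `[0,1]`).
#' @export
setClass("GeneratorParams",
  representation(imageSize = "integer", dmePrevalence = "numeric",
                 heCountRange = "integer", heSizeRange = "numeric",
                 annotatorJitterSd = "numeric", annotatorMissRate = "numeric",
                 annotatorSpuriousRate = "numeric",
                 backgroundNoiseSd = "numeric"),
  validity = function(object) {
    rates <- c(object@dmePrevalence, object@annotatorMissRate,
               object@annotatorSpuriousRate)
    if (any(rates < 0 | rates > 1))
      return("rates must lie in [0, 1]")
    if (object@imageSize < 64L)
      return("imageSize must be >= 64 for a feasible scene layout")
    if (length(object@heCountRange) != 2L ||
        object@heCountRange[1L] > object@heCountRange[2L] ||
        object@heCountRange[1L] < 0L)
      return("heCountRange must be a non-empty non-negative interval")
    if (length(object@heSizeRange) != 2L ||
        object@heSizeRange[1L] > object@heSizeRange[2L] ||
        object@heSizeRange[1L] < 2)
      return("heSizeRange must be a non-empty interval with min >= 2 px")
    if (object@annotatorJitterSd < 0 || object@backgroundNoiseSd < 0)
      return("noise SDs must be non-negative")
    TRUE
  })

#' @param imageSize,dmePrevalence,heCountRange,heSizeRange see
#'   [GeneratorParams-class].
#' @param annotatorJitterSd,annotatorMissRate,annotatorSpuriousRate,backgroundNoiseSd
#'   see [GeneratorParams-class].
#' @rdname GeneratorParams-class
#' @export
generatorParams <- function(imageSize = 256,
                            dmePrevalence = 0.42,
                            heCountRange = c(0L, 5L),
                            heSizeRange = NULL,
                            annotatorJitterSd = 2,
                            annotatorMissRate = 0.1,
                            annotatorSpuriousRate = 0.05,
                            backgroundNoiseSd = 0.02) {
  if (is.null(heSizeRange))
    heSizeRange <- round(c(0.035, 0.08) * imageSize)
  new("GeneratorParams", imageSize = as.integer(imageSize),
      dmePrevalence = as.numeric(dmePrevalence),
      heCountRange = as.integer(heCountRange),
      heSizeRange = as.numeric(heSizeRange),
      annotatorJitterSd = as.numeric(annotatorJitterSd),
      annotatorMissRate = as.numeric(annotatorMissRate),
      annotatorSpuriousRate = as.numeric(annotatorSpuriousRate),
      backgroundNoiseSd = as.numeric(backgroundNoiseSd))
}

#' Focal-loss parameters
#'
#' @slot alpha class-balance weight, `>= 0`; default 0.25.
#' @slot gamma focusing exponent, `>= 0`; default 2.
#' @export
setClass("FocalParams",
  representation(alpha = "numeric", gamma = "numeric"),
  validity = function(object) {
    if (object@alpha < 0 || object@gamma < 0)
      return("alpha and gamma must be >= 0")
    TRUE
  })

#' @param alpha,gamma see [FocalParams-class].
#' @rdname FocalParams-class
#' @export
focalParams <- function(alpha = 0.25, gamma = 2) {
  new("FocalParams", alpha = as.numeric(alpha), gamma = as.numeric(gamma))
}

#' Loss-combination weights for the fusion objective
#'
#' The combined objective is
#' `E_loss = omegaOb * E_ob + omegaCl * E_cl`. Defaults (0.5, 100) are the
#' retraining weights that balance the detector and classifier terms;
#' (1, 1) corresponds to the equal-weight initial training phase.
#'
#' @slot omegaOb weight on the detector loss, `> 0`.
#' @slot omegaCl weight on the classification focal loss, `> 0`.
#' @export
setClass("LossWeights",
  representation(omegaOb = "numeric", omegaCl = "numeric"),
  validity = function(object) {
    if (object@omegaOb <= 0 || object@omegaCl <= 0)
      return("loss weights must be strictly positive")
    TRUE
  })

#' @param omegaOb,omegaCl see [LossWeights-class].
#' @rdname LossWeights-class
#' @export
lossWeights <- function(omegaOb = 0.5, omegaCl = 100) {
  new("LossWeights", omegaOb = as.numeric(omegaOb),
      omegaCl = as.numeric(omegaCl))
}

#' Fusion network model handle
#'
#' @slot config configuration list from [fusionConfig()].
#' @slot params named list of parameter arrays.
#' @slot task `"fusion"`, `"detector"` or `"classifier"`.
#' @export
setClass("FusionModel",
  representation(config = "list", params = "list", task = "character"),
  validity = function(object) {
    if (!(object@task %in% c("fusion", "detector", "classifier")))
      return("task must be fusion, detector or classifier")
    TRUE
  })

setMethod("show", "BoundingBoxes", function(object) {
  n <- length(object)
  cat(sprintf("BoundingBoxes with %d box%s\n", n, if (n == 1L) "" else "es"))
  if (n > 0L) {
    df <- as.data.frame(object)
    print(utils::head(df, 6L))
    if (n > 6L) cat(sprintf("... and %d more\n", n - 6L))
  }
  invisible(object)
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: image '%s', annotator '%s', %d HE box(es)\n",
              object@imageId, object@annotatorId, length(object@boxes)))
  invisible(object)
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth '%s': %d HE lesion(s), DME label %d\n",
              object@imageId, length(object@heBoxes), object@dmeLabel))
  invisible(object)
})

setMethod("show", "LandmarkSet", function(object) {
  d <- if (length(object@discBox)) "present" else "absent"
  m <- if (length(object@maculaBox)) "present" else "absent"
  cat(sprintf("LandmarkSet: optic disc %s, macula %s\n", d, m))
  invisible(object)
})

setMethod("show", "FusionModel", function(object) {
  cat(sprintf("FusionModel (task: %s), input %dx%d, %d parameters\n",
              object@task, object@config$inputSize, object@config$inputSize,
              countParams(object)))
  invisible(object)
})

setMethod("show", "GeneratorParams", function(object) {
  cat(sprintf(
    "GeneratorParams: %dx%d scenes, DME prevalence %.2f, %d-%d HE of %g-%g px\n",
    object@imageSize, object@imageSize, object@dmePrevalence,
    object@heCountRange[1L], object@heCountRange[2L],
    object@heSizeRange[1L], object@heSizeRange[2L]))
  invisible(object)
})

#' @export
setMethod("length", "BoundingBoxes", function(x) nrow(x@coords))

#' @export
setMethod("[", "BoundingBoxes", function(x, i, j, ..., drop = TRUE) {
  new("BoundingBoxes", coords = x@coords[i, , drop = FALSE],
      score = x@score[i], category = x@category[i])
})

#' @export
setMethod("as.data.frame", "BoundingBoxes", function(x, ...) {
  data.frame(xmin = x@coords[, 1L], ymin = x@coords[, 2L],
             xmax = x@coords[, 3L], ymax = x@coords[, 4L],
             score = x@score, category = x@category,
             stringsAsFactors = FALSE)
})

## Accessors ----------------------------------------------------------------

#' Accessors for BoundingBoxes
#'
#' @param x a [BoundingBoxes-class] object.
#' @return `boxCoords` returns the n x 4 corner matrix; `boxScore` and
#'   `boxCategory` the per-box vectors.
#' @export
boxCoords <- function(x) x@coords

#' @rdname boxCoords
#' @export
boxScore <- function(x) x@score

#' @rdname boxCoords
#' @export
boxCategory <- function(x) x@category

#' Concatenate BoundingBoxes objects
#'
#' @param ... [BoundingBoxes-class] objects.
#' @export
combineBoxes <- function(...) {
  xs <- list(...)
  xs <- xs[vapply(xs, length, 1L) > 0L]
  if (!length(xs)) return(boundingBoxes())
  new("BoundingBoxes",
      coords = do.call(rbind, lapply(xs, boxCoords)),
      score = unlist(lapply(xs, boxScore)),
      category = unlist(lapply(xs, boxCategory)))
}

#' Accessors for AnnotationSet and SceneTruth
#'
#' @param x an [AnnotationSet-class] or [SceneTruth-class] object.
#' @export
imageId <- function(x) x@imageId

#' @rdname imageId
#' @export
annotatorId <- function(x) x@annotatorId

#' @rdname imageId
#' @export
annotationBoxes <- function(x) x@boxes

#' @rdname imageId
#' @export
heBoxes <- function(x) x@heBoxes

#' @rdname imageId
#' @export
discBox <- function(x) x@discBox

#' @rdname imageId
#' @export
maculaBox <- function(x) x@maculaBox

#' @rdname imageId
#' @export
dmeLabel <- function(x) x@dmeLabel

#' Pixel accessor for FundusImage
#'
#' @param x a [FundusImage-class] object.
#' @export
imagePixels <- function(x) x@pixels
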