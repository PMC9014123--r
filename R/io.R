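## File-format plumbing: a COCO-style JSON dialect for annotations and
## detections (x, y, width, height per box; corner form is used
## everywhere in memory and converted here), PNG image I/O, label CSVs,
## and config/manifest handling.

.boxesToRecords <- function(boxes) {
  if (length(boxes) == 0L) return(list())
  co <- boxCoords(boxes)
  lapply(seq_len(nrow(co)), function(i) {
    rec <- list(x = co[i, 1L], y = co[i, 2L],
                width = co[i, 3L] - co[i, 1L],
                height = co[i, 4L] - co[i, 2L],
                category = boxes@category[i])
    if (!is.na(boxes@score[i])) rec$score <- boxes@score[i]
    rec
  })
}

.boxesFromRecords <- function(recs) {
  if (!length(recs)) return(boundingBoxes())
  m <- t(vapply(recs, function(r)
    c(r$x, r$y, r$x + r$width, r$y + r$height,
      if (is.null(r$score)) NA_real_ else r$score), numeric(5L)))
  boundingBoxes(m[, 1L], m[, 2L], m[, 3L], m[, 4L], score = m[, 5L],
                category = vapply(recs, function(r)
                  if (is.null(r$category)) "HE" else r$category, ""))
}

#' Read and write annotation sets as COCO-style JSON
#'
#' The on-disk dialect is a JSON array of records
#' `{image_id, annotator_id, boxes: [{x, y, width, height, category,
#' score?}]}` with `x, y` the top-left corner. Corner-form coordinates
#' used in memory are converted at this boundary.
#'
#' @param sets a list of [AnnotationSet-class] objects.
#' @param path file path.
#' @return `readAnnotations` returns a list of [AnnotationSet-class].
#' @export
writeAnnotations <- function(sets, path) {
  recs <- lapply(sets, function(s) list(
    image_id = s@imageId, annotator_id = s@annotatorId,
    boxes = .boxesToRecords(s@boxes)))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r) {
    tryCatch(
      annotationSet(r$image_id, r$annotator_id, .boxesFromRecords(r$boxes)),
      error = function(e) stop("malformed annotation record for image '",
                               r$image_id, "': ", conditionMessage(e)))
  })
}

#' Write and read detection results (scored boxes) as COCO-style JSON
#'
#' Same dialect as [writeAnnotations()] but keyed per image without an
#' annotator, with scores mandatory, and carrying the affine transform of
#' the preprocessing step so detections can be mapped back to source
#' coordinates.
#'
#' @param detections named list (by image id) of [BoundingBoxes-class].
#' @param path file path.
#' @param transforms optional named list of [AffineTransform-class].
#' @export
writeDetections <- function(detections, path, transforms = NULL) {
  recs <- lapply(names(detections), function(id) {
    rec <- list(image_id = id, boxes = .boxesToRecords(detections[[id]]))
    tf <- transforms[[id]]
    if (!is.null(tf))
      rec$transform <- list(scale_x = tf@scaleX, scale_y = tf@scaleY,
                            offset_x = tf@offsetX, offset_y = tf@offsetY)
    rec
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) {
  recs <- jsonlite::read_json(path)
  out <- lapply(recs, function(r) .boxesFromRecords(r$boxes))
  names(out) <- vapply(recs, `[[`, "", "image_id")
  out
}

.truthToList <- function(truth) {
  list(image_id = truth@imageId, patient_id = truth@patientId,
       dme_label = truth@dmeLabel,
       disc = .boxesToRecords(truth@discBox)[[1L]],
       macula = .boxesToRecords(truth@maculaBox)[[1L]],
       he = .boxesToRecords(truth@heBoxes))
}

.truthFromList <- function(rec) {
  sceneTruth(rec$image_id,
             .boxesFromRecords(list(rec$disc)),
             .boxesFromRecords(list(rec$macula)),
             .boxesFromRecords(rec$he),
             rec$dme_label,
             if (is.null(rec$patient_id)) NA_character_ else rec$patient_id)
}

#' Read scene truths written by [generateDataset()]
#'
#' @param path path to `truth.json`.
#' @return A list of [SceneTruth-class] objects.
#' @export
readSceneTruths <- function(path) {
  lapply(jsonlite::read_json(path), .truthFromList)
}

#' Read and write fundus images (PNG/JPG)
#'
#' 8-bit image files are rescaled to `[0, 1]` in memory and written back
#' as 8-bit PNG.
#'
#' @param img a [FundusImage-class].
#' @param path file path.
#' @export
writeFundusImage <- function(img, path) {
  ebi <- EBImage::Image(aperm(img@pixels, c(2L, 1L, 3L)),
                        colormode = "Color")
  EBImage::writeImage(ebi, path, bits.per.sample = 8L)
  invisible(path)
}

#' @param imageId identifier for the read image (default: file name).
#' @rdname writeFundusImage
#' @export
readFundusImage <- function(path, imageId = NULL) {
  ebi <- EBImage::readImage(path)
  px <- EBImage::imageData(ebi)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3L] > 3L) px <- px[, , 1:3, drop = FALSE]
  px <- aperm(px, c(2L, 1L, 3L))
  px[px < 0] <- 0; px[px > 1] <- 1
  if (is.null(imageId)) imageId <- tools::file_path_sans_ext(basename(path))
  fundusImage(imageId, px, sourcePath = path)
}

#' Stable hash of a configuration object
#'
#' MD5 of the canonical JSON serialisation; embedded in run manifests so
#' artifacts can be traced to the exact configuration and seeds.
#'
#' @param cfg any JSON-serialisable list.
#' @return A 32-character hex string.
#' @export
configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Read image-level labels from a two-column CSV
#'
#' @param path CSV with at least columns `image_id` and `label`.
#' @return A data.frame.
#' @export
readLabels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_id", "label") %in% names(df)))
    stop("labels CSV must have columns image_id and label: ", path)
  df
}
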