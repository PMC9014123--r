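## Synthetic fundus scenes: a caricature of a 45-degree-FOV fundus
## photograph -- dark surround, bright circular fundus region, one bright
## near-circular optic disc nasally, one darker macula about 2.5 disc
## diameters temporal to it, and small bright high-contrast HE blobs. The
## DME label is drawn first and lesions are placed inside or outside the
## 1DD circle accordingly; the stored label is then recomputed from the
## realised geometry so truth and label agree exactly by construction.

.withSeed <- function(rngSeed, expr) {
  if (is.null(rngSeed)) return(expr)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rngSeed)
  expr
}

.sceneLayout <- function(params) {
  s <- params@imageSize
  dd <- 0.17 * s * stats::runif(1, 0.95, 1.05)
  discCx <- s * stats::runif(1, 0.20, 0.24)
  discCy <- s * stats::runif(1, 0.47, 0.53)
  a <- dd / 2 * stats::runif(1, 0.95, 1.05)  # semi-axes; near-circular
  b <- dd / 2
  disc <- boundingBoxes(discCx - a, discCy - b, discCx + a, discCy + b,
                        category = "optic_disc")
  ddAct <- discDiameter(disc)
  macCx <- discCx + 2.5 * ddAct
  macCy <- discCy + s * stats::runif(1, -0.02, 0.02)
  ma <- 0.45 * ddAct / 2 * c(1, 1)
  mac <- boundingBoxes(macCx - ma[1L], macCy - ma[2L],
                       macCx + ma[1L], macCy + ma[2L], category = "macula")
  list(size = s, center = c(s, s) / 2, fundusR = 0.48 * s,
       disc = disc, mac = mac, dd = ddAct,
       macCenter = maculaCenter(mac))
}

.boxInsideCircle <- function(box, center, radius) {
  xs <- box[c(1L, 3L, 1L, 3L)]; ys <- box[c(2L, 2L, 4L, 4L)]
  all(sqrt((xs - center[1L])^2 + (ys - center[2L])^2) <= radius)
}

.placeLesions <- function(layout, params, isDme) {
  k <- sample(seq(params@heCountRange[1L], params@heCountRange[2L]), 1L)
  ## DME presents as an exudate cluster near the macula: 2-3 lesions
  ## inside the 1DD circle (subject to the configured maximum)
  kNear <- if (isDme) max(1L, min(sample(2:3, 1L),
                                  params@heCountRange[2L])) else 0L
  if (isDme) k <- max(k, kNear)
  if (k == 0L) return(boundingBoxes())
  placed <- matrix(numeric(), 0L, 4L)
  obstacles <- rbind(boxCoords(layout$disc), boxCoords(layout$mac))
  mk <- function(cx, cy) {
    w <- stats::runif(1, params@heSizeRange[1L], params@heSizeRange[2L])
    h <- stats::runif(1, params@heSizeRange[1L], params@heSizeRange[2L])
    c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  }
  ok <- function(box, requireFar) {
    if (!.boxInsideCircle(box, layout$center, 0.95 * layout$fundusR))
      return(FALSE)
    if (any(boxIoU(matrix(box, 1L), obstacles) > 0)) return(FALSE)
    if (nrow(placed) && any(boxIoU(matrix(box, 1L), placed) > 0.3))
      return(FALSE)
    if (requireFar &&
        pointBoxDistance(layout$macCenter, box) <= 2.0 * layout$dd)
      return(FALSE)
    TRUE
  }
  for (i in seq_len(k)) {
    near <- isDme && i <= kNear
    for (try in 1:200) {
      if (near) {
        r <- stats::runif(1, 0.2, 0.55) * layout$dd
        th <- stats::runif(1, 0, 2 * pi)
        box <- mk(layout$macCenter[1L] + r * cos(th),
                  layout$macCenter[2L] + r * sin(th))
      } else {
        r <- layout$fundusR * 0.9 * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        box <- mk(layout$center[1L] + r * cos(th),
                  layout$center[2L] + r * sin(th))
      }
      if (ok(box, requireFar = !near)) {
        placed <- rbind(placed, box)
        break
      }
    }
  }
  if (nrow(placed) == 0L && isDme)
    stop("infeasible lesion placement: image too small for the geometry")
  if (nrow(placed) == 0L) return(boundingBoxes())
  boundingBoxes(placed[, 1L], placed[, 2L], placed[, 3L], placed[, 4L])
}

.ellipseMask <- function(X, Y, box) {
  cx <- (box[1L] + box[3L]) / 2; cy <- (box[2L] + box[4L]) / 2
  a <- (box[3L] - box[1L]) / 2; b <- (box[4L] - box[2L]) / 2
  ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1
}

.renderScene <- function(layout, he, params) {
  s <- layout$size
  X <- matrix(seq_len(s) - 0.5, s, s, byrow = TRUE)  # pixel-centre x
  Y <- matrix(seq_len(s) - 0.5, s, s)                # pixel-centre y
  d2 <- (X - layout$center[1L])^2 + (Y - layout$center[2L])^2
  fundus <- d2 <= layout$fundusR^2
  vign <- 1 - 0.30 * d2 / layout$fundusR^2
  base <- list(c(0.55, 0.28, 0.10), c(0.97, 0.88, 0.55),
               c(0.32, 0.12, 0.05), c(0.98, 0.95, 0.75))
  px <- array(0.02, c(s, s, 3L))
  discM <- .ellipseMask(X, Y, boxCoords(layout$disc)[1L, ])
  macM <- .ellipseMask(X, Y, boxCoords(layout$mac)[1L, ])
  heM <- matrix(FALSE, s, s)
  if (length(he) > 0L) {
    co <- boxCoords(he)
    for (i in seq_len(nrow(co))) heM <- heM | .ellipseMask(X, Y, co[i, ])
  }
  for (ch in 1:3) {
    layer <- px[, , ch]
    layer[fundus] <- base[[1L]][ch] * vign[fundus]
    layer[discM] <- base[[2L]][ch]
    layer[macM] <- base[[3L]][ch]
    layer[heM] <- base[[4L]][ch]
    px[, , ch] <- layer
  }
  if (params@backgroundNoiseSd > 0)
    px <- px + array(stats::rnorm(length(px), 0, params@backgroundNoiseSd),
                     dim(px))
  px[px < 0] <- 0; px[px > 1] <- 1
  px
}

#' Generate one synthetic fundus scene with exact ground truth
#'
#' @param params a [GeneratorParams-class].
#' @param rngSeed integer seed (bit-identical output on repeated calls
#'   with the same seed); `NULL` draws from the current RNG stream.
#' @param imageId identifier for the scene.
#' @param render if `FALSE`, only the geometric truth is produced
#'   (`image` is `NULL`), which is much faster for rule-level studies.
#' @return `list(image, truth)` with a [FundusImage-class] (or `NULL`)
#'   and a [SceneTruth-class] whose `dmeLabel` satisfies [dmeRule()]
#'   exactly.
#' @export
generateScene <- function(params = generatorParams(), rngSeed = NULL,
                          imageId = "scene", render = TRUE) {
  stopifnot(is(params, "GeneratorParams"))
  .withSeed(rngSeed, {
    layout <- .sceneLayout(params)
    isDme <- stats::runif(1) < params@dmePrevalence &&
      params@heCountRange[2L] > 0L
    he <- .placeLesions(layout, params, isDme)
    label <- dmeRule(he, layout$disc, layout$mac)
    truth <- sceneTruth(imageId, layout$disc, layout$mac, he, label)
    img <- if (render)
      fundusImage(imageId, .renderScene(layout, he, params)) else NULL
    list(image = img, truth = truth)
  })
}

.clampBox <- function(box, s) {
  x0 <- max(0, min(box[1L], s - 2)); x1 <- min(s, max(box[3L], x0 + 2))
  y0 <- max(0, min(box[2L], s - 2)); y1 <- min(s, max(box[4L], y0 + 2))
  if (x1 - x0 < 2) { m <- (x0 + x1) / 2; x0 <- m - 1; x1 <- m + 1 }
  if (y1 - y0 < 2) { m <- (y0 + y1) / 2; y0 <- m - 1; y1 <- m + 1 }
  c(x0, y0, x1, y1)
}

#' Simulate noisy annotators for a scene
#'
#' Each annotator independently sees every true HE box with Gaussian
#' corner jitter, misses it with probability `annotatorMissRate`, and with
#' probability `annotatorSpuriousRate` adds one spurious box elsewhere in
#' the fundus. Jittered boxes are re-validated to a minimum size of
#' 2 x 2 px.
#'
#' @param truth a [SceneTruth-class].
#' @param params a [GeneratorParams-class] (noise fields are used).
#' @param nAnnotators number of annotators (default 3).
#' @param rngSeed integer seed or `NULL`.
#' @return A list of `nAnnotators` [AnnotationSet-class] objects.
#' @export
simulateAnnotators <- function(truth, params = generatorParams(),
                               nAnnotators = 3L, rngSeed = NULL) {
  stopifnot(is(truth, "SceneTruth"))
  s <- params@imageSize
  .withSeed(rngSeed, {
    lapply(seq_len(nAnnotators), function(a) {
      out <- matrix(numeric(), 0L, 4L)
      if (length(truth@heBoxes) > 0L) {
        co <- boxCoords(truth@heBoxes)
        for (i in seq_len(nrow(co))) {
          if (stats::runif(1) < params@annotatorMissRate) next
          jit <- co[i, ] + stats::rnorm(4L, 0, params@annotatorJitterSd)
          out <- rbind(out, .clampBox(jit, s))
        }
      }
      if (stats::runif(1) < params@annotatorSpuriousRate) {
        r <- 0.85 * 0.48 * s * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        cx <- s / 2 + r * cos(th); cy <- s / 2 + r * sin(th)
        w <- stats::runif(1, params@heSizeRange[1L], params@heSizeRange[2L])
        h <- stats::runif(1, params@heSizeRange[1L], params@heSizeRange[2L])
        out <- rbind(out, .clampBox(c(cx - w / 2, cy - h / 2,
                                      cx + w / 2, cy + h / 2), s))
      }
      boxes <- if (nrow(out)) boundingBoxes(out[, 1L], out[, 2L],
                                            out[, 3L], out[, 4L])
               else boundingBoxes()
      annotationSet(truth@imageId, sprintf("annotator%d", a), boxes)
    })
  })
}

.assignSplits <- function(patientSizes, splitFractions) {
  nSplit <- length(splitFractions)
  splits <- names(splitFractions)
  total <- sum(patientSizes)
  target <- splitFractions * total
  got <- stats::setNames(numeric(nSplit), splits)
  assign <- character(length(patientSizes))
  for (i in seq_along(patientSizes)) {
    deficit <- target - got
    pick <- splits[which.max(deficit)]
    assign[i] <- pick
    got[pick] <- got[pick] + patientSizes[i]
  }
  assign
}

#' Generate a complete synthetic dataset with a patient-level split
#'
#' Synthetic patients own 1-4 images each; the train/validation/test split
#' partitions patients, never images, so no patient spans two splits.
#' Per-image products are the rendered scene, three simulated annotator
#' sets, their consensus ground truth ([consensusGT()]), and the DME
#' label. With `outDir` set, everything is written to disk (PNG images,
#' JSON annotations, CSV labels, JSON manifest); the dataset is also
#' returned invisibly.
#'
#' @param nImages number of images to generate.
#' @param params a [GeneratorParams-class].
#' @param splitFractions named fractions summing to 1
#'   (default `c(train = .7, val = .15, test = .15)`).
#' @param rngSeed integer seed for the whole dataset.
#' @param outDir output directory, or `NULL` for in-memory only.
#' @param render render pixel images (set `FALSE` for truth-only studies).
#' @return (Invisibly) a list with `scenes` (each holding `image`,
#'   `truth`, `annotators`, `consensus`, `split`), `manifest` (seed,
#'   parameters, split tables, config hash) and `labels` (data.frame).
#' @export
generateDataset <- function(nImages, params = generatorParams(),
                            splitFractions = c(train = 0.7, val = 0.15,
                                               test = 0.15),
                            rngSeed = 1L, outDir = NULL, render = TRUE) {
  stopifnot(abs(sum(splitFractions) - 1) < 1e-8)
  if (nImages < length(splitFractions))
    stop("nImages must be at least the number of splits")
  .withSeed(rngSeed, {
    sizes <- integer()
    while (sum(sizes) < nImages)
      sizes <- c(sizes, sample(1:4, 1L))
    sizes[length(sizes)] <- sizes[length(sizes)] -
      (sum(sizes) - nImages)
    sizes <- sizes[sizes > 0L]
    patients <- sprintf("P%05d", seq_along(sizes))
    splitOf <- .assignSplits(sizes, splitFractions)
    scenes <- vector("list", nImages)
    idx <- 0L
    for (p in seq_along(patients)) {
      for (k in seq_len(sizes[p])) {
        idx <- idx + 1L
        id <- sprintf("img%05d", idx)
        sc <- generateScene(params, rngSeed = NULL, imageId = id,
                            render = render)
        sc$truth@patientId <- patients[p]
        ann <- simulateAnnotators(sc$truth, params)
        scenes[[idx]] <- list(image = sc$image, truth = sc$truth,
                              annotators = ann,
                              consensus = consensusGT(ann),
                              split = splitOf[p])
      }
    }
    labels <- data.frame(
      image_id = vapply(scenes, function(s) s$truth@imageId, ""),
      label = vapply(scenes, function(s) s$truth@dmeLabel, 0L),
      patient_id = vapply(scenes, function(s) s$truth@patientId, ""),
      split = vapply(scenes, function(s) s$split, ""),
      stringsAsFactors = FALSE)
    manifest <- list(
      seed = rngSeed,
      n_images = nImages,
      params = .paramsToList(params),
      split_fractions = as.list(splitFractions),
      patients = data.frame(patient_id = patients, split = splitOf,
                            n_images = sizes, stringsAsFactors = FALSE),
      counts = as.list(table(labels$split)))
    manifest$config_hash <- configHash(manifest[c("seed", "n_images",
                                                  "params",
                                                  "split_fractions")])
    ds <- list(scenes = scenes, manifest = manifest, labels = labels)
    if (!is.null(outDir)) .writeDataset(ds, outDir)
    invisible(ds)
  })
}

.paramsToList <- function(params) {
  list(image_size = params@imageSize, dme_prevalence = params@dmePrevalence,
       he_count_range = params@heCountRange,
       he_size_range = params@heSizeRange,
       annotator_jitter_sd = params@annotatorJitterSd,
       annotator_miss_rate = params@annotatorMissRate,
       annotator_spurious_rate = params@annotatorSpuriousRate,
       background_noise_sd = params@backgroundNoiseSd)
}

.writeDataset <- function(ds, outDir) {
  dir.create(file.path(outDir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  for (s in ds$scenes) {
    if (!is.null(s$image))
      writeFundusImage(s$image, file.path(outDir, "images",
                                          paste0(s$truth@imageId, ".png")))
  }
  for (a in 1:3) {
    sets <- lapply(ds$scenes, function(s) s$annotators[[a]])
    writeAnnotations(sets, file.path(outDir,
                                     sprintf("annotator%d.json", a)))
  }
  writeAnnotations(lapply(ds$scenes, `[[`, "consensus"),
                   file.path(outDir, "consensus.json"))
  utils::write.csv(ds$labels, file.path(outDir, "labels.csv"),
                   row.names = FALSE)
  truths <- lapply(ds$scenes, function(s) .truthToList(s$truth))
  jsonlite::write_json(truths, file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(ds$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(NULL)
}
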