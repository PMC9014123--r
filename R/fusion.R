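## The fusion network: one shared convolutional backbone feeding (i) a
## bi-directional feature-pyramid detection head and (ii) a three-layer
## classification head (convolution -> global average pooling -> fully
## connected with dropout), trained jointly by minimising
## E_loss = omegaOb * E_ob + omegaCl * E_cl.

#' Fusion-model configuration
#'
#' @param inputSize square input side in pixels (multiple of 16). The
#'   full-scale configuration uses 640; the desk-scale default is 128.
#' @param baseWidth backbone channel width multiplier.
#' @param fpnWidth channel width of the feature pyramid.
#' @param clsWidth channel width of the classification convolution
#'   (default `8 * baseWidth`).
#' @param pyramidLevels subset of `c(3, 4)` (strides 8 and 16).
#' @param anchorScales anchor side lengths as multiples of the level
#'   stride (3 scales x 1 aspect ratio by default).
#' @param numClasses number of detection categories.
#' @param classes category names, length `numClasses`.
#' @param dropoutRate dropout on the pooled classification features
#'   (default 0.2).
#' @param learningRate initial AdamW learning rate (default 1e-4).
#' @param weightDecay decoupled weight decay (default 0.01).
#' @param batchSize minibatch size (default 16).
#' @param epochs default training epochs.
#' @param rngSeed seed controlling initialisation and training shuffles.
#' @param scoreThreshold,nmsIou inference-time score cut and
#'   non-maximum-suppression IoU (defaults 0.3 and 0.5).
#' @param posIou,negIou anchor-assignment bands: IoU >= `posIou` positive,
#'   < `negIou` negative, in between ignored.
#' @return A validated configuration list.
#' @export
fusionConfig <- function(inputSize = 128, baseWidth = 8, fpnWidth = 16,
                         clsWidth = 8L * baseWidth,
                         pyramidLevels = c(3L, 4L),
                         anchorScales = c(0.8, 1.26, 2.0),
                         numClasses = 1L, classes = "HE",
                         dropoutRate = 0.2, learningRate = 1e-4,
                         weightDecay = 0.01, batchSize = 16L,
                         epochs = 20L, rngSeed = 1L,
                         scoreThreshold = 0.3, nmsIou = 0.5,
                         posIou = 0.5, negIou = 0.4) {
  cfg <- list(inputSize = as.integer(inputSize),
              baseWidth = as.integer(baseWidth),
              fpnWidth = as.integer(fpnWidth),
              clsWidth = as.integer(clsWidth),
              pyramidLevels = sort(as.integer(pyramidLevels)),
              anchorScales = anchorScales,
              numClasses = as.integer(numClasses),
              classes = as.character(classes),
              dropoutRate = dropoutRate, learningRate = learningRate,
              weightDecay = weightDecay, batchSize = as.integer(batchSize),
              epochs = as.integer(epochs), rngSeed = as.integer(rngSeed),
              scoreThreshold = scoreThreshold, nmsIou = nmsIou,
              posIou = posIou, negIou = negIou)
  if (cfg$inputSize %% 16L != 0L || cfg$inputSize < 32L)
    stop("inputSize must be a positive multiple of 16")
  if (!length(cfg$pyramidLevels) ||
      !all(cfg$pyramidLevels %in% c(3L, 4L)))
    stop("pyramidLevels must be a non-empty subset of c(3, 4)")
  if (length(cfg$classes) != cfg$numClasses)
    stop("classes must have length numClasses")
  if (cfg$negIou > cfg$posIou)
    stop("negIou must not exceed posIou")
  cfg
}

#' Probability of the assigned class
#'
#' Returns `p` when the label is DME (1) and `1 - p` otherwise: the
#' probability the classifier assigns to the true class.
#'
#' @param p estimated DME probability in `[0, 1]`.
#' @param label binary 0/1 (1 = DME).
#' @return `p_t` in `[0, 1]`.
#' @export
ptTransform <- function(p, label) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  label <- as.integer(label)
  stopifnot(all(label %in% c(0L, 1L)))
  ifelse(label == 1L, p, 1 - p)
}

#' Classification focal term
#'
#' `E_cl = -alpha * (1 - p_t)^gamma * ln(p_t)` with `p_t` from
#' [ptTransform()], natural logarithm, and `p_t` clamped to
#' `[1e-7, 1 - 1e-7]` for numerical safety. With `gamma = 0, alpha = 1`
#' this reduces to plain cross-entropy.
#'
#' @param p estimated DME probability in `[0, 1]`.
#' @param label binary 0/1.
#' @param fp a [FocalParams-class] (defaults alpha 0.25, gamma 2).
#' @return Non-negative loss value(s).
#' @export
focalTerm <- function(p, label, fp = focalParams()) {
  pt <- ptTransform(p, label)
  pt <- pmin(pmax(pt, 1e-7), 1 - 1e-7)
  -fp@alpha * (1 - pt)^fp@gamma * log(pt)
}

#' Combine detector and classifier losses
#'
#' `E_total = omegaOb * E_ob + omegaCl * E_cl`.
#'
#' @param eOb detector loss value.
#' @param eCl classification focal loss value (`>= 0`).
#' @param w a [LossWeights-class] (defaults 0.5 and 100).
#' @return A list of class `LossBreakdown` with `eOb`, `eCl`, `eTotal`.
#' @export
combinedLoss <- function(eOb, eCl, w = lossWeights()) {
  stopifnot(is(w, "LossWeights"))
  if (eCl < 0) stop("eCl must be non-negative")
  out <- list(eOb = eOb, eCl = eCl,
              eTotal = w@omegaOb * eOb + w@omegaCl * eCl)
  class(out) <- "LossBreakdown"
  out
}

#' @export
print.LossBreakdown <- function(x, ...) {
  cat(sprintf("E_ob = %.6g, E_cl = %.6g, E_loss = %.6g\n",
              x$eOb, x$eCl, x$eTotal))
  invisible(x)
}

## -- anchors ----------------------------------------------------------------

.levelStride <- function(level) 2L^level

.anchorsForLevel <- function(inputSize, level, scales) {
  s <- .levelStride(level)
  g <- inputSize %/% s
  cy <- rep((seq_len(g) - 0.5) * s, times = g)   # position-major, y fastest
  cx <- rep((seq_len(g) - 0.5) * s, each = g)
  out <- lapply(scales, function(sc) {
    half <- s * sc / 2
    cbind(cx - half, cy - half, cx + half, cy + half)
  })
  do.call(rbind, out)  # anchor-scale-major blocks, matching head reshape
}

.anchorSet <- function(config) {
  lv <- config$pyramidLevels
  anchors <- lapply(lv, function(l)
    .anchorsForLevel(config$inputSize, l, config$anchorScales))
  list(levels = lv, perLevel = anchors, all = do.call(rbind, anchors),
       counts = vapply(anchors, nrow, 0L))
}

## Anchor assignment and regression targets for one image.
.detectionTargets <- function(anchors, gtBoxes, gtClasses, numClasses,
                              posIou, negIou) {
  N <- nrow(anchors)
  clsT <- matrix(0, N, numClasses)
  pos <- logical(N)
  neg <- rep(TRUE, N)
  regT <- NULL; posIdx <- integer()
  if (!is.null(gtBoxes) && nrow(gtBoxes) > 0L) {
    iou <- boxIoU(anchors, gtBoxes)
    maxIou <- apply(iou, 1L, max)
    assigned <- max.col(iou, ties.method = "first")
    pos <- maxIou >= posIou
    for (g in seq_len(ncol(iou))) {     # every GT gets its best anchor
      j <- which.max(iou[, g])
      pos[j] <- TRUE
      assigned[j] <- g
    }
    neg <- maxIou < negIou & !pos
    posIdx <- which(pos)
    clsT[cbind(posIdx, gtClasses[assigned[posIdx]])] <- 1
    if (length(posIdx)) {
      a <- anchors[posIdx, , drop = FALSE]
      gt <- gtBoxes[assigned[posIdx], , drop = FALSE]
      aw <- a[, 3L] - a[, 1L]; ah <- a[, 4L] - a[, 2L]
      acx <- (a[, 1L] + a[, 3L]) / 2; acy <- (a[, 2L] + a[, 4L]) / 2
      gw <- gt[, 3L] - gt[, 1L]; gh <- gt[, 4L] - gt[, 2L]
      gcx <- (gt[, 1L] + gt[, 3L]) / 2; gcy <- (gt[, 2L] + gt[, 4L]) / 2
      regT <- cbind((gcx - acx) / aw, (gcy - acy) / ah,
                    log(gw / aw), log(gh / ah))
    }
  }
  list(clsT = clsT, pos = pos, neg = neg, posIdx = posIdx, regT = regT)
}

#' Detector loss on per-anchor predictions
#'
#' Anchor-level sigmoid focal classification loss (conventional
#' `alpha_t` weighting: `alpha` on positives, `1 - alpha` on negatives)
#' plus a Huber regression loss on anchors matched to ground truth,
#' normalised by the matched-anchor count (minimum 1). Anchors in the
#' assignment dead band (`negIou <= IoU < posIou`) contribute nothing.
#' With no ground truth the result is the pure background classification
#' loss.
#'
#' @param clsLogits `N x K` matrix of per-anchor class logits.
#' @param boxPred `N x 4` matrix of per-anchor box offsets
#'   (dx, dy, dw, dh in anchor units).
#' @param anchors `N x 4` anchor corner matrix.
#' @param gtBoxes [BoundingBoxes-class] of ground truth (possibly empty),
#'   or an n x 4 matrix.
#' @param gtClasses integer class indices (1-based) per GT box.
#' @param fp a [FocalParams-class].
#' @param posIou,negIou assignment bands (defaults 0.5 / 0.4).
#' @return The scalar loss `E_ob` (with gradient matrices attached as
#'   attribute `"grads"` for internal reuse).
#' @export
detectorLoss <- function(clsLogits, boxPred, anchors, gtBoxes,
                         gtClasses = NULL, fp = focalParams(),
                         posIou = 0.5, negIou = 0.4) {
  clsLogits <- as.matrix(clsLogits)
  gtM <- if (is(gtBoxes, "BoundingBoxes")) boxCoords(gtBoxes) else
    if (is.null(gtBoxes)) matrix(numeric(), 0L, 4L) else as.matrix(gtBoxes)
  if (is.null(gtClasses)) gtClasses <- rep(1L, nrow(gtM))
  tg <- .detectionTargets(anchors, gtM, gtClasses, ncol(clsLogits),
                          posIou, negIou)
  .detectorLossGrad(clsLogits, boxPred, tg, fp)$eOb
}

.detectorLossGrad <- function(clsLogits, boxPred, tg, fp) {
  valid <- tg$pos | tg$neg
  K <- ncol(clsLogits)
  dCls <- matrix(0, nrow(clsLogits), K)
  flSum <- 0
  if (any(valid)) {
    L <- clsLogits[valid, , drop = FALSE]
    Tt <- tg$clsT[valid, , drop = FALSE]
    alphaT <- ifelse(Tt == 1, fp@alpha, 1 - fp@alpha)
    fg <- .focalGrad(L, Tt, alphaT, fp@gamma)
    flSum <- sum(fg$loss)
    dCls[valid, ] <- fg$dlogit
  }
  dBox <- matrix(0, nrow(boxPred), 4L)
  huberSum <- 0
  if (length(tg$posIdx)) {
    r <- boxPred[tg$posIdx, , drop = FALSE] - tg$regT
    huberSum <- sum(ifelse(abs(r) < 1, 0.5 * r^2, abs(r) - 0.5))
    dBox[tg$posIdx, ] <- pmin(pmax(r, -1), 1)
  }
  npos <- max(1L, length(tg$posIdx))
  list(eOb = (flSum + huberSum) / npos, dCls = dCls / npos,
       dBox = dBox / npos, nPos = length(tg$posIdx))
}

## -- model construction -----------------------------------------------------

#' Build a fusion, detector-only or classifier-only model
#'
#' The fusion model shares one backbone between a bi-directional
#' feature-pyramid detection path and a classification path of exactly
#' one convolution, one global average pooling and one fully connected
#' layer with dropout. `task = "detector"` and `task = "classifier"`
#' build the corresponding single-task models of the dual baseline using
#' identical components, so parameter counts are directly comparable.
#' Initialisation is deterministic in `config$rngSeed`.
#'
#' @param config a [fusionConfig()] list.
#' @param task `"fusion"` (default), `"detector"` or `"classifier"`.
#' @return A [FusionModel-class].
#' @export
buildFusion <- function(config = fusionConfig(),
                        task = c("fusion", "detector", "classifier")) {
  task <- match.arg(task)
  w <- config$baseWidth; d <- config$fpnWidth
  A <- length(config$anchorScales); K <- config$numClasses
  set.seed(config$rngSeed)
  p <- list(
    conv1 = .convParam(3L, 3L, w),
    conv2 = .convParam(3L, w, 2L * w),
    conv3 = .convParam(3L, 2L * w, 4L * w),
    conv4 = .convParam(3L, 4L * w, 4L * w))
  if (task %in% c("fusion", "detector")) {
    twoLv <- length(config$pyramidLevels) == 2L
    p$lat3 <- if (3L %in% config$pyramidLevels)
      .convParam(1L, 4L * w, d) else NULL
    p$lat4 <- if (4L %in% config$pyramidLevels)
      .convParam(1L, 4L * w, d) else NULL
    p$td3 <- if (3L %in% config$pyramidLevels) .convParam(3L, d, d)
    p$bu4 <- if (4L %in% config$pyramidLevels) .convParam(3L, d, d)
    if (twoLv) {
      p$fwTd <- c(1, 1)
      p$fwBu <- c(1, 1)
    }
    p$head <- .convParam(3L, d, d)
    ## rare-foreground prior on the classification bias stabilises the
    ## focal loss early in training
    p$cls <- .convParam(3L, d, A * K, biasInit = stats::qlogis(0.01))
    p$boxr <- .convParam(3L, d, 4L * A)
  }
  if (task %in% c("fusion", "classifier")) {
    cw <- config$clsWidth
    ## in the fusion model the classification convolution reads the
    ## shared trunk output: top backbone feature concatenated with the
    ## matching pyramid level (both derive from the single backbone);
    ## the standalone classifier reads the backbone top alone
    clsIn <- 4L * w + if (task == "fusion" &&
                          4L %in% config$pyramidLevels) d else 0L
    p$ccv <- .convParam(3L, clsIn, cw)
    p$cfcW <- matrix(stats::rnorm(cw, 0, sqrt(1 / cw)), cw, 1L)
    p$cfcb <- 0
    ## running per-feature statistics of the pooled vector
    ## (batch-normalisation semantics; updated by EMA during training,
    ## fixed at inference; not touched by the optimizer)
    p$bnMu <- rep(0, cw)
    p$bnVar <- rep(1, cw)
  }
  p <- p[!vapply(p, is.null, TRUE)]
  new("FusionModel", config = config, params = p, task = task)
}

#' Total trainable parameter count of a model
#'
#' @param model a [FusionModel-class].
#' @return Integer parameter count.
#' @export
countParams <- function(model) {
  pp <- model@params[setdiff(names(model@params), c("bnMu", "bnVar"))]
  sum(vapply(pp, function(x) {
    if (is.list(x)) length(x$W) + length(x$b) else length(x)
  }, 0))
}

## -- forward / backward -----------------------------------------------------

.fusionForward <- function(model, x, train = FALSE) {
  p <- model@params
  cfg <- model@config
  fw <- list()
  x <- x - 0.5                                # centre the intensities
  c1 <- .convForward(x, p$conv1, 2L, 1L);  a1 <- pmax(c1$y, 0)
  c2 <- .convForward(a1, p$conv2, 2L, 1L); a2 <- pmax(c2$y, 0)
  c3 <- .convForward(a2, p$conv3, 2L, 1L); a3 <- pmax(c3$y, 0)
  c4 <- .convForward(a3, p$conv4, 2L, 1L); a4 <- pmax(c4$y, 0)
  fw[c("c1", "c2", "c3", "c4")] <- list(c1, c2, c3, c4)
  fw[c("a1", "a2", "a3", "a4")] <- list(a1, a2, a3, a4)
  if (model@task %in% c("fusion", "detector")) {
    twoLv <- length(cfg$pyramidLevels) == 2L
    P <- list()
    if (twoLv) {
      l3 <- .convForward(a3, p$lat3, 1L, 0L)
      l4 <- .convForward(a4, p$lat4, 1L, 0L)
      u4 <- .upsample2(l4$y)
      wt <- pmax(p$fwTd, 0); st <- sum(wt) + 1e-4
      m3 <- (wt[1L] * l3$y + wt[2L] * u4) / st
      t3 <- .convForward(m3, p$td3, 1L, 1L); p3 <- pmax(t3$y, 0)
      d3 <- .avgpool2(p3)
      wb <- pmax(p$fwBu, 0); sb <- sum(wb) + 1e-4
      m4 <- (wb[1L] * l4$y + wb[2L] * d3) / sb
      b4 <- .convForward(m4, p$bu4, 1L, 1L); p4 <- pmax(b4$y, 0)
      fw[c("l3", "l4", "u4", "m3", "t3", "p3", "d3", "m4", "b4", "p4")] <-
        list(l3, l4, u4, m3, t3, p3, d3, m4, b4, p4)
      P <- list(p3, p4)
    } else if (cfg$pyramidLevels == 3L) {
      l3 <- .convForward(a3, p$lat3, 1L, 0L)
      t3 <- .convForward(l3$y, p$td3, 1L, 1L); p3 <- pmax(t3$y, 0)
      fw[c("l3", "t3", "p3")] <- list(l3, t3, p3)
      P <- list(p3)
    } else {
      l4 <- .convForward(a4, p$lat4, 1L, 0L)
      b4 <- .convForward(l4$y, p$bu4, 1L, 1L); p4 <- pmax(b4$y, 0)
      fw[c("l4", "b4", "p4")] <- list(l4, b4, p4)
      P <- list(p4)
    }
    fw$det <- lapply(P, function(Pl) {
      hc <- .convForward(Pl, p$head, 1L, 1L)
      h <- pmax(hc$y, 0)
      clc <- .convForward(h, p$cls, 1L, 1L)
      bxc <- .convForward(h, p$boxr, 1L, 1L)
      list(hc = hc, h = h, clc = clc, bxc = bxc)
    })
  }
  if (model@task %in% c("fusion", "classifier")) {
    clsIn <- a4
    if (model@task == "fusion" && !is.null(fw$p4)) {
      clsIn <- array(c(a4, fw$p4), c(dim(a4)[1:2],
                                     dim(a4)[3L] + dim(fw$p4)[3L]))
    }
    fw$clsIn <- clsIn
    c7 <- .convForward(clsIn, p$ccv, 1L, 1L); a7 <- pmax(c7$y, 0)
    g <- colMeans(matrix(a7, prod(dim(a7)[1:2]), dim(a7)[3L]))
    ## standardise each pooled feature by its running statistics: the
    ## read-out gradient then reflects between-class contrast instead of
    ## being dominated by the overall feature mean under class imbalance
    sdv <- sqrt(p$bnVar + 1e-5)
    z <- (g - p$bnMu) / sdv
    mask <- if (train && cfg$dropoutRate > 0) {
      (stats::runif(length(g)) >= cfg$dropoutRate) / (1 - cfg$dropoutRate)
    } else rep(1, length(g))
    gd <- z * mask
    logit <- sum(gd * p$cfcW[, 1L]) + p$cfcb
    fw[c("c7", "a7", "g", "sdv", "mask", "gd", "logit")] <-
      list(c7, a7, g, sdv, mask, gd, logit)
    fw$prob <- stats::plogis(logit)
  }
  fw
}

## Reshape a head output array (g, g, A*C) into a per-anchor matrix
## (g*g*A, C) whose row order matches .anchorsForLevel.
.headToAnchorMatrix <- function(arr, A, C) {
  g2 <- prod(dim(arr)[1:2])
  M <- matrix(arr, g2, A * C)
  do.call(rbind, lapply(seq_len(A), function(a)
    M[, (a - 1L) * C + seq_len(C), drop = FALSE]))
}

.anchorMatrixToHead <- function(mat, g, A, C) {
  M <- matrix(0, g * g, A * C)
  for (a in seq_len(A)) {
    M[, (a - 1L) * C + seq_len(C)] <-
      mat[(a - 1L) * g * g + seq_len(g * g), , drop = FALSE]
  }
  array(M, c(g, g, A * C))
}

## Full backward pass. grads: list(dDet = list per level of
## list(dCls array, dBox array) or NULL, dLogit scalar or NULL).
.fusionBackward <- function(model, fw, grads) {
  p <- model@params
  cfg <- model@config
  gr <- list()
  zeroLike <- function(a) array(0, dim(a))
  da3 <- zeroLike(fw$a3); da4 <- zeroLike(fw$a4)

  dP4cls <- NULL
  if (!is.null(grads$dLogit) && model@task %in% c("fusion", "classifier")) {
    dl <- grads$dLogit
    gr$cfcW <- matrix(fw$gd * dl, ncol = 1L)
    gr$cfcb <- dl
    dg <- p$cfcW[, 1L] * dl * fw$mask / fw$sdv
    d <- dim(fw$a7); hw <- prod(d[1:2])
    da7 <- array(rep(dg / hw, each = hw), d)
    dz7 <- da7 * (fw$c7$y > 0)
    cb <- .convBackward(dz7, p$ccv, fw$c7)
    gr$ccv <- cb[c("dW", "db")]
    nb <- dim(fw$a4)[3L]
    if (dim(cb$dx)[3L] > nb) {       # fusion: split trunk/pyramid parts
      da4 <- da4 + cb$dx[, , seq_len(nb), drop = FALSE]
      dP4cls <- cb$dx[, , (nb + 1L):dim(cb$dx)[3L], drop = FALSE]
    } else da4 <- da4 + cb$dx
  }

  if ((!is.null(grads$dDet) || !is.null(dP4cls)) &&
      model@task %in% c("fusion", "detector")) {
    twoLv <- length(cfg$pyramidLevels) == 2L
    accum <- function(a, b) if (is.null(a)) b else
      list(dW = a$dW + b$dW, db = a$db + b$db)
    hG <- clsG <- boxG <- NULL
    dP <- vector("list", length(fw$det))
    for (li in seq_along(fw$det)) {
      dt <- fw$det[[li]]
      if (!is.null(grads$dDet)) {
        gl <- grads$dDet[[li]]
        cbC <- .convBackward(gl$dCls, p$cls, dt$clc)
        cbB <- .convBackward(gl$dBox, p$boxr, dt$bxc)
        clsG <- accum(clsG, cbC[c("dW", "db")])
        boxG <- accum(boxG, cbB[c("dW", "db")])
        dh <- (cbC$dx + cbB$dx) * (dt$hc$y > 0)
        cbH <- .convBackward(dh, p$head, dt$hc)
        hG <- accum(hG, cbH[c("dW", "db")])
        dP[[li]] <- cbH$dx
      } else {
        dP[[li]] <- array(0, c(dim(dt$h)[1:2], cfg$fpnWidth))
      }
    }
    if (!is.null(grads$dDet)) {
      gr$cls <- clsG; gr$boxr <- boxG; gr$head <- hG
    }
    if (!is.null(dP4cls)) {
      i4 <- which(cfg$pyramidLevels == 4L)
      dP[[i4]] <- dP[[i4]] + dP4cls
    }
    if (twoLv) {
      wt <- pmax(p$fwTd, 0); st <- sum(wt) + 1e-4
      wb <- pmax(p$fwBu, 0); sb <- sum(wb) + 1e-4
      dz6 <- dP[[2L]] * (fw$b4$y > 0)
      cb6 <- .convBackward(dz6, p$bu4, fw$b4)
      gr$bu4 <- cb6[c("dW", "db")]
      dm4 <- cb6$dx
      dl4 <- dm4 * wb[1L] / sb
      dd3 <- dm4 * wb[2L] / sb
      dub <- c(sum(dm4 * (fw$l4$y - fw$m4)) / sb,
               sum(dm4 * (fw$d3 - fw$m4)) / sb)
      gr$fwBu <- dub * (p$fwBu > 0)
      dp3 <- dP[[1L]] + .avgpool2Back(dd3)
      dz5 <- dp3 * (fw$t3$y > 0)
      cb5 <- .convBackward(dz5, p$td3, fw$t3)
      gr$td3 <- cb5[c("dW", "db")]
      dm3 <- cb5$dx
      dl3 <- dm3 * wt[1L] / st
      du4 <- dm3 * wt[2L] / st
      dut <- c(sum(dm3 * (fw$l3$y - fw$m3)) / st,
               sum(dm3 * (fw$u4 - fw$m3)) / st)
      gr$fwTd <- dut * (p$fwTd > 0)
      dl4 <- dl4 + .upsample2Back(du4)
      cb3 <- .convBackward(dl3, p$lat3, fw$l3)
      gr$lat3 <- cb3[c("dW", "db")]
      da3 <- da3 + cb3$dx
      cb4 <- .convBackward(dl4, p$lat4, fw$l4)
      gr$lat4 <- cb4[c("dW", "db")]
      da4 <- da4 + cb4$dx
    } else if (cfg$pyramidLevels == 3L) {
      dz5 <- dP[[1L]] * (fw$t3$y > 0)
      cb5 <- .convBackward(dz5, p$td3, fw$t3)
      gr$td3 <- cb5[c("dW", "db")]
      cb3 <- .convBackward(cb5$dx, p$lat3, fw$l3)
      gr$lat3 <- cb3[c("dW", "db")]
      da3 <- da3 + cb3$dx
    } else {
      dz6 <- dP[[1L]] * (fw$b4$y > 0)
      cb6 <- .convBackward(dz6, p$bu4, fw$b4)
      gr$bu4 <- cb6[c("dW", "db")]
      cb4 <- .convBackward(cb6$dx, p$lat4, fw$l4)
      gr$lat4 <- cb4[c("dW", "db")]
      da4 <- da4 + cb4$dx
    }
  }

  dz4 <- da4 * (fw$c4$y > 0)
  cb4b <- .convBackward(dz4, p$conv4, fw$c4)
  gr$conv4 <- cb4b[c("dW", "db")]
  da3 <- da3 + cb4b$dx
  dz3 <- da3 * (fw$c3$y > 0)
  cb3b <- .convBackward(dz3, p$conv3, fw$c3)
  gr$conv3 <- cb3b[c("dW", "db")]
  dz2 <- cb3b$dx * (fw$c2$y > 0)
  cb2b <- .convBackward(dz2, p$conv2, fw$c2)
  gr$conv2 <- cb2b[c("dW", "db")]
  dz1 <- cb2b$dx * (fw$c1$y > 0)
  cb1b <- .convBackward(dz1, p$conv1, fw$c1, needDx = FALSE)
  gr$conv1 <- cb1b[c("dW", "db")]
  gr
}

## Per-anchor matrices of the detection outputs across levels.
.detOutputs <- function(model, fw, anchorSet) {
  A <- length(model@config$anchorScales)
  K <- model@config$numClasses
  cls <- list(); box <- list()
  for (li in seq_along(fw$det)) {
    cls[[li]] <- .headToAnchorMatrix(fw$det[[li]]$clc$y, A, K)
    box[[li]] <- .headToAnchorMatrix(fw$det[[li]]$bxc$y, A, 4L)
  }
  list(cls = do.call(rbind, cls), box = do.call(rbind, box))
}

## Split per-anchor gradient matrices back into per-level head arrays.
.detGradsToLevels <- function(model, dCls, dBox, anchorSet) {
  A <- length(model@config$anchorScales)
  K <- model@config$numClasses
  out <- list(); off <- 0L
  for (li in seq_along(anchorSet$perLevel)) {
    n <- anchorSet$counts[li]
    g <- as.integer(sqrt(n / A))
    out[[li]] <- list(
      dCls = .anchorMatrixToHead(dCls[off + seq_len(n), , drop = FALSE],
                                 g, A, K),
      dBox = .anchorMatrixToHead(dBox[off + seq_len(n), , drop = FALSE],
                                 g, A, 4L))
    off <- off + n
  }
  out
}

.decodeBoxes <- function(anchors, offsets, inputSize) {
  aw <- anchors[, 3L] - anchors[, 1L]; ah <- anchors[, 4L] - anchors[, 2L]
  acx <- (anchors[, 1L] + anchors[, 3L]) / 2
  acy <- (anchors[, 2L] + anchors[, 4L]) / 2
  cx <- acx + offsets[, 1L] * aw
  cy <- acy + offsets[, 2L] * ah
  w <- aw * exp(pmin(offsets[, 3L], 4))
  h <- ah * exp(pmin(offsets[, 4L], 4))
  x0 <- pmax(0, cx - w / 2); y0 <- pmax(0, cy - h / 2)
  x1 <- pmin(inputSize, cx + w / 2); y1 <- pmin(inputSize, cy + h / 2)
  cbind(x0, y0, x1, y1)
}

.nms <- function(boxes, scores, iouThr) {
  keep <- integer()
  ord <- order(-scores)
  while (length(ord)) {
    i <- ord[1L]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    rest <- ord[-1L]
    ious <- boxIoU(boxes[i, , drop = FALSE], boxes[rest, , drop = FALSE])
    ord <- rest[ious[1L, ] <= iouThr]
  }
  keep
}

#' Run the fusion model on one image
#'
#' A single forward pass of the shared backbone produces both the
#' detection output (score-thresholded, non-maximum-suppressed boxes)
#' and the DME probability. Inference is deterministic (dropout off).
#'
#' @param model a [FusionModel-class].
#' @param img a [FundusImage-class] or `H x W x 3` array whose side
#'   equals `config$inputSize`.
#' @return `list(boxes, classification)`: scored, categorised
#'   [BoundingBoxes-class] detections and the probability `p` (or `NULL`
#'   for a detector-only model).
#' @export
forwardFusion <- function(model, img) {
  px <- if (is(img, "FundusImage")) img@pixels else img
  S <- model@config$inputSize
  if (!all(dim(px) == c(S, S, 3L)))
    stop("input image must be ", S, " x ", S, " x 3 ",
         "(use cropAndResize first)")
  fw <- .fusionForward(model, px, train = FALSE)
  boxes <- boundingBoxes()
  if (model@task %in% c("fusion", "detector")) {
    aset <- .anchorSet(model@config)
    out <- .detOutputs(model, fw, aset)
    scores <- stats::plogis(out$cls)
    K <- model@config$numClasses
    keepAll <- list()
    for (k in seq_len(K)) {
      sel <- which(scores[, k] > model@config$scoreThreshold)
      if (!length(sel)) next
      dec <- .decodeBoxes(aset$all[sel, , drop = FALSE],
                          out$box[sel, , drop = FALSE], S)
      okBox <- dec[, 3L] - dec[, 1L] > 1e-6 & dec[, 4L] - dec[, 2L] > 1e-6
      dec <- dec[okBox, , drop = FALSE]
      sc <- scores[sel, k][okBox]
      if (!nrow(dec)) next
      ki <- .nms(dec, sc, model@config$nmsIou)
      keepAll[[length(keepAll) + 1L]] <- boundingBoxes(
        dec[ki, 1L], dec[ki, 2L], dec[ki, 3L], dec[ki, 4L],
        score = sc[ki], category = model@config$classes[k])
    }
    if (length(keepAll)) boxes <- do.call(combineBoxes, keepAll)
  }
  list(boxes = boxes,
       classification = if (model@task %in% c("fusion", "classifier"))
         fw$prob else NULL)
}

## -- training ---------------------------------------------------------------

.adamwInit <- function(params) {
  flat <- function(pp) if (is.list(pp)) list(W = pp$W * 0, b = pp$b * 0)
    else pp * 0
  list(m = lapply(params, flat), v = lapply(params, flat), t = 0L)
}

.adamwStep <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    w <- w - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + wd * w)
    list(w = w, m = m, v = v)
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.list(params[[nm]])) {
      uW <- upd(params[[nm]]$W, g$dW, state$m[[nm]]$W, state$v[[nm]]$W)
      ub <- upd(params[[nm]]$b, g$db, state$m[[nm]]$b, state$v[[nm]]$b)
      params[[nm]]$W <- uW$w; state$m[[nm]]$W <- uW$m
      state$v[[nm]]$W <- uW$v
      params[[nm]]$b <- ub$w; state$m[[nm]]$b <- ub$m
      state$v[[nm]]$b <- ub$v
    } else {
      u <- upd(params[[nm]], g, state$m[[nm]], state$v[[nm]])
      params[[nm]] <- u$w; state$m[[nm]] <- u$m; state$v[[nm]] <- u$v
    }
  }
  list(params = params, state = state)
}

.accumGrads <- function(total, gr) {
  if (is.null(total)) return(gr)
  for (nm in names(gr)) {
    if (is.null(total[[nm]])) { total[[nm]] <- gr[[nm]]; next }
    if (is.list(gr[[nm]])) {
      total[[nm]]$dW <- total[[nm]]$dW + gr[[nm]]$dW
      total[[nm]]$db <- total[[nm]]$db + gr[[nm]]$db
    } else total[[nm]] <- total[[nm]] + gr[[nm]]
  }
  total
}

.scaleGrads <- function(gr, f) {
  lapply(gr, function(g) {
    if (is.list(g)) list(dW = g$dW * f, db = g$db * f) else g * f
  })
}

## Loss and parameter gradients for one image. item: list(pixels, gtM,
## gtClasses, label, targets).
.imageLossGrad <- function(model, item, w, fp, train = TRUE,
                           needGrad = TRUE) {
  fw <- .fusionForward(model, item$pixels, train = train)
  eOb <- 0; eCl <- 0
  grads <- list(dDet = NULL, dLogit = NULL)
  detG <- NULL
  if (model@task %in% c("fusion", "detector")) {
    aset <- .anchorSet(model@config)
    out <- .detOutputs(model, fw, aset)
    dl <- .detectorLossGrad(out$cls, out$box, item$targets, fp)
    eOb <- dl$eOb
    if (needGrad)
      grads$dDet <- .detGradsToLevels(model, dl$dCls * w@omegaOb,
                                      dl$dBox * w@omegaOb, aset)
  }
  if (model@task %in% c("fusion", "classifier")) {
    fg <- .focalGrad(fw$logit, item$label, fp@alpha, fp@gamma)
    eCl <- fg$loss
    if (needGrad) grads$dLogit <- fg$dlogit * w@omegaCl
  }
  gr <- if (needGrad) .fusionBackward(model, fw, grads) else NULL
  list(eOb = eOb, eCl = eCl,
       eTotal = w@omegaOb * eOb + w@omegaCl * eCl, grads = gr,
       g = fw$g)
}

.flipBoxM <- function(gtM, S, horizontal, vertical) {
  if (nrow(gtM) == 0L) return(gtM)
  if (horizontal) gtM <- cbind(S - gtM[, 3L], gtM[, 2L],
                               S - gtM[, 1L], gtM[, 4L])
  if (vertical) gtM <- cbind(gtM[, 1L], S - gtM[, 4L],
                             gtM[, 3L], S - gtM[, 2L])
  gtM
}

.flipPixels <- function(px, horizontal, vertical) {
  d <- dim(px)
  if (horizontal) px <- px[, d[2L]:1, , drop = FALSE]
  if (vertical) px <- px[d[1L]:1, , , drop = FALSE]
  px
}

## Precompute anchors targets for the image and (for augmentation) its
## three flipped variants; variants are indexed h + 2v + 1.
.prepareItem <- function(model, scene, aset, augment = FALSE) {
  img <- scene$image
  px <- if (is(img, "FundusImage")) img@pixels else img
  S <- model@config$inputSize
  boxes <- scene$boxes
  gtM <- if (is(boxes, "BoundingBoxes")) boxCoords(boxes) else
    if (is.null(boxes)) matrix(numeric(), 0L, 4L) else as.matrix(boxes)
  gtClasses <- if (is(boxes, "BoundingBoxes") && length(boxes))
    match(boxes@category, model@config$classes) else rep(1L, nrow(gtM))
  if (anyNA(gtClasses))
    stop("ground-truth category not covered by config$classes")
  mkTargets <- function(m) {
    if (length(aset$all) == 0L) return(NULL)
    .detectionTargets(aset$all, m, gtClasses, model@config$numClasses,
                      model@config$posIou, model@config$negIou)
  }
  variants <- if (augment) {
    lapply(0:3, function(v) {
      h <- v %% 2L == 1L; vv <- v %/% 2L == 1L
      mkTargets(.flipBoxM(gtM, S, h, vv))
    })
  } else list(mkTargets(gtM))
  list(pixels = px, label = as.integer(scene$label),
       targets = variants[[1L]], targetVariants = variants)
}

#' Train a fusion (or single-task) model
#'
#' Joint minimisation of `E_loss = omegaOb * E_ob + omegaCl * E_cl` by
#' AdamW over shuffled minibatches; `E_cl` is averaged over the batch.
#' Per-epoch training (and optionally validation) values of both loss
#' terms are recorded so over/underfitting can be inspected. Training is
#' reproducible on CPU: shuffling, dropout and initialisation all derive
#' from `config$rngSeed`.
#'
#' @param model a [FusionModel-class] from [buildFusion()].
#' @param dataset a list of scenes, each
#'   `list(image, boxes, label)` with the image already at the model
#'   input size, `boxes` the consensus GT [BoundingBoxes-class] in input
#'   coordinates, and `label` the binary DME label.
#' @param w a [LossWeights-class]; default (0.5, 100).
#' @param fp a [FocalParams-class]; default (0.25, 2).
#' @param epochs number of epochs (default from config).
#' @param valData optional held-out list in the same format.
#' @param augment apply random horizontal/vertical flip augmentation to
#'   each training image at every epoch (default `TRUE`); the flip is
#'   applied consistently to pixels and ground-truth boxes, and leaves
#'   the image-level label unchanged.
#' @param verbose print per-epoch losses.
#' @return `list(model, history)` with `history` a data.frame of
#'   per-epoch loss terms.
#' @export
trainFusion <- function(model, dataset, w = lossWeights(),
                        fp = focalParams(), epochs = NULL, valData = NULL,
                        augment = TRUE, verbose = FALSE) {
  stopifnot(is(model, "FusionModel"), is(w, "LossWeights"),
            is(fp, "FocalParams"))
  if (!length(dataset)) stop("empty training dataset")
  cfg <- model@config
  if (is.null(epochs)) epochs <- cfg$epochs
  aset <- if (model@task %in% c("fusion", "detector"))
    .anchorSet(cfg) else list(all = matrix(numeric(), 0L, 4L))
  items <- lapply(dataset, .prepareItem, model = model, aset = aset,
                  augment = augment)
  valItems <- if (!is.null(valData))
    lapply(valData, .prepareItem, model = model, aset = aset)
  params <- model@params
  state <- .adamwInit(params)
  set.seed(cfg$rngSeed + 1L)
  n <- length(items)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    sums <- c(eOb = 0, eCl = 0)
    for (start in seq(1L, n, by = cfg$batchSize)) {
      bidx <- ord[start:min(start + cfg$batchSize - 1L, n)]
      bN <- length(bidx)
      model@params <- params
      total <- NULL
      gs <- list()
      for (i in bidx) {
        it <- items[[i]]
        if (augment) {
          h <- stats::runif(1) < 0.5; v <- stats::runif(1) < 0.5
          if (h || v) {
            it$pixels <- .flipPixels(it$pixels, h, v)
            it$targets <- it$targetVariants[[h + 2L * v + 1L]]
          }
        }
        r <- .imageLossGrad(model, it, w, fp, train = TRUE)
        sums <- sums + c(r$eOb, r$eCl)
        total <- .accumGrads(total, r$grads)
        if (!is.null(r$g)) gs[[length(gs) + 1L]] <- r$g
      }
      total <- .scaleGrads(total, 1 / bN)
      st <- .adamwStep(params, total, state, cfg$learningRate,
                       cfg$weightDecay)
      params <- st$params; state <- st$state
      for (gv in gs) {   # EMA update of the pooled-feature statistics
        params$bnMu <- 0.99 * params$bnMu + 0.01 * gv
        params$bnVar <- 0.99 * params$bnVar +
          0.01 * (gv - params$bnMu)^2
      }
    }
    model@params <- params
    row <- data.frame(epoch = ep, e_ob = sums[["eOb"]] / n,
                      e_cl = sums[["eCl"]] / n)
    row$e_total <- w@omegaOb * row$e_ob + w@omegaCl * row$e_cl
    if (!is.null(valItems)) {
      vs <- c(0, 0)
      for (it in valItems) {
        r <- .imageLossGrad(model, it, w, fp, train = FALSE,
                            needGrad = FALSE)
        vs <- vs + c(r$eOb, r$eCl)
      }
      row$val_e_ob <- vs[1L] / length(valItems)
      row$val_e_cl <- vs[2L] / length(valItems)
      row$val_e_total <- w@omegaOb * row$val_e_ob + w@omegaCl * row$val_e_cl
    }
    hist[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %d: E_ob %.4f E_cl %.4f E_loss %.4f",
                      ep, row$e_ob, row$e_cl, row$e_total))
  }
  list(model = model, history = do.call(rbind, hist))
}
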