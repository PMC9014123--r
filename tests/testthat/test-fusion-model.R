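tinyCfg <- fusionConfig(inputSize = 32, baseWidth = 2, fpnWidth = 4,
                        rngSeed = 3, dropoutRate = 0, batchSize = 4,
                        learningRate = 1e-3)

test_that("model building is seeded-deterministic and validates config", {
  m1 <- buildFusion(tinyCfg)
  m2 <- buildFusion(tinyCfg)
  expect_identical(m1@params, m2@params)
  m3 <- buildFusion(fusionConfig(inputSize = 32, baseWidth = 2,
                                 fpnWidth = 4, rngSeed = 4))
  expect_false(identical(m1@params$conv1$W, m3@params$conv1$W))
  expect_error(fusionConfig(inputSize = 100), "multiple of 16")
  expect_error(fusionConfig(pyramidLevels = c(2, 5)), "pyramidLevels")
})

test_that("the shared backbone makes the fusion model smaller than the dual model", {
  fusion <- buildFusion(tinyCfg)
  det <- buildFusion(tinyCfg, task = "detector")
  clf <- buildFusion(tinyCfg, task = "classifier")
  expect_lt(countParams(fusion), countParams(det) + countParams(clf))
  ## the saving is one backbone, minus the fusion classification conv's
  ## extra input channels (it also reads the shared pyramid output)
  backbone <- sum(vapply(fusion@params[c("conv1", "conv2", "conv3",
                                         "conv4")],
                         function(p) length(p$W) + length(p$b), 0))
  ccvExtra <- length(fusion@params$ccv$W) - length(clf@params$ccv$W)
  expect_equal(countParams(det) + countParams(clf) - countParams(fusion),
               backbone - ccvExtra)
})

test_that("forward pass is well-formed and deterministic in eval mode", {
  m <- buildFusion(tinyCfg)
  zero <- array(0, c(32, 32, 3))
  r <- forwardFusion(m, zero)
  expect_true(is.numeric(r$classification))
  expect_gte(r$classification, 0); expect_lte(r$classification, 1)
  expect_s4_class(r$boxes, "BoundingBoxes")
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  r1 <- forwardFusion(m, img); r2 <- forwardFusion(m, img)
  expect_identical(r1$classification, r2$classification)
  expect_identical(boxCoords(r1$boxes), boxCoords(r2$boxes))
  expect_error(forwardFusion(m, array(0, c(64, 64, 3))), "input image")
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("fundusfusion")
  set.seed(42)
  model <- buildFusion(tinyCfg)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  gt <- boundingBoxes(c(4, 18), c(6, 20), c(12, 26), c(14, 28))
  w <- lossWeights(0.5, 100); fp <- focalParams()
  aset <- ns$.anchorSet(tinyCfg)
  item <- ns$.prepareItem(model, list(image = img, boxes = gt, label = 1L),
                          aset)
  lossAt <- function(m) ns$.imageLossGrad(m, item, w, fp, train = FALSE,
                                          needGrad = FALSE)$eTotal
  r <- ns$.imageLossGrad(model, item, w, fp, train = FALSE)
  eps <- 1e-5
  for (nm in c("conv1", "conv3", "lat4", "td3", "head", "cls", "boxr",
               "ccv")) {
    g <- r$grads[[nm]]$dW
    arr <- model@params[[nm]]$W
    for (i in sample(length(arr), 3)) {
      m2 <- model; m2@params[[nm]]$W[i] <- arr[i] + eps
      m3 <- model; m3@params[[nm]]$W[i] <- arr[i] - eps
      num <- (lossAt(m2) - lossAt(m3)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 5e-3)
    }
  }
  ## fusion-weight scalars and the FC layer
  for (nm in c("fwTd", "fwBu", "cfcW")) {
    g <- r$grads[[nm]]
    arr <- model@params[[nm]]
    for (i in seq_len(min(2, length(arr)))) {
      m2 <- model; m2@params[[nm]][i] <- arr[i] + eps
      m3 <- model; m3@params[[nm]][i] <- arr[i] - eps
      num <- (lossAt(m2) - lossAt(m3)) / (2 * eps)
      expect_equal(as.numeric(g[i]), num, tolerance = 5e-3)
    }
  }
})

test_that("zero classification gradient leaves the classification head untouched", {
  ns <- asNamespace("fundusfusion")
  model <- buildFusion(tinyCfg)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  aset <- ns$.anchorSet(tinyCfg)
  item <- ns$.prepareItem(model, list(image = img,
                                      boxes = boundingBoxes(4, 4, 14, 14),
                                      label = 1L), aset)
  fw <- ns$.fusionForward(model, item$pixels, train = FALSE)
  out <- ns$.detOutputs(model, fw, aset)
  dl <- ns$.detectorLossGrad(out$cls, out$box, item$targets, focalParams())
  grads <- list(dDet = ns$.detGradsToLevels(model, dl$dCls, dl$dBox, aset),
                dLogit = NULL)
  gr <- ns$.fusionBackward(model, fw, grads)
  ## no gradient flows into the classification-only parameters ...
  expect_null(gr$ccv); expect_null(gr$cfcW); expect_null(gr$cfcb)
  ## ... so an optimizer step (zero weight decay) cannot move them
  st <- ns$.adamwStep(model@params, gr, ns$.adamwInit(model@params),
                      lr = 1e-3, wd = 0)
  expect_identical(st$params$ccv, model@params$ccv)
  expect_identical(st$params$cfcW, model@params$cfcW)
  expect_identical(st$params$cfcb, model@params$cfcb)
  ## while shared-backbone parameters do move
  expect_false(identical(st$params$conv1$W, model@params$conv1$W))
})

test_that("short joint training reduces the loss and is reproducible", {
  gp <- generatorParams(imageSize = 64, heSizeRange = c(4, 8),
                        heCountRange = c(0L, 2L), backgroundNoiseSd = 0.01)
  smallCfg <- fusionConfig(inputSize = 64, baseWidth = 2, fpnWidth = 4,
                           rngSeed = 3, dropoutRate = 0, batchSize = 4,
                           learningRate = 1e-3)
  set.seed(77)
  scenes <- makeTinyScenes(16, gp, smallCfg)
  fit1 <- trainFusion(buildFusion(smallCfg), scenes, epochs = 6,
                      augment = FALSE)
  expect_equal(nrow(fit1$history), 6L)
  ## smoothed trend is decreasing
  h <- fit1$history$e_total
  expect_lt(mean(h[4:6]), mean(h[1:3]))
  set.seed(77)
  scenes2 <- makeTinyScenes(16, gp, smallCfg)
  fit2 <- trainFusion(buildFusion(smallCfg), scenes2, epochs = 6,
                      augment = FALSE)
  expect_equal(fit1$model@params$conv1$W, fit2$model@params$conv1$W,
               tolerance = 1e-12)
  expect_identical(fit1$history, fit2$history)
  expect_error(trainFusion(buildFusion(smallCfg), list()), "empty")
})

test_that("model checkpoints round-trip with a JSON sidecar", {
  dir <- withr::local_tempdir()
  m <- buildFusion(tinyCfg)
  pth <- file.path(dir, "m.rds")
  saveModel(m, pth)
  expect_true(file.exists(paste0(pth, ".json")))
  m2 <- loadModel(pth)
  expect_identical(m2@params, m@params)
  expect_identical(m2@task, m@task)
  side <- jsonlite::read_json(paste0(pth, ".json"))
  expect_equal(side$n_params, countParams(m))
})
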