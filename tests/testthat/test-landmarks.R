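disc40 <- boundingBoxes(0, 0, 40, 40, category = "optic_disc")
mac <- boundingBoxes(80, 80, 120, 120, category = "macula")

test_that("disc diameter and macula centre follow box geometry", {
  expect_equal(discDiameter(disc40), 40)
  expect_equal(discDiameter(boundingBoxes(0, 0, 30, 50,
                                          category = "optic_disc")), 40)
  sc <- boundingBoxes(0, 0, 60, 100, category = "optic_disc")
  expect_equal(discDiameter(sc), 2 * discDiameter(
    boundingBoxes(0, 0, 30, 50, category = "optic_disc")))

  expect_equal(unname(maculaCenter(boundingBoxes(0, 0, 10, 10))), c(5, 5))
  expect_equal(unname(maculaCenter(boundingBoxes(10, 20, 30, 60))),
               c(20, 40))
  shifted <- boundingBoxes(10 + 7, 20 + 3, 30 + 7, 60 + 3)
  expect_equal(unname(maculaCenter(shifted)), c(27, 43))
})

test_that("the 1DD rule is inclusive at the boundary and exact either side", {
  ## macula centre (100,100), disc diameter 40
  expect_equal(dmeRule(boundingBoxes(141, 100, 151, 110), disc40, mac), 0L)
  expect_equal(dmeRule(boundingBoxes(139, 100, 149, 110), disc40, mac), 1L)
  ## exactly at 1DD: "at or within" is DME
  expect_equal(dmeRule(boundingBoxes(140, 100, 150, 110), disc40, mac), 1L)
  ## HE containing the macula centre: distance 0
  expect_equal(dmeRule(boundingBoxes(95, 95, 105, 105), disc40, mac), 1L)
  ## no HE at all is non-DME
  expect_equal(dmeRule(boundingBoxes(), disc40, mac), 0L)
  ## absent landmarks are ungradable, not non-DME
  expect_error(dmeRule(boundingBoxes(0, 0, 5, 5), boundingBoxes(), mac),
               "ungradable")
  expect_error(dmeRule(boundingBoxes(0, 0, 5, 5), disc40, NULL),
               "ungradable")
})

test_that("the 1DD rule is scale invariant and monotone in lesions", {
  set.seed(14)
  for (i in 1:60) {
    d <- randomBoxSet(1, 300)[1, ]
    m <- randomBoxSet(1, 300)[1, ] + 150
    he <- randomBoxSet(sample(1:4, 1), 400)
    db <- boundingBoxes(d[1], d[2], d[3], d[4], category = "optic_disc")
    mb <- boundingBoxes(m[1], m[2], m[3], m[4], category = "macula")
    hb <- boundingBoxes(he[, 1], he[, 2], he[, 3], he[, 4])
    lab <- dmeRule(hb, db, mb)
    k <- runif(1, 0.1, 8)
    scale <- function(x, cat) {
      cm <- boxCoords(x) * k
      boundingBoxes(cm[, 1], cm[, 2], cm[, 3], cm[, 4], category = cat)
    }
    expect_identical(dmeRule(scale(hb, "HE"), scale(db, "optic_disc"),
                             scale(mb, "macula")), lab)
    ## adding an HE box can only move the label towards DME
    extra <- randomBoxSet(1, 400)
    more <- combineBoxes(hb, boundingBoxes(extra[, 1], extra[, 2],
                                           extra[, 3], extra[, 4]))
    expect_gte(dmeRule(more, db, mb), lab)
  }
})

test_that("rule recovery on generated scenes is exact by construction", {
  gp <- generatorParams(imageSize = 128)
  set.seed(99)
  for (i in 1:100) {
    tr <- generateScene(gp, render = FALSE)$truth
    expect_identical(dmeRule(heBoxes(tr), discBox(tr), maculaBox(tr)),
                     dmeLabel(tr))
  }
})

test_that("landmark extraction keeps the highest-confidence candidates", {
  fake <- function(img) boundingBoxes(
    c(10, 15, 60, 100), c(10, 15, 60, 100), c(40, 45, 90, 130),
    c(40, 45, 90, 130),
    score = c(0.6, 0.9, 0.8, 0.2),
    category = c("optic_disc", "optic_disc", "macula", "macula"))
  img <- fundusImage("t", array(0, c(64, 64, 3)))
  lm <- detectLandmarks(fake, img)
  expect_equal(unname(boxCoords(lm@discBox)[1, ]), c(15, 15, 45, 45))
  expect_equal(boxScore(lm@discBox), 0.9)
  expect_equal(unname(boxCoords(lm@maculaBox)[1, ]), c(60, 60, 90, 90))

  none <- detectLandmarks(function(img) boundingBoxes(), img)
  expect_length(none@discBox, 0L)
  expect_length(none@maculaBox, 0L)
  expect_error(dmeRule(boundingBoxes(0, 0, 4, 4), none@discBox,
                       none@maculaBox), "ungradable")
})

test_that("overlay draws available elements and round-trips through PNG", {
  gp <- generatorParams(imageSize = 128)
  s <- generateScene(gp, rngSeed = 12)
  ## empty overlay leaves pixels untouched
  same <- renderOverlay(s$image)
  expect_identical(imagePixels(same), imagePixels(s$image))

  lm <- landmarkSet(discBox(s$truth), maculaBox(s$truth))
  ov <- renderOverlay(s$image, heBoxes(s$truth), lm)
  expect_false(identical(imagePixels(ov), imagePixels(s$image)))
  ## the 1DD circle: white pixels at radius ~ discDiameter from macula
  r <- discDiameter(discBox(s$truth))
  ctr <- maculaCenter(maculaBox(s$truth))
  px <- imagePixels(ov)
  probe <- c(round(ctr[2]) + 1L, round(ctr[1] + r) + 1L)
  expect_gt(min(px[probe[1], probe[2], ]), 0.9)

  ## missing macula: disc still drawn, warning emitted
  expect_warning(part <- renderOverlay(s$image, heBoxes(s$truth),
                                       landmarkSet(discBox(s$truth))),
                 "incomplete")
  expect_false(identical(imagePixels(part), imagePixels(s$image)))

  tmp <- withr::local_tempfile(fileext = ".png")
  writeFundusImage(ov, tmp)
  back <- readFundusImage(tmp)
  expect_lt(max(abs(imagePixels(back) - imagePixels(ov))), 1 / 255)
})
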