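test_that("per-image detection outcomes follow the four definitions", {
  e <- boundingBoxes()
  g <- boundingBoxes(0, 0, 10, 10)
  expect_equal(classifyDetectionImage(e, e), "TN")
  expect_equal(classifyDetectionImage(boundingBoxes(5, 0, 15, 10), g), "TP")
  expect_equal(classifyDetectionImage(boundingBoxes(50, 50, 60, 60), g),
               "FN")
  expect_equal(classifyDetectionImage(g, e), "FP")
  expect_equal(classifyDetectionImage(e, g), "FN")
  ## IoU exactly at the threshold counts as a miss ("IoU <= 0.15" is FN)
  thr <- boxIoU(c(0, 0, 10, 10), c(4, 0, 14, 10))[1, 1]
  expect_equal(classifyDetectionImage(boundingBoxes(4, 0, 14, 10), g,
                                      iouThreshold = thr), "FN")
})

test_that("every (pred, gt) instance lands in exactly one category", {
  set.seed(61)
  for (i in 1:150) {
    p <- randomBoxSet(sample(0:3, 1), 60)
    g <- randomBoxSet(sample(0:3, 1), 60)
    pb <- if (nrow(p)) boundingBoxes(p[, 1], p[, 2], p[, 3], p[, 4])
          else boundingBoxes()
    gb <- if (nrow(g)) boundingBoxes(g[, 1], g[, 2], g[, 3], g[, 4])
          else boundingBoxes()
    out <- classifyDetectionImage(pb, gb)
    expect_true(out %in% c("TP", "FP", "TN", "FN"))
    ## cross-check against a direct restatement of the definitions
    want <- if (length(gb) == 0 && length(pb) == 0) "TN"
      else if (length(gb) == 0) "FP"
      else if (length(pb) == 0) "FN"
      else if (any(boxIoU(pb, gb) > 0.15)) "TP" else "FN"
    expect_identical(out, want)
  }
})

test_that("detection metrics aggregate a constructed confusion table", {
  outcomes <- rep(c("TP", "FN", "TN", "FP"), c(290, 75, 600, 84))
  r <- detectionMetrics(outcomes)
  expect_equal(r$sensitivity$value, 290 / 365, tolerance = 1e-12)
  expect_equal(r$specificity$value, 600 / 684, tolerance = 1e-12)
  expect_equal(r$accuracy$value, 890 / 1049, tolerance = 1e-12)
  ## Wald CI arithmetic
  p <- 290 / 365
  half <- qnorm(0.975) * sqrt(p * (1 - p) / 365)
  expect_equal(r$sensitivity$lower, p - half, tolerance = 1e-10)
  ## permutation invariance
  r2 <- detectionMetrics(sample(outcomes))
  expect_equal(r2$sensitivity$value, r$sensitivity$value)
  ## zero denominator reported absent, not zero
  allTP <- detectionMetrics(rep("TP", 10))
  expect_equal(allTP$sensitivity$value, 1)
  expect_true(is.na(allTP$specificity$value))
  ## Wilson variant stays inside [0, 1]
  rw <- detectionMetrics(outcomes, ciMethod = "wilson")
  expect_gte(rw$sensitivity$lower, 0)
  expect_lte(rw$sensitivity$upper, 1)
})

test_that("AUC equals brute-force concordance and handles ties", {
  ## perfect separation
  expect_equal(rocAuc(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1))$auc, 1)
  ## constant scores
  expect_equal(rocAuc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(rocAuc(1:5, rep(1, 5)), "both classes")
  set.seed(17)
  for (i in 1:25) {
    n <- sample(10:100, 1)
    labs <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- round(runif(n), sample(c(1, 2, 5), 1))  # force some ties
    r <- rocAuc(sc, labs)
    expect_equal(r$auc, bruteAuc(sc, labs), tolerance = 1e-12)
    ## curve endpoints and monotonicity
    expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
    expect_equal(tail(r$curve$fpr, 1), 1)
    expect_equal(tail(r$curve$tpr, 1), 1)
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
  }
})

test_that("DeLong test agrees with pROC and honours degenerate contracts", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:20) {
    n <- 40
    labs <- c(rep(1, 15), rep(0, 25))
    sa <- runif(n) + labs * runif(1, 0, 1.5)
    sb <- runif(n) + labs * runif(1, 0, 1.5)
    got <- delongTest(sa, sb, labs)
    rocA <- pROC::roc(labs, sa, quiet = TRUE, direction = "<",
                      levels = c(0, 1))
    rocB <- pROC::roc(labs, sb, quiet = TRUE, direction = "<",
                      levels = c(0, 1))
    ref <- suppressWarnings(pROC::roc.test(rocA, rocB, method = "delong"))
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
    ci <- aucCiDelong(sa, labs)
    refCi <- suppressWarnings(pROC::ci.auc(rocA, method = "delong"))
    expect_equal(c(ci$lower, ci$upper), as.numeric(refCi[c(1, 3)]),
                 tolerance = 1e-6)
  }
  ## identical scores: AUC difference 0, p = 1
  labs <- rep(c(0, 1), 10)
  sc <- runif(20)
  same <- delongTest(sc, sc, labs)
  expect_equal(same$z, 0); expect_equal(same$p, 1)
  ## perfectly separating scores: CI clipped at 1
  sep <- c(rep(0.9, 10), rep(0.1, 10))
  lab2 <- rep(c(1, 0), each = 10)
  ci <- aucCiDelong(sep, lab2)
  expect_equal(ci$upper, 1)
  expect_warning(delongTest(sep, 1 - sep, lab2), "degenerate")
  expect_error(delongTest(1:6, 6:1, c(1, 1, 1, 0, 0, 0)), "at least 5")
})

test_that("DeLong p-values are near-uniform under the null", {
  set.seed(303)
  hits <- 0L
  for (i in 1:500) {
    labs <- rep(c(0, 1), each = 40)
    base <- runif(80) + labs * 0.5
    sa <- base + rnorm(80, 0, 0.3)
    sb <- base + rnorm(80, 0, 0.3)
    if (delongTest(sa, sb, labs)$p < 0.05) hits <- hits + 1L
  }
  expect_lt(abs(hits / 500 - 0.05), 0.03)
})

test_that("two-proportion z-test matches the pooled formula", {
  expect_equal(twoProportionZTest(50, 100, 50, 100)$p, 1)
  expect_equal(twoProportionZTest(30, 60, 25, 50)$z, 0)
  ## hand computation of the pooled formula
  x1 <- 290; n1 <- 365; x2 <- 266; n2 <- 365
  pp <- (x1 + x2) / (n1 + n2)
  zHand <- (x1 / n1 - x2 / n2) /
    sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  got <- twoProportionZTest(x1, n1, x2, n2)
  expect_equal(got$z, zHand, tolerance = 1e-10)
  expect_equal(got$p, 2 * pnorm(-abs(zHand)), tolerance = 1e-10)
  ## z^2 equals the uncorrected chi-squared statistic
  chi <- prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$statistic
  expect_equal(got$z^2, unname(chi), tolerance = 1e-9)
  expect_warning(r0 <- twoProportionZTest(0, 10, 0, 12), "degenerate")
  expect_equal(r0$p, 1)
})

test_that("dataset profile reproduces printed-count percentages", {
  prof <- datasetProfile(list(
    training = rep(c(0, 1), c(18921, 13765)),
    validation = rep(c(0, 1), c(1140, 126)),
    testing = rep(c(0, 1), c(939, 110))))
  getp <- function(sp, cl)
    prof$pct[prof$split == sp & prof$class == cl]
  expect_equal(getp("training", "non-DME"), 57.89)
  expect_equal(getp("training", "DME"), 42.11)
  expect_equal(getp("validation", "non-DME"), 90.05)
  expect_equal(getp("validation", "DME"), 9.95)
  expect_equal(getp("testing", "non-DME"), 89.51)
  expect_equal(getp("testing", "DME"), 10.49)
  ## single-class split and normalisation
  one <- datasetProfile(list(s = c(1)))
  expect_equal(one$pct[one$class == "DME"], 100)
  sums <- tapply(prof$pct[prof$class != "total"],
                 prof$split[prof$class != "total"], sum)
  expect_true(all(abs(sums - 100) <= 0.01))
})

test_that("Messidor grades map to the binary label", {
  expect_equal(mapMessidorGrade(c(0, 1, 2)), c(0L, 0L, 1L))
  expect_error(mapMessidorGrade(3), "grade")
})

test_that("the Youden threshold maximises sensitivity + specificity", {
  set.seed(5)
  labs <- rep(c(0, 1), each = 30)
  sc <- runif(60) + labs
  th <- youdenThreshold(sc, labs)
  j <- function(t) mean(sc[labs == 1] >= t) + mean(sc[labs == 0] < t) - 1
  grid <- sort(unique(sc))
  expect_equal(j(th), max(vapply(grid, j, 0)), tolerance = 1e-12)
})
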