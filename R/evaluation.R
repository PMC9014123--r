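## Evaluation protocol and statistics: per-image detection confusion
## categories at IoU > 0.15, sensitivity/specificity/accuracy with 95%
## CIs, ROC/AUC (midrank concordance), the DeLong test for correlated
## AUCs, the pooled two-proportion z-test, dataset profiling, and the
## Messidor DME-grade mapping.

#' Per-image detection outcome
#'
#' Image-level scoring of a detector: TP if ground truth has lesions and
#' any predicted box overlaps any GT box with IoU strictly above the
#' threshold; TN if both GT and prediction are empty; FP if GT is empty
#' but predictions exist; FN if GT has lesions and either no prediction
#' exists or every prediction has IoU at or below the threshold.
#'
#' @param pred,gt [BoundingBoxes-class] objects (possibly empty).
#' @param iouThreshold overlap threshold, default 0.15.
#' @return One of `"TP"`, `"FP"`, `"TN"`, `"FN"`.
#' @export
classifyDetectionImage <- function(pred, gt, iouThreshold = 0.15) {
  nP <- length(pred); nG <- length(gt)
  if (nG == 0L) return(if (nP == 0L) "TN" else "FP")
  if (nP == 0L) return("FN")
  if (max(boxIoU(pred, gt)) > iouThreshold) "TP" else "FN"
}

.waldCI <- function(p, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(lower = max(0, p - half), upper = min(1, p + half))
}

.wilsonCI <- function(p, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, mid - half), upper = min(1, mid + half))
}

.rate <- function(num, den, ciMethod) {
  if (den == 0L)
    return(list(value = NA_real_, lower = NA_real_, upper = NA_real_,
                n = 0L))
  p <- num / den
  ci <- if (ciMethod == "wilson") .wilsonCI(p, den) else .waldCI(p, den)
  list(value = p, lower = unname(ci[1L]), upper = unname(ci[2L]), n = den)
}

#' Aggregate detection metrics with 95% confidence intervals
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy
#' `(TP+TN)/N`, each with a 95% CI (Wald normal approximation by default,
#' Wilson optionally). A rate with a zero denominator is reported as
#' absent (`NA`), never as 0.
#'
#' @param outcomes character vector of `"TP"/"FP"/"TN"/"FN"` categories,
#'   one per image (order is irrelevant).
#' @param ciMethod `"wald"` (default) or `"wilson"`.
#' @return A list of class `MetricsReport` with elements `sensitivity`,
#'   `specificity`, `accuracy` (each `value`, `lower`, `upper`, `n`) and
#'   `counts`.
#' @export
detectionMetrics <- function(outcomes, ciMethod = c("wald", "wilson")) {
  ciMethod <- match.arg(ciMethod)
  stopifnot(length(outcomes) > 0L,
            all(outcomes %in% c("TP", "FP", "TN", "FN")))
  k <- vapply(c("TP", "FP", "TN", "FN"),
              function(x) sum(outcomes == x), 0L)
  out <- list(
    sensitivity = .rate(k[["TP"]], k[["TP"]] + k[["FN"]], ciMethod),
    specificity = .rate(k[["TN"]], k[["TN"]] + k[["FP"]], ciMethod),
    accuracy = .rate(k[["TP"]] + k[["TN"]], sum(k), ciMethod),
    counts = as.list(k))
  class(out) <- "MetricsReport"
  out
}

#' @export
print.MetricsReport <- function(x, ...) {
  fmt <- function(r, nm) {
    if (is.na(r$value))
      cat(sprintf("  %-12s undefined (zero denominator)\n", nm))
    else
      cat(sprintf("  %-12s %.4f (95%% CI %.4f-%.4f, n = %d)\n",
                  nm, r$value, r$lower, r$upper, r$n))
  }
  cat("Image-level detection metrics\n")
  cat(sprintf("  counts: TP=%d FP=%d TN=%d FN=%d\n", x$counts$TP,
              x$counts$FP, x$counts$TN, x$counts$FN))
  fmt(x$sensitivity, "sensitivity")
  fmt(x$specificity, "specificity")
  fmt(x$accuracy, "accuracy")
  invisible(x)
}

## Midrank (tie-corrected) placement values; AUC is their mean. This is
## the Mann-Whitney concordance probability.
.placements <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (r[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = sum(r[seq_len(m)]) / (m * n) -
         (m + 1) / (2 * n))
}

#' Empirical ROC curve and AUC
#'
#' The AUC is computed as the tie-corrected Mann-Whitney concordance
#' probability (equivalently, trapezoidal integration of the empirical
#' ROC). Ties contribute 0.5 per discordant pair, so a constant score
#' yields AUC 0.5.
#'
#' @param scores numeric predicted probabilities or scores.
#' @param labels binary 0/1 vector; both classes must be present.
#' @return `list(curve, auc)` where `curve` is a data.frame with columns
#'   `threshold` (descending), `fpr`, `tpr`, starting at (0, 0) and ending
#'   at (1, 1).
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present to compute a ROC curve")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / m, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n, 0)
  curve <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  auc <- .placements(scores, labels)$auc
  list(curve = curve, auc = auc)
}

#' DeLong confidence interval for a single AUC
#'
#' Variance from the DeLong placement components; the interval is clipped
#' to `[0, 1]`, so a perfectly separating score has upper bound 1.
#'
#' @param scores,labels as in [rocAuc()].
#' @param level confidence level (default 0.95).
#' @return `list(auc, lower, upper, se)`.
#' @export
aucCiDelong <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  pl <- .placements(scores, labels)
  m <- length(pl$v10); n <- length(pl$v01)
  v <- stats::var(pl$v10) / m + stats::var(pl$v01) / n
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = pl$auc, lower = max(0, pl$auc - z * se),
       upper = min(1, pl$auc + z * se), se = se)
}

#' DeLong test comparing two correlated AUCs
#'
#' Both score vectors must be paired (same images, same labels). Uses
#' midrank placement values and the DeLong covariance estimate for
#' correlated ROC curves; the z statistic is referred to the standard
#' normal for a two-sided p-value. When both models separate perfectly
#' the variance of the difference degenerates and the p-value is
#' reported as `NA` with a warning.
#'
#' @param scoresA,scoresB paired score vectors.
#' @param labels binary 0/1 vector; at least 5 per class.
#' @return `list(aucA, aucB, z, p)`.
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scoresA) == length(labels),
            length(scoresB) == length(labels))
  if (sum(labels == 1L) < 5L || sum(labels == 0L) < 5L)
    stop("delongTest requires at least 5 observations per class")
  pa <- .placements(scoresA, labels)
  pb <- .placements(scoresB, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  vDiff <- (s10[1L, 1L] + s10[2L, 2L] - 2 * s10[1L, 2L]) / m +
    (s01[1L, 1L] + s01[2L, 2L] - 2 * s01[1L, 2L]) / n
  d <- pa$auc - pb$auc
  if (vDiff <= .Machine$double.eps) {
    if (abs(d) < 1e-12)
      return(list(aucA = pa$auc, aucB = pb$auc, z = 0, p = 1))
    warning("degenerate DeLong variance (perfect separation in both); ",
            "p-value reported as NA")
    return(list(aucA = pa$auc, aucB = pb$auc, z = NA_real_, p = NA_real_))
  }
  z <- d / sqrt(vDiff)
  list(aucA = pa$auc, aucB = pb$auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Pooled two-proportion z-test
#'
#' Compares two observed proportions `x1/n1` and `x2/n2` with the pooled
#' standard error and a two-sided normal p-value (no continuity
#' correction). A pooled proportion of exactly 0 or 1 carries no
#' information; `z = 0, p = 1` is returned with a warning.
#'
#' @param x1,n1,x2,n2 counts, `0 <= x <= n`, `n >= 1`.
#' @return `list(z, p, p1, p2)`.
#' @export
twoProportionZTest <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    warning("pooled proportion is degenerate (0 or 1); returning p = 1")
    return(list(z = 0, p = 1, p1 = p1, p2 = p2))
  }
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Per-split class profile of a dataset
#'
#' @param labelsBySplit named list of binary 0/1 label vectors, one per
#'   split.
#' @return A data.frame with one row per (split, class) plus a total row
#'   per split: columns `split`, `class`, `n`, `pct` (percent, rounded to
#'   two decimals).
#' @examples
#' datasetProfile(list(training = rep(c(0, 1), c(18921, 13765))))
#' @export
datasetProfile <- function(labelsBySplit) {
  stopifnot(is.list(labelsBySplit), length(labelsBySplit) > 0L,
            !is.null(names(labelsBySplit)))
  rows <- lapply(names(labelsBySplit), function(sp) {
    lab <- as.integer(labelsBySplit[[sp]])
    stopifnot(length(lab) > 0L, all(lab %in% c(0L, 1L)))
    n <- length(lab)
    data.frame(
      split = sp,
      class = c("non-DME", "DME", "total"),
      n = c(sum(lab == 0L), sum(lab == 1L), n),
      pct = round(100 * c(sum(lab == 0L), sum(lab == 1L), n) / n, 2L),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Map a Messidor DME risk grade to the binary DME label
#'
#' Grades 0 ("no visible HE") and 1 ("HE at least 1DD from the macula")
#' map to non-DME; grade 2 ("HE within 1DD of the macula") maps to DME.
#'
#' @param grade integer vector with values in `{0, 1, 2}`.
#' @return Integer 0/1 vector.
#' @export
mapMessidorGrade <- function(grade) {
  grade <- as.integer(grade)
  if (any(!grade %in% c(0L, 1L, 2L)))
    stop("Messidor DME risk grade must be 0, 1 or 2")
  as.integer(grade == 2L)
}

#' Youden-optimal operating threshold
#'
#' Chooses the score cut maximising sensitivity + specificity - 1 on a
#' validation set (ties resolved toward the higher threshold). The
#' operating point converting probabilities into the reported
#' sensitivity/specificity is otherwise left free; AUC is threshold-free.
#'
#' @param scores,labels as in [rocAuc()].
#' @return A scalar threshold.
#' @export
youdenThreshold <- function(scores, labels) {
  rc <- rocAuc(scores, labels)$curve
  j <- rc$tpr - rc$fpr
  best <- which(j == max(j))
  th <- rc$threshold[best[1L]]
  if (!is.finite(th)) th <- max(scores) + 1e-9
  th
}
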