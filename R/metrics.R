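# Quantitative evaluation: pixel confusion counts, the five scalar
# segmentation metrics, pooled precision-recall curves, the radar-percentage
# transform, relative-difference reporting, Kruskal-Wallis comparison, and
# cross-validation fold summaries.

#' Pixel confusion counts between two binary masks
#'
#' @param pred predicted binary mask (matrix/array or logical).
#' @param truth reference binary mask, same shape.
#' @return named list with integer `tp`, `fp`, `fn`, `tn`
#'   (summing to the pixel count).
#' @export
confusionCounts <- function(pred, truth) {
  if (!identical(dim(pred) %||% length(pred),
                 dim(truth) %||% length(truth))) {
    stop("confusionCounts: mask shapes differ", call. = FALSE)
  }
  p <- as.numeric(pred)
  y <- as.numeric(truth)
  if (!isBinary(p) || !isBinary(y)) {
    stop("confusionCounts: masks must be binary", call. = FALSE)
  }
  tp <- sum(p == 1 & y == 1)
  fp <- sum(p == 1 & y == 0)
  fn <- sum(p == 0 & y == 1)
  tn <- sum(p == 0 & y == 0)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Five scalar segmentation metrics from confusion counts
#'
#' Dice `2tp/(2tp+fp+fn)`, Jaccard `tp/(tp+fp+fn)`, precision `tp/(tp+fp)`,
#' specificity `tn/(tn+fp)`, sensitivity `tp/(tp+fn)`. Degenerate
#' denominators follow the empty-mask conventions: a slice where truth and
#' prediction are both empty scores 1 on dice/jaccard/precision/sensitivity;
#' an empty truth with a non-empty prediction scores 0.
#'
#' @param cc confusion counts from [confusionCounts()].
#' @return named list `dsc`, `jaccard`, `precision`, `specificity`,
#'   `sensitivity`, each in `[0, 1]`.
#' @export
scalarMetrics <- function(cc) {
  tp <- cc$tp; fp <- cc$fp; fn <- cc$fn; tn <- cc$tn
  safe <- function(num, den, empty) if (den > 0) num / den else empty
  bothEmpty <- (tp + fn == 0) && (fp == 0)
  list(
    dsc = safe(2 * tp, 2 * tp + fp + fn, 1),
    jaccard = safe(tp, tp + fp + fn, 1),
    precision = safe(tp, tp + fp, if (fn == 0) 1 else 0),
    specificity = safe(tn, tn + fp, 1),
    sensitivity = safe(tp, tp + fn, if (bothEmpty) 1 else 0)
  )
}

#' Pooled precision-recall curve and its area
#'
#' Pools all pixels, sweeps every distinct score as a threshold (predict
#' positive at `score >= threshold`), and integrates precision over recall by
#' the trapezoidal rule, anchoring the curve at recall 0 with the first
#' achievable precision.
#'
#' @param scores numeric vector of predicted probabilities (pooled pixels).
#' @param truths binary vector of the same length.
#' @return list with `points` (data.frame `threshold`, `recall`, `precision`,
#'   recall non-decreasing) and `auc`.
#' @export
prCurve <- function(scores, truths) {
  scores <- as.numeric(scores)
  truths <- as.numeric(truths)
  if (length(scores) != length(truths) || length(scores) == 0L) {
    stop("prCurve: scores and truths must be non-empty and equal length",
         call. = FALSE)
  }
  if (!isBinary(truths)) stop("prCurve: truths must be binary", call. = FALSE)
  P <- sum(truths)
  if (P == 0) {
    stop("prCurve: no positive pixels; the curve is undefined",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truths[ord]
  ctp <- cumsum(y)
  cfp <- cumsum(1 - y)
  # last index of each distinct-score run = one operating point
  last <- which(s != c(s[-1], NA_real_))
  last[length(last) + 1L] <- length(s)
  last <- unique(last)
  recall <- ctp[last] / P
  precision <- ctp[last] / (ctp[last] + cfp[last])
  pts <- data.frame(threshold = s[last], recall = recall,
                    precision = precision)
  r <- c(0, recall)
  p <- c(precision[1], precision)
  auc <- sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Radar-percentage transform of a metric value
#'
#' Rescales a metric so that 0.5 maps to 0% and the best observed value of
#' that metric maps to 100%: `Y = (x - 0.5) / (max - 0.5) * 100`.
#'
#' @param x metric value.
#' @param max_value the maximum of that metric across compared models
#'   (must exceed 0.5).
#' @return percentage.
#' @examples
#' radarPercentage(0.790, 0.816)  # 91.77...
#' @export
radarPercentage <- function(x, max_value) {
  if (max_value <= 0.5) {
    stop("radarPercentage: max_value must exceed 0.5", call. = FALSE)
  }
  (x - 0.5) / (max_value - 0.5) * 100
}

#' Signed relative difference between two metric values
#'
#' `100 * (b - a) / max(a, b)`, rounded to two decimals for reporting: the
#' magnitude is the percentage separation relative to the larger value, and a
#' negative sign means `b` is lower than `a`.
#'
#' @param a reference metric value (> 0).
#' @param b compared metric value (> 0).
#' @return signed percentage, rounded to 2 decimals.
#' @examples
#' relativeDifference(0.816, 0.790)  # -3.19: b is 3.19% lower
#' @export
relativeDifference <- function(a, b) {
  if (a <= 0 || b <= 0) {
    stop("relativeDifference: values must be positive", call. = FALSE)
  }
  round(100 * (b - a) / max(a, b), 2)
}

#' Kruskal-Wallis rank test across groups
#'
#' Standard rank-based H statistic with tie correction and the chi-square
#' p-value approximation (delegated to [stats::kruskal.test()]). Used to test
#' whether per-slice Dice distributions of different model variants differ.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return list with `statistic` (H) and `p.value`.
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L ||
      any(vapply(groups, length, integer(1)) == 0L)) {
    stop("kruskalWallis: need at least two non-empty groups", call. = FALSE)
  }
  vals <- unlist(groups)
  if (length(unique(vals)) == 1L) {
    return(list(statistic = 0, p.value = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Mean and standard deviation of per-fold metrics
#'
#' Arithmetic mean and sample (n-1) standard deviation, the convention used
#' for cross-validation summary columns.
#'
#' @param values numeric vector of per-fold metric values (non-empty).
#' @return list with `mean` and `sd` (`sd = 0` for a single value).
#' @examples
#' foldSummary(c(0.8020, 0.8044, 0.8030, 0.7552, 0.7923))$mean  # 0.7914
#' @export
foldSummary <- function(values) {
  if (length(values) == 0L) {
    stop("foldSummary: empty input", call. = FALSE)
  }
  list(mean = mean(values),
       sd = if (length(values) > 1L) sd(values) else 0)
}
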