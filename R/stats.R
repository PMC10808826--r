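#' Evaluation statistics for the ALWSS risk score
#'
#' The score is evaluated exactly as in the clinical analysis: an empirical
#' ROC curve with trapezoidal AUC (equivalently the Mann-Whitney
#' concordance with ties weighted 0.5), an accuracy-optimal decision
#' threshold with the "positive if score is higher than the threshold"
#' orientation, Pearson correlation with a t-distribution p-value, and
#' Mood's median test for two-group comparisons of covariates.
#'
#' @name stats_analysis
NULL

check_two_class <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  labels
}

#' Empirical ROC curve and AUC
#'
#' Thresholds sweep the unique score values; tied scores move the curve
#' diagonally, so the trapezoidal AUC equals the Mann-Whitney statistic
#' `U/(n1*n0)` with ties counted 0.5.
#'
#' @param scores numeric risk scores (higher = more positive).
#' @param labels binary 0/1 outcomes.
#' @return object of class `roc_result`: `points` (data.frame of `fpr`,
#'   `tpr`, `threshold`), `auc`, and the accuracy-optimal `best_threshold`
#'   and `correctly_classified_ratio` from
#'   [best_threshold_by_accuracy()].
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_two_class(scores, labels)
  n1 <- as.numeric(sum(labels == 1L))
  n0 <- as.numeric(sum(labels == 0L))
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), numeric(1))
  points <- data.frame(
    fpr = c(0, fp / n0), tpr = c(0, tp / n1),
    threshold = c(Inf, thr)
  )
  # trapezoid accumulated in integer pair counts: AUC * n1 * n0 is an exact
  # half-integer, so the ratio matches the Mann-Whitney statistic exactly
  tp_c <- c(0, tp)
  fp_c <- c(0, fp)
  k <- length(tp_c)
  pairs <- sum(diff(fp_c) * (tp_c[-1] + tp_c[-k])) / 2
  auc <- pairs / (n1 * n0)
  best <- best_threshold_by_accuracy(scores, labels)
  structure(list(points = points, auc = auc,
                 best_threshold = best$threshold,
                 correctly_classified_ratio = best$ratio),
            class = "roc_result")
}

#' Accuracy-optimal decision threshold
#'
#' Scans candidate thresholds (midpoints between consecutive sorted unique
#' scores, plus -Inf and +Inf), classifying positive when `score >
#' threshold`, and returns the threshold maximizing the correctly
#' classified ratio; ties broken toward the smallest threshold.
#'
#' @inheritParams roc_auc
#' @return list with `threshold` and `ratio`.
#' @export
best_threshold_by_accuracy <- function(scores, labels) {
  labels <- check_two_class(scores, labels)
  u <- sort(unique(scores))
  candidates <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  acc <- vapply(candidates, function(t)
    mean((scores > t) == (labels == 1L)), numeric(1))
  i <- which.max(acc)  # which.max returns the first (smallest) maximizer
  list(threshold = candidates[i], ratio = acc[i])
}

#' Pearson correlation with significance
#'
#' Sample Pearson r with the two-sided p-value from
#' `t = r * sqrt((n-2)/(1-r^2))` on `n-2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3, non-zero variance).
#' @return list with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Mood's median test
#'
#' Compares two groups by the pooled grand median: counts above versus at
#' or below the median per group form a 2x2 table tested by the Pearson
#' chi-square statistic on 1 degree of freedom, without continuity
#' correction. Values equal to the grand median count as "at or below".
#'
#' @param group1,group2 numeric vectors (non-empty; pooled data must not
#'   yield a degenerate table).
#' @return list with `chi2`, `p`, `grand_median` and the 2x2 `table`
#'   (rows = groups, cols = c(above, at_or_below)).
#' @export
moods_median_test <- function(group1, group2) {
  if (length(group1) == 0 || length(group2) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  med <- median(c(group1, group2))
  tab <- rbind(
    group1 = c(above = sum(group1 > med), at_or_below = sum(group1 <= med)),
    group2 = c(above = sum(group2 > med), at_or_below = sum(group2 <= med))
  )
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    stop("degenerate 2x2 table (zero margin); groups too similar or ",
         "all-tied data", call. = FALSE)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value,
       grand_median = med, table = tab)
}
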