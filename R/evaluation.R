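#' Confusion counts for binary calls against truth labels
#'
#' @param calls Logical vector of predicted positives.
#' @param truth Logical vector of true positives.
#' @return List of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(calls, truth) {
  if (length(calls) != length(truth)) {
    stop("calls and truth lengths differ", call. = FALSE)
  }
  calls <- as.logical(calls)
  truth <- as.logical(truth)
  structure(
    list(
      tp = sum(calls & truth), fp = sum(calls & !truth),
      fn = sum(!calls & truth), tn = sum(!calls & !truth)
    ),
    class = "confusion_counts"
  )
}

#' Unweighted F-score
#'
#' `F = TP / (TP + (FP + FN) / 2)` — the harmonic mean of precision and
#' recall, unweighted. Equals 1 exactly for a perfect classifier with at
#' least one positive, 0 when there are no true positives. Undefined (error)
#' when tp = fp = fn = 0.
#'
#' @param counts `confusion_counts`.
#' @return Scalar in \[0, 1\].
#' @export
f_score <- function(counts) {
  with(counts, {
    if (tp + fp + fn == 0) {
      stop("F-score undefined: no positives in calls or truth", call. = FALSE)
    }
    tp / (tp + 0.5 * (fp + fn))
  })
}

#' Sensitivity and specificity
#'
#' @param counts `confusion_counts`.
#' @return Named numeric vector `c(sensitivity=, specificity=)`.
#' @export
sens_spec <- function(counts) {
  with(counts, c(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `AUC = P(score_pos > score_neg) + 0.5 * P(score_pos == score_neg)`,
#' computed from midranks, so ties contribute one half. Inverting the labels
#' maps an AUC of a to 1 - a.
#'
#' @param scores Numeric vector of classifier scores.
#' @param labels Logical (or 0/1) vector; `TRUE` = positive class.
#' @return Scalar in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels lengths differ", call. = FALSE)
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)                       # midranks handle ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' F-score-optimal probability threshold
#'
#' Sweeps candidate thresholds at the midpoints between consecutive sorted
#' unique probabilities, plus 0 and 1 (exact for the step function that the
#' empirical F-score is), calling positives strictly above the threshold.
#' Ties in F are broken toward the smallest threshold.
#'
#' @param p Numeric vector of probabilities.
#' @param truth Logical truth labels (both classes present).
#' @return List with `threshold`, `f_score`, and the full `sweep` table
#'   (threshold, f, sensitivity, specificity).
#' @export
optimize_threshold <- function(p, truth) {
  truth <- as.logical(truth)
  if (all(truth) || !any(truth)) {
    stop("threshold optimization needs both classes in truth", call. = FALSE)
  }
  u <- sort(unique(p))
  candidates <- sort(unique(c(0, 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  sweep <- do.call(rbind, lapply(candidates, function(t) {
    cc <- confusion_counts(p > t, truth)
    f <- if (cc$tp + cc$fp + cc$fn == 0) 0 else f_score(cc)
    ss <- sens_spec(cc)
    data.frame(threshold = t, f = f, sensitivity = ss[["sensitivity"]],
               specificity = ss[["specificity"]])
  }))
  best <- which.max(sweep$f)               # which.max takes the first = smallest
  list(threshold = sweep$threshold[best], f_score = sweep$f[best], sweep = sweep)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Wrapper over [stats::wilcox.test()] with the normal approximation and tie
#' correction, as used to compare per-iteration AUC distributions between
#' simulation conditions.
#'
#' @param a,b Non-empty numeric vectors.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("rank-sum test needs non-empty samples", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1L) return(1)  # all values tied
  stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                     correct = TRUE)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Convenience wrapper over [stats::p.adjust()] for multi-comparison
#' simulation outputs.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}
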