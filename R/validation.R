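.split_classes <- function(values, labels) {
  if (is.data.frame(labels)) labels <- labels$class
  y <- .as_class_factor(labels)
  if (length(values) != length(y))
    stop("values and labels differ in length")
  list(case = values[y == "case"], control = values[y == "control"])
}

#' AUC by Mann-Whitney pair counting
#'
#' The probability that a random case sample scores above a random
#' control sample, with ties counted one half:
#' `AUC = (#pairs case > control + 0.5 * #ties) / (n_case * n_control)`.
#' Computed via midranks, it equals the trapezoidal area under the ROC
#' curve.
#'
#' @param values per-sample scores (e.g. one gene's expression).
#' @param labels class labels aligned with `values`.
#' @param orient if `TRUE`, report `max(auc, 1 - auc)` with the chosen
#'   orientation attached as attribute `"direction"` (`"case_high"` or
#'   `"case_low"`), matching orientation-free AUC reporting.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(values, labels, orient = FALSE) {
  cls <- .split_classes(values, labels)
  n1 <- length(cls$case); n0 <- length(cls$control)
  r <- rank(c(cls$case, cls$control))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (orient) {
    dir <- if (auc >= 0.5) "case_high" else "case_low"
    auc <- max(auc, 1 - auc)
    attr(auc, "direction") <- dir
  }
  auc
}

#' ROC curve by threshold sweep
#'
#' Sweeps thresholds over the unique score values in descending order
#' (predicting `case` when the score is at or above the threshold) and
#' records the (FPR, TPR) staircase from (0, 0) to (1, 1).  The
#' trapezoidal area under this curve equals [auc_mann_whitney()] to
#' numerical precision, including under ties.
#'
#' @inheritParams auc_mann_whitney
#' @return object of class `roc_result`: list with `curve` (data.frame
#'   `fpr`, `tpr`, `threshold`) and `auc`.
#' @export
roc_points <- function(values, labels) {
  cls <- .split_classes(values, labels)
  n1 <- length(cls$case); n0 <- length(cls$control)
  thr <- sort(unique(values), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(cls$case >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(cls$control >= t) / n0, numeric(1))
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                      threshold = c(Inf, thr))
  auc <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
  structure(list(curve = curve, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC curve:", nrow(x$curve), "points, AUC =", round(x$auc, 4), "\n")
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "s", xlab = "False positive rate",
       ylab = "True positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3, col = "grey50")
  text(0.7, 0.1, sprintf("AUC = %.3f", x$auc))
  invisible(x)
}

#' Re-filter candidate genes on the testing cohort
#'
#' Retains candidates that still differentiate the classes in the
#' held-out cohort: a two-sided rank-sum (Wilcoxon) test per gene must
#' give p < `alpha`.  Genes with no between-class difference are
#' excluded, mirroring testing-set confirmation of training-derived
#' candidates.
#'
#' @param candidates a `candidate_set` (or data.frame with a `gene`
#'   column).
#' @param expr_test genes x samples matrix of the testing cohort.
#' @param labels_test class labels for the testing samples.
#' @param alpha significance level of the rank-sum test.
#' @param test `"wilcox"` (default) or `"t"` (Welch).
#' @return the retained subset of `candidates`, with a `p_test` column
#'   appended.
#' @export
test_set_filter <- function(candidates, expr_test, labels_test, alpha = 0.05,
                            test = c("wilcox", "t")) {
  test <- match.arg(test)
  if (nrow(candidates) == 0L) stop("empty candidate set")
  genes <- candidates$gene
  missing <- setdiff(genes, rownames(expr_test))
  if (length(missing))
    stop("testing matrix lacks candidate gene(s): ",
         paste(head(missing, 5), collapse = ", "))
  y <- if (is.data.frame(labels_test)) labels_test$class else labels_test
  y <- .as_class_factor(y)
  p <- vapply(genes, function(g) {
    v <- expr_test[g, ]
    if (test == "wilcox")
      suppressWarnings(wilcox.test(v[y == "case"], v[y == "control"])$p.value)
    else
      stats::t.test(v[y == "case"], v[y == "control"])$p.value
  }, numeric(1))
  p[is.na(p)] <- 1                  # fully tied genes cannot differentiate
  out <- candidates[p < alpha, , drop = FALSE]
  out$p_test <- p[p < alpha]
  attr(out, "alpha") <- alpha
  attr(out, "excluded") <- genes[!(p < alpha)]
  out
}

#' Relative qPCR quantification against a reference gene
#'
#' Delta-Ct quantification: the relative content of the target in each
#' sample is `2^-(Ct_target - Ct_reference)`, i.e. scaled to the
#' reference gene (typically GAPDH).  With a `calibrator` sample given,
#' the delta-delta-Ct form `2^-(dCt - dCt_calibrator)` is returned
#' instead.
#'
#' @param ct_target cycle-threshold values of the target gene.
#' @param ct_reference cycle-threshold values of the reference gene,
#'   same samples.
#' @param calibrator optional index (or name) of the calibrator sample
#'   for delta-delta-Ct.
#' @return positive relative-content values, one per sample.
#' @export
relative_qpcr <- function(ct_target, ct_reference, calibrator = NULL) {
  if (length(ct_target) != length(ct_reference))
    stop("target and reference Ct vectors differ in length")
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite")
  dct <- ct_target - ct_reference
  if (!is.null(calibrator)) dct <- dct - dct[calibrator]
  2^(-dct)
}
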