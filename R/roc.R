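#' One-vs-rest ROC curve and AUC
#'
#' Sweeps all unique scores as thresholds (predicted positive when
#' `score >= threshold`), from `Inf` down, and integrates the curve by the
#' trapezoidal rule. The AUC equals the Mann-Whitney pairwise concordance
#' probability (ties counted 1/2).
#'
#' @param scores Numeric vector of scores for the positive class, or a
#'   posterior matrix with a column named `positive_class`.
#' @param labels Class labels, same length as rows of `scores`.
#' @param positive_class The class treated as positive.
#' @return An object of class `roc_result`: `thresholds` (decreasing,
#'   starting at `Inf`), `tpr`, `fpr`, `auc`, `positive_class`, and
#'   `defined` (`FALSE` when either the positive or negative side is empty,
#'   in which case `auc` is `NA` and the curve is degenerate).
#' @export
roc_curve <- function(scores, labels, positive_class) {
  if (is.matrix(scores) || is.data.frame(scores)) {
    if (!positive_class %in% colnames(scores)) {
      stopf("no score column for class '%s'", positive_class)
    }
    scores <- as.numeric(as.matrix(scores)[, positive_class])
  }
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive_class
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    return(structure(list(thresholds = Inf, tpr = 0, fpr = 0, auc = NA_real_,
                          positive_class = positive_class, defined = FALSE),
                     class = "roc_result"))
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  tp_cum <- cumsum(pos[ord])
  fp_cum <- cumsum(!pos[ord])
  # last row index at each unique threshold in the sorted order
  last <- cumsum(rle(scores[ord])$lengths)
  tpr <- c(0, tp_cum[last] / n_pos)
  fpr <- c(0, fp_cum[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, thr), tpr = tpr, fpr = fpr, auc = auc,
                 positive_class = positive_class, defined = TRUE),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("ROC (positive = %s): undefined (one-sided labels)\n",
                x$positive_class))
  } else {
    cat(sprintf("ROC (positive = %s): AUC = %.4f over %d thresholds\n",
                x$positive_class, x$auc, length(x$thresholds)))
  }
  invisible(x)
}

# Per-class one-vs-rest ROC plus macro-average AUC over the defined classes.
roc_multiclass <- function(posteriors, labels,
                           classes = colnames(posteriors)) {
  per_class <- lapply(classes, function(cl) roc_curve(posteriors, labels, cl))
  names(per_class) <- classes
  aucs <- vapply(per_class, function(r) r$auc, numeric(1))
  list(per_class = per_class, auc = aucs,
       macro_auc = mean(aucs[!is.na(aucs)]))
}

#' Youden-optimal ROC cutoff
#'
#' The threshold maximizing Youden's J = TPR - FPR (equivalently
#' TPR + TNR - 1). Ties are resolved towards the lower threshold, i.e. the
#' more sensitive operating point.
#'
#' @param roc A [roc_curve()] result with `defined = TRUE`.
#' @return The optimal threshold (a score value, or `Inf` if no finite
#'   threshold improves on predicting nothing positive).
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  if (!roc$defined) stopf("cutoff undefined: class '%s' has a one-sided curve",
                          roc$positive_class)
  j <- roc$tpr - roc$fpr
  best <- max(j)
  # thresholds are decreasing: the last maximizer is the lowest threshold
  roc$thresholds[max(which(j >= best - 1e-12))]
}

#' Classify posteriors against per-class cutoffs
#'
#' One-vs-rest exceedance rule: a class is a candidate when its posterior
#' meets its cutoff. If exactly one candidate exceeds, it is predicted; with
#' several, the class with the largest margin (posterior minus cutoff) wins;
#' with none, the class with the least-negative margin wins. Margin ties go
#' to the earlier class in column order, so the rule is deterministic.
#'
#' @param posteriors Numeric matrix, rows = observations, named columns =
#'   classes.
#' @param cutoffs Single threshold or named per-class vector (default 0.5).
#' @return Factor of predicted classes (levels = posterior columns).
#' @export
classify_at_cutoff <- function(posteriors, cutoffs = 0.5) {
  posteriors <- as.matrix(posteriors)
  classes <- colnames(posteriors)
  if (is.null(classes)) stopf("posteriors must have class column names")
  if (length(cutoffs) == 1) {
    cutoffs <- stats::setNames(rep(cutoffs, length(classes)), classes)
  }
  if (!all(classes %in% names(cutoffs))) {
    stopf("cutoffs must cover all classes")
  }
  margin <- sweep(posteriors, 2, cutoffs[classes], "-")
  pick <- vapply(seq_len(nrow(margin)), function(i) {
    m <- margin[i, ]
    cand <- which(m >= 0)
    if (!length(cand)) cand <- seq_along(m)
    cand[which.max(m[cand])]
  }, integer(1))
  factor(classes[pick], levels = classes)
}

#' Prevalence-weighted overall accuracy
#'
#' Combines per-class true positive rates into an overall accuracy weighted
#' by class prevalence: `sum(n_c * TPR_c) / sum(n_c)`.
#'
#' @param per_class_tpr Per-class true positive rates (fractions or
#'   percentages).
#' @param class_counts Class sizes, same order.
#' @return Overall accuracy on the scale of the input TPRs.
#' @examples
#' overall_accuracy(c(90.9, 38.9, 88.4), c(192, 22, 84))  # 86.4
#' @export
overall_accuracy <- function(per_class_tpr, class_counts) {
  stopifnot(length(per_class_tpr) == length(class_counts),
            all(class_counts >= 0))
  sum(per_class_tpr * class_counts) / sum(class_counts)
}
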