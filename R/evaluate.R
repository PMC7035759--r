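#' Pixel-level confusion counts
#'
#' Standard 2x2 counts of a predicted against a ground-truth binary
#' mask, with panicle as the positive class.
#'
#' @param pred,truth logical vectors of equal length.
#' @return A list of class `confusion_counts` with integer `tp`, `fp`,
#'   `tn`, `fn` summing to `length(pred)`.
#' @export
confusion <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  structure(list(tp = sum(pred & truth), fp = sum(pred & !truth),
                 tn = sum(!pred & !truth), fn = sum(!pred & truth)),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Recall `tp/(tp+fn)`, precision `tp/(tp+fp)`, their harmonic mean
#' F1, and the ROC coordinates (true positive rate = recall, false
#' positive rate `fp/(fp+tn)`). A metric whose denominator is zero is
#' undefined and reported as `NA`, never as 0.
#'
#' @param cc a `confusion_counts` object (or a list with `tp`, `fp`,
#'   `tn`, `fn`).
#' @return A list with `recall`, `precision`, `f1`, `tpr`, `fpr`.
#' @export
seg_metrics <- function(cc) {
  recall <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_
  precision <- if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  fpr <- if (cc$fp + cc$tn > 0) cc$fp / (cc$fp + cc$tn) else NA_real_
  list(recall = recall, precision = precision, f1 = f1,
       tpr = recall, fpr = fpr)
}

#' ROC sweep over the panicle posterior threshold
#'
#' Traces the operating characteristic of the thresholded classifier:
#' each point applies [threshold_classify()] at one threshold and
#' records the true and false positive rates against the ground
#' truth. As the threshold decreases both rates are non-decreasing.
#'
#' @param posteriors n x k posterior matrix.
#' @param component panicle component index.
#' @param truth length-n logical ground-truth mask.
#' @param thresholds decreasing sequence of thresholds.
#' @return A data frame of class `roc_curve` with columns `threshold`,
#'   `tpr`, `fpr`.
#' @export
roc_sweep <- function(posteriors, component, truth,
                      thresholds = seq(1, 0, by = -0.01)) {
  if (is.unsorted(rev(thresholds), strictly = FALSE))
    stop("thresholds must be sorted in decreasing order")
  pts <- vapply(thresholds, function(th) {
    m <- seg_metrics(confusion(threshold_classify(posteriors, component, th),
                               truth))
    c(m$tpr, m$fpr)
  }, numeric(2))
  structure(data.frame(threshold = thresholds, tpr = pts[1L, ],
                       fpr = pts[2L, ]),
            class = c("roc_curve", "data.frame"))
}

#' Average ROC curves over images
#'
#' Pointwise mean of the true and false positive rates at matched
#' thresholds, the way per-image curves taken at the same flight
#' altitude are summarized.
#'
#' @param curves list of `roc_curve` data frames sharing one
#'   threshold grid.
#' @return A single `roc_curve` on the common grid.
#' @export
average_curves <- function(curves) {
  if (length(curves) == 0L) stop("no curves to average")
  grid <- curves[[1L]]$threshold
  for (cv in curves)
    if (!isTRUE(all.equal(cv$threshold, grid)))
      stop("curves must share the same threshold grid")
  structure(data.frame(
    threshold = grid,
    tpr = rowMeans(vapply(curves, function(cv) cv$tpr, numeric(length(grid)))),
    fpr = rowMeans(vapply(curves, function(cv) cv$fpr, numeric(length(grid))))),
    class = c("roc_curve", "data.frame"))
}
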