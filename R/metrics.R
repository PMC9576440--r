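#' Voxelwise confusion counts between gold standard and prediction
#'
#' @param e binary gold-standard `mask_volume` or array.
#' @param f binary predicted `mask_volume` or array, same shape.
#' @return object of class `confusion_counts`: list with tp, tn, fp, fn.
#' @export
confusion <- function(e, f) {
  ev <- as_voxels(e); fv <- as_voxels(f)
  check_same_shape(ev, fv, "gold standard and prediction")
  check_binary(ev, "gold standard"); check_binary(fv, "prediction")
  tp <- sum(ev == 1 & fv == 1)
  tn <- sum(ev == 0 & fv == 0)
  fp <- sum(ev == 0 & fv == 1)
  fn <- sum(ev == 1 & fv == 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' Per-case segmentation scores from confusion counts
#'
#' IOU = TP/(TP+FP+FN), Dice = 2TP/(2TP+FP+FN), Precision = TP/(TP+FP),
#' Recall = TP/(TP+FN). When a denominator is zero because prediction and
#' gold standard are both empty the score is defined as 1 (perfect agreement
#' on absence); an empty side against a nonempty one scores 0.
#'
#' @param counts a [confusion()] result (or list with tp, tn, fp, fn).
#' @param case_id identifier attached to the result.
#' @return object of class `case_metrics`: list with case_id, iou, dice,
#'   precision, recall.
#' @export
case_metrics <- function(counts, case_id = "case") {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, counts$tn, fp, fn) < 0))
    stop("confusion counts must be non-negative", call. = FALSE)
  safe <- function(num, den) if (den == 0) 1 else num / den
  structure(list(case_id = case_id,
                 iou = safe(tp, tp + fp + fn),
                 dice = safe(2 * tp, 2 * tp + fp + fn),
                 precision = safe(tp, tp + fp),
                 recall = safe(tp, tp + fn)),
            class = "case_metrics")
}

#' @rdname case_metrics
#' @param e,f gold-standard and predicted masks (shortcut computing
#'   [confusion()] first).
#' @export
score_case <- function(e, f, case_id = "case") {
  case_metrics(confusion(e, f), case_id = case_id)
}

#' Macro-average metrics over cases
#'
#' Unweighted arithmetic mean of IOU, Dice, precision and recall across
#' cases (each case counts equally, regardless of its voxel count).
#'
#' @param cases list of [case_metrics()] results.
#' @return `case_metrics` with case_id "Average".
#' @export
aggregate_metrics <- function(cases) {
  if (length(cases) == 0) stop("no cases to aggregate", call. = FALSE)
  structure(list(case_id = "Average",
                 iou = mean(vapply(cases, `[[`, 0, "iou")),
                 dice = mean(vapply(cases, `[[`, 0, "dice")),
                 precision = mean(vapply(cases, `[[`, 0, "precision")),
                 recall = mean(vapply(cases, `[[`, 0, "recall"))),
            class = "case_metrics")
}

#' Tabulate per-case metrics with an Average row
#'
#' @param cases list of [case_metrics()].
#' @return data.frame with columns case_id, iou, dice, precision, recall;
#'   the last row is the macro average.
#' @export
metrics_table <- function(cases) {
  rows <- c(cases, list(aggregate_metrics(cases)))
  do.call(rbind, lapply(rows, function(m)
    data.frame(case_id = m$case_id, iou = m$iou, dice = m$dice,
               precision = m$precision, recall = m$recall,
               stringsAsFactors = FALSE)))
}

#' @export
print.case_metrics <- function(x, ...) {
  cat(sprintf("<case '%s': IOU %.4f  Dice %.4f  Precision %.4f  Recall %.4f>\n",
              x$case_id, x$iou, x$dice, x$precision, x$recall))
  invisible(x)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion tp=%d tn=%d fp=%d fn=%d>\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}
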