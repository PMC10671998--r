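# Single-class detection evaluation: IOU-thresholded confusion counts with
# TN = FN fixed at zero (there is exactly one class, "lesion", and every
# ground-truth box yields a matched pair), and the derived accuracy,
# precision, sensitivity, F1 and mean IOU. Under this accounting accuracy
# always equals precision, and sensitivity is 1 for any evaluation with at
# least one detection.

#' Greedy matching of predicted to ground-truth boxes
#'
#' Pairs are assigned greedily in descending IOU order; every non-sentinel
#' ground-truth box is matched to at most one non-sentinel predicted box, and
#' ground-truth boxes left unmatched (no prediction, or all predictions
#' taken) are paired with IOU 0. Sentinel entries on either side are ignored.
#'
#' @param pred,actual box arrays.
#' @return data frame with columns `actual_index`, `pred_index` (`NA` when
#'   unmatched) and `iou`, one row per non-sentinel ground-truth box.
#' @export
match_boxes <- function(pred, actual) {
  pred <- unclass(pred); actual <- unclass(actual)
  ai <- which(!is_sentinel_box(actual))
  pi <- which(!is_sentinel_box(pred))
  out <- data.frame(actual_index = integer(0), pred_index = integer(0),
                    iou = numeric(0))
  if (!length(ai)) return(out)
  iom <- matrix(0, length(ai), length(pi))
  for (a in seq_along(ai)) for (p in seq_along(pi))
    iom[a, p] <- box_iou(actual[ai[a], ], pred[pi[p], ])
  used_a <- logical(length(ai)); used_p <- logical(length(pi))
  rows <- list()
  while (length(pi) && any(!used_a) && any(!used_p)) {
    sub <- iom
    sub[used_a, ] <- -1; sub[, used_p] <- -1
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]  # first index on ties
    if (sub[best[1], best[2]] < 0) break
    used_a[best[1]] <- TRUE; used_p[best[2]] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      actual_index = ai[best[1]], pred_index = pi[best[2]],
      iou = iom[best[1], best[2]])
  }
  for (a in which(!used_a))
    rows[[length(rows) + 1L]] <- data.frame(actual_index = ai[a],
                                            pred_index = NA_integer_, iou = 0)
  out <- do.call(rbind, rows)
  out[order(out$actual_index), , drop = FALSE]
}

#' Confusion counts from matched IOUs
#'
#' A matched pair is a true positive when its IOU exceeds the threshold and a
#' false positive otherwise (an IOU exactly at the threshold counts as FP);
#' true negatives and false negatives are fixed at zero by the single-class
#' protocol.
#'
#' @param matched_ious numeric vector of matched IOUs in `[0,1]`.
#' @param threshold IOU threshold (default 0.5).
#' @return list with `tp`, `fp`, `tn = 0`, `fn = 0`.
#' @export
confusion_counts <- function(matched_ious, threshold = 0.5) {
  stopifnot(all(matched_ious >= 0 & matched_ious <= 1))
  list(tp = sum(matched_ious > threshold),
       fp = sum(matched_ious <= threshold), tn = 0L, fn = 0L)
}

#' Summary metrics of a single-class evaluation
#'
#' With `tn = fn = 0`: precision `= tp/(tp+fp)`, accuracy
#' `= tp/(tp+fp+tn+fn) = precision`, sensitivity `= tp/(tp+fn) = 1` by
#' convention whenever there is at least one detection (0, with a warning
#' flag, when there is none), and `F1 = 2*p*s/(p+s)`.
#'
#' @param tp,fp confusion counts.
#' @param matched_ious the matched IOUs the counts came from (for mean IOU
#'   and the per-image record).
#' @param per_image optional list of per-image IOU vectors kept in the
#'   report.
#' @return an object of class `detection_report`.
#' @export
summarize_detections <- function(tp, fp, matched_ious, per_image = NULL) {
  n <- tp + fp
  no_detections <- n == 0
  precision <- if (no_detections) 0 else tp / n
  sensitivity <- if (no_detections) 0 else 1
  f1 <- if (precision + sensitivity == 0) 0 else
    2 * precision * sensitivity / (precision + sensitivity)
  structure(list(tp = tp, fp = fp, tn = 0L, fn = 0L,
                 accuracy = precision, precision = precision,
                 sensitivity = sensitivity, f1 = f1,
                 mean_iou = if (length(matched_ious)) mean(matched_ious) else 0,
                 per_image = per_image, no_detections = no_detections),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat("Single-class detection report\n")
  cat(sprintf("  TP %d  FP %d  (TN = FN = 0 by protocol)\n", x$tp, x$fp))
  cat(sprintf("  accuracy    %.4f\n  precision   %.4f\n", x$accuracy, x$precision))
  cat(sprintf("  sensitivity %.4f\n  F1          %.4f\n", x$sensitivity, x$f1))
  cat(sprintf("  mean IOU    %.4f over %d matched pairs\n",
              x$mean_iou, x$tp + x$fp))
  if (x$no_detections) cat("  [warning: no detections]\n")
  invisible(x)
}

#' Write a detection report to disk
#'
#' A flat key-value text file plus, when per-image IOUs are present, a CSV
#' `<path>_per_image.csv` of matched IOUs.
#'
#' @param report a `detection_report`.
#' @param path destination for the key-value report.
#' @export
write_report <- function(report, path) {
  keys <- c("tp", "fp", "tn", "fn", "accuracy", "precision", "sensitivity",
            "f1", "mean_iou")
  writeLines(sprintf("%s=%.10g", keys,
                     vapply(keys, function(k) as.numeric(report[[k]]), 0)), path)
  if (!is.null(report$per_image)) {
    rows <- do.call(rbind, lapply(seq_along(report$per_image), function(i)
      if (length(report$per_image[[i]]))
        data.frame(image = i, iou = report$per_image[[i]]) else NULL))
    utils::write.csv(rows, paste0(tools::file_path_sans_ext(path),
                                  "_per_image.csv"), row.names = FALSE)
  }
  invisible(path)
}
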