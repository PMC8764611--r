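#' Threshold a probability map into a binary mask
#'
#' A pixel is called positive when its probability is greater than or equal
#' to the threshold (inclusive comparison).
#'
#' @param probabilities Numeric matrix (or array with a trailing singleton
#'   channel) of per-pixel probabilities in \[0, 1\].
#' @param threshold Scalar in (0, 1); default 0.5.
#' @return Integer matrix in \{0, 1\} of the same spatial size.
#' @export
binarize <- function(probabilities, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop_user("`threshold` must be a single number in (0, 1)")
  p <- drop_channel(probabilities)
  m <- (p >= threshold) + 0L
  dim(m) <- dim(p)
  m
}

drop_channel <- function(x) {
  d <- dim(x)
  if (!is.null(d) && length(d) == 3 && d[3] == 1) dim(x) <- d[1:2]
  if (is.null(dim(x)) || length(dim(x)) != 2)
    stop_user("expected a 2-D grid (or H x W x 1 array)")
  x
}

#' Per-image intersection over union with empty-mask conventions
#'
#' For slices whose ground truth contains no ascites the usual IoU is
#' undefined; the convention used here scores an empty prediction on an
#' empty truth as exactly 1 (the model correctly segmented nothing) and any
#' spurious prediction on an empty truth as exactly 0.
#'
#' @param pred,truth Binary masks (matrices in \{0, 1\}) on the same grid.
#' @return A list of class `iou_score` with elements `value` (in \[0, 1\])
#'   and `case` (`"standard"`, `"empty_empty"` or `"spurious_on_normal"`).
#' @examples
#' iou(matrix(0, 4, 4), matrix(0, 4, 4))$value  # 1: nothing to find, nothing found
#' @export
iou <- function(pred, truth) {
  pred <- drop_channel(pred); truth <- drop_channel(truth)
  if (!identical(dim(pred), dim(truth)))
    stop_user("`pred` and `truth` must be on the same grid")
  check_binary(pred); check_binary(truth)
  np <- sum(pred != 0); nt <- sum(truth != 0)
  if (nt == 0) {
    out <- if (np == 0) list(value = 1, case = "empty_empty")
           else list(value = 0, case = "spurious_on_normal")
  } else {
    inter <- sum(pred != 0 & truth != 0)
    union <- np + nt - inter
    out <- list(value = inter / union, case = "standard")
  }
  structure(out, class = "iou_score")
}

check_binary <- function(m) {
  if (!all(m %in% c(0, 1)))
    stop_user("masks must contain only 0 and 1")
  invisible(m)
}

#' Mean IoU over a set of slices
#'
#' @param scores List of `iou_score` objects (or a numeric vector of IoU
#'   values).
#' @return Arithmetic mean of the IoU values.
#' @export
mean_iou <- function(scores) {
  if (length(scores) == 0) stop_user("`scores` is empty")
  v <- if (is.numeric(scores)) scores
       else vapply(scores, function(s) s$value, numeric(1))
  mean(v)
}

#' Slice-level detection score from a predicted mask
#'
#' At inference time no ground truth exists, so a slice is scored by the
#' fraction of its pixels predicted positive; sweeping a threshold over
#' this score yields the detection ROC curve.
#'
#' @param pred Binary mask.
#' @return Fraction of positive pixels, in \[0, 1\].
#' @export
detection_score <- function(pred) {
  pred <- drop_channel(pred)
  check_binary(pred)
  sum(pred != 0) / length(pred)
}

#' Classify slices as ascites/normal from detection scores
#'
#' A slice is declared ascites when its score is equal to or greater than
#' the threshold.
#'
#' @param scores Numeric vector of per-slice detection scores.
#' @param threshold Declaration threshold (inclusive).
#' @return Character vector of `"ascites"`/`"normal"`.
#' @export
classify_slices <- function(scores, threshold) {
  ifelse(scores >= threshold, "ascites", "normal")
}

#' ROC curve and AUROC for slice-level detection
#'
#' Thresholds are placed at the distinct score values (ties grouped),
#' scanned in descending order; AUROC is the trapezoidal area, which with
#' this tie handling equals the rank statistic P(score_pos > score_neg)
#' with ties credited 1/2.
#'
#' @param scores Numeric vector of detection scores.
#' @param labels Vector in \{0, 1\} (1 = ascites), same length as `scores`.
#' @return A list of class `roc_curve` with `thresholds` (descending),
#'   `fpr`, `tpr` (each starting at 0 and ending at 1) and `auroc`.
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop_user("`scores` and `labels` differ in length")
  if (!all(labels %in% c(0, 1))) stop_user("`labels` must be 0/1")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop_user("both classes must be present to plot an ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- c(s[-length(s)] != s[-1], TRUE)  # last index of each tie group
  tp <- cumsum(l == 1)[keep]
  fp <- cumsum(l == 0)[keep]
  tpr <- c(0, tp / npos); fpr <- c(0, fp / nneg)
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(thresholds = c(Inf, s[keep]), fpr = fpr, tpr = tpr,
                 auroc = auroc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, AUROC = %.4f\n",
              length(x$thresholds), x$auroc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("AUROC = %.3f", x$auroc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Confusion counts for slice-level detection
#'
#' @param truth,pred Vectors of class labels; anything equal to 1 or
#'   `"ascites"` counts as positive.
#' @return A list of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop_user("`truth` and `pred` differ in length")
  t1 <- truth == 1 | truth == "ascites"
  p1 <- pred == 1 | pred == "ascites"
  structure(list(TP = sum(t1 & p1), FP = sum(!t1 & p1),
                 TN = sum(!t1 & !p1), FN = sum(t1 & !p1)),
            class = "confusion_counts")
}

#' Detection metrics from confusion counts
#'
#' Sensitivity = TP/(TP+FN), Specificity = TN/(TN+FP),
#' Accuracy = (TP+TN)/n, Balanced accuracy = (Sens+Spec)/2,
#' Precision = TP/(TP+FP), F1 = 2 Sens Prec/(Sens+Prec).
#' A metric whose denominator is zero raises an error naming the metric;
#' silent zeros would corrupt averaged summaries.
#'
#' @param counts A `confusion_counts` object (or list with TP/FP/TN/FN).
#' @return Named list: sensitivity, specificity, accuracy,
#'   balanced_accuracy, precision, f1.
#' @export
detection_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (any(c(TP, FP, TN, FN) < 0)) stop_user("counts must be non-negative")
  if (TP + FN == 0) stop_user("sensitivity undefined: no positive cases (TP+FN = 0)")
  if (TN + FP == 0) stop_user("specificity undefined: no negative cases (TN+FP = 0)")
  if (TP + FP == 0) stop_user("precision undefined: no predicted positives (TP+FP = 0)")
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  acc  <- (TP + TN) / (TP + TN + FP + FN)
  prec <- TP / (TP + FP)
  if (sens + prec == 0) stop_user("f1 undefined: sensitivity + precision = 0")
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       balanced_accuracy = (sens + spec) / 2, precision = prec,
       f1 = 2 * sens * prec / (sens + prec))
}

#' Balanced accuracy and F1 from already-computed rates
#'
#' Useful for checking the internal consistency of published metric tables:
#' balanced accuracy and F1 are determined by sensitivity, specificity and
#' precision alone.
#'
#' @param sensitivity,specificity,precision Fractions in \[0, 1\].
#' @return List with `balanced_accuracy` and `f1` at full precision plus
#'   `balanced_accuracy_2dp` and `f1_2dp` rounded half-up to 2 decimals.
#' @export
metrics_from_rates <- function(sensitivity, specificity, precision) {
  stopifnot(all(c(sensitivity, specificity, precision) >= 0),
            all(c(sensitivity, specificity, precision) <= 1))
  if (sensitivity + precision <= 0)
    stop_user("f1 undefined: sensitivity + precision = 0")
  ba <- (sensitivity + specificity) / 2
  f1 <- 2 * sensitivity * precision / (sensitivity + precision)
  list(balanced_accuracy = ba, f1 = f1,
       balanced_accuracy_2dp = round_half_up(ba, 2),
       f1_2dp = round_half_up(f1, 2))
}

# round() ties-to-even differs from how metric tables are usually printed
round_half_up <- function(x, digits) floor(x * 10^digits + 0.5) / 10^digits

#' Estimate fluid volume from a stack of segmentation masks
#'
#' Volume (mL) = sum over slices of |mask| x row spacing x col spacing x
#' slice thickness / 1000. When masks were produced on a down-sampled grid,
#' pass `source_grid` (the acquisition grid size); the pixel spacing is then
#' scaled by `source_grid / mask grid` per axis.
#'
#' @param masks List of binary masks (one per slice).
#' @param pixel_spacing_mm Length-1 or length-2 numeric, mm per pixel at the
#'   acquisition grid (row, col).
#' @param slice_thickness_mm Slice thickness in mm.
#' @param source_grid Optional acquisition grid size in pixels, if the masks
#'   are on a resized grid.
#' @return List of class `volume_estimate`: `volume_ml` and
#'   `per_slice_areas_mm2`.
#' @export
estimate_volume <- function(masks, pixel_spacing_mm, slice_thickness_mm,
                            source_grid = NULL) {
  if (is.null(pixel_spacing_mm) || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0))
    stop_user("`pixel_spacing_mm` metadata is missing or invalid")
  if (is.null(slice_thickness_mm) || !is.finite(slice_thickness_mm) ||
      slice_thickness_mm <= 0)
    stop_user("`slice_thickness_mm` metadata is missing or invalid")
  if (length(pixel_spacing_mm) == 1)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  if (!is.list(masks)) masks <- list(masks)
  areas <- vapply(masks, function(m) {
    m <- drop_channel(m)
    check_binary(m)
    sp <- pixel_spacing_mm
    if (!is.null(source_grid)) sp <- sp * source_grid / dim(m)
    sum(m != 0) * sp[1] * sp[2]
  }, numeric(1))
  structure(list(volume_ml = sum(areas) * slice_thickness_mm / 1000,
                 per_slice_areas_mm2 = areas),
            class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("Estimated fluid volume: %.1f mL over %d slices\n",
              x$volume_ml, length(x$per_slice_areas_mm2)))
  invisible(x)
}

#' Joint segmentation/detection evaluation of a fitted model
#'
#' Runs the model on every slice of a preprocessed dataset and computes the
#' per-image IoU (with the empty-mask conventions of [iou()]), mIoU,
#' detection ROC/AUROC over the predicted-area score, confusion counts and
#' metrics at `detect_threshold`, and the predicted fluid volume.
#'
#' @param object A fitted [resunet] model.
#' @param data A `seg_data` set (see [preprocess_dataset()]).
#' @param threshold Pixel probability threshold for [binarize()].
#' @param detect_threshold Area-fraction threshold declaring a slice
#'   ascites; default 1e-3 (a handful of pixels).
#' @return List of class `evaluation_report`: `per_slice` data frame,
#'   `miou`, `roc`, `auroc`, `confusion`, `metrics`, `volume`.
#' @export
evaluate_model <- function(object, data, threshold = 0.5,
                           detect_threshold = 1e-3) {
  stopifnot(inherits(object, "resunet"), inherits(data, "seg_data"))
  prob <- predict(object, data$x)
  n <- dim(data$x)[3]
  ious <- numeric(n); cases <- character(n); scores <- numeric(n)
  pred_masks <- vector("list", n)
  for (i in seq_len(n)) {
    pm <- binarize(prob[, , i, 1], threshold)
    tm <- data$y[, , i, 1]
    sc <- iou(pm, tm)
    ious[i] <- sc$value; cases[i] <- sc$case
    scores[i] <- detection_score(pm)
    pred_masks[[i]] <- pm
  }
  labels <- as.integer(data$manifest$has_ascites)
  roc <- roc_curve(scores, labels)
  pred_lab <- classify_slices(scores, detect_threshold)
  cm <- confusion(labels, as.integer(pred_lab == "ascites"))
  vol <- estimate_volume(pred_masks, data$pixel_spacing_mm,
                         data$slice_thickness_mm,
                         source_grid = data$source_grid)
  # degenerate operating points (e.g. a model that declares nothing) leave
  # the rate metrics undefined; report NULL rather than abort the evaluation
  metrics <- tryCatch(detection_metrics(cm), error = function(e) NULL)
  structure(list(
    per_slice = data.frame(subject_id = data$manifest$subject_id,
                           slice_index = data$manifest$slice_index,
                           has_ascites = data$manifest$has_ascites,
                           iou = ious, case = cases, score = scores),
    miou = mean(ious), roc = roc, auroc = roc$auroc,
    confusion = cm, metrics = metrics, volume = vol),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d slices\n", nrow(x$per_slice)))
  cat(sprintf("  mIoU:  %.3f\n", x$miou))
  cat(sprintf("  AUROC: %.3f\n", x$auroc))
  m <- x$metrics
  if (!is.null(m))
    cat(sprintf("  sens %.2f | spec %.2f | acc %.2f | bal acc %.2f | prec %.2f | F1 %.2f\n",
                m$sensitivity, m$specificity, m$accuracy,
                m$balanced_accuracy, m$precision, m$f1))
  cat(sprintf("  predicted fluid volume: %.1f mL\n", x$volume$volume_ml))
  invisible(x)
}
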