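# Detection metrics (precision, recall, AP, mAP@0.5) and the field-trial
# delivery metrics with trial-group aggregation.

round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Confusion counts
#'
#' @param TP,FP,FN,TN Non-negative counts.
#' @return List of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, FN, TN = 0L) {
  if (any(c(TP, FP, FN, TN) < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN),
            class = "confusion_counts")
}

#' Precision and recall
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`. A zero denominator yields
#' 0 with a warning.
#'
#' @param c A [confusion_counts()].
#' @return Named vector `c(precision, recall)`.
#' @export
precision_recall <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  p <- if (c$TP + c$FP > 0) c$TP / (c$TP + c$FP) else {
    warning("TP + FP = 0; precision defined as 0")
    0
  }
  r <- if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else {
    warning("TP + FN = 0; recall defined as 0")
    0
  }
  c(precision = p, recall = r)
}

std_boxes <- function(df) {
  if (!is.null(df$cx)) {
    data.frame(cx = df$cx, cy = df$cy, w = df$w, h = df$h)
  } else {
    data.frame(cx = df$x, cy = df$y, w = df$w, h = df$h)
  }
}

#' Average precision of a ranked detection list
#'
#' Detections are matched greedily in decreasing confidence order (ties
#' broken by detection index): a detection is a true positive when its
#' IoU with an unmatched ground-truth box of the same image reaches the
#' threshold. The precision-recall curve is integrated with the all-point
#' interpolation (precision at each recall level is the maximum precision
#' at any recall at least as large).
#'
#' @param detections Data frame with centre-format box columns (`cx`,
#'   `cy`, `w`, `h` or `x`, `y`, `w`, `h`), `conf`, optional `image`.
#' @param gts Data frame with the same box columns, optional `image`;
#'   must be non-empty.
#' @param iou_threshold Matching threshold (default 0.5).
#' @return AP in \\[0, 1\\].
#' @export
average_precision <- function(detections, gts, iou_threshold = 0.5) {
  if (is.null(gts) || nrow(gts) == 0L)
    stop("average precision is undefined without ground truths",
         call. = FALSE)
  n_gt <- nrow(gts)
  if (is.null(detections) || nrow(detections) == 0L) return(0)
  db <- std_boxes(detections)
  gb <- std_boxes(gts)
  dimg <- detections$image %||% rep(1L, nrow(db))
  gimg <- gts$image %||% rep(1L, nrow(gb))
  ord <- order(-detections$conf, seq_len(nrow(db)))
  gt_used <- logical(n_gt)
  tp <- numeric(length(ord))
  gxy <- cxcywh_to_xyxy(as.matrix(gb))
  dxy <- cxcywh_to_xyxy(as.matrix(db))
  for (k in seq_along(ord)) {
    i <- ord[k]
    cand <- which(gimg == dimg[i] & !gt_used)
    if (length(cand)) {
      ious <- iou_matrix(matrix(dxy[i, ], 1L), gxy[cand, , drop = FALSE])[1L, ]
      j <- which.max(ious)
      if (ious[j] >= iou_threshold) {
        tp[k] <- 1
        gt_used[cand[j]] <- TRUE
      }
    }
  }
  ctp <- cumsum(tp)
  prec <- ctp / seq_along(tp)
  rec <- ctp / n_gt
  # all-point interpolation
  iprec <- rev(cummax(rev(prec)))
  ap <- 0
  prev_r <- 0
  for (k in seq_along(rec)) {
    if (rec[k] > prev_r) {
      ap <- ap + (rec[k] - prev_r) * iprec[k]
      prev_r <- rec[k]
    }
  }
  ap
}

#' Mean average precision over classes at IoU 0.5
#'
#' @param aps Numeric vector of per-class APs.
#' @return Their arithmetic mean.
#' @export
map50 <- function(aps) {
  if (!length(aps)) stop("no classes", call. = FALSE)
  mean(aps)
}

#' Field-trial counts of one test group
#'
#' @param n_total Plants tested.
#' @param n_identified Plants identified by the detector.
#' @param n_success Plants that received granules at the target area.
#' @return List of class `field_trial_counts`.
#' @export
field_trial_counts <- function(n_total, n_identified, n_success) {
  if (!(n_success <= n_identified && n_identified <= n_total))
    stop("need n_success <= n_identified <= n_total", call. = FALSE)
  if (n_total < 0) stop("counts must be >= 0", call. = FALSE)
  structure(list(n_total = n_total, n_identified = n_identified,
                 n_success = n_success),
            class = "field_trial_counts")
}

#' Delivery-system metrics of one trial group
#'
#' Delivery rate `= 100 n_success / n_total`, detection accuracy
#' `= 100 n_identified / n_total` (the field instantiation of the
#' correctly-identified-over-total-leaf-areas ratio) and delivery
#' precision `= 100 n_success / n_identified`. The identity
#' `rate = accuracy x precision / 100` holds exactly on the unrounded
#' values.
#'
#' @param c A [field_trial_counts()].
#' @param digits Decimal places for the returned percentages (half-up
#'   rounding, as tabulated in field reports); `NULL` returns unrounded
#'   values.
#' @return Named vector `c(delivery_rate, detection_accuracy,
#'   delivery_precision)` in percent.
#' @export
delivery_metrics <- function(c, digits = 1L) {
  stopifnot(inherits(c, "field_trial_counts"))
  if (c$n_identified == 0L)
    stop("delivery precision undefined: no identified plants",
         call. = FALSE)
  if (c$n_total == 0L) stop("empty trial group", call. = FALSE)
  v <- c(delivery_rate = 100 * c$n_success / c$n_total,
         detection_accuracy = 100 * c$n_identified / c$n_total,
         delivery_precision = 100 * c$n_success / c$n_identified)
  if (!is.null(digits)) v <- round_half_up(v, digits)
  v
}

#' Summarise several trial groups
#'
#' Per-group percentages are computed (and tabulated) to one decimal, and
#' the group summary is the mean and sample standard deviation (n - 1
#' denominator) of those tabulated values, again to one decimal -- the
#' convention under which the published group table and its mean +/- SD
#' row are mutually consistent.
#'
#' @param groups List of [field_trial_counts()] (>= 2 groups).
#' @return List with `per_group` (matrix of per-group percentages),
#'   `mean` and `sd` (named vectors over the three metrics).
#' @export
summarize_trials <- function(groups) {
  if (length(groups) < 2L)
    stop("need >= 2 groups for a standard deviation", call. = FALSE)
  per <- t(vapply(groups, delivery_metrics, numeric(3L)))
  list(per_group = per,
       mean = round_half_up(colMeans(per), 1L),
       sd = round_half_up(apply(per, 2L, stats::sd), 1L))
}

#' Read field-trial counts from CSV
#'
#' Expected columns: `group`, `n_total`, `n_identified`, `n_success`.
#'
#' @param path CSV file path.
#' @return Named list of [field_trial_counts()], one per row.
#' @export
read_field_counts <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("n_total", "n_identified", "n_success") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i)
    field_trial_counts(df$n_total[i], df$n_identified[i], df$n_success[i]))
  names(out) <- df$group %||% seq_len(nrow(df))
  out
}
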