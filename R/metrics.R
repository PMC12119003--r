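# Detection evaluation: IoU, greedy confidence-ordered matching, precision/
# recall, average precision (101-point COCO-style interpolation by default),
# mAP50 and mAP50:95, confusion matrices, and a per-class CSV report.
#
# Conventions: boxes are corner-format (x1, y1, x2, y2); a zero-area box has
# IoU 0 with everything; P = 1 when TP = FP = 0 and R = 1 when TP = FN = 0;
# classes with zero ground-truth objects are excluded from class means.

#' Intersection over union of two boxes
#'
#' @param a,b numeric length-4 corner-format boxes `(x1, y1, x2, y2)`.
#' @return IoU in `[0, 1]`; degenerate (zero-area) boxes give 0.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
#' @export
iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (un <= 0) 0 else inter / un
}

iou_matrix <- function(A, B) {
  # A: n x 4, B: m x 4 matrices
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    ix <- pmax(0, pmin(A[i, 3], B[, 3]) - pmax(A[i, 1], B[, 1]))
    iy <- pmax(0, pmin(A[i, 4], B[, 4]) - pmax(A[i, 2], B[, 2]))
    inter <- ix * iy
    un <- (A[i, 3] - A[i, 1]) * (A[i, 4] - A[i, 2]) +
      (B[, 3] - B[, 1]) * (B[, 4] - B[, 2]) - inter
    out[i, ] <- ifelse(un > 0, inter / un, 0)
  }
  out
}

box_cols <- c("x1", "y1", "x2", "y2")

#' Match detections to ground truth boxes
#'
#' Greedy matching in descending confidence: each prediction claims the
#' unclaimed same-class ground-truth box of highest IoU, provided
#' IoU >= `iou_thr`. Matching is per image (`image_id` column, optional when
#' evaluating a single image).
#'
#' @param preds data frame with `class_id`, `conf`, `x1`, `y1`, `x2`, `y2`
#'   and optionally `image_id`.
#' @param gts data frame with `class_id`, `x1`, `y1`, `x2`, `y2` and
#'   optionally `image_id`.
#' @param iou_thr IoU threshold for a correct detection.
#' @return list with `counts` (TP/FP/FN per class over all classes present),
#'   `tp_flags` (logical per prediction, in descending-confidence order
#'   within the returned `order`), and `assignment` (gt row index or NA per
#'   prediction).
#' @export
match_detections <- function(preds, gts, iou_thr = 0.5) {
  if (is.null(preds$image_id)) preds$image_id <- 1L
  if (is.null(gts$image_id)) gts$image_id <- 1L
  ord <- order(-preds$conf)
  tp <- logical(nrow(preds))
  assign_gt <- rep(NA_integer_, nrow(preds))
  gt_used <- logical(nrow(gts))
  for (i in ord) {
    cand <- which(!gt_used & gts$image_id == preds$image_id[i] &
                    gts$class_id == preds$class_id[i])
    if (!length(cand)) next
    ious <- vapply(cand, function(j) {
      iou(as.numeric(preds[i, box_cols]), as.numeric(gts[j, box_cols]))
    }, numeric(1))
    best <- which.max(ious)
    if (ious[best] >= iou_thr) {
      tp[i] <- TRUE
      gt_used[cand[best]] <- TRUE
      assign_gt[i] <- cand[best]
    }
  }
  classes <- sort(unique(c(preds$class_id, gts$class_id)))
  counts <- do.call(rbind, lapply(classes, function(cl) {
    np <- sum(preds$class_id == cl)
    ng <- sum(gts$class_id == cl)
    ntp <- sum(tp & preds$class_id == cl)
    data.frame(class_id = cl, TP = ntp, FP = np - ntp, FN = ng - ntp)
  }))
  list(counts = counts, tp_flags = tp, assignment = assign_gt, order = ord)
}

#' Precision and recall from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, with the zero-denominator
#' conventions `P = 1` when no predictions and `R = 1` when no ground truth.
#'
#' @param counts a row (or aggregated counts) with `TP`, `FP`, `FN`.
#' @return precision / recall fraction.
#' @export
precision <- function(counts) {
  tp <- sum(counts$TP); fp <- sum(counts$FP)
  if (tp + fp == 0) 1 else tp / (tp + fp)
}

#' @rdname precision
#' @export
recall <- function(counts) {
  tp <- sum(counts$TP); fn <- sum(counts$FN)
  if (tp + fn == 0) 1 else tp / (tp + fn)
}

#' Average precision at a fixed IoU threshold
#'
#' Predictions of one class are sorted by descending confidence and matched
#' greedily; precision is taken to its envelope over recall and integrated
#' with 101-point interpolation (`interpolation = "101"`, the default) or
#' at every distinct recall value (`"all"`).
#'
#' @param preds,gts single-class data frames (see [match_detections()]).
#' @param iou_thr IoU threshold.
#' @param interpolation `"101"` or `"all"`.
#' @return AP in `[0, 1]`; 0 when there are ground truths but no
#'   predictions; NA when there is no ground truth.
#' @export
average_precision <- function(preds, gts, iou_thr = 0.5,
                              interpolation = c("101", "all")) {
  interpolation <- match.arg(interpolation)
  ng <- nrow(gts)
  if (ng == 0) return(NA_real_)
  if (nrow(preds) == 0) return(0)
  m <- match_detections(preds, gts, iou_thr)
  tp <- m$tp_flags[m$order]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  rec <- cum_tp / ng
  prec <- cum_tp / (cum_tp + cum_fp)
  # precision envelope (monotone non-increasing over recall)
  env <- rev(cummax(rev(prec)))
  if (interpolation == "101") {
    rs <- seq(0, 1, by = 0.01)
    idx <- findInterval(rs, rec, left.open = TRUE) + 1L
    mean(ifelse(idx <= length(env), env[idx], 0))
  } else {
    dr <- diff(c(0, rec))
    sum(env * dr)
  }
}

#' Mean average precision over classes and IoU thresholds
#'
#' `map_at` averages per-class AP at one IoU threshold (unweighted over
#' classes with at least one ground truth); `map50_95` averages `map_at`
#' over IoU 0.50 to 0.95 in 0.05 steps.
#'
#' @param preds,gts data frames (multi-class; see [match_detections()]).
#' @param num_classes class count (ids `0..num_classes-1`).
#' @param iou_thr IoU threshold for `map_at`.
#' @param interpolation passed to [average_precision()].
#' @return mAP fraction in `[0, 1]`.
#' @export
map_at <- function(preds, gts, num_classes, iou_thr = 0.5,
                   interpolation = "101") {
  aps <- vapply(seq_len(num_classes) - 1L, function(cl) {
    average_precision(preds[preds$class_id == cl, , drop = FALSE],
                      gts[gts$class_id == cl, , drop = FALSE],
                      iou_thr, interpolation)
  }, numeric(1))
  if (all(is.na(aps))) return(NA_real_)
  mean(aps, na.rm = TRUE)
}

#' @rdname map_at
#' @export
map50_95 <- function(preds, gts, num_classes, interpolation = "101") {
  thrs <- seq(0.5, 0.95, by = 0.05)
  mean(vapply(thrs, function(t) {
    map_at(preds, gts, num_classes, t, interpolation)
  }, numeric(1)), na.rm = TRUE)
}

#' Confusion matrix with a background class
#'
#' Predictions above `conf_thr` are matched to ground truths class-
#' agnostically (greedy, descending confidence, IoU >= `iou_thr`); matched
#' pairs increment `(predicted, true)`, unmatched predictions go to
#' `(predicted, background)` and unmatched ground truths to
#' `(background, true)`.
#'
#' @param preds,gts data frames (see [match_detections()]).
#' @param num_classes class count.
#' @param conf_thr confidence threshold.
#' @param iou_thr IoU threshold.
#' @return `(num_classes+1) x (num_classes+1)` integer matrix; the last
#'   row/column is background.
#' @export
confusion_matrix <- function(preds, gts, num_classes, conf_thr = 0.25,
                             iou_thr = 0.5) {
  K <- num_classes
  cm <- matrix(0L, K + 1, K + 1,
               dimnames = list(pred = c(0:(K - 1), "bg"),
                               true = c(0:(K - 1), "bg")))
  if (is.null(preds$image_id)) preds$image_id <- rep(1L, nrow(preds))
  if (is.null(gts$image_id)) gts$image_id <- rep(1L, nrow(gts))
  preds <- preds[preds$conf >= conf_thr, , drop = FALSE]
  gt_used <- logical(nrow(gts))
  ord <- order(-preds$conf)
  for (i in ord) {
    cand <- which(!gt_used & gts$image_id == preds$image_id[i])
    matched <- FALSE
    if (length(cand)) {
      ious <- vapply(cand, function(j) {
        iou(as.numeric(preds[i, box_cols]), as.numeric(gts[j, box_cols]))
      }, numeric(1))
      best <- which.max(ious)
      if (ious[best] >= iou_thr) {
        j <- cand[best]
        gt_used[j] <- TRUE
        cm[preds$class_id[i] + 1L, gts$class_id[j] + 1L] <-
          cm[preds$class_id[i] + 1L, gts$class_id[j] + 1L] + 1L
        matched <- TRUE
      }
    }
    if (!matched) {
      cm[preds$class_id[i] + 1L, K + 1L] <- cm[preds$class_id[i] + 1L, K + 1L] + 1L
    }
  }
  for (j in which(!gt_used)) {
    cm[K + 1L, gts$class_id[j] + 1L] <- cm[K + 1L, gts$class_id[j] + 1L] + 1L
  }
  cm
}

#' Per-class evaluation summary
#'
#' Produces the per-class report schema: instances, precision and recall at
#' `conf_thr`, AP50 and AP50:95 per class, unweighted overall means, and the
#' confusion matrix.
#'
#' @param preds,gts data frames (see [match_detections()]).
#' @param num_classes class count.
#' @param class_names optional names for the report.
#' @param conf_thr confidence threshold for the P/R columns and the
#'   confusion matrix.
#' @param iou_thr IoU threshold for the P/R columns.
#' @return list with `table` (data frame: Class, Instances, P, R, mAP50,
#'   `mAP50_95`; first row "all") and `confusion`.
#' @export
eval_summary <- function(preds, gts, num_classes, class_names = NULL,
                         conf_thr = 0.25, iou_thr = 0.5) {
  if (is.null(class_names)) {
    class_names <- sprintf("class_%02d", seq_len(num_classes) - 1L)
  }
  pc <- preds[preds$conf >= conf_thr, , drop = FALSE]
  rows <- lapply(seq_len(num_classes) - 1L, function(cl) {
    p_cl <- preds[preds$class_id == cl, , drop = FALSE]
    pc_cl <- pc[pc$class_id == cl, , drop = FALSE]
    g_cl <- gts[gts$class_id == cl, , drop = FALSE]
    m <- match_detections(pc_cl, g_cl, iou_thr)
    data.frame(
      Class = class_names[cl + 1L],
      Instances = nrow(g_cl),
      P = precision(m$counts), R = recall(m$counts),
      mAP50 = average_precision(p_cl, g_cl, 0.5),
      mAP50_95 = mean(vapply(seq(0.5, 0.95, 0.05), function(t) {
        average_precision(p_cl, g_cl, t)
      }, numeric(1)))
    )
  })
  tab <- do.call(rbind, rows)
  seen <- tab$Instances > 0
  all_row <- data.frame(
    Class = "all", Instances = sum(tab$Instances),
    P = mean(tab$P[seen]), R = mean(tab$R[seen]),
    mAP50 = mean(tab$mAP50[seen]),
    mAP50_95 = mean(tab$mAP50_95[seen])
  )
  if (!any(seen)) all_row[, c("P", "R", "mAP50", "mAP50_95")] <- NA_real_
  list(table = rbind(all_row, tab),
       confusion = confusion_matrix(preds, gts, num_classes, conf_thr,
                                    iou_thr))
}

#' Write the per-class report as CSV
#'
#' @param summary an [eval_summary()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_csv <- function(summary, path) {
  tab <- summary$table
  names(tab)[names(tab) == "mAP50_95"] <- "mAP50-95"
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Plot per-class precision-recall curves
#'
#' @param preds,gts data frames (see [match_detections()]).
#' @param num_classes class count.
#' @param path PNG output path.
#' @param iou_thr IoU threshold.
#' @return `path`, invisibly.
#' @export
plot_pr_curves <- function(preds, gts, num_classes, path, iou_thr = 0.5) {
  grDevices::png(path, width = 700, height = 600)
  on.exit(grDevices::dev.off())
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1), xlab = "recall",
                 ylab = "precision",
                 main = sprintf("PR curves @ IoU %.2f", iou_thr))
  cols <- grDevices::rainbow(num_classes)
  for (cl in seq_len(num_classes) - 1L) {
    p_cl <- preds[preds$class_id == cl, , drop = FALSE]
    g_cl <- gts[gts$class_id == cl, , drop = FALSE]
    if (!nrow(g_cl) || !nrow(p_cl)) next
    m <- match_detections(p_cl, g_cl, iou_thr)
    tp <- m$tp_flags[m$order]
    rec <- cumsum(tp) / nrow(g_cl)
    prec <- cumsum(tp) / seq_along(tp)
    graphics::lines(rec, prec, col = cols[cl + 1L])
  }
  invisible(path)
}
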