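# ---- detection/ground-truth matching --------------------------------------

#' Greedy matching of detections to ground truth
#'
#' Matches detections of one image and one class to ground-truth boxes.
#' Detections are visited in descending-confidence order; each is assigned to
#' the not-yet-matched ground truth with the highest IoU and flagged TP if
#' that IoU reaches \code{iou_threshold}, otherwise FP. Each ground truth
#' matches at most one detection; leftovers are FN.
#'
#' @param dets Detection data.frame (confidences used for ordering).
#' @param gts Ground-truth data.frame (boxes; conf ignored).
#' @param iou_threshold Minimum IoU for a true positive; default 0.5.
#' @return A list with \code{tp} (logical, in the order of \code{dets}),
#'   \code{conf}, \code{fn} (count of unmatched ground truths), and the
#'   summary counts \code{n_tp}, \code{n_fp}, \code{n_gt}.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  dets <- validate_detections(dets)
  gts <- validate_detections(gts)
  nd <- nrow(dets); ng <- nrow(gts)
  tp <- logical(nd)
  if (nd && ng) {
    iou <- box_iou_matrix(as.matrix(dets[, c("x1", "y1", "x2", "y2")]),
                          as.matrix(gts[, c("x1", "y1", "x2", "y2")]))
    taken <- logical(ng)
    for (i in order(-dets$conf)) {
      cand <- which(!taken)
      if (!length(cand)) break
      j <- cand[which.max(iou[i, cand])]
      if (iou[i, j] >= iou_threshold) {
        tp[i] <- TRUE
        taken[j] <- TRUE
      }
    }
  }
  list(tp = tp, conf = dets$conf, fn = ng - sum(tp),
       n_tp = sum(tp), n_fp = nd - sum(tp), n_gt = ng)
}

#' Precision and recall from match counts
#'
#' \eqn{Precision = TP/(TP+FP)}, \eqn{Recall = TP/(TP+FN)}; both defined as
#' 0 when the denominator is 0.
#'
#' @param match Either a match result from \code{\link{match_detections}} or
#'   a TP count.
#' @param fp,fn FP and FN counts when \code{match} is a TP count.
#' @return Named numeric vector \code{c(precision = , recall = )}.
#' @export
precision_recall <- function(match, fp = NULL, fn = NULL) {
  if (is.list(match)) {
    tp <- match$n_tp; fp <- match$n_fp; fn <- match$fn
  } else {
    tp <- match
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(precision = p, recall = r)
}

# ---- average precision ----------------------------------------------------

#' Average precision from ranked TP/FP flags
#'
#' Computes the area under the precision envelope as a function of recall
#' for one class, from TP/FP flags already ranked by descending confidence.
#' The default integrates over every recall change (all-point
#' interpolation); \code{method = "coco101"} samples the envelope at 101
#' equally spaced recall points instead.
#'
#' @param tp Logical vector of TP flags in descending-confidence order.
#' @param n_gt Number of ground-truth instances for the class.
#' @param method "all_points" (default) or "coco101".
#' @return AP in \[0, 1\]; 0 when there is no ground truth or no TP.
#' @export
#' @examples
#' average_precision(c(TRUE, FALSE, TRUE), n_gt = 2)  # 0.8333...
average_precision <- function(tp, n_gt, method = c("all_points", "coco101")) {
  method <- match.arg(method)
  tp <- as.logical(tp)
  if (n_gt <= 0 || !length(tp) || !any(tp)) return(0)
  cum_tp <- cumsum(tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / seq_along(tp)
  # precision envelope: best precision achievable at recall >= r
  mrec <- c(0, recall, recall[length(recall)] + 1e-3)
  mpre <- c(1, precision, 0)
  mpre <- rev(cummax(rev(mpre)))
  if (method == "all_points") {
    i <- which(mrec[-1] != mrec[-length(mrec)])
    sum((mrec[i + 1] - mrec[i]) * mpre[i + 1])
  } else {
    x <- seq(0, 1, length.out = 101)
    mean(stats::approx(mrec, mpre, xout = x, method = "linear",
                       ties = "ordered", rule = 2)$y)
  }
}

#' Mean average precision over classes and IoU thresholds
#'
#' Averages per-class AP values: unweighted over classes at IoU 0.5, and over
#' classes and the IoU grid for the mAP@0.5:0.95-style summary. Classes with
#' no ground truth (all-NA rows) are excluded from the mean.
#'
#' @param ap_matrix Numeric matrix of APs, classes x IoU thresholds, with
#'   NA rows for classes absent from the ground truth.
#' @param iou_grid IoU thresholds (columns); default \code{seq(0.5, 0.95,
#'   0.05)}.
#' @return Named vector \code{c(map50 = , map50_95 = )}.
#' @export
mean_ap <- function(ap_matrix, iou_grid = seq(0.5, 0.95, by = 0.05)) {
  ap_matrix <- as.matrix(ap_matrix)
  stopifnot(ncol(ap_matrix) == length(iou_grid))
  present <- !apply(ap_matrix, 1, function(r) all(is.na(r)))
  if (!any(present)) return(c(map50 = 0, map50_95 = 0))
  m <- ap_matrix[present, , drop = FALSE]
  i50 <- which.min(abs(iou_grid - 0.5))
  c(map50 = mean(m[, i50]), map50_95 = mean(m))
}

# ---- dataset-level evaluation ---------------------------------------------

# Pooled per-class AP at one IoU threshold: detections of all images are
# ranked globally by confidence and matched greedily within their image.
pooled_class_ap <- function(det_list, gt_list, cls, iou_threshold,
                            method = "all_points") {
  ids <- union(names(det_list), names(gt_list))
  recs <- list(); n_gt <- 0L
  for (id in ids) {
    d <- det_list[[id]]; g <- gt_list[[id]]
    d <- if (is.null(d)) empty_detections() else validate_detections(d)
    g <- if (is.null(g)) empty_detections() else validate_detections(g)
    d <- d[d$cls == cls, , drop = FALSE]
    g <- g[g$cls == cls, , drop = FALSE]
    n_gt <- n_gt + nrow(g)
    if (nrow(d)) recs[[id]] <- list(d = d, g = g)
  }
  if (n_gt == 0L) return(NA_real_)
  if (!length(recs)) return(0)
  conf <- unlist(lapply(recs, function(r) r$d$conf), use.names = FALSE)
  img <- rep(seq_along(recs), vapply(recs, function(r) nrow(r$d), integer(1)))
  within <- unlist(lapply(recs, function(r) seq_len(nrow(r$d))), use.names = FALSE)
  ord <- order(-conf)
  taken <- lapply(recs, function(r) logical(nrow(r$g)))
  tp <- logical(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    r <- recs[[img[i]]]
    free <- which(!taken[[img[i]]])
    if (!length(free)) next
    iou <- box_iou(r$g[free, c("x1", "y1", "x2", "y2"), drop = FALSE],
                   as.numeric(r$d[within[i], c("x1", "y1", "x2", "y2")]))
    j <- which.max(iou)
    if (iou[j] >= iou_threshold) {
      tp[k] <- TRUE
      taken[[img[i]]][free[j]] <- TRUE
    }
  }
  average_precision(tp, n_gt, method = method)
}

#' Evaluate detections against ground truth
#'
#' Dataset-level evaluation: per-class AP on the IoU grid, mAP@0.5 and
#' mAP@0.5:0.95, plus precision and recall at the maximum-F1 operating point
#' of the pooled IoU-0.5 precision-recall curve. Classes with no ground-truth
#' instances are excluded from the class means (and listed in the result).
#'
#' @param det_list Named list of detection data.frames (one per image).
#' @param gt_list Named list of ground-truth data.frames; names must match.
#' @param iou_grid IoU thresholds; default \code{seq(0.5, 0.95, 0.05)}.
#' @param ap_method AP integration, "all_points" (default) or "coco101".
#' @return An object of class \code{"fbstr_eval"}: list with \code{ap}
#'   (class x threshold matrix), \code{map50}, \code{map50_95},
#'   \code{precision}, \code{recall}, \code{per_class} summary data.frame and
#'   \code{skipped_classes}.
#' @export
evaluate_detections <- function(det_list, gt_list,
                                iou_grid = seq(0.5, 0.95, by = 0.05),
                                ap_method = "all_points") {
  classes <- fbstr_classes()
  ap <- matrix(NA_real_, nrow = length(classes), ncol = length(iou_grid),
               dimnames = list(classes, sprintf("iou%.2f", iou_grid)))
  for (ci in seq_along(classes)) {
    for (ti in seq_along(iou_grid)) {
      ap[ci, ti] <- pooled_class_ap(det_list, gt_list, ci - 1L, iou_grid[ti],
                                    method = ap_method)
    }
  }
  maps <- mean_ap(ap, iou_grid)
  skipped <- classes[apply(ap, 1, function(r) all(is.na(r)))]
  if (length(skipped)) {
    message("classes without ground truth skipped in the mean: ",
            paste(skipped, collapse = ", "))
  }

  # max-F1 operating point on the pooled IoU-0.5 curve
  i50 <- which.min(abs(iou_grid - 0.5))
  pr <- class_pr_curves(det_list, gt_list, iou_threshold = iou_grid[i50])
  op <- max_f1_point(pr)

  per_class <- data.frame(class = classes,
                          n_gt = vapply(seq_along(classes) - 1L, function(k) {
                            sum(vapply(gt_list, function(g) sum(g$cls == k),
                                       numeric(1)))
                          }, numeric(1)),
                          ap50 = ap[, i50],
                          ap50_95 = rowMeans(ap))
  structure(list(ap = ap, iou_grid = iou_grid,
                 map50 = unname(maps["map50"]),
                 map50_95 = unname(maps["map50_95"]),
                 precision = op["precision"], recall = op["recall"],
                 conf_at_f1 = op["conf"],
                 per_class = per_class, pr_curves = pr,
                 skipped_classes = skipped),
            class = "fbstr_eval")
}

# per-class cumulative PR curves at one IoU threshold (pooled over images)
class_pr_curves <- function(det_list, gt_list, iou_threshold = 0.5) {
  classes <- fbstr_classes()
  out <- list()
  for (ci in seq_along(classes)) {
    cls <- ci - 1L
    ids <- union(names(det_list), names(gt_list))
    confs <- numeric(); tps <- logical(); n_gt <- 0L
    for (id in ids) {
      d <- det_list[[id]]; g <- gt_list[[id]]
      d <- if (is.null(d)) empty_detections() else d[d$cls == cls, , drop = FALSE]
      g <- if (is.null(g)) empty_detections() else g[g$cls == cls, , drop = FALSE]
      n_gt <- n_gt + nrow(g)
      if (!nrow(d)) next
      m <- match_detections(d, g, iou_threshold)
      confs <- c(confs, m$conf); tps <- c(tps, m$tp)
    }
    if (!length(confs)) {
      out[[classes[ci]]] <- data.frame(conf = numeric(), precision = numeric(),
                                       recall = numeric(), n_gt = integer())
      next
    }
    ord <- order(-confs)
    ct <- cumsum(tps[ord])
    out[[classes[ci]]] <- data.frame(
      conf = confs[ord],
      precision = ct / seq_along(ord),
      recall = if (n_gt > 0) ct / n_gt else 0,
      n_gt = n_gt)
  }
  out
}

max_f1_point <- function(pr_curves) {
  conf <- unlist(lapply(pr_curves, function(d) d$conf), use.names = FALSE)
  if (!length(conf)) return(c(precision = 0, recall = 0, conf = NA_real_))
  grid <- sort(unique(conf), decreasing = TRUE)
  best <- c(precision = 0, recall = 0, conf = NA_real_); best_f1 <- -1
  for (thr in grid) {
    tp <- 0; nd <- 0; ng <- 0
    for (d in pr_curves) {
      if (!nrow(d)) next
      k <- sum(d$conf >= thr)
      nd <- nd + k
      if (k > 0) tp <- tp + d$recall[k] * d$n_gt[1]
      ng <- ng + if (nrow(d)) d$n_gt[1] else 0
    }
    p <- if (nd > 0) tp / nd else 0
    r <- if (ng > 0) tp / ng else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    if (f1 > best_f1) { best_f1 <- f1; best <- c(precision = p, recall = r, conf = thr) }
  }
  best
}

#' @export
print.fbstr_eval <- function(x, ...) {
  cat("Detection evaluation\n")
  cat(sprintf("  mAP@0.5      : %.4f\n", x$map50))
  cat(sprintf("  mAP@0.5:0.95 : %.4f\n", x$map50_95))
  cat(sprintf("  Precision    : %.4f  (max-F1 point, conf >= %.3f)\n",
              x$precision, x$conf_at_f1))
  cat(sprintf("  Recall       : %.4f\n", x$recall))
  if (length(x$skipped_classes)) {
    cat("  classes skipped (no ground truth): ",
        paste(x$skipped_classes, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes the evaluation as JSON (full per-class AP table) and as a
#' plain-text table with the usual detection-benchmark columns (Precision,
#' Recall, mAP@0.5, mAP@0.5:0.95, Parameters (M)), plus one CSV of the
#' per-class precision-recall curves.
#'
#' @param eval An \code{fbstr_eval} object.
#' @param dir Output directory (created if needed).
#' @param params_m Optional parameter count in millions for the table column.
#' @return Invisibly, the directory.
#' @export
write_eval_report <- function(eval, dir, params_m = NA_real_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(
    map50 = eval$map50, map50_95 = eval$map50_95,
    precision = unname(eval$precision), recall = unname(eval$recall),
    per_class = eval$per_class, skipped_classes = eval$skipped_classes,
    ap = as.data.frame(eval$ap)
  ), file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)

  tab <- sprintf("%-12s %-10s %-10s %-10s %-14s %-14s\n%-12s %-10.4f %-10.4f %-10.4f %-14.4f %-14s",
                 "Model", "Precision", "Recall", "mAP@0.5", "mAP@0.5:0.95",
                 "Parameters (M)", "detector", eval$precision, eval$recall,
                 eval$map50, eval$map50_95,
                 ifelse(is.na(params_m), "-", sprintf("%.1f", params_m)))
  writeLines(tab, file.path(dir, "metrics.txt"))

  curves <- do.call(rbind, lapply(names(eval$pr_curves), function(cl) {
    d <- eval$pr_curves[[cl]]
    if (!nrow(d)) return(NULL)
    cbind(class = cl, d)
  }))
  if (is.null(curves)) curves <- data.frame(class = character())
  utils::write.csv(curves, file.path(dir, "pr_curves.csv"), row.names = FALSE)
  invisible(dir)
}
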