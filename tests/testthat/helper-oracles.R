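# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (counting, O(n^2) scans, scalar arithmetic) and share no
# code with the package implementation they check.

# IoU by rasterisation: count sub-pixel grid points falling in each box
iou_raster_oracle <- function(a, b, step = 0.01) {
  xs <- seq(min(a[1], b[1]) + step / 2, max(a[3], b[3]), by = step)
  ys <- seq(min(a[2], b[2]) + step / 2, max(a[4], b[4]), by = step)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  in_a <- gx > a[1] & gx < a[3] & gy > a[2] & gy < a[4]
  in_b <- gx > b[1] & gx < b[3] & gy > b[2] & gy < b[4]
  if (!any(in_a | in_b)) return(0)
  sum(in_a & in_b) / sum(in_a | in_b)
}

# scalar evaluation of the SIoU penalty terms, written from the formulas
siou_scalar_oracle <- function(gt, pred, theta = 4) {
  cgt <- c((gt[1] + gt[3]) / 2, (gt[2] + gt[4]) / 2,
           gt[3] - gt[1], gt[4] - gt[2])
  cpr <- c((pred[1] + pred[3]) / 2, (pred[2] + pred[4]) / 2,
           pred[3] - pred[1], pred[4] - pred[2])
  sigma <- sqrt((cgt[1] - cpr[1])^2 + (cgt[2] - cpr[2])^2)
  a_h <- abs(cgt[2] - cpr[2])
  lam <- if (sigma == 0) 0 else 1 - 2 * sin(asin(min(a_h / sigma, 1)) - pi / 4)^2
  cw <- max(gt[3], pred[3]) - min(gt[1], pred[1])
  ch <- max(gt[4], pred[4]) - min(gt[2], pred[2])
  rx <- if (cw > 0) ((cgt[1] - cpr[1]) / cw)^2 else 0
  ry <- if (ch > 0) ((cgt[2] - cpr[2]) / ch)^2 else 0
  gam <- 2 - lam
  delta <- (1 - exp(-gam * rx)) + (1 - exp(-gam * ry))
  ow <- if (max(cgt[3], cpr[3]) > 0) abs(cpr[3] - cgt[3]) / max(cgt[3], cpr[3]) else 0
  oh <- if (max(cgt[4], cpr[4]) > 0) abs(cpr[4] - cgt[4]) / max(cgt[4], cpr[4]) else 0
  omega <- (1 - exp(-ow))^theta + (1 - exp(-oh))^theta
  iw <- max(0, min(gt[3], pred[3]) - max(gt[1], pred[1]))
  ih <- max(0, min(gt[4], pred[4]) - max(gt[2], pred[2]))
  inter <- iw * ih
  un <- (gt[3] - gt[1]) * (gt[4] - gt[2]) +
    (pred[3] - pred[1]) * (pred[4] - pred[2]) - inter
  iou <- if (un > 0) inter / un else 0
  list(iou = iou, lambda = lam, delta = delta, omega = omega,
       loss = 1 - iou + (delta + omega) / 2)
}

# scalar CIoU written independently (Zheng et al. formulation)
ciou_scalar_oracle <- function(gt, pred) {
  o <- siou_scalar_oracle(gt, pred)
  cgt <- c((gt[1] + gt[3]) / 2, (gt[2] + gt[4]) / 2)
  cpr <- c((pred[1] + pred[3]) / 2, (pred[2] + pred[4]) / 2)
  rho2 <- sum((cgt - cpr)^2)
  cw <- max(gt[3], pred[3]) - min(gt[1], pred[1])
  ch <- max(gt[4], pred[4]) - min(gt[2], pred[2])
  c2 <- cw^2 + ch^2
  wg <- gt[3] - gt[1]; hg <- gt[4] - gt[2]
  wp <- pred[3] - pred[1]; hp <- pred[4] - pred[2]
  v <- 4 / pi^2 * (atan2(wg, hg) - atan2(wp, hp))^2
  alpha <- if (v > 0) v / ((1 - o$iou) + v + 1e-12) else 0
  1 - o$iou + (if (c2 > 0) rho2 / c2 else 0) + alpha * v
}

# O(n^2) reference NMS: a detection survives iff no surviving same-class
# detection of strictly higher rank overlaps it above the threshold
nms_reference <- function(dets, thr) {
  ord <- order(-dets$conf)
  d <- dets[ord, , drop = FALSE]
  n <- nrow(d)
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      if (!alive[j] || d$cls[j] != d$cls[i]) next
      a <- as.numeric(d[j, c("x1", "y1", "x2", "y2")])
      b <- as.numeric(d[i, c("x1", "y1", "x2", "y2")])
      iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
      ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
      inter <- iw * ih
      un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
      if (un > 0 && inter / un > thr) { alive[i] <- FALSE; break }
    }
  }
  d[alive, , drop = FALSE]
}

# brute-force average precision: precision envelope integrated over every
# distinct recall, computed with an O(n^2) max scan
ap_envelope_oracle <- function(tp, n_gt) {
  if (n_gt == 0 || !any(tp)) return(0)
  n <- length(tp)
  rec <- cumsum(tp) / n_gt
  prec <- cumsum(tp) / seq_len(n)
  ap <- 0; prev_r <- 0
  for (i in seq_len(n)) {
    if (!tp[i]) next
    r <- rec[i]
    p_env <- max(prec[i:n])   # best precision at recall >= r
    ap <- ap + (r - prev_r) * p_env
    prev_r <- r
  }
  ap
}

random_boxes <- function(n, lim = 100) {
  x1 <- runif(n, 0, lim); y1 <- runif(n, 0, lim)
  cbind(x1, y1, x1 + runif(n, 0.5, lim / 2), y1 + runif(n, 0.5, lim / 2))
}

random_detections <- function(n, lim = 100, classes = 0:11) {
  b <- random_boxes(n, lim)
  detections(b[, 1], b[, 2], b[, 3], b[, 4], conf = runif(n),
             cls = sample(classes, n, replace = TRUE))
}

# the worked plane-filter fixture: confidences chosen so every step of the
# filter is exercised (prior rejection, strict gate, best-per-class, CP top-2)
tlvap_fixture <- function() {
  detections(x1 = c(10, 40, 60, 80, 30, 35, 100, 120),
             y1 = c(10, 40, 60, 80, 30, 35, 100, 120),
             x2 = c(20, 50, 70, 90, 40, 45, 110, 130),
             y2 = c(20, 50, 70, 90, 40, 45, 110, 130),
             conf = c(0.95, 0.9, 0.8, 0.6, 0.7, 0.55, 0.9, 0.45),
             cls = c("CB", "CP", "CP", "CP", "BM", "BM", "NB", "FV"))
}
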