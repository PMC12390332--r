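#' @useDynLib fbstrnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- box representations --------------------------------------------------
#
# Boxes live in continuous pixel coordinates with the origin at the top-left
# corner of the image and y increasing downward. Corner form ("xyxy") stores
# (x1, y1, x2, y2) with x2 >= x1, y2 >= y1; area is (x2 - x1) * (y2 - y1)
# (no half-open pixel semantics). Center form ("cxcywh") stores
# (cx, cy, w, h). Every function below is vectorised over the rows of an
# n x 4 matrix; a plain length-4 vector is treated as one box.

as_box_matrix <- function(b, what = "box") {
  if (is.null(dim(b))) b <- matrix(b, ncol = 4L, byrow = TRUE)
  b <- as.matrix(b)
  if (ncol(b) != 4L) stop(what, " must have 4 columns")
  if (!all(is.finite(b))) stop(what, " has non-finite coordinates")
  storage.mode(b) <- "double"
  b
}

check_xyxy <- function(b, what = "box") {
  b <- as_box_matrix(b, what)
  if (any(b[, 3] < b[, 1]) || any(b[, 4] < b[, 2])) {
    stop(what, ": x2 < x1 or y2 < y1 (invalid corner-form box)")
  }
  b
}

check_cxcywh <- function(b, what = "box") {
  b <- as_box_matrix(b, what)
  if (any(b[, 3] < 0) || any(b[, 4] < 0)) stop(what, ": negative width or height")
  b
}

#' Convert between corner-form and center-form boxes
#'
#' `xyxy_to_cxcywh()` maps (x1, y1, x2, y2) to (cx, cy, w, h);
#' `cxcywh_to_xyxy()` is its inverse. The round trip is lossless up to
#' floating precision.
#'
#' @param b A length-4 numeric vector or an n x 4 matrix of boxes.
#' @return A matrix of the same shape in the other representation.
#' @export
xyxy_to_cxcywh <- function(b) {
  b <- check_xyxy(b)
  out <- cbind(cx = (b[, 1] + b[, 3]) / 2, cy = (b[, 2] + b[, 4]) / 2,
               w = b[, 3] - b[, 1], h = b[, 4] - b[, 2])
  out
}

#' @rdname xyxy_to_cxcywh
#' @export
cxcywh_to_xyxy <- function(b) {
  b <- check_cxcywh(b)
  cbind(x1 = b[, 1] - b[, 3] / 2, y1 = b[, 2] - b[, 4] / 2,
        x2 = b[, 1] + b[, 3] / 2, y2 = b[, 2] + b[, 4] / 2)
}

#' Intersection over union of paired boxes
#'
#' Row-wise IoU between two sets of corner-form boxes. Disjoint pairs give 0;
#' pairs with zero union area (both boxes degenerate) give 0 by convention.
#'
#' @param a,b Corner-form boxes (length-4 vectors or n x 4 matrices; rows are
#'   recycled if one argument has a single row).
#' @return Numeric vector of IoU values in \[0, 1\].
#' @export
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
box_iou <- function(a, b) {
  a <- check_xyxy(a, "a"); b <- check_xyxy(b, "b")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  union <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
    (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
  as.numeric(ifelse(union > 0, inter / union, 0))
}

#' Cross IoU matrix
#'
#' IoU between every row of `a` and every row of `b`.
#'
#' @inheritParams box_iou
#' @return An nrow(a) x nrow(b) matrix of IoU values.
#' @export
box_iou_matrix <- function(a, b) {
  a <- check_xyxy(a, "a"); b <- check_xyxy(b, "b")
  na <- nrow(a); nb <- nrow(b)
  iw <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  ih <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- iw * ih
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  union <- outer(area_a, area_b, `+`) - inter
  out <- matrix(0, na, nb)
  pos <- union > 0
  out[pos] <- inter[pos] / union[pos]
  out
}

# ---- SIoU components ------------------------------------------------------

#' Angle penalty of the SIoU loss
#'
#' \eqn{\Lambda = 1 - 2\sin^2(\arcsin(a_h/\sigma) - \pi/4)} where \eqn{a_h}
#' is the absolute center-height offset and \eqn{\sigma} the Euclidean center
#' distance between ground truth and prediction. \eqn{\Lambda} is 0 when the
#' centers are axis-aligned (or coincident, by the \eqn{\sigma = 0}
#' convention \eqn{a_h/\sigma := 0}) and 1 when the center offset is at 45
#' degrees. Symmetric in its arguments.
#'
#' @param gt,pred Center-form boxes (cx, cy, w, h); vectors or n x 4 matrices.
#' @return Numeric vector of angle penalties in \[0, 1\].
#' @export
angle_loss <- function(gt, pred) {
  gt <- check_cxcywh(gt, "gt"); pred <- check_cxcywh(pred, "pred")
  sigma <- sqrt((gt[, 1] - pred[, 1])^2 + (gt[, 2] - pred[, 2])^2)
  a_h <- abs(gt[, 2] - pred[, 2])
  ratio <- ifelse(sigma > 0, pmin(a_h / sigma, 1), 0)
  as.numeric(1 - 2 * sin(asin(ratio) - pi / 4)^2)
}

#' Distance penalty of the SIoU loss
#'
#' \eqn{\Delta = (1 - e^{-\gamma\rho_x}) + (1 - e^{-\gamma\rho_y})} with
#' \eqn{\gamma = 2 - \Lambda} and \eqn{\rho_x, \rho_y} the squared center
#' offsets normalised by the width and height of the smallest rectangle
#' enclosing both boxes. When both boxes are degenerate points the enclosing
#' box is empty and \eqn{\Delta = 0}.
#'
#' @inheritParams angle_loss
#' @param lambda_angle Angle penalty \eqn{\Lambda}; computed with
#'   \code{\link{angle_loss}} if missing.
#' @return Numeric vector of distance penalties in \[0, 2).
#' @export
distance_loss <- function(gt, pred, lambda_angle = NULL) {
  gt <- check_cxcywh(gt, "gt"); pred <- check_cxcywh(pred, "pred")
  if (is.null(lambda_angle)) lambda_angle <- angle_loss(gt, pred)
  g <- cxcywh_to_xyxy(gt); p <- cxcywh_to_xyxy(pred)
  c_w <- pmax(g[, 3], p[, 3]) - pmin(g[, 1], p[, 1])
  c_h <- pmax(g[, 4], p[, 4]) - pmin(g[, 2], p[, 2])
  rho_x <- ifelse(c_w > 0, ((gt[, 1] - pred[, 1]) / c_w)^2, 0)
  rho_y <- ifelse(c_h > 0, ((gt[, 2] - pred[, 2]) / c_h)^2, 0)
  gamma <- 2 - lambda_angle
  as.numeric((1 - exp(-gamma * rho_x)) + (1 - exp(-gamma * rho_y)))
}

#' Shape penalty of the SIoU loss
#'
#' \eqn{\Omega = (1 - e^{-\omega_w})^\theta + (1 - e^{-\omega_h})^\theta}
#' with \eqn{\omega_w = |w - w_{gt}| / \max(w, w_{gt})} and likewise for the
#' height. A dimension pair that is zero in both boxes contributes 0.
#'
#' @inheritParams angle_loss
#' @param theta Shape-concern exponent; must be positive. Default 4.
#' @return Numeric vector of shape penalties in \[0, 2).
#' @export
shape_loss <- function(gt, pred, theta = 4) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0) {
    stop("theta must be a positive number")
  }
  gt <- check_cxcywh(gt, "gt"); pred <- check_cxcywh(pred, "pred")
  mw <- pmax(gt[, 3], pred[, 3]); mh <- pmax(gt[, 4], pred[, 4])
  omega_w <- ifelse(mw > 0, abs(pred[, 3] - gt[, 3]) / mw, 0)
  omega_h <- ifelse(mh > 0, abs(pred[, 4] - gt[, 4]) / mh, 0)
  as.numeric((1 - exp(-omega_w))^theta + (1 - exp(-omega_h))^theta)
}

#' SIoU bounding-box regression loss
#'
#' The SIoU loss \eqn{L = 1 - IoU + (\Delta + \Omega)/2} combining overlap,
#' angle-aware center distance (\eqn{\Delta}) and shape mismatch
#' (\eqn{\Omega}). Returns every intermediate quantity, which is useful for
#' testing and for diagnosing regression behaviour.
#'
#' @param gt,pred Corner-form boxes (x1, y1, x2, y2); vectors or n x 4
#'   matrices with matching row counts.
#' @param theta Shape-concern exponent, default 4.
#' @return A data.frame with one row per box pair and columns
#'   \code{iou}, \code{lambda_angle}, \code{sigma}, \code{a_h}, \code{c_w},
#'   \code{c_h}, \code{rho_x}, \code{rho_y}, \code{gamma}, \code{delta},
#'   \code{omega_w}, \code{omega_h}, \code{omega}, \code{theta}, \code{loss}.
#' @export
#' @examples
#' siou_loss(c(0, 0, 2, 2), c(2, 0, 4, 2))$loss  # ~1.1967
siou_loss <- function(gt, pred, theta = 4) {
  gt <- check_xyxy(gt, "gt"); pred <- check_xyxy(pred, "pred")
  n <- max(nrow(gt), nrow(pred))
  if (nrow(gt) == 1L && n > 1L) gt <- gt[rep(1L, n), , drop = FALSE]
  if (nrow(pred) == 1L && n > 1L) pred <- pred[rep(1L, n), , drop = FALSE]
  g <- xyxy_to_cxcywh(gt); p <- xyxy_to_cxcywh(pred)

  iou <- box_iou(gt, pred)
  sigma <- sqrt((g[, 1] - p[, 1])^2 + (g[, 2] - p[, 2])^2)
  a_h <- abs(g[, 2] - p[, 2])
  lambda_angle <- angle_loss(g, p)
  c_w <- pmax(gt[, 3], pred[, 3]) - pmin(gt[, 1], pred[, 1])
  c_h <- pmax(gt[, 4], pred[, 4]) - pmin(gt[, 2], pred[, 2])
  rho_x <- ifelse(c_w > 0, ((g[, 1] - p[, 1]) / c_w)^2, 0)
  rho_y <- ifelse(c_h > 0, ((g[, 2] - p[, 2]) / c_h)^2, 0)
  gamma <- 2 - lambda_angle
  delta <- (1 - exp(-gamma * rho_x)) + (1 - exp(-gamma * rho_y))
  mw <- pmax(g[, 3], p[, 3]); mh <- pmax(g[, 4], p[, 4])
  omega_w <- ifelse(mw > 0, abs(p[, 3] - g[, 3]) / mw, 0)
  omega_h <- ifelse(mh > 0, abs(p[, 4] - g[, 4]) / mh, 0)
  if (theta <= 0) stop("theta must be a positive number")
  omega <- (1 - exp(-omega_w))^theta + (1 - exp(-omega_h))^theta
  loss <- 1 - iou + (delta + omega) / 2

  data.frame(iou = iou, lambda_angle = lambda_angle, sigma = sigma, a_h = a_h,
             c_w = c_w, c_h = c_h, rho_x = rho_x, rho_y = rho_y,
             gamma = gamma, delta = delta, omega_w = omega_w,
             omega_h = omega_h, omega = omega, theta = theta, loss = loss)
}

#' CIoU bounding-box regression loss
#'
#' The standard complete-IoU loss
#' \eqn{L = 1 - IoU + \rho^2(b, b_{gt})/c^2 + \alpha v}, where \eqn{\rho} is
#' the center distance, \eqn{c} the diagonal of the smallest enclosing box,
#' \eqn{v = \frac{4}{\pi^2}(\arctan\frac{w_{gt}}{h_{gt}} -
#' \arctan\frac{w}{h})^2} the aspect-ratio consistency term and
#' \eqn{\alpha = v / ((1 - IoU) + v)} its trade-off weight. Zero for
#' identical boxes.
#'
#' @inheritParams siou_loss
#' @return Numeric vector of loss values.
#' @export
ciou_loss <- function(gt, pred) {
  gt <- check_xyxy(gt, "gt"); pred <- check_xyxy(pred, "pred")
  n <- max(nrow(gt), nrow(pred))
  if (nrow(gt) == 1L && n > 1L) gt <- gt[rep(1L, n), , drop = FALSE]
  if (nrow(pred) == 1L && n > 1L) pred <- pred[rep(1L, n), , drop = FALSE]
  g <- xyxy_to_cxcywh(gt); p <- xyxy_to_cxcywh(pred)
  iou <- box_iou(gt, pred)
  rho2 <- (g[, 1] - p[, 1])^2 + (g[, 2] - p[, 2])^2
  cw <- pmax(gt[, 3], pred[, 3]) - pmin(gt[, 1], pred[, 1])
  ch <- pmax(gt[, 4], pred[, 4]) - pmin(gt[, 2], pred[, 2])
  c2 <- cw^2 + ch^2
  dist_term <- ifelse(c2 > 0, rho2 / c2, 0)
  v <- 4 / pi^2 * (atan2(g[, 3], g[, 4]) - atan2(p[, 3], p[, 4]))^2
  alpha <- ifelse(v > 0, v / ((1 - iou) + v + 1e-12), 0)
  as.numeric(1 - iou + dist_term + alpha * v)
}

# lean internal penalty evaluators used by the training loss (no input
# validation, no data.frame construction); semantics identical to
# siou_loss()/ciou_loss()
siou_value <- function(g, p, theta = 4) {
  gx <- (g[, 1] + g[, 3]) / 2; gy <- (g[, 2] + g[, 4]) / 2
  gw <- g[, 3] - g[, 1]; gh <- g[, 4] - g[, 2]
  px <- (p[, 1] + p[, 3]) / 2; py <- (p[, 2] + p[, 4]) / 2
  pw <- p[, 3] - p[, 1]; ph <- p[, 4] - p[, 2]
  iw <- pmax(0, pmin(g[, 3], p[, 3]) - pmax(g[, 1], p[, 1]))
  ih <- pmax(0, pmin(g[, 4], p[, 4]) - pmax(g[, 2], p[, 2]))
  inter <- iw * ih
  un <- gw * gh + pw * ph - inter
  iou <- ifelse(un > 0, inter / un, 0)
  sigma <- sqrt((gx - px)^2 + (gy - py)^2)
  a_h <- abs(gy - py)
  lam <- ifelse(sigma > 0, 1 - 2 * sin(asin(pmin(a_h / pmax(sigma, 1e-300), 1)) - pi / 4)^2, 0)
  c_w <- pmax(g[, 3], p[, 3]) - pmin(g[, 1], p[, 1])
  c_h <- pmax(g[, 4], p[, 4]) - pmin(g[, 2], p[, 2])
  rho_x <- ifelse(c_w > 0, ((gx - px) / c_w)^2, 0)
  rho_y <- ifelse(c_h > 0, ((gy - py) / c_h)^2, 0)
  gam <- 2 - lam
  delta <- (1 - exp(-gam * rho_x)) + (1 - exp(-gam * rho_y))
  mw <- pmax(gw, pw); mh <- pmax(gh, ph)
  ow <- ifelse(mw > 0, abs(pw - gw) / mw, 0)
  oh <- ifelse(mh > 0, abs(ph - gh) / mh, 0)
  omega <- (1 - exp(-ow))^theta + (1 - exp(-oh))^theta
  1 - iou + (delta + omega) / 2
}

ciou_value <- function(g, p) {
  gx <- (g[, 1] + g[, 3]) / 2; gy <- (g[, 2] + g[, 4]) / 2
  gw <- g[, 3] - g[, 1]; gh <- g[, 4] - g[, 2]
  px <- (p[, 1] + p[, 3]) / 2; py <- (p[, 2] + p[, 4]) / 2
  pw <- p[, 3] - p[, 1]; ph <- p[, 4] - p[, 2]
  iw <- pmax(0, pmin(g[, 3], p[, 3]) - pmax(g[, 1], p[, 1]))
  ih <- pmax(0, pmin(g[, 4], p[, 4]) - pmax(g[, 2], p[, 2]))
  inter <- iw * ih
  un <- gw * gh + pw * ph - inter
  iou <- ifelse(un > 0, inter / un, 0)
  rho2 <- (gx - px)^2 + (gy - py)^2
  cw <- pmax(g[, 3], p[, 3]) - pmin(g[, 1], p[, 1])
  ch <- pmax(g[, 4], p[, 4]) - pmin(g[, 2], p[, 2])
  c2 <- cw^2 + ch^2
  v <- 4 / pi^2 * (atan2(gw, gh) - atan2(pw, ph))^2
  alpha <- ifelse(v > 0, v / ((1 - iou) + v + 1e-12), 0)
  1 - iou + ifelse(c2 > 0, rho2 / c2, 0) + alpha * v
}
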