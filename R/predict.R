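# ---- decoding and prediction ----------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# normalise any accepted image input to an H x W matrix in [0, 1]
as_gray_image <- function(image) {
  if (inherits(image, "phantom_sample")) return(image$image)
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) == 3L) image <- apply(image[, , 1:3, drop = FALSE],
                                               c(1, 2), mean)
  if (!is.matrix(image)) stop("image must be a matrix, array, PNG path or phantom_sample")
  if (max(image) > 1 + 1e-9 || min(image) < -1e-9) {
    stop("image intensities must lie in [0, 1]")
  }
  image
}

# image matrix -> (H, W, C) input cube for the stem
image_to_input <- function(img, in_channels) {
  array(rep(img, in_channels), c(nrow(img), ncol(img), in_channels))
}

# nearest-neighbour resize used when an image size is not a multiple of 32
resize_nearest <- function(img, h, w) {
  ri <- pmin(nrow(img), pmax(1L, round((seq_len(h) - 0.5) * nrow(img) / h + 0.5)))
  ci <- pmin(ncol(img), pmax(1L, round((seq_len(w) - 0.5) * ncol(img) / w + 0.5)))
  img[ri, ci, drop = FALSE]
}

# raw level outputs -> candidate detections (pixel xyxy + conf + cls)
decode_outputs <- function(model, outs, img_h, img_w, conf_thres = 0.25) {
  cfg <- model$config
  na <- cfg$num_anchors; nc <- cfg$num_classes
  meta <- model$graph$out_meta
  res <- list()
  for (lev in 1:3) {
    stride <- cfg$strides[lev]
    if (!cfg$decoupled) {
      P <- outs[[which(vapply(meta, function(m) m$level == lev, logical(1)))]]
      H <- dim(P)[1]; W <- dim(P)[2]
      ch <- function(a, j) P[, , (a - 1L) * (5L + nc) + j]
      get_cls <- function(a) P[, , (a - 1L) * (5L + nc) + 5L + seq_len(nc),
                               drop = FALSE]
    } else {
      idx <- which(vapply(meta, function(m) m$level == lev, logical(1)))
      parts <- vapply(meta[idx], function(m) m$part, character(1))
      Pc <- outs[[idx[parts == "cls"]]]
      Pr <- outs[[idx[parts == "reg"]]]
      Po <- outs[[idx[parts == "obj"]]]
      H <- dim(Pr)[1]; W <- dim(Pr)[2]
      ch <- function(a, j) {
        if (j <= 4L) Pr[, , (a - 1L) * 4L + j] else Po[, , a]
      }
      get_cls <- function(a) Pc[, , (a - 1L) * nc + seq_len(nc), drop = FALSE]
    }
    gx <- matrix(seq_len(W) - 1L, H, W, byrow = TRUE)
    gy <- matrix(seq_len(H) - 1L, H, W)
    for (a in seq_len(na)) {
      obj <- sigmoid(ch(a, 5L))
      if (all(obj <= conf_thres)) next
      cls_sig <- sigmoid(get_cls(a))
      best_c <- apply(cls_sig, c(1, 2), which.max)
      best_p <- apply(cls_sig, c(1, 2), max)
      conf <- obj * best_p
      keep <- which(conf > conf_thres)
      if (!length(keep)) next
      px <- (2 * sigmoid(ch(a, 1L)) - 0.5 + gx) * stride
      py <- (2 * sigmoid(ch(a, 2L)) - 0.5 + gy) * stride
      pw <- (2 * sigmoid(ch(a, 3L)))^2 * cfg$anchors[lev, a, 1]
      ph <- (2 * sigmoid(ch(a, 4L)))^2 * cfg$anchors[lev, a, 2]
      res[[length(res) + 1L]] <- data.frame(
        x1 = pmin(pmax(px[keep] - pw[keep] / 2, 0), img_w),
        y1 = pmin(pmax(py[keep] - ph[keep] / 2, 0), img_h),
        x2 = pmin(pmax(px[keep] + pw[keep] / 2, 0), img_w),
        y2 = pmin(pmax(py[keep] + ph[keep] / 2, 0), img_h),
        conf = conf[keep], cls = best_c[keep] - 1L)
    }
  }
  if (!length(res)) return(empty_detections())
  d <- do.call(rbind, res)
  d <- d[(d$x2 - d$x1) > 1e-6 & (d$y2 - d$y1) > 1e-6, , drop = FALSE]
  validate_detections(d)
}

#' Detect structures in an image
#'
#' Runs the detector on one image: forward pass, anchor decoding, a
#' confidence gate, class-wise NMS, and optionally the plane-aware
#' post-filter. Images whose sides are not multiples of 32 are resized
#' (nearest neighbour) for the forward pass and the boxes are mapped back.
#'
#' @param object A trained \code{fbstrnet} model.
#' @param image Image matrix in \[0, 1\], a PNG path, or a
#'   \code{phantom_sample}.
#' @param conf_thres Confidence gate before NMS; default 0.25.
#' @param iou_thres NMS IoU threshold; default 0.45.
#' @param apply_filter Run \code{\link{filter_detections}}; default FALSE.
#' @param plane Plane name for the filter, or \code{"auto"} to infer it
#'   with \code{\link{infer_plane}} from the NMS survivors.
#' @param filter_conf Confidence gate used by the post-filter; default 0.5.
#' @param norm_stats Batch-norm statistics at inference: "image" (default;
#'   per-image spatial statistics, the same normalisation the optimiser
#'   trains against in this batch-of-one engine) or "running" (conventional
#'   accumulated statistics; see \code{\link{recalibrate_bn}}).
#' @param ... Unused.
#' @return A detection data.frame in the image's pixel coordinates.
#' @export
predict.fbstrnet <- function(object, image, conf_thres = 0.25,
                             iou_thres = 0.45, apply_filter = FALSE,
                             plane = NULL, filter_conf = 0.5,
                             norm_stats = c("image", "running"), ...) {
  norm_stats <- match.arg(norm_stats)
  img <- as_gray_image(image)
  h0 <- nrow(img); w0 <- ncol(img)
  h <- max(32L, as.integer(round(h0 / 32) * 32))
  w <- max(32L, as.integer(round(w0 / 32) * 32))
  if (h != h0 || w != w0) img <- resize_nearest(img, h, w)
  fw <- forward_graph(object$graph, object$params,
                      image_to_input(img, object$config$in_channels),
                      train = FALSE, stats = norm_stats)
  d <- decode_outputs(object, fw$outs, h, w, conf_thres)
  if (h != h0 || w != w0) {
    d$x1 <- d$x1 * w0 / w; d$x2 <- d$x2 * w0 / w
    d$y1 <- d$y1 * h0 / h; d$y2 <- d$y2 * h0 / h
  }
  d <- nms(d, iou_thres)
  if (apply_filter) {
    if (identical(plane, "auto") || is.null(plane)) {
      if (!nrow(d)) {
        warning("no detections to infer a plane from; returning raw NMS output")
        return(d)
      }
      plane <- infer_plane(d)
    }
    d <- filter_detections(d, plane, conf_threshold = filter_conf)
  }
  d
}

#' Average per-image inference time
#'
#' Informational timing harness: mean wall-clock forward+decode time per
#' image at batch size 1.
#'
#' @param model A model.
#' @param images List of images (any form accepted by
#'   \code{\link{predict.fbstrnet}}).
#' @param reps Repetitions over the list; default 1.
#' @return Mean seconds per image.
#' @export
time_inference <- function(model, images, reps = 1L) {
  t0 <- proc.time()[["elapsed"]]
  n <- 0L
  for (r in seq_len(reps)) {
    for (im in images) {
      predict(model, im)
      n <- n + 1L
    }
  }
  (proc.time()[["elapsed"]] - t0) / n
}
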