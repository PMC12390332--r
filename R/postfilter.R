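# ---- detection records ----------------------------------------------------

#' Build a detection table
#'
#' A detection is a corner-form box plus a confidence and a class. Detections
#' are stored as a plain data.frame with columns \code{x1, y1, x2, y2, conf,
#' cls} (0-based class index) and \code{name} (class name, derived).
#'
#' @param x1,y1,x2,y2 Box corners in pixels (top-left origin).
#' @param conf Confidence scores in \[0, 1\].
#' @param cls Class as 0-based integer index or class name
#'   (see \code{\link{fbstr_classes}}).
#' @return A data.frame of detections.
#' @export
#' @examples
#' detections(0, 0, 10, 10, 0.9, "CB")
detections <- function(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                       y2 = numeric(), conf = numeric(), cls = integer()) {
  if (is.character(cls)) cls <- class_index(cls)
  cls <- as.integer(cls)
  d <- data.frame(x1 = as.numeric(x1), y1 = as.numeric(y1),
                  x2 = as.numeric(x2), y2 = as.numeric(y2),
                  conf = as.numeric(conf), cls = cls)
  validate_detections(d)
}

#' @rdname detections
#' @export
empty_detections <- function() {
  detections()
}

validate_detections <- function(d) {
  stopifnot(is.data.frame(d))
  need <- c("x1", "y1", "x2", "y2", "conf", "cls")
  if (!all(need %in% names(d))) {
    stop("detections need columns: ", paste(need, collapse = ", "))
  }
  if (nrow(d)) {
    check_xyxy(as.matrix(d[, c("x1", "y1", "x2", "y2")]), "detection box")
    if (any(d$conf < 0 | d$conf > 1)) stop("conf must lie in [0, 1]")
    if (any(d$cls < 0L | d$cls > 11L)) stop("cls must be a 0-based index in 0..11")
  }
  d$name <- if (nrow(d)) class_name(d$cls) else character()
  d
}

# ---- non-maximum suppression ----------------------------------------------

#' Class-wise greedy non-maximum suppression
#'
#' Detections are swept in order of descending confidence; a detection is
#' suppressed if it shares its class with an already-kept detection and
#' overlaps it with IoU greater than \code{iou_threshold}. The output keeps
#' descending-confidence order (stable for ties).
#'
#' @param dets A detection data.frame (see \code{\link{detections}}).
#' @param iou_threshold Suppression threshold in \[0, 1\]; default 0.45.
#' @return The surviving detections.
#' @export
nms <- function(dets, iou_threshold = 0.45) {
  if (!is.numeric(iou_threshold) || length(iou_threshold) != 1L ||
      is.na(iou_threshold) || iou_threshold < 0 || iou_threshold > 1) {
    stop("iou_threshold must be a single value in [0, 1]")
  }
  dets <- validate_detections(dets)
  if (nrow(dets) < 2L) return(dets)
  ord <- order(-dets$conf)
  dets <- dets[ord, , drop = FALSE]
  boxes <- as.matrix(dets[, c("x1", "y1", "x2", "y2")])
  keep <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    prev <- which(keep & dets$cls == dets$cls[i])
    if (!length(prev) ||
        all(box_iou(boxes[prev, , drop = FALSE],
                    boxes[i, , drop = FALSE]) <= iou_threshold)) {
      keep[i] <- TRUE
    }
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- plane-aware post-filter ----------------------------------------------

#' Plane-aware filtering and sorting of detections
#'
#' The clinically informed post-filter applied after NMS. Given the standard
#' plane of the image it (1) discards detections whose class is not expected
#' in that plane, (2) among those with confidence strictly greater than
#' \code{conf_threshold} keeps the single most confident detection per class,
#' (3) for the paired choroid plexus (CP) keeps the top two by confidence,
#' and (4) deduplicates exact records and sorts ascending by class index
#' (within CP, descending by confidence). Idempotent; never fabricates
#' records.
#'
#' @param dets A detection data.frame.
#' @param plane One of \code{"TLVAP"}, \code{"TTAP"}, \code{"TPFAP"},
#'   \code{"MSP"}.
#' @param prior Plane-to-class prior; default \code{\link{plane_priors}()}.
#' @param conf_threshold Strict lower confidence gate; default 0.5.
#' @return The retained detections, sorted by class index.
#' @export
#' @examples
#' d <- detections(c(0, 10, 40), c(0, 10, 40), c(9, 19, 49), c(9, 19, 49),
#'                 c(.95, .9, .8), c("CB", "CP", "CP"))
#' filter_detections(d, "TLVAP")
filter_detections <- function(dets, plane, prior = plane_priors(),
                              conf_threshold = 0.5) {
  check_plane(plane)
  dets <- validate_detections(dets)
  expected <- prior[[plane]]

  # Step 1: drop classes foreign to the plane
  surv <- dets[dets$name %in% expected, , drop = FALSE]
  # Step 2: strict confidence gate, then best per class
  surv <- surv[surv$conf > conf_threshold, , drop = FALSE]
  if (!nrow(surv)) return(surv[0, , drop = FALSE])
  ord <- order(-surv$conf)
  surv <- surv[ord, , drop = FALSE]
  best <- surv[!duplicated(surv$cls), , drop = FALSE]
  # Step 3: the paired choroid plexus keeps the top two
  cp <- surv[surv$name == "CP", , drop = FALSE]
  top_cp <- utils::head(cp, 2L)
  # Step 4: concatenate, exact-duplicate removal, sort by class
  out <- rbind(best, top_cp)
  out <- out[!duplicated(out[, c("x1", "y1", "x2", "y2", "conf", "cls")]), ,
             drop = FALSE]
  out <- out[order(out$cls, -out$conf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer the standard plane from detected classes
#'
#' The plane identity of an image is normally supplied by the operator (the
#' scanning protocol names the plane being acquired). When it is not, this
#' helper scores each plane by (number of detected classes expected in the
#' plane) minus (number of detected classes foreign to it) and returns the
#' best-scoring plane; ties are broken by the smaller expected-class set,
#' then by the fixed order TLVAP, TTAP, TPFAP, MSP.
#'
#' @param dets A non-empty detection data.frame.
#' @param prior Plane-to-class prior; default \code{\link{plane_priors}()}.
#' @return A plane name.
#' @export
infer_plane <- function(dets, prior = plane_priors()) {
  dets <- validate_detections(dets)
  if (!nrow(dets)) stop("cannot infer a plane from zero detections")
  present <- unique(dets$name)
  planes <- names(prior)
  score <- vapply(planes, function(p) {
    sum(present %in% prior[[p]]) - sum(!present %in% prior[[p]])
  }, numeric(1))
  size <- lengths(prior)
  ord <- order(-score, size, match(planes, fbstr_planes()))
  planes[ord[1L]]
}

# ---- YOLO txt and COCO-style JSON I/O -------------------------------------

#' Read YOLO-format labels
#'
#' Reads a YOLO txt label file (one line per box: `class cx cy w h [conf]`,
#' coordinates normalised to \[0, 1\]) and denormalises to pixel corner form.
#' A missing file yields an empty detection table (the YOLO convention for
#' images without objects).
#'
#' @param path Label file path.
#' @param image_width,image_height Image size in pixels used to denormalise.
#' @return A detection data.frame; boxes without a stored confidence get
#'   conf = 1.
#' @export
read_yolo_labels <- function(path, image_width, image_height) {
  if (!file.exists(path)) return(empty_detections())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_detections())
  fields <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  nf <- lengths(fields)
  if (any(nf < 5L | nf > 6L)) stop("malformed YOLO label line in ", path)
  m <- t(vapply(fields, function(f) c(f, rep(1, 6 - length(f))), numeric(6)))
  cx <- m[, 2] * image_width; cy <- m[, 3] * image_height
  w <- m[, 4] * image_width; h <- m[, 5] * image_height
  detections(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2,
             conf = m[, 6], cls = as.integer(m[, 1]))
}

#' Write YOLO-format labels
#'
#' Writes detections as YOLO txt: `class cx cy w h` normalised to \[0, 1\],
#' with the confidence appended as a sixth column when
#' \code{with_conf = TRUE}.
#'
#' @param dets A detection data.frame.
#' @param path Output file path.
#' @param image_width,image_height Image size in pixels used to normalise.
#' @param with_conf Append the confidence column? Default FALSE (ground-truth
#'   convention).
#' @return Invisibly, `path`.
#' @export
write_yolo_labels <- function(dets, path, image_width, image_height,
                              with_conf = FALSE) {
  dets <- validate_detections(dets)
  cx <- (dets$x1 + dets$x2) / 2 / image_width
  cy <- (dets$y1 + dets$y2) / 2 / image_height
  w <- (dets$x2 - dets$x1) / image_width
  h <- (dets$y2 - dets$y1) / image_height
  fmt <- function(x) formatC(x, digits = 6, format = "f")
  lines <- paste(dets$cls, fmt(cx), fmt(cy), fmt(w), fmt(h))
  if (with_conf) lines <- paste(lines, fmt(dets$conf))
  writeLines(lines, path)
  invisible(path)
}

#' Write detections as a COCO-style results array
#'
#' Serialises per-image detections to the COCO detection-results JSON layout:
#' an array of records with fields `image_id`, `category_id` (0-based class
#' index), `bbox` as `[x, y, width, height]` and `score`.
#'
#' @param det_list Named list of detection data.frames; names are image ids.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_coco_json <- function(det_list, path) {
  recs <- list()
  for (id in names(det_list)) {
    d <- validate_detections(det_list[[id]])
    for (i in seq_len(nrow(d))) {
      recs[[length(recs) + 1L]] <- list(
        image_id = id,
        category_id = d$cls[i],
        bbox = c(d$x1[i], d$y1[i], d$x2[i] - d$x1[i], d$y2[i] - d$y1[i]),
        score = d$conf[i]
      )
    }
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO-style results array
#'
#' Inverse of \code{\link{write_coco_json}}.
#'
#' @param path JSON path.
#' @return Named list of detection data.frames keyed by image id.
#' @export
read_coco_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  ids <- vapply(recs, function(r) as.character(r$image_id), character(1))
  out <- list()
  for (id in unique(ids)) {
    sel <- recs[ids == id]
    bb <- t(vapply(sel, function(r) as.numeric(unlist(r$bbox)), numeric(4)))
    out[[id]] <- detections(bb[, 1], bb[, 2], bb[, 1] + bb[, 3], bb[, 2] + bb[, 4],
                            conf = vapply(sel, function(r) r$score, numeric(1)),
                            cls = vapply(sel, function(r) as.integer(r$category_id),
                                         integer(1)))
  }
  out
}
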