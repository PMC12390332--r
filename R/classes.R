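#' Canonical anatomical structure classes
#'
#' The twelve fetal-brain anatomical structures targeted by the detector, in
#' canonical index order (0-based indices 0..11, as used in YOLO label files):
#' CB cranial bone, BM brain midline, CP choroid plexus, CM cisterna magna,
#' B brainstem, FV fourth ventricle, AS aqueduct of Sylvius, T&P thalamus and
#' cerebral peduncles, NB nasal bone, M mandible, TV third ventricle,
#' HP hard palate.
#'
#' @return Character vector of length 12; element \code{i} is the name of
#'   class index \code{i - 1}.
#' @export
#' @examples
#' fbstr_classes()
fbstr_classes <- function() {
  c("CB", "BM", "CP", "CM", "B", "FV", "AS", "T&P", "NB", "M", "TV", "HP")
}

#' Standard plane names
#'
#' The four first-trimester fetal-brain ultrasound standard planes:
#' trans-lateral-ventricular axial (TLVAP), trans-thalamic axial (TTAP),
#' trans-posterior-fossa axial (TPFAP) and mid-sagittal (MSP). The order is
#' the canonical tie-break order used by \code{\link{infer_plane}}.
#'
#' @return Character vector of length 4.
#' @export
fbstr_planes <- function() {
  c("TLVAP", "TTAP", "TPFAP", "MSP")
}

#' Plane-to-structure clinical prior
#'
#' Maps each standard plane to the set of anatomical structure classes
#' expected to be visible in it. This is the clinical prior consumed by the
#' plane-aware post-filter: a detection whose class is not in the set for the
#' image's plane is treated as a false positive. The choroid plexus (CP)
#' appears only in the TLVAP set and is the one paired structure, so the
#' filter retains up to two CP detections.
#'
#' @return Named list of character vectors, one per plane.
#' @seealso \code{\link{filter_detections}}, \code{\link{infer_plane}}
#' @export
#' @examples
#' plane_priors()$TLVAP
plane_priors <- function() {
  list(
    TLVAP = c("CB", "BM", "CP"),
    TTAP  = c("CB", "BM", "AS", "T&P"),
    TPFAP = c("CB", "CM", "B", "FV"),
    MSP   = c("CB", "CM", "B", "FV", "NB", "M", "TV", "HP")
  )
}

# class name -> 0-based index; errors on unknown names
class_index <- function(cls) {
  idx <- match(cls, fbstr_classes()) - 1L
  if (anyNA(idx)) {
    stop("unknown class name(s): ", paste(unique(cls[is.na(idx)]), collapse = ", "))
  }
  idx
}

# 0-based index -> class name
class_name <- function(idx) {
  nm <- fbstr_classes()[as.integer(idx) + 1L]
  if (anyNA(nm)) stop("class index out of range 0..11")
  nm
}

check_plane <- function(plane) {
  if (length(plane) != 1L || !plane %in% fbstr_planes()) {
    stop("unknown plane '", plane, "'; valid planes: ",
         paste(fbstr_planes(), collapse = ", "))
  }
  plane
}
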