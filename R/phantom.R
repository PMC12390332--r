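# ---- synthetic ultrasound phantoms ----------------------------------------
#
# The phantom generator renders schematic fetal-brain ultrasound images: a
# dark fan-shaped insonation field, a bright elliptical cranial-bone ring,
# and plane-appropriate primitives for the structures expected in each of
# the four standard planes, degraded by smoothed multiplicative Rayleigh
# speckle. Layouts are schematic (class-consistent, learnable structure),
# not anatomically calibrated. Ground truth is emitted as one tight box per
# structure, matching the plane-to-structure prior exactly (the choroid
# plexus twice in the TLVAP).

# layout tables: offsets/sizes are fractions of the image size, relative to
# the skull center; echo is the rendered intensity in [0, 1].
phantom_layout <- function(plane) {
  row <- function(cls, shape, dx, dy, ax, ay, rot, echo)
    data.frame(cls = cls, shape = shape, dx = dx, dy = dy, ax = ax, ay = ay,
               rot = rot, echo = echo, stringsAsFactors = FALSE)
  skull <- row("CB", "ring", 0, 0, 0.385, 0.310, 0, 0.92)
  bm <- row("BM", "bar", 0, 0, 0.011, 0.215, 0, 0.88)
  switch(plane,
    TLVAP = rbind(
      skull, bm,
      row("CP", "ellipse", -0.135, -0.015, 0.052, 0.125, 8, 0.80),
      row("CP", "ellipse",  0.135, -0.015, 0.052, 0.125, -8, 0.80)),
    TTAP = rbind(
      skull, bm,
      row("AS", "ellipse", 0, 0.105, 0.026, 0.024, 0, 0.10),
      row("T&P", "pair", 0, 0.020, 0.072, 0.052, 0, 0.62)),
    TPFAP = rbind(
      skull,
      row("CM", "ellipse", 0, 0.215, 0.120, 0.042, 0, 0.10),
      row("B", "ellipse", 0, 0.015, 0.102, 0.078, 0, 0.55),
      row("FV", "ellipse", 0, 0.118, 0.047, 0.032, 0, 0.14)),
    MSP = rbind(
      row("CB", "ring", 0.02, -0.03, 0.340, 0.285, 0, 0.92),
      row("CM", "ellipse", 0.165, 0.115, 0.062, 0.040, 20, 0.10),
      row("B", "ellipse", -0.015, 0.055, 0.092, 0.068, 10, 0.50),
      row("FV", "ellipse", 0.085, 0.090, 0.037, 0.029, 0, 0.14),
      row("NB", "bar", -0.270, 0.095, 0.068, 0.015, -18, 0.95),
      row("M", "bar", -0.195, 0.235, 0.058, 0.017, 6, 0.85),
      row("TV", "ellipse", -0.010, -0.045, 0.035, 0.024, 0, 0.18),
      row("HP", "bar", -0.225, 0.165, 0.078, 0.016, -6, 0.90)),
    stop("unknown plane '", plane, "'")
  )
}

#' Specification of one synthetic ultrasound phantom
#'
#' Collects every parameter of one rendered phantom: the plane, image size,
#' skull-ellipse geometry, the per-structure layout (relative offsets,
#' semi-axes, rotation, echogenicity), the speckle model (multiplicative
#' noise scale and Gaussian smoothing sigma, in pixels) and the fan-mask
#' geometry. Randomised placement jitter is derived deterministically from
#' \code{seed}.
#'
#' @param plane One of the four standard planes.
#' @param image_size Square image side in pixels; default 640.
#' @param seed Integer seed; fixes the phantom bit-for-bit.
#' @param speckle_scale Multiplicative speckle strength in \[0, 1\];
#'   default 0.30.
#' @param smooth_sigma Gaussian smoothing of the speckle field, pixels;
#'   default 1.5.
#' @param jitter Relative placement/size jitter amplitude; default 0.012.
#' @param fan_apex_y Fan apex y as a fraction of image size (above the
#'   image); default -0.15.
#' @param fan_half_angle Angular half-width of the fan in degrees;
#'   default 38.
#' @return An object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(plane, image_size = 640, seed = 1L,
                         speckle_scale = 0.30, smooth_sigma = 1.5,
                         jitter = 0.012, fan_apex_y = -0.15,
                         fan_half_angle = 38) {
  check_plane(plane)
  stopifnot(image_size >= 64, speckle_scale >= 0, speckle_scale <= 1)
  structure(list(plane = plane, image_size = as.integer(image_size),
                 seed = as.integer(seed), speckle_scale = speckle_scale,
                 smooth_sigma = smooth_sigma, jitter = jitter,
                 fan_apex_y = fan_apex_y, fan_half_angle = fan_half_angle,
                 skull_center = c(0.5, 0.53),
                 layout = phantom_layout(plane)),
            class = "phantom_spec")
}

# analytic masks on the pixel grid (continuous coordinates, pixel centers
# at i - 0.5); returns logical matrix H x W
ellipse_mask <- function(size, cx, cy, ax, ay, rot_deg = 0) {
  v <- seq_len(size) - 0.5
  X <- matrix(v, size, size, byrow = TRUE)
  Y <- matrix(v, size, size)
  th <- rot_deg * pi / 180
  xr <- (X - cx) * cos(th) + (Y - cy) * sin(th)
  yr <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
  (xr / ax)^2 + (yr / ay)^2 <= 1
}

fan_mask <- function(size, apex_y_frac, half_angle_deg) {
  v <- seq_len(size) - 0.5
  X <- matrix(v, size, size, byrow = TRUE)
  Y <- matrix(v, size, size)
  ax <- size / 2; ay <- apex_y_frac * size
  ang <- atan2(X - ax, Y - ay) * 180 / pi
  r <- sqrt((X - ax)^2 + (Y - ay)^2)
  abs(ang) <= half_angle_deg & r <= 1.25 * size & Y >= 0
}

mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  # pixel (r, c) covers [c-1, c] x [r-1, r]
  c(x1 = min(idx[, 2]) - 1, y1 = min(idx[, 1]) - 1,
    x2 = max(idx[, 2]), y2 = max(idx[, 1]))
}

#' Render one synthetic phantom
#'
#' Deterministically renders the phantom described by a
#' \code{\link{phantom_spec}}: fan-shaped field, tissue-filled skull ring and
#' plane-appropriate structures, multiplicative smoothed Rayleigh speckle,
#' and a tight ground-truth box per structure. The global RNG state is left
#' untouched.
#'
#' @param spec A \code{phantom_spec}.
#' @return An object of class \code{"phantom_sample"}: list with
#'   \code{image} (H x W matrix in \[0, 1\]), \code{labels} (detections with
#'   conf = 1), \code{plane} and \code{seed}.
#' @export
#' @examples
#' p <- generate_phantom(phantom_spec("TLVAP", image_size = 160, seed = 7))
#' table(p$labels$name)
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  size <- spec$image_size
  rng <- local_rng(spec$seed)
  on.exit(rng(), add = TRUE)

  fan <- fan_mask(size, spec$fan_apex_y, spec$fan_half_angle)
  img <- matrix(0.02, size, size)
  img[fan] <- 0.22

  sc <- spec$skull_center * size
  sc <- sc + stats::runif(2, -spec$jitter, spec$jitter) * size
  scale <- stats::runif(1, 0.93, 1.07)

  lay <- spec$layout
  boxes <- vector("list", nrow(lay))

  # skull interior first so structures render on top of tissue gray
  skull <- lay[lay$shape == "ring", ][1, ]
  ax <- skull$ax * size * scale; ay <- skull$ay * size * scale
  scx <- sc[1] + skull$dx * size; scy <- sc[2] + skull$dy * size
  interior <- ellipse_mask(size, scx, scy, ax, ay)
  img[interior & fan] <- 0.38

  ord <- order(lay$echo)  # dark structures first, bright overwrite
  for (k in ord) {
    st <- lay[k, ]
    jx <- stats::runif(1, -spec$jitter, spec$jitter) * size
    jy <- stats::runif(1, -spec$jitter, spec$jitter) * size
    sz <- stats::runif(1, 0.88, 1.12) * scale
    rot <- st$rot + stats::runif(1, -6, 6)
    echo <- min(1, max(0, st$echo + stats::runif(1, -0.04, 0.04)))
    cx <- sc[1] + st$dx * size * scale + jx
    cy <- sc[2] + st$dy * size * scale + jy
    a <- st$ax * size * sz; b <- st$ay * size * sz
    m <- switch(st$shape,
      ring = {
        thick <- 0.055 * size * sz
        ellipse_mask(size, cx, cy, a + thick, b + thick) &
          !ellipse_mask(size, cx, cy, a, b)
      },
      ellipse = ellipse_mask(size, cx, cy, a, b, rot),
      bar = ellipse_mask(size, cx, cy, a, b, rot),
      pair = {
        sep <- a * 1.35
        ellipse_mask(size, cx - sep, cy, a, b, rot) |
          ellipse_mask(size, cx + sep, cy, a, b, rot)
      },
      stop("unknown shape ", st$shape))
    m <- m & fan
    bb <- mask_bbox(m)
    if (is.null(bb)) {
      stop("structure ", st$cls, " fell outside the fan/image for seed ",
           spec$seed)
    }
    img[m] <- echo
    boxes[[k]] <- data.frame(cls = st$cls, x1 = bb["x1"], y1 = bb["y1"],
                             x2 = bb["x2"], y2 = bb["y2"])
  }

  # smoothed multiplicative Rayleigh speckle, then light smoothing
  if (spec$speckle_scale > 0) {
    sigma_r <- sqrt(2 / pi)  # unit-mean Rayleigh
    noise <- matrix(sigma_r * sqrt(-2 * log(stats::runif(size * size))),
                    size, size)
    noise <- gaussian_blur(noise, spec$smooth_sigma)
    img <- img * (1 - spec$speckle_scale + spec$speckle_scale * noise)
  }
  img <- gaussian_blur(img, 0.8)
  img[img < 0] <- 0; img[img > 1] <- 1

  bdf <- do.call(rbind, boxes)
  labels <- detections(bdf$x1, bdf$y1, bdf$x2, bdf$y2,
                       conf = rep(1, nrow(bdf)), cls = bdf$cls)
  structure(list(image = img, labels = labels, plane = spec$plane,
                 seed = spec$seed),
            class = "phantom_sample")
}

# separable Gaussian blur (reflected edges), sigma in pixels
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  cpp_sepconv(mat, k)
}

# run expr under a private RNG stream; returns restore function
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed %% .Machine$integer.max)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# stable per-image seed derivation: pure function of (seed, plane, index)
derive_seed <- function(seed, plane, index) {
  p <- match(plane, fbstr_planes())
  h <- (as.double(seed) * 2654435761 + p * 40503 + index * 69069) %% 2147483647
  as.integer(h)
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("phantom: %s plane, %dx%d, seed %d, %d labelled structures\n",
              x$plane, nrow(x$image), ncol(x$image), x$seed, nrow(x$labels)))
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes \code{n_per_plane} phantoms per standard plane as PNG images with
#' YOLO txt labels, split into train and validation, plus a dataset manifest
#' (YAML) naming the class list, the splits and each image's plane.
#' Per-image seeds are a pure function of \code{(seed, plane, index)}, so a
#' dataset regenerates bit-identically from the same seed.
#'
#' @param out_dir Output directory (created).
#' @param n_per_plane Images per plane; at least 1.
#' @param seed Master integer seed.
#' @param image_size Image side in pixels; default 640.
#' @param val_fraction Fraction of each plane's images placed in the
#'   validation split; default 0.2.
#' @param ... Passed to \code{\link{phantom_spec}} (speckle, fan, jitter).
#' @return Invisibly, the manifest as a list (with \code{$path} the manifest
#'   file path).
#' @export
generate_dataset <- function(out_dir, n_per_plane, seed = 1L,
                             image_size = 640, val_fraction = 0.2, ...) {
  stopifnot(n_per_plane >= 1)
  for (d in c("images/train", "images/val", "labels/train", "labels/val")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  train <- character(); val <- character(); planes <- list()
  for (plane in fbstr_planes()) {
    n_val <- max(if (n_per_plane >= 2) 1L else 0L,
                 floor(n_per_plane * val_fraction))
    for (i in seq_len(n_per_plane)) {
      split <- if (i > n_per_plane - n_val) "val" else "train"
      stem <- sprintf("%s_%04d", tolower(gsub("&", "", plane)), i)
      rel_img <- file.path("images", split, paste0(stem, ".png"))
      s <- generate_phantom(phantom_spec(plane, image_size = image_size,
                                         seed = derive_seed(seed, plane, i),
                                         ...))
      png::writePNG(s$image, file.path(out_dir, rel_img))
      write_yolo_labels(s$labels,
                        file.path(out_dir, "labels", split, paste0(stem, ".txt")),
                        image_size, image_size)
      if (split == "train") train <- c(train, rel_img) else val <- c(val, rel_img)
      planes[[stem]] <- plane
    }
  }
  manifest <- list(path = normalizePath(out_dir), nc = 12L,
                   names = fbstr_classes(), image_size = as.integer(image_size),
                   train = as.list(train), val = as.list(val), planes = planes,
                   seed = as.integer(seed))
  mpath <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  manifest$path <- mpath
  invisible(manifest)
}

#' Read a dataset manifest
#'
#' @param path Manifest YAML path.
#' @return The manifest list with resolved directory in \code{$dir}.
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  m$dir <- dirname(normalizePath(path))
  if (!identical(unlist(m$names), fbstr_classes())) {
    stop("manifest class list does not match the canonical class table")
  }
  m
}

# label path for an image path under the YOLO layout
label_path <- function(img_rel) {
  sub("\\.png$", ".txt", sub("^images/", "labels/", img_rel))
}

#' Mean contrast between structures and their local background
#'
#' For each labelled structure, the absolute difference between the mean
#' image intensity inside its box and in a surrounding margin. Used to
#' assert that phantoms are learnable (structures distinguishable from
#' background).
#'
#' @param sample A \code{phantom_sample}.
#' @param margin Background margin in pixels; default 12.
#' @return Numeric vector of contrasts, one per label.
#' @export
phantom_contrast <- function(sample, margin = 12) {
  img <- sample$image; n <- nrow(img)
  vapply(seq_len(nrow(sample$labels)), function(i) {
    b <- sample$labels[i, ]
    xi <- max(1, floor(b$x1) + 1):min(n, ceiling(b$x2))
    yi <- max(1, floor(b$y1) + 1):min(n, ceiling(b$y2))
    xo <- max(1, floor(b$x1) - margin + 1):min(n, ceiling(b$x2) + margin)
    yo <- max(1, floor(b$y1) - margin + 1):min(n, ceiling(b$y2) + margin)
    inside <- mean(img[yi, xi])
    ring_sum <- sum(img[yo, xo]) - sum(img[yi, xi])
    ring_n <- length(yo) * length(xo) - length(yi) * length(xi)
    abs(inside - ring_sum / max(1, ring_n))
  }, numeric(1))
}
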