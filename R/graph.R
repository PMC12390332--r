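# ---- layer-graph construction ---------------------------------------------
#
# The detector is represented as a flat DAG of primitive nodes (conv,
# maxpool, upsample, concat, add, slice). Composite blocks (Conv+BN+SiLU,
# GhostConv, C3, C3Ghost, SPPF, the heads) expand into primitives at build
# time, so parameter counting, the forward pass and backpropagation all
# operate on one representation. Nodes are created in topological order;
# node 0 is the image input.

new_graph <- function(in_channels) {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  add_node(g, "input", from = integer(), c_out = in_channels,
           comp = "input", mod = "input")
  g
}

add_node <- function(g, op, from, c_out, comp, mod, ...) {
  id <- length(g$nodes) + 1L
  g$nodes[[id]] <- c(list(id = id, op = op, from = as.integer(from),
                          c_out = as.integer(c_out), comp = comp, mod = mod),
                     list(...))
  id
}

channels_of <- function(g, id) g$nodes[[id]]$c_out

# Conv2d [+ BatchNorm + SiLU] fused node
conv_bn <- function(g, from, c2, k = 1L, s = 1L, p = NULL, groups = 1L,
                    act = TRUE, bn = TRUE, bias = !bn, comp = "backbone",
                    mod = "Conv") {
  c1 <- channels_of(g, from)
  if (c1 <= 0 || c2 <= 0) stop("invalid channel count: ", c1, " -> ", c2)
  if (c1 %% groups != 0 || c2 %% groups != 0) {
    stop("channels not divisible by groups at module ", mod)
  }
  if (is.null(p)) p <- k %/% 2L
  add_node(g, "conv", from = from, c_out = c2, comp = comp, mod = mod,
           c_in = c1, k = as.integer(k), s = as.integer(s), p = as.integer(p),
           groups = as.integer(groups), bn = bn, act = if (act) "silu" else "none",
           bias = bias)
}

slice_node <- function(g, from, n_channels, comp, mod) {
  add_node(g, "slice", from = from, c_out = n_channels, comp = comp,
           mod = mod, take = as.integer(n_channels))
}

# Ghost convolution: a dense primary conv produces the intrinsic features
# (half the output channels, rounded up), a cheap 5x5 depthwise conv derives
# the ghost features from them, and the two are concatenated.
ghost_conv <- function(g, from, c2, k = 1L, s = 1L, act = TRUE,
                       comp = "backbone", mod = "GhostConv") {
  if (c2 < 2L) stop("GhostConv needs at least 2 output channels")
  ci <- as.integer(ceiling(c2 / 2))   # intrinsic
  cg <- c2 - ci                       # ghost
  y1 <- conv_bn(g, from, ci, k = k, s = s, act = act, comp = comp, mod = mod)
  src <- if (cg < ci) slice_node(g, y1, cg, comp, mod) else y1
  y2 <- conv_bn(g, src, cg, k = 5L, s = 1L, groups = cg, act = act,
                comp = comp, mod = mod)
  add_node(g, "concat", from = c(y1, y2), c_out = ci + cg, comp = comp,
           mod = mod)
}

bottleneck <- function(g, from, c2, shortcut = TRUE, comp, mod = "C3") {
  y <- conv_bn(g, from, c2, k = 1L, comp = comp, mod = mod)
  y <- conv_bn(g, y, c2, k = 3L, comp = comp, mod = mod)
  if (shortcut && channels_of(g, from) == c2) {
    add_node(g, "add", from = c(from, y), c_out = c2, comp = comp, mod = mod)
  } else y
}

ghost_bottleneck <- function(g, from, c2, comp, mod = "C3Ghost") {
  mid <- as.integer(c2 / 2)
  y <- ghost_conv(g, from, mid, k = 1L, act = TRUE, comp = comp, mod = mod)
  y <- ghost_conv(g, y, c2, k = 1L, act = FALSE, comp = comp, mod = mod)
  add_node(g, "add", from = c(from, y), c_out = c2, comp = comp, mod = mod)
}

c3_block <- function(g, from, c2, n = 1L, shortcut = TRUE, ghost = FALSE,
                     comp = "backbone") {
  mod <- if (ghost) "C3Ghost" else "C3"
  c_ <- as.integer(c2 / 2)
  y1 <- conv_bn(g, from, c_, k = 1L, comp = comp, mod = mod)
  y2 <- conv_bn(g, from, c_, k = 1L, comp = comp, mod = mod)
  m <- y1
  for (i in seq_len(n)) {
    m <- if (ghost) ghost_bottleneck(g, m, c_, comp = comp, mod = mod)
         else bottleneck(g, m, c_, shortcut = shortcut, comp = comp, mod = mod)
  }
  cat_id <- add_node(g, "concat", from = c(m, y2), c_out = 2L * c_,
                     comp = comp, mod = mod)
  conv_bn(g, cat_id, c2, k = 1L, comp = comp, mod = mod)
}

sppf_block <- function(g, from, c2, k = 5L, comp = "backbone") {
  c1 <- channels_of(g, from)
  c_ <- as.integer(c1 / 2)
  y <- conv_bn(g, from, c_, k = 1L, comp = comp, mod = "SPPF")
  m1 <- add_node(g, "maxpool", from = y, c_out = c_, comp = comp,
                 mod = "SPPF", k = k)
  m2 <- add_node(g, "maxpool", from = m1, c_out = c_, comp = comp,
                 mod = "SPPF", k = k)
  m3 <- add_node(g, "maxpool", from = m2, c_out = c_, comp = comp,
                 mod = "SPPF", k = k)
  cat_id <- add_node(g, "concat", from = c(y, m1, m2, m3), c_out = 4L * c_,
                     comp = comp, mod = "SPPF")
  conv_bn(g, cat_id, c2, k = 1L, comp = comp, mod = "SPPF")
}

make_divisible <- function(x, divisor = 8L) {
  as.integer(ceiling(x / divisor) * divisor)
}

#' Architecture configuration
#'
#' All structural knobs of the detector. The default scale is the small
#' (s) variant of the YOLOv5 family (depth multiple 0.33, width multiple
#' 0.50), identified by the published parameter budget of the baseline at 12
#' classes. \code{ghost} substitutes GhostConv for the strided backbone
#' convolutions and C3Ghost for the backbone C3 blocks; \code{decoupled}
#' replaces the coupled prediction layer with per-level decoupled heads
#' (1x1 stem to \code{head_hidden} channels, then parallel classification
#' and regression branches of two 3x3 convolutions, with an IoU/objectness
#' branch on the regression path). The stem takes \code{in_channels} image
#' channels (1 for native grayscale ultrasound).
#'
#' @param num_classes Number of object classes; default 12.
#' @param ghost Use Ghost backbone substitutions; default TRUE.
#' @param decoupled Use the decoupled head; default TRUE.
#' @param loss_name Box-regression loss, "SIoU" or "CIoU"; default "SIoU".
#' @param depth_multiple,width_multiple Compound scaling of block repeats
#'   and channel widths.
#' @param in_channels Image channels expected by the stem; default 1.
#' @param input_size Nominal square input size in pixels; default 640.
#' @param head_hidden Decoupled-head hidden width at width_multiple 0.5
#'   (scales with \code{width_multiple}); nominal 256, i.e. 128 effective.
#' @param theta SIoU shape-concern exponent; default 4.
#' @param anchors 3x3x2 array (level, anchor, w/h) of anchor sizes in input
#'   pixels; default the YOLOv5 P3/P4/P5 anchors.
#' @return A list of class \code{"arch_config"}.
#' @export
arch_config <- function(num_classes = 12L, ghost = TRUE, decoupled = TRUE,
                        loss_name = c("SIoU", "CIoU"),
                        depth_multiple = 0.33, width_multiple = 0.50,
                        in_channels = 1L, input_size = 640L,
                        head_hidden = NULL, theta = 4, anchors = NULL) {
  loss_name <- match.arg(loss_name)
  stopifnot(num_classes >= 1, depth_multiple > 0, width_multiple > 0,
            in_channels >= 1, theta > 0)
  if (is.null(anchors)) {
    anchors <- array(c(10, 16, 33, 30, 62, 59, 116, 156, 373,
                       13, 30, 23, 61, 45, 119, 90, 198, 326),
                     dim = c(3, 3, 2))  # [level, anchor, (w,h)]
  }
  if (any(anchors <= 0)) stop("anchors must be positive")
  if (is.null(head_hidden)) head_hidden <- make_divisible(256 * width_multiple)
  structure(list(num_classes = as.integer(num_classes), ghost = ghost,
                 decoupled = decoupled, loss_name = loss_name,
                 depth_multiple = depth_multiple,
                 width_multiple = width_multiple,
                 in_channels = as.integer(in_channels),
                 input_size = as.integer(input_size),
                 head_hidden = as.integer(head_hidden), theta = theta,
                 anchors = anchors, num_anchors = 3L,
                 strides = c(8L, 16L, 32L)),
            class = "arch_config")
}

#' Ghost module as a standalone layer graph
#'
#' Builds one Ghost convolution module (primary convolution producing the
#' intrinsic features, cheap depthwise convolution producing the ghost
#' features, concatenation) as a self-contained graph, mainly for
#' inspection and testing.
#'
#' @param in_channels,out_channels Channel counts (positive).
#' @param kernel Primary convolution kernel size; default 1.
#' @return An \code{fbstr_graph} whose final node outputs
#'   \code{out_channels} channels.
#' @export
build_ghost_module <- function(in_channels, out_channels, kernel = 1L) {
  if (in_channels < 1 || out_channels < 1) {
    stop("channel counts must be positive")
  }
  g <- new_graph(as.integer(in_channels))
  out <- ghost_conv(g, 1L, as.integer(out_channels), k = as.integer(kernel))
  finish_graph(g, out_ids = out)
}

finish_graph <- function(g, out_ids, meta = NULL, config = NULL) {
  structure(list(nodes = g$nodes, out_ids = out_ids, out_meta = meta,
                 config = config),
            class = "fbstr_graph")
}

# Backbone + neck; returns graph env plus the three pyramid tap ids
build_trunk <- function(config) {
  gw <- function(c_nominal) make_divisible(c_nominal * config$width_multiple)
  gd <- function(n) max(1L, round(n * config$depth_multiple))
  ghost <- isTRUE(config$ghost)
  g <- new_graph(config$in_channels)

  # backbone (P1..P5); ghost substitution applies to the strided convs and
  # C3 blocks after the stem; stem and SPPF stay dense
  x0 <- conv_bn(g, 1L, gw(64), k = 6L, s = 2L, p = 2L, mod = "Conv")       # 0 P1/2
  dconv <- function(from, c2) {
    if (ghost) ghost_conv(g, from, c2, k = 3L, s = 2L)
    else conv_bn(g, from, c2, k = 3L, s = 2L, mod = "Conv")
  }
  x1 <- dconv(x0, gw(128))                                                 # 1 P2/4
  x2 <- c3_block(g, x1, gw(128), n = gd(3), ghost = ghost)                 # 2
  x3 <- dconv(x2, gw(256))                                                 # 3 P3/8
  x4 <- c3_block(g, x3, gw(256), n = gd(6), ghost = ghost)                 # 4
  x5 <- dconv(x4, gw(512))                                                 # 5 P4/16
  x6 <- c3_block(g, x5, gw(512), n = gd(9), ghost = ghost)                 # 6
  x7 <- dconv(x6, gw(1024))                                                # 7 P5/32
  x8 <- c3_block(g, x7, gw(1024), n = gd(3), ghost = ghost)                # 8
  x9 <- sppf_block(g, x8, gw(1024))                                        # 9

  # PANet neck (dense; unmodified by the ghost flag)
  nc3 <- function(from, c2) {
    c3_block(g, from, c2, n = gd(3), shortcut = FALSE, comp = "neck")
  }
  y10 <- conv_bn(g, x9, gw(512), k = 1L, comp = "neck", mod = "Conv")
  y11 <- add_node(g, "upsample", from = y10, c_out = channels_of(g, y10),
                  comp = "neck", mod = "Upsample")
  y12 <- add_node(g, "concat", from = c(y11, x6),
                  c_out = channels_of(g, y11) + channels_of(g, x6),
                  comp = "neck", mod = "Concat")
  y13 <- nc3(y12, gw(512))
  y14 <- conv_bn(g, y13, gw(256), k = 1L, comp = "neck", mod = "Conv")
  y15 <- add_node(g, "upsample", from = y14, c_out = channels_of(g, y14),
                  comp = "neck", mod = "Upsample")
  y16 <- add_node(g, "concat", from = c(y15, x4),
                  c_out = channels_of(g, y15) + channels_of(g, x4),
                  comp = "neck", mod = "Concat")
  p3 <- nc3(y16, gw(256))
  y18 <- conv_bn(g, p3, gw(256), k = 3L, s = 2L, comp = "neck", mod = "Conv")
  y19 <- add_node(g, "concat", from = c(y18, y14),
                  c_out = channels_of(g, y18) + channels_of(g, y14),
                  comp = "neck", mod = "Concat")
  p4 <- nc3(y19, gw(512))
  y21 <- conv_bn(g, p4, gw(512), k = 3L, s = 2L, comp = "neck", mod = "Conv")
  y22 <- add_node(g, "concat", from = c(y21, y10),
                  c_out = channels_of(g, y21) + channels_of(g, y10),
                  comp = "neck", mod = "Concat")
  p5 <- nc3(y22, gw(1024))

  list(g = g, taps = c(p3, p4, p5))
}

# Attach the prediction head; returns out ids + per-output metadata
attach_head <- function(g, taps, config) {
  na <- config$num_anchors; nc <- config$num_classes
  out_ids <- integer(); meta <- list()
  if (!config$decoupled) {
    for (lev in 1:3) {
      o <- conv_bn(g, taps[lev], na * (5L + nc), k = 1L, act = FALSE,
                   bn = FALSE, bias = TRUE, comp = "head", mod = "Detect")
      out_ids <- c(out_ids, o)
      meta[[length(meta) + 1L]] <- list(level = lev, part = "coupled",
                                        stride = config$strides[lev])
    }
  } else {
    h <- config$head_hidden
    for (lev in 1:3) {
      stem <- conv_bn(g, taps[lev], h, k = 1L, comp = "head",
                      mod = "Decoupled")
      cls <- conv_bn(g, stem, h, k = 3L, comp = "head", mod = "Decoupled")
      cls <- conv_bn(g, cls, h, k = 3L, comp = "head", mod = "Decoupled")
      cls_p <- conv_bn(g, cls, na * nc, k = 1L, act = FALSE, bn = FALSE,
                       bias = TRUE, comp = "head", mod = "Decoupled")
      reg <- conv_bn(g, stem, h, k = 3L, comp = "head", mod = "Decoupled")
      reg <- conv_bn(g, reg, h, k = 3L, comp = "head", mod = "Decoupled")
      reg_p <- conv_bn(g, reg, na * 4L, k = 1L, act = FALSE, bn = FALSE,
                       bias = TRUE, comp = "head", mod = "Decoupled")
      obj_p <- conv_bn(g, reg, na * 1L, k = 1L, act = FALSE, bn = FALSE,
                       bias = TRUE, comp = "head", mod = "Decoupled")
      out_ids <- c(out_ids, cls_p, reg_p, obj_p)
      meta <- c(meta, list(
        list(level = lev, part = "cls", stride = config$strides[lev]),
        list(level = lev, part = "reg", stride = config$strides[lev]),
        list(level = lev, part = "obj", stride = config$strides[lev])))
    }
  }
  list(out_ids = out_ids, meta = meta)
}

build_graph <- function(config) {
  trunk <- build_trunk(config)
  head <- attach_head(trunk$g, trunk$taps, config)
  gr <- finish_graph(trunk$g, out_ids = head$out_ids, meta = head$meta,
                     config = config)
  gr$taps <- trunk$taps
  gr
}

# ---- parameter counting ---------------------------------------------------

node_param_count <- function(nd) {
  if (nd$op != "conv") return(0)
  n <- nd$k^2 * (nd$c_in %/% nd$groups) * nd$c_out
  if (isTRUE(nd$bn)) n <- n + 2L * nd$c_out
  if (isTRUE(nd$bias)) n <- n + nd$c_out
  n
}

#' Count trainable parameters
#'
#' Exact trainable-parameter count of a model or layer graph (convolution
#' weights and biases, batch-norm scale and shift), broken down by
#' component, with the conventional "millions, one decimal" rounding used
#' when reporting detector sizes. The count is independent of input
#' resolution.
#'
#' @param model An \code{fbstrnet} model or \code{fbstr_graph}.
#' @return A list of class \code{"parameter_report"}: \code{total},
#'   \code{by_component} (named vector), \code{millions_rounded}.
#' @export
#' @examples
#' count_parameters(build_ghost_module(64, 64))
count_parameters <- function(model) {
  nodes <- if (inherits(model, "fbstrnet")) model$graph$nodes
           else if (inherits(model, "fbstr_graph")) model$nodes
           else stop("not a model or layer graph")
  counts <- vapply(nodes, node_param_count, numeric(1))
  comp <- vapply(nodes, function(nd) nd$comp, character(1))
  by_comp <- tapply(counts, comp, sum)
  by_comp <- by_comp[setdiff(names(by_comp), "input")]
  total <- sum(counts)
  structure(list(total = total, by_component = c(by_comp),
                 millions_rounded = round(total / 1e6, 1)),
            class = "parameter_report")
}

#' @export
print.parameter_report <- function(x, ...) {
  cat(sprintf("trainable parameters: %s (%.1f M)\n",
              format(x$total, big.mark = ","), x$millions_rounded))
  for (nm in names(x$by_component)) {
    cat(sprintf("  %-9s %s\n", nm, format(x$by_component[[nm]],
                                          big.mark = ",")))
  }
  invisible(x)
}
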