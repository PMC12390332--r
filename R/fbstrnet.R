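#' Construct the fetal-brain structure detector
#'
#' Builds the single-stage detector as a classed model object: a YOLOv5-s
#' scale backbone/neck with optional Ghost substitutions in the backbone, a
#' coupled or decoupled anchor-based prediction head over the stride-8/16/32
#' feature pyramid, and randomly initialised weights (He initialisation;
#' prediction biases set to a low-objectness prior). The object is ready for
#' \code{\link{fbstrnet_train}} or \code{\link[=predict.fbstrnet]{predict}}
#' (an untrained model predicts noise, but all shapes are live).
#'
#' @param num_classes Number of structure classes; default 12.
#' @param ghost Substitute GhostConv/C3Ghost in the backbone; default TRUE.
#' @param decoupled Use the decoupled prediction head; default TRUE.
#' @param loss_name Box-regression loss, "SIoU" (default) or "CIoU".
#' @param seed Integer seed for weight initialisation.
#' @param ... Further arguments to \code{\link{arch_config}}
#'   (\code{width_multiple}, \code{in_channels}, \code{anchors}, ...).
#' @return An object of class \code{"fbstrnet"} with elements
#'   \code{config}, \code{graph}, \code{params} and (after training)
#'   \code{history}.
#' @export
#' @examples
#' m <- fbstrnet(ghost = FALSE, decoupled = FALSE)
#' count_parameters(m)
fbstrnet <- function(num_classes = 12L, ghost = TRUE, decoupled = TRUE,
                     loss_name = c("SIoU", "CIoU"), seed = 0L, ...) {
  loss_name <- match.arg(loss_name)
  config <- arch_config(num_classes = num_classes, ghost = ghost,
                        decoupled = decoupled, loss_name = loss_name, ...)
  graph <- build_graph(config)
  model <- structure(list(config = config, graph = graph,
                          params = init_params(graph, seed = seed),
                          history = NULL, trained = FALSE),
                     class = "fbstrnet")
  init_detect_biases(model)
}

#' @export
print.fbstrnet <- function(x, ...) {
  cfg <- x$config
  rep <- count_parameters(x)
  cat(sprintf("fbstrnet detector (%s backbone, %s head, %s box loss)\n",
              if (cfg$ghost) "Ghost" else "dense",
              if (cfg$decoupled) "decoupled" else "coupled", cfg$loss_name))
  cat(sprintf("  classes: %d | input channels: %d | depth x width: %.2f x %.2f\n",
              cfg$num_classes, cfg$in_channels, cfg$depth_multiple,
              cfg$width_multiple))
  cat(sprintf("  parameters: %s (%.1f M)\n", format(rep$total, big.mark = ","),
              rep$millions_rounded))
  if (!is.null(x$history)) {
    cat(sprintf("  trained: %d epochs, final loss %.4f\n",
                max(x$history$epoch), utils::tail(x$history$loss, 1)))
  }
  invisible(x)
}

#' @export
summary.fbstrnet <- function(object, ...) {
  nodes <- object$graph$nodes
  df <- data.frame(
    id = vapply(nodes, function(n) n$id, integer(1)),
    op = vapply(nodes, function(n) n$op, character(1)),
    module = vapply(nodes, function(n) n$mod, character(1)),
    component = vapply(nodes, function(n) n$comp, character(1)),
    channels = vapply(nodes, function(n) n$c_out, integer(1)),
    params = vapply(nodes, node_param_count, numeric(1)))
  structure(list(layers = df, report = count_parameters(object),
                 config = object$config),
            class = "summary.fbstrnet")
}

#' @export
print.summary.fbstrnet <- function(x, ...) {
  agg <- stats::aggregate(params ~ component + module, data = x$layers, sum)
  agg <- agg[order(match(agg$component, c("backbone", "neck", "head"))), ]
  print(agg, row.names = FALSE)
  cat("\n"); print(x$report)
  invisible(x)
}

#' @export
plot.fbstrnet <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history; fit it first")
  graphics::matplot(h$epoch, h[, c("box", "obj", "cls")], type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss component",
                    main = "training loss", ...)
  graphics::legend("topright", c("box", "obj", "cls"), col = 1:3, lty = 1,
                   bty = "n")
  invisible(x)
}

#' Save and load a detector checkpoint
#'
#' The checkpoint container is an RDS file holding the architecture
#' configuration, all weights and running statistics, and the training
#' history; the layer graph is rebuilt from the configuration on load, so a
#' checkpoint is portable across sessions.
#'
#' @param model An \code{fbstrnet} model.
#' @param path Checkpoint path (.rds).
#' @return \code{save_fbstrnet}: invisibly, \code{path};
#'   \code{load_fbstrnet}: the restored model.
#' @export
save_fbstrnet <- function(model, path) {
  stopifnot(inherits(model, "fbstrnet"))
  saveRDS(list(config = unclass(model$config), params = model$params,
               history = model$history, trained = model$trained,
               format = 1L), path)
  invisible(path)
}

#' @rdname save_fbstrnet
#' @export
load_fbstrnet <- function(path) {
  ck <- readRDS(path)
  config <- structure(ck$config, class = "arch_config")
  graph <- build_graph(config)
  structure(list(config = config, graph = graph, params = ck$params,
                 history = ck$history, trained = isTRUE(ck$trained)),
            class = "fbstrnet")
}

#' Write or read the architecture configuration as YAML
#'
#' Mirrors \code{\link{arch_config}} field-for-field so configurations can
#' be versioned alongside datasets.
#'
#' @param config An \code{arch_config}.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  x$anchors <- as.vector(x$anchors)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  anchors <- array(as.numeric(unlist(x$anchors)), dim = c(3, 3, 2))
  arch_config(num_classes = x$num_classes, ghost = x$ghost,
              decoupled = x$decoupled, loss_name = x$loss_name,
              depth_multiple = x$depth_multiple,
              width_multiple = x$width_multiple,
              in_channels = x$in_channels, input_size = x$input_size,
              head_hidden = x$head_hidden, theta = x$theta,
              anchors = anchors)
}
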