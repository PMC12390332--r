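# Bridge to the single-precision C++ training path. The graph description
# is serialised once per model; forward keeps its caches in C++ and the
# loss side stays in R on the (double) head outputs.

OP_CODES <- c(input = 0L, conv = 1L, maxpool = 2L, upsample = 3L,
              concat = 4L, add = 5L, slice = 6L)

graph_desc32 <- function(graph) {
  lapply(graph$nodes, function(nd) {
    list(op = OP_CODES[[nd$op]],
         from = as.integer(nd$from),
         c_out = nd$c_out,
         k = if (is.null(nd$k)) 0L else nd$k,
         s = if (is.null(nd$s)) 1L else nd$s,
         p = if (is.null(nd$p)) 0L else nd$p,
         groups = if (is.null(nd$groups)) 1L else nd$groups,
         bn = as.integer(isTRUE(nd$bn)),
         act = as.integer(identical(nd$act, "silu")),
         bias = as.integer(isTRUE(nd$bias)),
         take = if (is.null(nd$take)) 0L else nd$take)
  })
}

bn_node_ids <- function(graph) {
  which(vapply(graph$nodes, function(nd) {
    nd$op == "conv" && isTRUE(nd$bn)
  }, logical(1)))
}

# single-image forward+backward on the float engine; same contract as
# image_step (double reference path)
image_step32 <- function(model, img, labels, hyp, desc = NULL) {
  if (is.null(desc)) desc <- graph_desc32(model$graph)
  x <- image_to_input(img, model$config$in_channels)
  fw <- cpp32_forward(desc, model$params, x, model$graph$out_ids)
  bn_ids <- bn_node_ids(model$graph)
  for (j in seq_along(bn_ids)) {
    id <- bn_ids[j]
    p <- model$params[[id]]
    model$params[[id]]$rmean <- as.numeric((1 - BN_MOMENTUM) * p$rmean +
      BN_MOMENTUM * fw$bn_mean[[j]])
    model$params[[id]]$rvar <- as.numeric((1 - BN_MOMENTUM) * p$rvar +
      BN_MOMENTUM * fw$bn_var[[j]])
  }
  ll <- yolo_loss_grads(model, fw$outs, labels, hyp)
  grads <- cpp32_backward(fw$state, unname(ll$gout))
  list(model = model, grads = grads, loss = ll)
}
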