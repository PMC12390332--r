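# ---- parameter store, forward and backward passes -------------------------
#
# Parameters live in a plain list indexed by node id. Convolution nodes own
# W (c_out x k^2*c_in/groups, rows in im2col patch order), optionally a bias
# b, and batch-norm gamma/beta plus running statistics. The forward pass
# caches exactly what the backward pass needs (conv output z, batch-norm
# statistics, pre-activation); everything else is recomputed.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.03

init_params <- function(graph, seed = 0L) {
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  params <- vector("list", length(graph$nodes))
  for (nd in graph$nodes) {
    if (nd$op != "conv") next
    fan_in <- nd$k^2 * (nd$c_in %/% nd$groups)
    p <- list(W = matrix(stats::rnorm(nd$c_out * fan_in, sd = sqrt(2 / fan_in)),
                         nrow = nd$c_out))
    if (isTRUE(nd$bias)) p$b <- numeric(nd$c_out)
    if (isTRUE(nd$bn)) {
      p$gamma <- rep(1, nd$c_out); p$beta <- numeric(nd$c_out)
      p$rmean <- numeric(nd$c_out); p$rvar <- rep(1, nd$c_out)
    }
    params[[nd$id]] <- p
  }
  params
}

# prior-aware initialisation of the prediction biases (objectness biased to
# the expected object density, class scores to a small uniform prior)
init_detect_biases <- function(model) {
  cfg <- model$config
  na <- cfg$num_anchors; nc <- cfg$num_classes
  for (i in seq_along(model$graph$out_ids)) {
    id <- model$graph$out_ids[i]
    m <- model$graph$out_meta[[i]]
    b <- model$params[[id]]$b
    obj_b <- log(8 / (cfg$input_size / m$stride)^2)
    cls_b <- log(0.6 / (nc - 0.99))
    if (m$part == "coupled") {
      for (a in seq_len(na) - 1L) {
        b[a * (5L + nc) + 5L] <- obj_b
        b[a * (5L + nc) + 5L + seq_len(nc)] <- cls_b
      }
    } else if (m$part == "obj") {
      b[] <- obj_b
    } else if (m$part == "cls") {
      b[] <- cls_b
    }
    model$params[[id]]$b <- b
  }
  model
}

forward_graph <- function(graph, params, x, train = FALSE,
                          stats = c("image", "running")) {
  stats <- match.arg(stats)
  nodes <- graph$nodes
  acts <- vector("list", length(nodes))
  cache <- if (train) vector("list", length(nodes)) else NULL
  acts[[1L]] <- x
  for (nd in nodes) {
    if (nd$op == "input") next
    id <- nd$id
    out <- switch(nd$op,
      conv = {
        xin <- acts[[nd$from]]
        p <- params[[id]]
        z <- cpp_conv_fwd(xin, p$W, if (is.null(p$b)) numeric(0) else p$b,
                          nd$k, nd$s, nd$p, nd$groups)
        pre <- z
        if (isTRUE(nd$bn)) {
          if (train) {
            bn <- cpp_bn_fwd(z, p$gamma, p$beta, BN_EPS)
            pre <- bn$y
            params[[id]]$rmean <- as.numeric((1 - BN_MOMENTUM) * p$rmean +
              BN_MOMENTUM * bn$mean)
            params[[id]]$rvar <- as.numeric((1 - BN_MOMENTUM) * p$rvar +
              BN_MOMENTUM * bn$var)
            cache[[id]]$z <- z
            cache[[id]]$mean <- bn$mean
            cache[[id]]$var <- bn$var
          } else if (stats == "image") {
            pre <- cpp_bn_fwd(z, p$gamma, p$beta, BN_EPS)$y
          } else {
            pre <- cpp_bn_eval(z, p$gamma, p$beta, p$rmean, p$rvar, BN_EPS)
          }
        }
        if (nd$act == "silu") {
          if (train) cache[[id]]$pre <- pre
          cpp_silu_fwd(pre)
        } else pre
      },
      maxpool = {
        mp <- cpp_maxpool_fwd(acts[[nd$from]], nd$k)
        if (train) cache[[id]] <- list(arg = mp$arg)
        mp$y
      },
      upsample = cpp_upsample2_fwd(acts[[nd$from]]),
      concat = {
        ins <- lapply(nd$from, function(i) acts[[i]])
        do.call(abind3, ins)
      },
      add = acts[[nd$from[1]]] + acts[[nd$from[2]]],
      slice = acts[[nd$from]][, , seq_len(nd$take), drop = FALSE],
      stop("unknown op ", nd$op))
    acts[[id]] <- out
  }
  list(acts = acts, cache = cache, params = params,
       outs = acts[graph$out_ids])
}

abind3 <- function(...) {
  ins <- list(...)
  d <- dim(ins[[1]])
  cs <- vapply(ins, function(a) dim(a)[3], numeric(1))
  out <- array(0, c(d[1], d[2], sum(cs)))
  at <- 0L
  for (a in ins) {
    out[, , at + seq_len(dim(a)[3])] <- a
    at <- at + dim(a)[3]
  }
  out
}

# gout: list indexed by node id with gradient cubes for the output nodes
backward_graph <- function(graph, params, acts, cache, gout) {
  nodes <- graph$nodes
  gacc <- vector("list", length(nodes))
  for (id in names(gout)) gacc[[as.integer(id)]] <- gout[[id]]
  grads <- vector("list", length(nodes))
  for (i in rev(seq_along(nodes))) {
    g <- gacc[[i]]
    if (is.null(g)) next
    nd <- nodes[[i]]
    if (nd$op == "input") next
    push <- function(to, gr) {
      gacc[[to]] <<- if (is.null(gacc[[to]])) gr else gacc[[to]] + gr
    }
    switch(nd$op,
      conv = {
        p <- params[[i]]; cc <- cache[[i]]
        if (nd$act == "silu") g <- cpp_silu_bwd(cc$pre, g)
        gr <- list()
        if (isTRUE(nd$bn)) {
          bw <- cpp_bn_bwd(cc$z, p$gamma, cc$mean, cc$var, g, BN_EPS)
          gr$dgamma <- bw$dgamma; gr$dbeta <- bw$dbeta
          g <- bw$dx
        }
        cb <- cpp_conv_bwd(acts[[nd$from]], p$W, g, nd$k, nd$s, nd$p,
                           nd$groups, need_dx = nd$from != 1L,
                           need_db = isTRUE(nd$bias))
        gr$dW <- cb$dW
        if (isTRUE(nd$bias)) gr$db <- as.numeric(cb$db)
        grads[[i]] <- gr
        if (nd$from != 1L) push(nd$from, cb$dx)
      },
      maxpool = push(nd$from, cpp_maxpool_bwd(cache[[i]]$arg, g)),
      upsample = push(nd$from, cpp_upsample2_bwd(g)),
      concat = {
        at <- 0L
        for (f in nd$from) {
          cf <- dim(acts[[f]])[3]
          push(f, g[, , at + seq_len(cf), drop = FALSE])
          at <- at + cf
        }
      },
      add = { push(nd$from[1], g); push(nd$from[2], g) },
      slice = {
        full <- array(0, dim(acts[[nd$from]]))
        full[, , seq_len(nd$take)] <- g
        push(nd$from, full)
      })
    gacc[[i]] <- NULL  # free
  }
  grads
}

# accumulate grads element-wise (for mini-batch averaging)
merge_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(b)) {
    if (is.null(b[[i]])) next
    if (is.null(a[[i]])) { a[[i]] <- b[[i]]; next }
    for (nm in names(b[[i]])) {
      a[[i]][[nm]] <- if (is.null(a[[i]][[nm]])) b[[i]][[nm]]
                      else a[[i]][[nm]] + b[[i]][[nm]]
    }
  }
  a
}

scale_grads <- function(grads, f) {
  lapply(grads, function(g) {
    if (is.null(g)) return(NULL)
    lapply(g, function(v) v * f)
  })
}

new_sgd_state <- function() new.env(parent = emptyenv())

# SGD with momentum; weight decay applies to convolution weights only
sgd_step <- function(params, grads, state, lr, momentum = 0.937,
                     weight_decay = 0) {
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    if (is.null(g)) next
    key <- as.character(i)
    v <- state[[key]]
    if (is.null(v)) v <- list()
    for (nm in names(g)) {
      pname <- c(dW = "W", db = "b", dgamma = "gamma", dbeta = "beta")[[nm]]
      gr <- g[[nm]]
      if (pname == "W" && weight_decay > 0) {
        gr <- gr + weight_decay * params[[i]][[pname]]
      }
      v[[pname]] <- if (is.null(v[[pname]])) gr else momentum * v[[pname]] + gr
      params[[i]][[pname]] <- params[[i]][[pname]] - lr * v[[pname]]
    }
    state[[key]] <- v
  }
  params
}
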