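# The compute kernels are checked against naive R reference implementations
# and the assembled backward pass against finite differences.

naive_conv <- function(x, Wt, bias, k, s, p, groups) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  Cout <- nrow(Wt)
  cgi <- Cin / groups; cgo <- Cout / groups
  Ho <- (H + 2 * p - k) %/% s + 1; Wo <- (W + 2 * p - k) %/% s + 1
  out <- array(0, c(Ho, Wo, Cout))
  for (co in seq_len(Cout)) {
    g <- (co - 1) %/% cgo
    for (oh in seq_len(Ho)) for (ow in seq_len(Wo)) {
      acc <- if (length(bias)) bias[co] else 0
      for (ci in seq_len(cgi)) for (dw in seq_len(k)) for (dh in seq_len(k)) {
        ih <- (oh - 1) * s - p + dh; iw <- (ow - 1) * s - p + dw
        if (ih < 1 || ih > H || iw < 1 || iw > W) next
        widx <- dh + k * (dw - 1) + k * k * (ci - 1)
        acc <- acc + Wt[co, widx] * x[ih, iw, g * cgi + ci]
      }
      out[oh, ow, co] <- acc
    }
  }
  out
}

test_that("convolution matches a naive reference (stride, pad, groups)", {
  set.seed(201)
  cases <- list(list(k = 1, s = 1, p = 0, g = 1, ci = 4, co = 6),
                list(k = 3, s = 1, p = 1, g = 1, ci = 3, co = 5),
                list(k = 3, s = 2, p = 1, g = 1, ci = 4, co = 4),
                list(k = 6, s = 2, p = 2, g = 1, ci = 1, co = 3),
                list(k = 5, s = 1, p = 2, g = 4, ci = 4, co = 4))
  for (cs in cases) {
    x <- array(rnorm(9 * 9 * cs$ci), c(9, 9, cs$ci))
    Wt <- matrix(rnorm(cs$co * cs$k^2 * cs$ci / cs$g), nrow = cs$co)
    b <- rnorm(cs$co)
    got <- fbstrnet:::cpp_conv_fwd(x, Wt, b, cs$k, cs$s, cs$p, cs$g)
    want <- naive_conv(x, Wt, b, cs$k, cs$s, cs$p, cs$g)
    expect_equal(got, want, tolerance = 1e-12,
                 label = paste0("k", cs$k, "s", cs$s, "g", cs$g))
  }
})

test_that("batch norm normalises per channel and backward is exact", {
  set.seed(211)
  x <- array(rnorm(8 * 8 * 3, mean = 2, sd = 3), c(8, 8, 3))
  gamma <- runif(3, 0.5, 2); beta <- rnorm(3)
  fw <- fbstrnet:::cpp_bn_fwd(x, gamma, beta, 1e-5)
  for (c in 1:3) {
    expect_equal(mean(fw$y[, , c]), beta[c], tolerance = 1e-9)
    expect_equal(sd(as.vector(fw$y[, , c])) * sqrt(63 / 64), gamma[c],
                 tolerance = 1e-3)
  }
  g <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  bw <- fbstrnet:::cpp_bn_bwd(x, gamma, fw$mean, fw$var, g, 1e-5)
  h <- 1e-6
  for (probe in 1:5) {
    i <- sample(length(x), 1)
    x2 <- x; x2[i] <- x2[i] + h
    x3 <- x; x3[i] <- x3[i] - h
    f2 <- sum(fbstrnet:::cpp_bn_fwd(x2, gamma, beta, 1e-5)$y * g)
    f3 <- sum(fbstrnet:::cpp_bn_fwd(x3, gamma, beta, 1e-5)$y * g)
    expect_equal(bw$dx[i], (f2 - f3) / (2 * h), tolerance = 1e-4)
  }
})

test_that("maxpool and upsampling match naive references", {
  set.seed(221)
  x <- array(rnorm(7 * 7 * 2), c(7, 7, 2))
  mp <- fbstrnet:::cpp_maxpool_fwd(x, 5)
  for (c in 1:2) for (oh in 1:7) for (ow in 1:7) {
    win <- x[max(1, oh - 2):min(7, oh + 2), max(1, ow - 2):min(7, ow + 2), c]
    expect_equal(mp$y[oh, ow, c], max(win))
  }
  up <- fbstrnet:::cpp_upsample2_fwd(x)
  expect_equal(dim(up), c(14, 14, 2))
  expect_equal(up[2 * (1:7), 2 * (1:7) - 1, ], x[1:7, 1:7, ])
})

test_that("assembled backward pass agrees with finite differences", {
  set.seed(231)
  m <- fbstrnet(width_multiple = 0.125, seed = 3)
  g <- m$graph
  x <- array(runif(32 * 32), c(32, 32, 1))
  fw <- fbstrnet:::forward_graph(g, m$params, x, train = TRUE)
  Rs <- lapply(fw$outs, function(o) array(rnorm(length(o)), dim(o)))
  gout <- Rs; names(gout) <- as.character(g$out_ids)
  grads <- fbstrnet:::backward_graph(g, m$params, fw$acts, fw$cache, gout)
  lossval <- function(params) {
    f <- fbstrnet:::forward_graph(g, params, x, train = TRUE)
    sum(mapply(function(o, r) sum(o * r), f$outs, Rs))
  }
  conv_ids <- which(!vapply(grads, is.null, logical(1)))
  h <- 1e-5
  for (probe in 1:12) {
    id <- sample(conv_ids, 1)
    fld <- sample(names(grads[[id]]), 1)
    pn <- c(dW = "W", db = "b", dgamma = "gamma", dbeta = "beta")[[fld]]
    k <- sample(length(m$params[[id]][[pn]]), 1)
    p2 <- m$params; p2[[id]][[pn]][k] <- p2[[id]][[pn]][k] + h
    p3 <- m$params; p3[[id]][[pn]][k] <- p3[[id]][[pn]][k] - h
    num <- (lossval(p2) - lossval(p3)) / (2 * h)
    ana <- grads[[id]][[fld]][k]
    expect_equal(ana, num, tolerance = 5e-3,
                 label = sprintf("node %d %s[%d]", id, fld, k))
  }
})

test_that("detection-loss gradients agree with finite differences", {
  set.seed(241)
  m <- fbstrnet(width_multiple = 0.125, seed = 2)
  p <- generate_phantom(phantom_spec("TTAP", image_size = 64, seed = 5))
  x <- fbstrnet:::image_to_input(p$image, 1)
  fw <- fbstrnet:::forward_graph(m$graph, m$params, x, train = TRUE)
  ll <- fbstrnet:::yolo_loss_grads(m, fw$outs, p$labels)
  expect_true(ll$n_assigned > 0)
  h <- 1e-5
  for (probe in 1:20) {
    oi <- sample(length(fw$outs), 1)
    k <- sample(length(fw$outs[[oi]]), 1)
    part <- m$graph$out_meta[[oi]]$part
    o2 <- fw$outs; o2[[oi]][k] <- o2[[oi]][k] + h
    o3 <- fw$outs; o3[[oi]][k] <- o3[[oi]][k] - h
    l2 <- fbstrnet:::yolo_loss_grads(m, o2, p$labels)
    l3 <- fbstrnet:::yolo_loss_grads(m, o3, p$labels)
    # regression logits: difference only the box+cls parts, because the
    # objectness target (decoded-box IoU) is deliberately detached
    num <- if (part == "reg") (l2$box + l2$cls - l3$box - l3$cls) / (2 * h)
           else (l2$total - l3$total) / (2 * h)
    ana <- ll$gout[[oi]][k]
    expect_equal(ana, num, tolerance = 2e-3)
  }
})

test_that("the single-precision fast path matches the reference engine", {
  set.seed(251)
  m <- fbstrnet(width_multiple = 0.125, seed = 6)
  p <- generate_phantom(phantom_spec("TPFAP", image_size = 96, seed = 9))
  hyp <- fbstrnet:::default_hyp(12)
  a <- fbstrnet:::image_step(m, p$image, p$labels, hyp)
  b <- fbstrnet:::image_step32(m, p$image, p$labels, hyp)
  expect_equal(b$loss$total, a$loss$total, tolerance = 1e-4)
  expect_equal(b$loss$box, a$loss$box, tolerance = 1e-3)
  # every parameter gradient agrees to single-precision accumulation noise
  for (i in seq_along(a$grads)) {
    if (is.null(a$grads[[i]])) next
    node_scale <- max(1e-6, max(vapply(a$grads[[i]], function(v)
      max(abs(as.numeric(v))), numeric(1))))
    for (nm in names(a$grads[[i]])) {
      ga <- as.numeric(a$grads[[i]][[nm]])
      gb <- as.numeric(b$grads[[i]][[nm]])
      expect_lt(max(abs(ga - gb)) / node_scale, 0.05,
                label = sprintf("grad %s at node %d", nm, i))
    }
  }
  # running BN statistics agree
  bn <- fbstrnet:::bn_node_ids(m$graph)[1]
  expect_equal(b$model$params[[bn]]$rmean, a$model$params[[bn]]$rmean,
               tolerance = 1e-5)
})
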