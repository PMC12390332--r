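test_that("ghost module splits channels into intrinsic + ghost halves", {
  g <- build_ghost_module(64, 64, kernel = 3)
  expect_equal(g$nodes[[g$out_ids]]$c_out, 64L)
  convs <- Filter(function(n) n$op == "conv", g$nodes)
  expect_equal(vapply(convs, function(n) n$c_out, integer(1)), c(32L, 32L))
  expect_equal(convs[[2]]$groups, 32L)  # cheap op is depthwise
  # strictly cheaper than a dense 3x3 convolution with the same channels
  dense <- 64 * 64 * 9 + 2 * 64
  expect_lt(count_parameters(g)$total, dense)
  # minimal case: one intrinsic + one ghost channel
  g2 <- build_ghost_module(1, 2)
  expect_equal(g2$nodes[[g2$out_ids]]$c_out, 2L)
  expect_error(build_ghost_module(0, 4), "positive")
})

test_that("ghost substitution shrinks every substituted backbone block", {
  base <- fbstrnet:::build_trunk(arch_config(ghost = FALSE))
  ghost <- fbstrnet:::build_trunk(arch_config(ghost = TRUE))
  per_mod <- function(tr, mods) {
    counts <- vapply(tr$g$nodes, fbstrnet:::node_param_count, numeric(1))
    mod <- vapply(tr$g$nodes, function(n) n$mod, character(1))
    comp <- vapply(tr$g$nodes, function(n) n$comp, character(1))
    sum(counts[comp == "backbone" & mod %in% mods])
  }
  # the four strided convs and four C3 blocks, as groups
  expect_lt(per_mod(ghost, "GhostConv"), per_mod(base, "Conv") -
            fbstrnet:::node_param_count(base$g$nodes[[2]]))  # minus the stem
  expect_lt(per_mod(ghost, "C3Ghost"), per_mod(base, "C3"))
  # block-by-block: each strided downsampling stage got cheaper
  for (ch in list(c(32L, 64L), c(64L, 128L), c(128L, 256L), c(256L, 512L))) {
    dense <- ch[1] * ch[2] * 9 + 2 * ch[2]
    gh <- count_parameters(build_ghost_module(ch[1], ch[2], kernel = 3))$total
    expect_lt(gh, dense)
  }
  # SPPF and the neck are untouched
  cnt <- function(tr, comp_want) {
    counts <- vapply(tr$g$nodes, fbstrnet:::node_param_count, numeric(1))
    comp <- vapply(tr$g$nodes, function(n) n$comp, character(1))
    mod <- vapply(tr$g$nodes, function(n) n$mod, character(1))
    sum(counts[comp == comp_want & mod == "SPPF"])
  }
  expect_equal(cnt(ghost, "backbone"), cnt(base, "backbone"))
})

test_that("the canonical scale reproduces the published 80-class budget", {
  # YOLOv5-s at 80 classes with an RGB stem is the community reference point
  r <- count_parameters(fbstrnet:::build_graph(arch_config(
    num_classes = 80, ghost = FALSE, decoupled = FALSE, in_channels = 3)))
  expect_equal(r$total, 7235389)
})

test_that("parameter counts respect structural invariants", {
  base <- count_parameters(fbstrnet:::build_graph(arch_config(
    ghost = FALSE, decoupled = FALSE)))
  ghost <- count_parameters(fbstrnet:::build_graph(arch_config(
    ghost = TRUE, decoupled = FALSE)))
  dec <- count_parameters(fbstrnet:::build_graph(arch_config(
    ghost = FALSE, decoupled = TRUE)))
  full <- count_parameters(fbstrnet:::build_graph(arch_config(
    ghost = TRUE, decoupled = TRUE)))
  expect_lt(ghost$total, base$total)
  expect_gt(dec$total, base$total)
  # the two swaps are additive
  expect_equal(full$total, ghost$total + dec$total - base$total)
  expect_equal(base$total, sum(base$by_component))
  expect_equal(base$millions_rounded, round(base$total / 1e6, 1))
  # input resolution does not change the count (fully convolutional)
  hi <- count_parameters(fbstrnet:::build_graph(arch_config(
    ghost = FALSE, decoupled = FALSE, input_size = 1280)))
  expect_equal(hi$total, base$total)
  # loss choice changes zero parameters
  siou <- count_parameters(fbstrnet(loss_name = "SIoU", width_multiple = 0.125))
  ciou <- count_parameters(fbstrnet(loss_name = "CIoU", width_multiple = 0.125))
  expect_equal(siou$total, ciou$total)
})

test_that("decoupled head has per-level parallel branches with no sharing", {
  g <- fbstrnet:::build_graph(arch_config(decoupled = TRUE))
  meta <- g$out_meta
  parts <- vapply(meta, function(m) m$part, character(1))
  levels <- vapply(meta, function(m) m$level, integer(1))
  expect_equal(sort(unique(parts)), c("cls", "obj", "reg"))
  expect_equal(levels, rep(1:3, each = 3))
  # output channels: na * nc, na * 4, na * 1 per level
  outs <- vapply(g$out_ids, function(i) g$nodes[[i]]$c_out, integer(1))
  expect_equal(outs, rep(c(3L * 12L, 3L * 4L, 3L * 1L), 3))
  expect_equal(sum(outs[1:3]), 3L * (4L + 1L + 12L))
  # classification and regression branches share no nodes below the stem
  trace_back <- function(id, stop_mod = "Decoupled") {
    seen <- integer()
    stack <- id
    while (length(stack)) {
      i <- stack[[1]]; stack <- stack[-1]
      nd <- g$nodes[[i]]
      if (nd$mod != "Decoupled") next
      seen <- c(seen, i)
      stack <- c(stack, nd$from)
    }
    seen
  }
  for (lev in 1:3) {
    idx <- which(levels == lev)
    cls_anc <- trace_back(g$out_ids[idx[parts[idx] == "cls"]])
    reg_anc <- trace_back(g$out_ids[idx[parts[idx] == "reg"]])
    shared <- intersect(cls_anc, reg_anc)
    # the only shared decoupled-head node is the 1x1 stem
    expect_length(shared, 1L)
  }
})

test_that("forward pass yields finite pyramid outputs of documented shapes", {
  set.seed(251)
  m <- fbstrnet(ghost = TRUE, decoupled = TRUE, seed = 9)
  x <- array(runif(640 * 640), c(640, 640, 1))
  fw <- fbstrnet:::forward_graph(m$graph, m$params, x, train = FALSE)
  hw <- t(vapply(fw$outs, function(o) dim(o)[1:2], integer(2)))
  expect_equal(unique(hw[1:3, 1]), 80L)
  expect_equal(unique(hw[4:6, 1]), 40L)
  expect_equal(unique(hw[7:9, 1]), 20L)
  expect_true(all(vapply(fw$outs, function(o) all(is.finite(o)), logical(1))))
  # pyramid taps at strides 8/16/32
  taps <- m$graph$taps
  expect_equal(vapply(taps, function(i) dim(fw$acts[[i]])[1], integer(1)),
               c(80L, 40L, 20L))
})

test_that("a 200-step single-phantom overfit drives the loss downward", {
  p <- generate_phantom(phantom_spec("TLVAP", image_size = 96, seed = 11))
  m <- fbstrnet(width_multiple = 0.125, seed = 1, input_size = 96)
  hyp <- fbstrnet:::default_hyp(12)
  state <- fbstrnet:::new_sgd_state()
  losses <- numeric(200)
  for (i in 1:200) {
    st <- fbstrnet:::image_step(m, p$image, p$labels, hyp)
    m <- st$model
    m$params <- fbstrnet:::sgd_step(m$params, st$grads, state, lr = 0.01,
                                    momentum = 0.937)
    losses[i] <- st$loss$total
  }
  smooth <- stats::filter(losses, rep(1 / 41, 41), sides = 1)
  smooth <- smooth[!is.na(smooth)]
  expect_lt(smooth[length(smooth)], 0.8 * smooth[1])
  expect_true(all(diff(smooth) < 0.005))
})
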