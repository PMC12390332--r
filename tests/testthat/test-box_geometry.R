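test_that("IoU handles identity, disjoint and partial overlap", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  # partial overlap checked against the rasterisation counting oracle
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7,
               tolerance = 1e-12)
  expect_equal(iou_raster_oracle(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7,
               tolerance = 2e-2)
  # degenerate boxes give 0, even when identical
  expect_equal(box_iou(c(1, 1, 1, 1), c(1, 1, 1, 1)), 0)
  expect_error(box_iou(c(0, 0, NA, 2), c(0, 0, 1, 1)), "non-finite")
  expect_error(box_iou(c(2, 0, 0, 2), c(0, 0, 1, 1)), "x2 < x1")
})

test_that("IoU agrees with the rasterisation oracle on random pairs", {
  set.seed(101)
  for (i in 1:20) {
    a <- as.numeric(random_boxes(1, 10)); b <- as.numeric(random_boxes(1, 10))
    expect_equal(box_iou(a, b), iou_raster_oracle(a, b, 0.005),
                 tolerance = 5e-2)
  }
})

test_that("angle penalty is 0 on axis alignment, 1 at 45 degrees, symmetric", {
  expect_equal(angle_loss(c(1, 1, 2, 2), c(3, 1, 2, 2)), 0, tolerance = 1e-12)
  expect_equal(angle_loss(c(1, 1, 2, 2), c(2, 2, 2, 2)), 1, tolerance = 1e-12)
  expect_equal(angle_loss(c(1, 1, 2, 2), c(1, 1, 4, 4)), 0)  # sigma = 0
  # vertical alignment is also a zero (a_h/sigma = 1)
  expect_equal(angle_loss(c(1, 1, 2, 2), c(1, 5, 2, 2)), 0, tolerance = 1e-12)
  set.seed(7)
  g <- cbind(runif(50, 0, 9), runif(50, 0, 9), runif(50, 1, 3), runif(50, 1, 3))
  p <- cbind(runif(50, 0, 9), runif(50, 0, 9), runif(50, 1, 3), runif(50, 1, 3))
  expect_equal(angle_loss(g, p), angle_loss(p, g), tolerance = 1e-12)
  expect_true(all(angle_loss(g, p) >= 0 & angle_loss(g, p) <= 1 + 1e-12))
})

test_that("angle penalty over a full circle peaks at diagonals, dips on axes", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  lam <- vapply(th, function(t) {
    angle_loss(c(0, 0, 1, 1), c(5 * cos(t), 5 * sin(t), 1, 1))
  }, numeric(1))
  expect_true(all(lam >= -1e-9 & lam <= 1 + 1e-9))
  on_axis <- abs(sin(2 * th)) < 1e-9
  expect_true(all(abs(lam[on_axis]) < 1e-9))
  diag45 <- abs(abs(th %% (pi / 2)) - pi / 4) < 1e-9
  expect_true(all(abs(lam[diag45] - 1) < 1e-9))
})

test_that("distance penalty matches scalar evaluation of its formula", {
  # identical boxes
  expect_equal(distance_loss(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  # gt center (1,1), pred center (3,1), enclosing 4x2, Lambda = 0
  expect_equal(distance_loss(c(1, 1, 2, 2), c(3, 1, 2, 2), lambda_angle = 0),
               1 - exp(-0.5), tolerance = 1e-9)
  # gt center (1,1), pred center (2,2), 3x3 boxes -> enclosing 4x4, Lambda = 1
  expect_equal(distance_loss(c(1, 1, 3, 3), c(2, 2, 3, 3), lambda_angle = 1),
               2 * (1 - exp(-0.0625)), tolerance = 1e-9)
})

test_that("shape penalty matches scalar evaluation and rejects bad theta", {
  expect_equal(shape_loss(c(5, 7, 2, 2), c(1, 1, 2, 2)), 0)
  expect_equal(shape_loss(c(0, 0, 2, 2), c(0, 0, 4, 4), theta = 4),
               2 * (1 - exp(-0.5))^4, tolerance = 1e-9)
  expect_equal(shape_loss(c(0, 0, 2, 2), c(0, 0, 2, 4), theta = 4),
               (1 - exp(-0.5))^4, tolerance = 1e-9)
  expect_error(shape_loss(c(0, 0, 2, 2), c(0, 0, 2, 4), theta = 0),
               "positive")
})

test_that("SIoU composes its terms and is zero for a perfect match", {
  expect_equal(siou_loss(c(0, 0, 2, 2), c(0, 0, 2, 2))$loss, 0)
  # hand-derived composite values, re-derived by the scalar oracle
  o1 <- siou_scalar_oracle(c(0, 0, 2, 2), c(2, 0, 4, 2))
  expect_equal(o1$loss, 1.196735, tolerance = 1e-5)
  expect_equal(siou_loss(c(0, 0, 2, 2), c(2, 0, 4, 2))$loss, o1$loss,
               tolerance = 1e-9)
  o2 <- siou_scalar_oracle(c(0, 0, 2, 2), c(0, 0, 4, 4))
  expect_equal(o2$loss, 0.834555, tolerance = 1e-5)
  r2 <- siou_loss(c(0, 0, 2, 2), c(0, 0, 4, 4))
  expect_equal(r2$loss, o2$loss, tolerance = 1e-9)
  expect_equal(r2$iou, 0.25)
  expect_equal(r2$lambda_angle, 1, tolerance = 1e-12)
  expect_equal(r2$gamma, 1, tolerance = 1e-12)
})

test_that("SIoU terms match the scalar oracle and stay in their ranges", {
  set.seed(11)
  for (i in 1:50) {
    g <- as.numeric(random_boxes(1, 20)); p <- as.numeric(random_boxes(1, 20))
    r <- siou_loss(g, p)
    o <- siou_scalar_oracle(g, p)
    expect_equal(r$loss, o$loss, tolerance = 1e-10)
    expect_equal(r$lambda_angle, o$lambda, tolerance = 1e-10)
    expect_equal(r$delta, o$delta, tolerance = 1e-10)
    expect_equal(r$omega, o$omega, tolerance = 1e-10)
    expect_true(r$loss >= 0 && r$loss < 3)
    expect_true(r$gamma >= 1 && r$gamma <= 2)
    expect_true(r$delta >= 0 && r$delta < 2)
    expect_true(r$omega >= 0 && r$omega < 2)
  }
})

test_that("SIoU terms are invariant to joint translation and uniform scaling", {
  set.seed(21)
  n <- 200
  g <- random_boxes(n); p <- random_boxes(n)
  base <- siou_loss(g, p)
  shift <- cbind(rnorm(n, sd = 30), rnorm(n, sd = 30))
  tg <- g + shift[, c(1, 2, 1, 2)]
  tp <- p + shift[, c(1, 2, 1, 2)]
  moved <- siou_loss(tg, tp)
  expect_equal(moved$loss, base$loss, tolerance = 1e-9)
  expect_equal(moved$lambda_angle, base$lambda_angle, tolerance = 1e-9)
  s <- runif(n, 0.1, 10)
  scaled <- siou_loss(g * s, p * s)
  expect_equal(scaled$loss, base$loss, tolerance = 1e-9)
  expect_equal(scaled$delta, base$delta, tolerance = 1e-9)
  expect_equal(scaled$omega, base$omega, tolerance = 1e-9)
})

test_that("SIoU grows with axis-aligned separation once boxes are disjoint", {
  d <- seq(2, 40, by = 0.5)
  loss <- vapply(d, function(dx) {
    siou_loss(c(0, 0, 2, 2), c(dx, 0, dx + 2, 2))$loss
  }, numeric(1))
  expect_true(all(diff(loss) >= -1e-12))
})

test_that("CIoU is zero on identity, penalises distance, matches a reference", {
  expect_equal(ciou_loss(c(0, 0, 2, 2), c(0, 0, 2, 2)), 0)
  # disjoint equal shapes: loss strictly exceeds 1 - IoU = 1
  expect_gt(ciou_loss(c(0, 0, 2, 2), c(10, 0, 12, 2)), 1)
  set.seed(31)
  for (i in 1:50) {
    g <- as.numeric(random_boxes(1, 20)); p <- as.numeric(random_boxes(1, 20))
    expect_equal(ciou_loss(g, p), ciou_scalar_oracle(g, p), tolerance = 1e-6)
  }
})

test_that("box representation round-trips losslessly", {
  set.seed(41)
  b <- random_boxes(100)
  expect_equal(unname(cxcywh_to_xyxy(xyxy_to_cxcywh(b))), unname(b),
               tolerance = 1e-12)
})
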