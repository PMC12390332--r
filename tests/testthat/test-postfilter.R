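test_that("NMS keeps the best of overlapping same-class boxes", {
  d <- detections(c(0, 1), c(0, 1), c(10, 11), c(10, 11), c(0.9, 0.8),
                  c("CB", "CB"))
  out <- nms(d, 0.45)
  expect_equal(nrow(out), 1L)
  expect_equal(out$conf, 0.9)
  # disjoint same-class boxes both survive
  d2 <- detections(c(0, 50), c(0, 50), c(10, 60), c(10, 60), c(0.9, 0.8),
                   c("CB", "CB"))
  expect_equal(nrow(nms(d2, 0.45)), 2L)
  # different classes never suppress each other
  d3 <- detections(c(0, 1), c(0, 1), c(10, 11), c(10, 11), c(0.9, 0.8),
                   c("CB", "BM"))
  expect_equal(nrow(nms(d3, 0.45)), 2L)
  expect_error(nms(d3, 1.5), "iou_threshold")
})

test_that("NMS equals the exhaustive reference on random jittered stacks", {
  set.seed(51)
  for (rep in 1:25) {
    n <- sample(2:50, 1)
    base <- random_boxes(max(2, n %/% 3), 60)
    pick <- sample(nrow(base), n, replace = TRUE)
    jit <- matrix(rnorm(4 * n, sd = 2), n)
    b <- base[pick, , drop = FALSE] + jit
    b <- cbind(pmin(b[, 1], b[, 3]), pmin(b[, 2], b[, 4]),
               pmax(b[, 1], b[, 3]) + 0.1, pmax(b[, 2], b[, 4]) + 0.1)
    d <- detections(b[, 1], b[, 2], b[, 3], b[, 4], conf = runif(n),
                    cls = sample(0:3, n, replace = TRUE))
    thr <- runif(1, 0.2, 0.7)
    got <- nms(d, thr)
    ref <- nms_reference(d, thr)
    expect_equal(got[, 1:6], ref[, 1:6], ignore_attr = TRUE)
  }
})

test_that("plane filter reproduces the worked TLVAP trace", {
  out <- filter_detections(tlvap_fixture(), "TLVAP")
  expect_equal(out$name, c("CB", "BM", "CP", "CP"))
  expect_equal(out$conf, c(0.95, 0.7, 0.9, 0.8))
  expect_equal(out$cls, c(0L, 1L, 2L, 2L))  # sorted ascending by class
})

test_that("plane filter confidence gate is strictly greater than 0.5", {
  d <- detections(c(0, 20), c(0, 20), c(10, 30), c(10, 30), c(0.45, 0.5),
                  c("CB", "BM"))
  expect_equal(nrow(filter_detections(d, "TLVAP")), 0L)
  d2 <- detections(0, 0, 10, 10, 0.500001, "CB")
  expect_equal(nrow(filter_detections(d2, "TLVAP")), 1L)
  expect_equal(nrow(filter_detections(empty_detections(), "MSP")), 0L)
  expect_error(filter_detections(d, "AXIAL"), "TLVAP")
})

test_that("plane filter satisfies its invariants on random inputs", {
  set.seed(61)
  for (rep in 1:30) {
    plane <- sample(fbstr_planes(), 1)
    d <- random_detections(sample(1:40, 1))
    out <- filter_detections(d, plane)
    # idempotence
    expect_equal(filter_detections(out, plane), out)
    # subset of the input records (never fabricates)
    if (nrow(out)) {
      key <- function(x) paste(x$x1, x$y1, x$x2, x$y2, x$conf, x$cls)
      expect_true(all(key(out) %in% key(d)))
    }
    # cardinality: <= 1 per class, except CP <= 2; classes within the prior
    tab <- table(out$name)
    expect_true(all(tab[names(tab) != "CP"] <= 1))
    expect_true(all(tab[names(tab) == "CP"] <= 2))
    expect_true(all(out$name %in% plane_priors()[[plane]]))
    expect_true(all(out$conf > 0.5))
    # sorted ascending by class, CP descending by confidence
    expect_true(!is.unsorted(out$cls))
    cp <- out$conf[out$name == "CP"]
    expect_true(!is.unsorted(rev(cp)))
  }
})

test_that("plane inference prefers exact and distinctive class sets", {
  d <- function(cls) {
    n <- length(cls)
    detections(seq_len(n) * 20, seq_len(n) * 20, seq_len(n) * 20 + 10,
               seq_len(n) * 20 + 10, rep(0.9, n), cls)
  }
  expect_equal(infer_plane(d(c("CB", "BM", "CP"))), "TLVAP")
  expect_equal(infer_plane(d(c("CB", "CM", "B", "FV", "NB"))), "MSP")
  # a bare CB ties every plane; smallest expected set, then order -> TLVAP
  expect_equal(infer_plane(d("CB")), "TLVAP")
  expect_error(infer_plane(empty_detections()), "zero detections")
  # exhaustive scoring check on random class subsets
  set.seed(71)
  for (rep in 1:20) {
    cls <- sample(fbstr_classes(), sample(1:6, 1))
    got <- infer_plane(d(cls))
    score <- vapply(fbstr_planes(), function(p) {
      sum(cls %in% plane_priors()[[p]]) - sum(!cls %in% plane_priors()[[p]])
    }, numeric(1))
    best <- score[got]
    expect_true(all(score <= best))
    smaller <- fbstr_planes()[score == best &
      lengths(plane_priors()) < length(plane_priors()[[got]])]
    expect_length(smaller, 0)
  }
})

test_that("YOLO labels round-trip through write and read", {
  set.seed(81)
  d <- random_detections(12, lim = 600)
  f <- withr::local_tempfile(fileext = ".txt")
  write_yolo_labels(d, f, 640, 640, with_conf = TRUE)
  back <- read_yolo_labels(f, 640, 640)
  expect_equal(back$cls, d$cls)
  for (col in c("x1", "y1", "x2", "y2")) {
    expect_equal(back[[col]], d[[col]], tolerance = 1e-2)
  }
  expect_equal(back$conf, d$conf, tolerance = 1e-5)
  # missing file is an empty detection set
  expect_equal(nrow(read_yolo_labels(file.path(tempdir(), "nope.txt"),
                                     64, 64)), 0L)
})

test_that("COCO-style JSON round-trips detections by image", {
  set.seed(91)
  dl <- list(img1 = random_detections(5), img2 = random_detections(3))
  f <- withr::local_tempfile(fileext = ".json")
  write_coco_json(dl, f)
  back <- read_coco_json(f)
  expect_setequal(names(back), names(dl))
  expect_equal(back$img1[, 1:6], dl$img1[, 1:6], tolerance = 1e-12)
})
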