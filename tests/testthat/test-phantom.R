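test_that("phantoms are deterministic and plane-consistent", {
  s <- phantom_spec("TLVAP", image_size = 160, seed = 7)
  p1 <- generate_phantom(s); p2 <- generate_phantom(s)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$labels, p2$labels)
  expect_equal(sort(p1$labels$name), c("BM", "CB", "CP", "CP"))
  # different seed changes the rendering
  p3 <- generate_phantom(phantom_spec("TLVAP", image_size = 160, seed = 8))
  expect_false(identical(p1$image, p3$image))
})

test_that("each plane emits exactly its expected class multiset", {
  for (plane in fbstr_planes()) {
    p <- generate_phantom(phantom_spec(plane, image_size = 160,
                                       seed = 3))
    want <- plane_priors()[[plane]]
    if (plane == "TLVAP") want <- c(want, "CP")
    expect_equal(sort(p$labels$name), sort(want), label = plane)
  }
  # MSP: eight labels covering its full set regardless of seed
  for (seed in c(1, 9, 23)) {
    p <- generate_phantom(phantom_spec("MSP", image_size = 160, seed = seed))
    expect_equal(nrow(p$labels), 8L)
    expect_setequal(p$labels$name, plane_priors()$MSP)
  }
})

test_that("labels are valid boxes inside the image with real contrast", {
  for (plane in fbstr_planes()) {
    p <- generate_phantom(phantom_spec(plane, image_size = 192, seed = 5))
    L <- p$labels
    expect_true(all(L$x1 >= 0 & L$y1 >= 0 & L$x2 <= 192 & L$y2 <= 192))
    expect_true(all(L$x2 - L$x1 > 1 & L$y2 - L$y1 > 1))
    expect_true(all(p$image >= 0 & p$image <= 1))
    expect_true(all(phantom_contrast(p) > 0.03))
  }
})

test_that("dataset generation writes a reproducible YOLO layout", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  m1 <- generate_dataset(dir1, n_per_plane = 2, seed = 4, image_size = 96)
  m2 <- generate_dataset(dir2, n_per_plane = 2, seed = 4, image_size = 96)
  imgs <- list.files(dir1, pattern = "\\.png$", recursive = TRUE)
  labs <- list.files(dir1, pattern = "\\.txt$", recursive = TRUE)
  expect_length(imgs, 8L)
  expect_length(labs, 8L)
  expect_equal(length(unlist(m1$train)) + length(unlist(m1$val)), 8L)
  expect_true(file.exists(file.path(dir1, "manifest.yaml")))
  # regeneration with the same seed is bit-identical
  for (f in imgs) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6), label = f)
  }
  for (f in labs) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  # manifest round-trip and total labels for one image per plane: 4+4+4+8
  mm <- read_manifest(file.path(dir1, "manifest.yaml"))
  expect_equal(unlist(mm$names), fbstr_classes())
  n1 <- generate_dataset(withr::local_tempdir(), n_per_plane = 1, seed = 2,
                         image_size = 96)
  dir3 <- dirname(n1$path)
  lines <- sum(vapply(list.files(file.path(dir3, "labels"), recursive = TRUE,
                                 full.names = TRUE),
                      function(f) length(readLines(f)), integer(1)))
  expect_equal(lines, 20L)
})

test_that("YOLO label round-trip through the dataset layout is exact", {
  dir <- withr::local_tempdir()
  generate_dataset(dir, n_per_plane = 1, seed = 6, image_size = 128)
  m <- read_manifest(file.path(dir, "manifest.yaml"))
  rel <- unlist(c(m$train, m$val))[1]
  p <- generate_phantom(phantom_spec(
    m$planes[[sub("\\.png$", "", basename(rel))]], image_size = 128,
    seed = fbstrnet:::derive_seed(6, m$planes[[sub("\\.png$", "",
                                                   basename(rel))]], 1)))
  back <- read_yolo_labels(file.path(dir, fbstrnet:::label_path(rel)),
                           128, 128)
  expect_equal(back$cls, p$labels$cls)
  for (col in c("x1", "y1", "x2", "y2")) {
    expect_equal(back[[col]], p$labels[[col]], tolerance = 1e-2)
  }
})

test_that("structure placement outside the fan is an error", {
  s <- phantom_spec("TLVAP", image_size = 160, seed = 1,
                    fan_half_angle = 3)  # fan too narrow to hold the skull
  expect_error(generate_phantom(s), "outside the fan")
})
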