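# Augmentation must keep image and annotation consistent: photometric ops
# change pixels only, geometric ops transform both identically.

photometric_off <- function(...) {
  ph <- list(hue = list(p = 0, range = 0.1), saturation = list(p = 0, range = 0.1),
             noise = list(p = 0, sd = 10), blur = list(p = 0, sigma = 2),
             invert = list(p = 0), contrast = list(p = 0, range = c(0.8, 1.2)),
             value = list(p = 0, range = 20))
  utils::modifyList(ph, list(...))
}

test_that("a horizontal flip reflects x coordinates exactly", {
  set.seed(31)
  img <- random_image(20, 30)
  ps <- point_set("img", 30, 20, cbind(c(0, 7.5, 29), c(1, 10, 19)))
  cfg <- augment_config(rotation_range = 0, p_rotate = 0, flip = "horizontal",
                        p_flip = 1, photometric = photometric_off())
  out <- augment_pair(img, ps, cfg, seed = 1)
  expect_equal(out$ps$points[, "x"], 29 - ps$points[, "x"])
  expect_equal(out$ps$points[, "y"], ps$points[, "y"])
  expect_equal(out$img$pixels[, 30:1, ], img$pixels)
})

test_that("two horizontal flips restore the original exactly", {
  set.seed(32)
  img <- random_image(16, 16)
  ps <- random_point_set(10, 16, 16)
  cfg <- augment_config(rotation_range = 0, p_rotate = 0, flip = "horizontal",
                        p_flip = 1, photometric = photometric_off())
  once <- augment_pair(img, ps, cfg, seed = 2)
  twice <- augment_pair(once$img, once$ps, cfg, seed = 3)
  expect_equal(twice$ps$points, ps$points)
  expect_equal(twice$img$pixels, img$pixels)
})

test_that("photometric-only variants keep the annotation untouched", {
  set.seed(33)
  img <- random_image(24, 24)
  ps <- random_point_set(15, 24, 24)
  cfg <- augment_config(rotation_range = 0, p_rotate = 0, flip = "horizontal",
                        p_flip = 0,
                        photometric = photometric_off(noise = list(p = 1, sd = 10),
                                                      contrast = list(p = 1, range = c(0.8, 1.2))))
  out <- augment_pair(img, ps, cfg, seed = 4)
  expect_identical(out$ps$points, ps$points)
  expect_false(identical(out$img$pixels, img$pixels))
})

test_that("point rotation matches the 2-D rotation-matrix oracle", {
  rot <- sorghumnet:::rotate_points_xy
  # 90 degrees about the centre of a 21 x 21 image: corner (0, 0) -> (20, 0)
  pts <- cbind(x = c(0, 20, 10), y = c(0, 0, 10))
  got <- rot(pts, pi / 2, 21, 21)
  theta <- pi / 2; cx <- 10; cy <- 10
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  oracle <- t(R %*% t(sweep(pts, 2, c(cx, cy)))) + rep(c(cx, cy), each = 3)
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
  expect_equal(unname(got[1, ]), c(20, 0), tolerance = 1e-12)
})

test_that("rotating pixels and points stays consistent", {
  # put a single bright pixel in an otherwise black image; after rotation the
  # transformed annotation must land on the bright pixel
  px <- array(0L, c(41, 41, 3)); px[31, 11, ] <- 255L  # row 31, col 11
  img <- image_record("dot", px)
  ps <- point_set("dot", 41, 41, cbind(10, 30))       # 0-based (x=col, y=row)
  cfg <- augment_config(rotation_range = 25, p_rotate = 1, flip = "horizontal",
                        p_flip = 0, photometric = photometric_off())
  out <- augment_pair(img, ps, cfg, seed = 7)
  hit <- which(out$img$pixels[, , 1] > 0, arr.ind = TRUE)
  pt <- out$ps$points
  expect_equal(nrow(pt), 1)
  # nearest-neighbour resampling quantizes to the pixel grid
  expect_lt(abs(hit[1, "row"] - 1 - pt[1, "y"]), 1.5)
  expect_lt(abs(hit[1, "col"] - 1 - pt[1, "x"]), 1.5)
})

test_that("augmentation is deterministic under a fixed seed", {
  set.seed(34)
  img <- random_image(20, 20)
  ps <- random_point_set(8, 20, 20)
  cfg <- augment_config()
  a <- augment_pair(img, ps, cfg, seed = 99)
  b <- augment_pair(img, ps, cfg, seed = 99)
  expect_identical(a$img$pixels, b$img$pixels)
  expect_identical(a$ps$points, b$ps$points)
})

make_tiny_dataset <- function(d, n_sources = 2) {
  rows <- lapply(seq_len(n_sources), function(i) {
    id <- sprintf("src%d", i)
    set.seed(100 + i)
    img <- random_image(16, 16, id = id)
    ps <- random_point_set(6, 16, 16, id = id)
    png::writePNG(img$pixels / 255, file.path(d, paste0(id, ".png")))
    write_point_annotations(ps, file.path(d, paste0(id, ".json")))
    data.frame(image_id = id, image = paste0(id, ".png"),
               annotation = paste0(id, ".json"), mask = NA, side = "A",
               panicle_id = id, observed_total = 50, stringsAsFactors = FALSE)
  })
  write_manifest(do.call(rbind, rows), file.path(d, "manifest.csv"))
  read_manifest(file.path(d, "manifest.csv"))
}

test_that("dataset expansion yields variants-per-image records, originals dropped", {
  d <- withr::local_tempdir()
  manifest <- make_tiny_dataset(d, n_sources = 2)
  cfg <- augment_config(variants_per_image = 3, seed = 5)
  out <- expand_dataset(manifest, cfg, file.path(d, "aug"))
  expect_equal(nrow(out), 2 * 3)
  expect_false(any(manifest$image_id %in% out$image_id))
  expect_true(all(file.exists(out$image)))
  expect_true(all(file.exists(out$annotation)))
  expect_equal(out$source_id, rep(manifest$image_id, each = 3))

  # single source, single variant
  out1 <- expand_dataset(manifest[1, ], augment_config(variants_per_image = 1),
                         file.path(d, "aug1"))
  expect_equal(nrow(out1), 1)
})

test_that("dataset expansion is byte-identical under a fixed seed", {
  d <- withr::local_tempdir()
  manifest <- make_tiny_dataset(d)
  cfg <- augment_config(variants_per_image = 2, seed = 17)
  o1 <- expand_dataset(manifest, cfg, file.path(d, "a1"))
  o2 <- expand_dataset(manifest, cfg, file.path(d, "a2"))
  expect_identical(md5_of(o1$image), md5_of(o2$image))
  expect_identical(md5_of(o1$annotation), md5_of(o2$annotation))
})

test_that("expansion requires annotations", {
  d <- withr::local_tempdir()
  manifest <- make_tiny_dataset(d)
  manifest$annotation[2] <- NA
  expect_error(expand_dataset(manifest, augment_config(), file.path(d, "x")),
               "src2")
})

test_that("geometric augmentation composes with density-map regeneration", {
  set.seed(36)
  img <- random_image(64, 64)
  ps <- random_point_set(40, 64, 64)
  cfg <- augment_config(rotation_range = 25, p_rotate = 1, p_flip = 0.5,
                        photometric = photometric_off())
  for (s in 1:5) {
    out <- augment_pair(img, ps, cfg, seed = s)
    dm <- build_density_map(out$ps, density_map_config(c(64, 64), sigma = 3))
    expect_equal(count_from_density(dm), nrow(out$ps$points), tolerance = 1e-6)
    expect_lte(nrow(out$ps$points), nrow(ps$points))
  }
})

test_that("train/test splits partition the data at both levels", {
  fake <- data.frame(image_id = sprintf("r%03d", 1:40),
                     source_id = rep(sprintf("s%02d", 1:10), each = 4))
  # record level: 4,800-style arithmetic at small scale
  sp <- split_dataset(fake, 0.8, "record", seed = 1)
  expect_equal(nrow(sp$train), 32)
  expect_equal(nrow(sp$test), 8)
  for (seed in 1:5) {
    sp2 <- split_dataset(fake, 0.7, "record", seed = seed)
    expect_length(intersect(sp2$train$image_id, sp2$test$image_id), 0)
    expect_setequal(c(sp2$train$image_id, sp2$test$image_id), fake$image_id)
  }
  # source level keeps augmented twins together
  sps <- split_dataset(fake, 0.8, "source", seed = 2)
  expect_equal(length(unique(sps$train$source_id)), 8)
  expect_equal(length(unique(sps$test$source_id)), 2)
  expect_length(intersect(sps$train$source_id, sps$test$source_id), 0)

  one <- fake[fake$source_id == "s01", ]
  expect_error(split_dataset(one, 0.8, "source", seed = 1), "2 groups")
  expect_error(split_dataset(fake, 1.2, "record"), "fraction")
})
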