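# Whole-panicle estimation: masking, three-patch cutting, count aggregation,
# polynomial calibration and the two-side symmetry analysis.

test_that("apply_mask zeroes background and preserves foreground exactly", {
  set.seed(61)
  px <- array(sample.int(256, 12 * 10 * 3, TRUE) - 1L, c(12, 10, 3))

  ones <- image_record("a", px, matrix(1, 12, 10))
  expect_identical(apply_mask(ones)$pixels, px)

  zeros <- image_record("b", px, matrix(0, 12, 10))
  expect_true(all(apply_mask(zeros)$pixels == 0))

  chk <- matrix((outer(1:12, 1:10, "+") %% 2), 12, 10)
  out <- apply_mask(image_record("c", px, chk))$pixels
  for (ch in 1:3) {
    expect_identical(out[, , ch][chk == 1], px[, , ch][chk == 1])
    expect_true(all(out[, , ch][chk == 0] == 0))
  }

  expect_error(apply_mask(image_record("d", px)), "mask")
})

test_that("three-patch cutting gives floor heights with remainder at the bottom", {
  img300 <- random_image(300, 10)
  expect_equal(split_patches(img300, c(8, 8))$heights, c(100, 100, 100))
  img301 <- random_image(301, 10)
  expect_equal(split_patches(img301, c(8, 8))$heights, c(100, 100, 101))
  expect_error(split_patches(random_image(2, 10)), "height")
})

test_that("pre-resize patches reassemble the source image bit-for-bit", {
  set.seed(62)
  for (H in c(3, 17, 100, 301)) {
    img <- random_image(H, 8)
    ps <- split_patches(img, c(8, 8))
    expect_equal(sum(ps$heights), H)
    glued <- do.call(abind_rows <- function(...) {
      arrays <- list(...)
      out <- array(0L, c(sum(sapply(arrays, function(a) dim(a)[1])),
                         dim(arrays[[1]])[2], 3))
      at <- 1
      for (a in arrays) {
        out[at:(at + dim(a)[1] - 1), , ] <- a
        at <- at + dim(a)[1]
      }
      out
    }, ps$raw)
    expect_identical(glued, img$pixels)
  }
})

test_that("patch annotations partition the points with shifted coordinates", {
  ps <- point_set("a", 10, 300, cbind(c(1, 2, 3), c(0, 150, 299)))
  parts <- split_patch_annotations(ps, c(100, 100, 100))
  expect_equal(nrow(parts[[1]]$points), 1)
  expect_equal(nrow(parts[[2]]$points), 1)
  expect_equal(nrow(parts[[3]]$points), 1)
  expect_equal(unname(parts[[2]]$points[1, "y"]), 50)
  expect_equal(unname(parts[[3]]$points[1, "y"]), 99)
  expect_equal(sum(sapply(parts, function(p) nrow(p$points))), 3)
})

test_that("a panicle side count is the sum of its three patch integrals", {
  set.seed(63)
  H <- 96; W <- 64
  mask <- matrix(0L, H, W); mask[10:86, 16:48] <- 1L
  img <- random_image(H, W, mask = mask)
  net <- build_network(tiny_arch(16L), seed = 11)
  est <- count_panicle_side(img, net, side = "A")
  expect_length(est$per_patch, 3)
  expect_identical(est$total_visible, sum(est$per_patch))
  expect_true(all(est$per_patch >= 0))
  expect_equal(est$side, "A")
})

test_that("a noiseless quadratic is recovered exactly", {
  x <- seq(10, 200, length.out = 20)
  records <- data.frame(total_visible = x,
                        observed_total = 2 * x^2 + 3 * x + 100)
  fit <- fit_panicle_model(records, degree = 2, seed = 42)
  expect_equal(unname(coef(fit)), c(100, 3, 2), tolerance = 1e-6)
  expect_equal(fit$fit_metrics$r2, 1, tolerance = 1e-9)
  expect_equal(fit$degree, 2)
})

test_that("noiseless polynomials of degree up to 4 are recovered exactly", {
  set.seed(64)
  x <- seq(1, 30, length.out = 40)
  for (deg in 1:4) {
    cf <- round(runif(deg + 1, -2, 2), 2)
    y <- outer(x, 0:deg, "^") %*% cf
    fit <- fit_panicle_model(data.frame(total_visible = x, observed_total = y),
                             degree = deg, seed = deg)
    expect_equal(unname(coef(fit)), as.vector(cf), tolerance = 1e-6)
  }
})

test_that("degree 0 fits the training mean and degenerate designs fail", {
  records <- data.frame(total_visible = 1:10, observed_total = (1:10) * 7)
  fit <- fit_panicle_model(records, degree = 0, seed = 3)
  expect_equal(unname(coef(fit)), mean(fit$train_data$y))

  same_x <- data.frame(total_visible = rep(5, 10), observed_total = 1:10)
  expect_error(fit_panicle_model(same_x, degree = 1, seed = 1), "degenerate")
  expect_error(fit_panicle_model(records[1:3, ], degree = 2, seed = 1),
               "training points")
})

test_that("polynomial prediction clips at zero and matches naive evaluation", {
  model <- structure(list(degree = 2L, coefficients = c(100, 3, 2)),
                     class = "panicle_poly")
  expect_equal(predict_total(model, 10), 330)
  expect_equal(predict_total(model, 0), 100)

  neg <- structure(list(degree = 1L, coefficients = c(-50, 1)),
                   class = "panicle_poly")
  expect_equal(predict_total(neg, 10), 0)
  expect_equal(predict_total(neg, 100), 50)

  set.seed(65)
  cf <- c(-3, 0.5, 0.02, -1e-4)
  m <- structure(list(degree = 3L, coefficients = cf), class = "panicle_poly")
  x <- runif(1000, 0, 100)
  naive <- pmax(0, cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3)
  expect_equal(predict_total(m, x), naive, tolerance = 1e-9)
})

test_that("the symmetry report compares the two sides with the metric suite", {
  same <- data.frame(panicle_id = c("p1", "p2"),
                     visible_A = c(100, 200), visible_B = c(100, 200))
  s0 <- symmetry_report(same)
  expect_equal(s0$mae, 0); expect_equal(s0$rmse, 0)

  df <- data.frame(panicle_id = c("p1", "p2"),
                   visible_A = c(100, 200), visible_B = c(110, 190))
  s <- symmetry_report(df)
  expect_equal(s$mae, 10); expect_equal(s$mse, 100); expect_equal(s$rmse, 10)

  ref <- evaluate_counts(df$visible_A, df$visible_B)
  expect_equal(s$mae, ref$mae); expect_equal(s$rmse, ref$rmse)

  recs <- list(panicle_record("p1", 100, 110, 900),
               panicle_record("p2", 200, 190, 1500))
  s2 <- symmetry_report(recs)
  expect_equal(s2$rmse, 10)

  df$visible_B[2] <- NA
  expect_error(symmetry_report(df), "p2")
})

test_that("calibration models persist as JSON", {
  d <- withr::local_tempdir()
  x <- seq(10, 100, length.out = 20)
  fit <- fit_panicle_model(data.frame(total_visible = x,
                                      observed_total = x * 2 + 5),
                           degree = 1, seed = 2)
  path <- file.path(d, "model.json")
  write_panicle_model(fit, path)
  back <- read_panicle_model(path)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(predict_total(back, 55), predict_total(fit, 55))
})
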