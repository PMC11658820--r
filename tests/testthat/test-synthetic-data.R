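# The scene generator must deliver exactly known ground truth: |points| ==
# true_visible, every point inside the mask, and paired sides sharing a
# machine-counted total.

small_cfg <- function(...) {
  # a reduced canvas with proportionally reduced totals so scenes stay cheap
  scene_config(canvas = c(192L, 96L), grain_diameter = 6, clutter = 0.3,
               total_range = c(100L, 500L), total_mean = 280, total_sd = 80,
               ...)
}

test_that("scenes carry exact annotations inside the panicle mask", {
  sc <- generate_scene(small_cfg(), "pan0001", "A", visible_count = 60,
                       seed = 71)
  expect_s3_class(sc$image, "image_record")
  expect_equal(nrow(sc$points$points), 60)
  expect_identical(sc$true_visible, 60L)
  pts <- sc$points$points
  inside <- sc$image$mask[cbind(round(pts[, "y"]) + 1, round(pts[, "x"]) + 1)]
  expect_true(all(inside > 0))
})

test_that("a zero-grain scene still has a mask and an empty annotation", {
  sc <- generate_scene(small_cfg(), "pan0002", "A", visible_count = 0,
                       seed = 72)
  expect_equal(nrow(sc$points$points), 0)
  expect_gt(sum(sc$image$mask), 0)
})

test_that("scene generation is deterministic and seeds differ", {
  a <- generate_scene(small_cfg(), "p", "A", visible_count = 40, seed = 73)
  b <- generate_scene(small_cfg(), "p", "A", visible_count = 40, seed = 73)
  c <- generate_scene(small_cfg(), "p", "A", visible_count = 40, seed = 74)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$points$points, b$points$points)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("an infeasible grain count is rejected with advice", {
  expect_error(generate_scene(small_cfg(), "p", "A", visible_count = 100000,
                              seed = 75),
               "larger canvas")
})

test_that("ground-truth density maps integrate to the visible count", {
  sc <- generate_scene(small_cfg(), "p", "A", visible_count = 55, seed = 76)
  dm <- build_density_map(rescale_points(sc$points, c(112, 112)),
                          density_map_config(c(112, 112), sigma = 5))
  expect_equal(count_from_density(dm), 55, tolerance = 1e-6)
})

test_that("sampled totals match the configured truncated normal", {
  cfg <- scene_config()
  totals <- sample_panicle_totals(cfg, 1000, seed = 77)
  expect_true(all(totals >= 672 & totals <= 4156))
  expect_lt(abs(mean(totals) - 2363) / 2363, 0.05)
})

test_that("zero asymmetry makes the two sides equal; spread grows with sigma", {
  cfg0 <- scene_config(asymmetry = 0)
  r0 <- sample_visibility_records(cfg0, 50, seed = 78)
  expect_identical(r0$visible_A, r0$visible_B)

  gaps <- sapply(c(0.05, 0.15, 0.4), function(s) {
    r <- sample_visibility_records(scene_config(asymmetry = s), 200, seed = 79)
    mean(abs(r$visible_A - r$visible_B))
  })
  expect_true(all(diff(gaps) > 0))
})

test_that("visibility records obey the quadratic relation", {
  cfg <- scene_config(sigma_rel = 0, asymmetry = 0)
  r <- sample_visibility_records(cfg, 50, seed = 80)
  rel <- cfg$relation
  expect_equal(rel["a"] * r$visible_mean^2 + rel["b"] * r$visible_mean +
                 rel["c"], r$observed_total, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(r$observed_total >= r$visible_mean))
})

test_that("noiseless generated records recover the relation exactly", {
  cfg <- scene_config(sigma_rel = 0, asymmetry = 0)
  r <- sample_visibility_records(cfg, 60, seed = 81)
  fit <- fit_panicle_model(data.frame(total_visible = r$visible_mean,
                                      observed_total = r$observed_total),
                           degree = 2, seed = 5)
  expect_equal(unname(coef(fit)), unname(cfg$relation[c("c", "b", "a")]),
               tolerance = 1e-6)
})

test_that("relation coefficients are estimated consistently as n grows", {
  # at the default 5% relation noise the quadratic design over the observed
  # total range is strongly collinear, so consistency shows up at large n
  cfg <- scene_config()
  r <- sample_visibility_records(cfg, 20000, seed = 82)
  fit <- fit_panicle_model(data.frame(total_visible = r$visible_mean,
                                      observed_total = r$observed_total),
                           degree = 2, train_fraction = 0.9, seed = 6)
  rel_err <- abs(coef(fit) - cfg$relation[c("c", "b", "a")]) /
    abs(cfg$relation[c("c", "b", "a")])
  expect_true(all(rel_err < 0.10))
})

test_that("benchmarks write a complete, deterministic, round-trippable dataset", {
  d <- withr::local_tempdir()
  cfg <- small_cfg()
  m <- generate_benchmark(cfg, 2, file.path(d, "b1"), seed = 83)
  expect_equal(nrow(m), 4)
  expect_setequal(m$side, c("A", "B"))
  expect_true(all(file.exists(m$image)))
  expect_true(all(file.exists(m$mask)))
  expect_true(all(file.exists(m$annotation)))
  expect_equal(m$observed_total[1], m$observed_total[2])

  back <- read_manifest(file.path(d, "b1", "manifest.csv"))
  expect_equal(nrow(back), 4)
  ps <- read_point_annotations(back$annotation[1])
  expect_gt(nrow(ps$points), 0)

  m2 <- generate_benchmark(cfg, 2, file.path(d, "b2"), seed = 83)
  expect_identical(unname(tools::md5sum(m$image)),
                   unname(tools::md5sum(m2$image)))
  expect_identical(unname(tools::md5sum(m$annotation)),
                   unname(tools::md5sum(m2$annotation)))
})

test_that("paired scenes share the total and differ in pixels", {
  pair <- generate_panicle_pair(small_cfg(), "pan0009", seed = 84)
  expect_equal(pair$A$true_total, pair$B$true_total)
  expect_equal(pair$A$true_total, pair$observed_total)
  expect_false(identical(pair$A$image$pixels, pair$B$image$pixels))
})
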