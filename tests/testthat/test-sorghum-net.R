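# Architecture construction and exact parameter accounting.

# Independent layer-by-layer arithmetic oracle for the parameter count:
# per conv k^2*c_in*c_out + c_out; per batch-norm channel 2 trainable
# (gamma, beta) + 2 statistics (running mean, variance); 1x1 head included.
param_oracle <- function(columns, c_in = 3, concat = NULL, head = 2,
                         with_stats = TRUE) {
  total <- 0
  last <- integer(0)
  for (col in columns) {
    k <- col$k
    cin <- c_in
    for (cout in col$dims) {
      total <- total + k^2 * cin * cout + cout          # conv weights + bias
      total <- total + (if (with_stats) 4 else 2) * cout # batch norm
      cin <- cout
    }
    last <- c(last, cin)
  }
  concat <- concat %||% sum(last)
  total + concat * head + head                           # 1x1 head
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the default architecture counts 568K parameters", {
  net <- build_network(arch_config(), seed = 1)
  oracle <- param_oracle(list(list(k = 3, dims = c(80, 160, 80, 40)),
                              list(k = 5, dims = c(40, 80, 40, 20)),
                              list(k = 7, dims = c(20, 40, 20, 40))))
  got <- count_parameters(net, include_statistics = TRUE)
  expect_identical(got, as.integer(oracle))
  expect_identical(round(got / 1000), 568)
  # internal consistency with the per-layer report
  rep_ <- parameter_report(net)
  expect_identical(got, as.integer(sum(rep_$trainable) + sum(rep_$statistics)))
  # statistics toggle removes exactly the running mean/variance values
  expect_identical(got - count_parameters(net, include_statistics = FALSE),
                   as.integer(sum(rep_$statistics)))
})

test_that("the smallest network matches the hand parameter formula", {
  arch <- arch_config(input_size = c(8L, 8L, 3L),
                      columns = list(column_spec(3L, 1L, integer(0))),
                      head_channels = 1L)
  net <- build_network(arch)
  # conv: 3^2*3*1 + 1 = 28; bn: 2 + 2; head: 1*1 + 1 = 2
  expect_identical(count_parameters(net, TRUE), 34L)
  expect_identical(count_parameters(net, FALSE), 32L)
})

test_that("channel arithmetic: the default concatenation is 100 wide", {
  net <- build_network(arch_config())
  expect_identical(dim(net$params$head_W), c(100L, 2L))
})

test_that("the parameter count is invariant to the input spatial size", {
  n224 <- build_network(arch_config(input_size = c(224L, 224L, 3L)))
  n112 <- build_network(arch_config(input_size = c(112L, 112L, 3L)))
  expect_identical(count_parameters(n224), count_parameters(n112))
})

test_that("the forward pass maps (H, W, 3) to a non-negative (H, W) density", {
  net <- build_network(tiny_arch(16L), seed = 9)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  d <- predict_density(net, x)
  expect_equal(dim(d), c(16, 16))
  expect_true(all(is.finite(d)))
  expect_true(all(d >= 0))
  expect_gte(count_from_density(d), 0)

  zero <- predict_density(net, array(0, c(16, 16, 3)))
  expect_true(all(is.finite(zero)))

  expect_error(predict_density(net, array(0, c(15, 16, 3))), "divisible")
  expect_error(predict_density(net, matrix(0, 16, 16)), "H x W x 3")
})

test_that("predictions are deterministic for a fixed build seed", {
  set.seed(41)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  n1 <- build_network(tiny_arch(16L), seed = 123)
  n2 <- build_network(tiny_arch(16L), seed = 123)
  expect_identical(predict_density(n1, x), predict_density(n1, x))
  expect_identical(predict_density(n1, x), predict_density(n2, x))
  n3 <- build_network(tiny_arch(16L), seed = 124)
  expect_false(identical(predict_density(n1, x), predict_density(n3, x)))
})

test_that("inference preserves batch independence", {
  nf <- sorghumnet:::net_forward
  net <- build_network(tiny_arch(16L), seed = 5)
  set.seed(42)
  xa <- matrix(runif(256 * 3), 256, 3)
  xb <- matrix(runif(256 * 3), 256, 3)
  batch <- nf(net, rbind(xa, xb), 16, 16, nimg = 2)$out
  single <- rbind(nf(net, xa, 16, 16, nimg = 1)$out,
                  nf(net, xb, 16, 16, nimg = 1)$out)
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("bilinear upsampling is available and preserves shape", {
  arch <- arch_config(input_size = c(16L, 16L, 3L),
                      columns = list(column_spec(3L, c(4L, 4L))),
                      upsample_mode = "bilinear")
  net <- build_network(arch, seed = 2)
  d <- predict_density(net, array(runif(16 * 16 * 3), c(16, 16, 3)))
  expect_equal(dim(d), c(16, 16))
  expect_true(all(is.finite(d)))
})

test_that("invalid architectures are rejected at construction", {
  expect_error(column_spec(4L, c(8L, 8L)), "odd")
  expect_error(column_spec(3L, c(8L, 8L), pool_after = 3L), "range")
  expect_error(arch_config(columns = list(column_spec(3L, c(4L, 4L), 1:2),
                                          column_spec(5L, c(4L, 4L), 1L))),
               "same number")
  expect_error(arch_config(input_size = c(30L, 30L, 3L)), "divisible")
})

test_that("checkpoints round-trip with an architecture sidecar", {
  d <- withr::local_tempdir()
  net <- build_network(tiny_arch(16L), seed = 3)
  path <- file.path(d, "ckpt.rds")
  save_network(net, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_network(path)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(predict_density(net, x), predict_density(back, x))
  js <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(length(js$columns$kernel_size), 2)
})
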