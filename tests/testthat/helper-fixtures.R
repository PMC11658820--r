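# Small fixtures shared across the test files; everything is generated in
# code at test time.

random_point_set <- function(n, width = 224, height = 224, id = "img") {
  pts <- if (n > 0) {
    cbind(runif(n, 0, width - 1e-6), runif(n, 0, height - 1e-6))
  } else NULL
  point_set(id, width, height, pts)
}

random_image <- function(H = 32, W = 32, id = "img", mask = NULL) {
  px <- array(sample.int(256, H * W * 3, replace = TRUE) - 1L, c(H, W, 3))
  image_record(id, px, mask)
}

# a deliberately small two-column architecture for fast training tests
tiny_arch <- function(hw = 16L, head_channels = 2L,
                      final_activation = "relu") {
  arch_config(input_size = c(hw, hw, 3L),
              columns = list(column_spec(3L, c(4L, 6L, 4L, 3L)),
                             column_spec(5L, c(3L, 4L, 3L, 2L))),
              head_channels = head_channels,
              final_activation = final_activation)
}

# deterministic synthetic (image, density) pair at the tiny size
tiny_pair <- function(hw = 16L, n_points = 5L, seed = 1) {
  set.seed(seed)
  ps <- random_point_set(n_points, hw, hw)
  dm <- build_density_map(ps, density_map_config(c(hw, hw), sigma = 2))
  x <- array(runif(hw * hw * 3), c(hw, hw, 3))
  list(x = x, y = dm$values)
}

md5_of <- function(paths) unname(tools::md5sum(sort(paths)))
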