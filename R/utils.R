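# Shared numeric helpers: seeded evaluation, image resizing, Gaussian
# filtering with scipy-compatible boundary handling, HSV conversion.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards (same contract as stats::simulate).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed below 2^31 from a base seed and indices.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 1000003 + as.double(p)) %% 2147483647
  as.integer(s)
}

#' Resize an image array
#'
#' Bilinear (default) or nearest-neighbour resampling with half-pixel centre
#' alignment, the convention used by mainstream image libraries.
#'
#' @param px numeric matrix (H x W) or array (H x W x C).
#' @param out_h,out_w output height and width in pixels.
#' @param method `"bilinear"` or `"nearest"`.
#' @return resized matrix or array with the input's channel count.
#' @export
resize_image <- function(px, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  two_d <- length(dim(px)) == 2 || is.null(dim(px))
  if (is.null(dim(px))) fail_validation("resize_image: input has no dimensions")
  if (two_d) px <- array(px, c(dim(px), 1L))
  d <- dim(px); H <- d[1]; W <- d[2]; C <- d[3]
  if (out_h < 1 || out_w < 1) fail_validation("resize_image: output size must be positive")
  ys <- (seq_len(out_h) - 0.5) * (H / out_h) + 0.5
  xs <- (seq_len(out_w) - 0.5) * (W / out_w) + 0.5
  out <- array(0, c(out_h, out_w, C))
  if (method == "nearest") {
    yi <- pmin(pmax(round(ys), 1), H)
    xi <- pmin(pmax(round(xs), 1), W)
    out <- px[yi, xi, , drop = FALSE]
  } else {
    y0 <- pmin(pmax(floor(ys), 1), H); y1 <- pmin(y0 + 1, H)
    x0 <- pmin(pmax(floor(xs), 1), W); x1 <- pmin(x0 + 1, W)
    fy <- pmin(pmax(ys - y0, 0), 1);   fx <- pmin(pmax(xs - x0, 0), 1)
    waa <- outer(1 - fy, 1 - fx); wab <- outer(1 - fy, fx)
    wba <- outer(fy, 1 - fx);     wbb <- outer(fy, fx)
    for (ch in seq_len(C)) {
      M <- matrix(px[, , ch], H, W)   # keep matrix shape even when H or W is 1
      out[, , ch] <- waa * M[y0, x0, drop = FALSE] + wab * M[y0, x1, drop = FALSE] +
                     wba * M[y1, x0, drop = FALSE] + wbb * M[y1, x1, drop = FALSE]
    }
  }
  if (two_d) out[, , 1] else out
}

# Half-sample symmetric reflection of 1-based indices into 1..n
# (the 'reflect' boundary rule of standard n-d image filters).
reflect_index <- function(j, n) {
  m <- (j - 1) %% (2 * n)
  m <- ifelse(m < 0, m + 2 * n, m)
  ifelse(m < n, m, 2 * n - 1 - m) + 1
}

# n x n matrix applying a normalized, truncated 1-D Gaussian along one axis.
# Row i holds the weights contributing to output position i; with the reflect
# boundary every column also sums to 1, so filtering conserves total mass.
gaussian_blur_matrix <- function(n, sigma, truncate = 4,
                                 mode = c("reflect", "constant")) {
  mode <- match.arg(mode)
  if (sigma <= 0) fail_validation("sigma must be > 0")
  r <- as.integer(truncate * sigma + 0.5)
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  M <- matrix(0, n, n)
  i <- seq_len(n)
  for (t in seq_along(w)) {
    j <- i + (t - r - 1L)
    if (mode == "reflect") {
      jr <- reflect_index(j, n)
      M[cbind(i, jr)] <- M[cbind(i, jr)] + w[t]
    } else {
      ok <- j >= 1 & j <= n
      M[cbind(i[ok], j[ok])] <- M[cbind(i[ok], j[ok])] + w[t]
    }
  }
  M
}

#' Separable 2-D Gaussian filter
#'
#' Filters a matrix with a normalized Gaussian kernel truncated at
#' `truncate` standard deviations, with either half-sample-symmetric
#' (`"reflect"`, mass-conserving) or zero (`"constant"`) boundaries.
#'
#' @param x numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @param mode boundary handling, `"reflect"` or `"constant"`.
#' @param truncate kernel truncation radius in standard deviations.
#' @return filtered matrix of the same size.
#' @export
gaussian_filter_2d <- function(x, sigma, mode = c("reflect", "constant"),
                               truncate = 4) {
  mode <- match.arg(mode)
  if (!is.matrix(x)) fail_validation("gaussian_filter_2d expects a matrix")
  Kr <- gaussian_blur_matrix(nrow(x), sigma, truncate, mode)
  Kc <- if (ncol(x) == nrow(x)) Kr else gaussian_blur_matrix(ncol(x), sigma, truncate, mode)
  Kr %*% x %*% t(Kc)
}

# Vectorized HSV -> RGB (h, s, v in [0,1]; returns n x 3 matrix in [0,1]).
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
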