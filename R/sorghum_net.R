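# Sorghum-Net: a multicolumn convolutional network for density-map
# regression. Three parallel columns with kernel sizes 3/5/7 look at the
# grains at different receptive fields; each column is four Conv-BN-ReLU
# blocks with 2x2/stride-2 max pooling after the first two convolutions.
# The columns' feature maps are concatenated channel-wise, upsampled back to
# the input resolution and reduced by a 1x1 convolution head. Counting then
# integrates the predicted density (channel 1 of the head).

#' Column specification
#'
#' @param kernel_size odd convolution kernel size in pixels.
#' @param channel_dims integer vector of output channels, one per conv layer.
#' @param pool_after indices of the layers followed by 2x2/stride-2 max
#'   pooling (default the first two).
#' @return object of class `column_spec`.
#' @export
column_spec <- function(kernel_size, channel_dims, pool_after = c(1L, 2L)) {
  if (kernel_size %% 2 != 1 || kernel_size < 1) {
    fail_validation("kernel_size must be odd and positive")
  }
  if (any(channel_dims < 1)) fail_validation("channel_dims must be positive")
  if (length(pool_after) > 0 &&
      (any(pool_after < 1) || any(pool_after > length(channel_dims)))) {
    fail_validation("pool_after indices out of range 1..%d", length(channel_dims))
  }
  structure(list(kernel_size = as.integer(kernel_size),
                 channel_dims = as.integer(channel_dims),
                 pool_after = sort(as.integer(pool_after))),
            class = "column_spec")
}

#' Architecture configuration
#'
#' The defaults are the published Sorghum-Net: columns
#' 3x3: (80, 160, 80, 40), 5x5: (40, 80, 40, 20), 7x7: (20, 40, 20, 40),
#' concatenated (100 channels), upsampled x4 and fed to a 1x1 convolution of
#' dimension 2. Batch normalization follows every column convolution, in
#' front of the ReLU activation.
#'
#' @param input_size `(H, W, channels)` of the input, default `(224, 224, 3)`.
#' @param columns list of [column_spec()]s; all columns must pool the same
#'   number of times so their outputs can be concatenated.
#' @param upsample_mode `"nearest"` (default) or `"bilinear"`.
#' @param head_channels output channels of the 1x1 head (default 2; the
#'   density is channel 1, the remaining channels are unused).
#' @param final_activation `"relu"` (default, guarantees non-negative
#'   densities) or `"linear"`.
#' @return object of class `arch_config`.
#' @export
arch_config <- function(input_size = c(224L, 224L, 3L),
                        columns = list(
                          column_spec(3L, c(80L, 160L, 80L, 40L)),
                          column_spec(5L, c(40L, 80L, 40L, 20L)),
                          column_spec(7L, c(20L, 40L, 20L, 40L))),
                        upsample_mode = c("nearest", "bilinear"),
                        head_channels = 2L,
                        final_activation = c("relu", "linear")) {
  upsample_mode <- match.arg(upsample_mode)
  final_activation <- match.arg(final_activation)
  if (length(input_size) != 3 || any(input_size < 1)) {
    fail_validation("input_size must be (H, W, channels)")
  }
  if (length(columns) < 1) fail_validation("need at least one column")
  for (cs in columns) {
    if (!inherits(cs, "column_spec")) fail_validation("columns must be column_spec objects")
  }
  npool <- vapply(columns, function(cs) length(cs$pool_after), integer(1))
  if (length(unique(npool)) != 1) {
    fail_validation("all columns must pool the same number of times (got %s)",
                    paste(npool, collapse = ", "))
  }
  factor <- 2L^npool[1]
  if (any(input_size[1:2] %% factor != 0)) {
    fail_validation("input H and W must be divisible by %d", factor)
  }
  if (head_channels < 1) fail_validation("head_channels must be >= 1")
  structure(list(input_size = as.integer(input_size), columns = columns,
                 upsample_factor = factor, upsample_mode = upsample_mode,
                 head_channels = as.integer(head_channels), head_kernel = 1L,
                 final_activation = final_activation),
            class = "arch_config")
}

concat_channels <- function(arch) {
  sum(vapply(arch$columns, function(cs) cs$channel_dims[length(cs$channel_dims)],
             integer(1)))
}

#' Build a Sorghum-Net network
#'
#' Creates the trainable network for an [arch_config()]: per column,
#' Conv-BN-ReLU blocks with max pooling after the configured layers;
#' channel-wise concatenation; upsampling back to the input size; a 1x1
#' convolution head. Weights use He (variance-scaling) initialization.
#'
#' @param arch an [arch_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `sorghum_net`.
#' @export
build_network <- function(arch = arch_config(), seed = 1L) {
  stopifnot(inherits(arch, "arch_config"))
  params <- list(); state <- list()
  with_seed(seed, {
    for (ci in seq_along(arch$columns)) {
      cs <- arch$columns[[ci]]
      cin <- arch$input_size[3]
      for (li in seq_along(cs$channel_dims)) {
        cout <- cs$channel_dims[li]
        k <- cs$kernel_size
        nm <- sprintf("col%d_conv%d", ci, li)
        fan_in <- k * k * cin
        params[[paste0(nm, "_W")]] <- matrix(rnorm(fan_in * cout, 0,
                                                   sqrt(2 / fan_in)),
                                             fan_in, cout)
        params[[paste0(nm, "_b")]] <- numeric(cout)
        bn <- sprintf("col%d_bn%d", ci, li)
        params[[paste0(bn, "_gamma")]] <- rep(1, cout)
        params[[paste0(bn, "_beta")]] <- numeric(cout)
        state[[paste0(bn, "_mean")]] <- numeric(cout)
        state[[paste0(bn, "_var")]] <- rep(1, cout)
        cin <- cout
      }
    }
    cc <- concat_channels(arch)
    # the head regresses a density whose pixel values are O(0.01); start it
    # at that scale with a small positive bias so the ReLU output is active
    # from the first step (a unit-scale init drives the whole output
    # negative within a few optimizer steps and the ReLU then blocks all
    # gradient — the classic dead head)
    params$head_W <- matrix(rnorm(cc * arch$head_channels, 0,
                                  0.05 * sqrt(2 / cc)),
                            cc, arch$head_channels)
    params$head_b <- rep(0.01, arch$head_channels)
  })
  structure(list(arch = arch, params = params, state = state,
                 bn_eps = 1e-3, bn_momentum = 0.9,
                 n_updates = 0L, history = NULL, best_epoch = NA_integer_,
                 seed = as.integer(seed)),
            class = "sorghum_net")
}

#' Per-layer parameter report
#'
#' One row per weight tensor with its shape, trainable parameter count and
#' (for batch-norm running mean/variance) statistic count.
#'
#' @param net a `sorghum_net`.
#' @return data.frame with columns `name`, `shape`, `trainable`, `statistics`.
#' @export
parameter_report <- function(net) {
  stopifnot(inherits(net, "sorghum_net"))
  shape_of <- function(x) {
    if (is.matrix(x)) paste(dim(x), collapse = "x") else as.character(length(x))
  }
  rows <- lapply(names(net$params), function(nm) {
    data.frame(name = nm, shape = shape_of(net$params[[nm]]),
               trainable = length(net$params[[nm]]), statistics = 0L,
               stringsAsFactors = FALSE)
  })
  srows <- lapply(names(net$state), function(nm) {
    data.frame(name = nm, shape = shape_of(net$state[[nm]]),
               trainable = 0L, statistics = length(net$state[[nm]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, srows))
}

#' Count network parameters
#'
#' @param net a `sorghum_net`.
#' @param include_statistics also count batch-norm running mean/variance
#'   (2 statistic values per channel, on top of the 2 trainable ones); this
#'   is the convention under which the architecture totals 568K.
#' @return integer parameter count.
#' @export
count_parameters <- function(net, include_statistics = TRUE) {
  rep_ <- parameter_report(net)
  s <- sum(rep_$trainable)
  if (include_statistics) s <- s + sum(rep_$statistics)
  as.integer(s)
}

#' @export
print.sorghum_net <- function(x, ...) {
  a <- x$arch
  cols <- vapply(a$columns, function(cs) {
    sprintf("%dx%d:(%s)", cs$kernel_size, cs$kernel_size,
            paste(cs$channel_dims, collapse = ","))
  }, character(1))
  cat("<sorghum_net> multicolumn density-regression network\n")
  cat(sprintf("  input %s | columns %s | concat %d | head %d (%s)\n",
              paste(a$input_size, collapse = "x"), paste(cols, collapse = " "),
              concat_channels(a), a$head_channels, a$final_activation))
  cat(sprintf("  parameters: %s trainable + %s statistics = %s\n",
              format(count_parameters(x, FALSE), big.mark = ","),
              format(count_parameters(x, TRUE) - count_parameters(x, FALSE),
                     big.mark = ","),
              format(count_parameters(x, TRUE), big.mark = ",")))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epoch(s); best validation loss %.6g at epoch %d\n",
                nrow(x$history), min(x$history$val_loss), x$best_epoch))
  }
  invisible(x)
}

#' @export
summary.sorghum_net <- function(object, ...) {
  rep_ <- parameter_report(object)
  structure(list(report = rep_,
                 total = count_parameters(object, TRUE),
                 trainable = count_parameters(object, FALSE),
                 history = object$history),
            class = "summary.sorghum_net")
}

#' @export
print.summary.sorghum_net <- function(x, ...) {
  print(x$report, row.names = FALSE)
  cat(sprintf("total: %s (trainable %s, statistics %s)\n",
              format(x$total, big.mark = ","),
              format(x$trainable, big.mark = ","),
              format(x$total - x$trainable, big.mark = ",")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Forward / backward engine. Activations are lists (one element per image in
# the batch) of (H*W) x C matrices in column-major pixel order.

upsample_indices <- function(H, W, f) {
  # output row (y, x) reads input row (ceil(y/f), ceil(x/f))
  src_y <- ceiling(seq_len(H * f) / f)
  src_x <- ceiling(seq_len(W * f) / f)
  as.vector(outer(src_y, (src_x - 1) * H, "+"))
}

bilinear_upsample_weights <- function(H, W, f) {
  # sparse 4-tap representation: out row i reads in rows idx[i, 1..4] with
  # weights w[i, 1..4] (half-pixel alignment)
  ys <- (seq_len(H * f) - 0.5) / f + 0.5
  xs <- (seq_len(W * f) - 0.5) / f + 0.5
  y0 <- clamp(floor(ys), 1, H); y1 <- pmin(y0 + 1, H); fy <- clamp(ys - y0, 0, 1)
  x0 <- clamp(floor(xs), 1, W); x1 <- pmin(x0 + 1, W); fx <- clamp(xs - x0, 0, 1)
  no <- H * f * W * f
  Y0 <- rep(y0, times = W * f); Y1 <- rep(y1, times = W * f)
  FY <- rep(fy, times = W * f)
  X0 <- rep(x0, each = H * f); X1 <- rep(x1, each = H * f)
  FX <- rep(fx, each = H * f)
  idx <- cbind(Y0 + H * (X0 - 1), Y0 + H * (X1 - 1),
               Y1 + H * (X0 - 1), Y1 + H * (X1 - 1))
  w <- cbind((1 - FY) * (1 - FX), (1 - FY) * FX, FY * (1 - FX), FY * FX)
  list(idx = idx, w = w)
}

net_forward <- function(net, X, H, W, nimg, training = FALSE,
                        keep_cache = FALSE) {
  arch <- net$arch
  p <- net$params; st <- net$state
  cache <- if (keep_cache) list(cols = vector("list", length(arch$columns))) else NULL
  col_out <- vector("list", length(arch$columns))
  col_dims <- vector("list", length(arch$columns))
  new_state <- st

  for (ci in seq_along(arch$columns)) {
    cs <- arch$columns[[ci]]
    a <- X; h <- H; w <- W
    ccache <- list()
    for (li in seq_along(cs$channel_dims)) {
      k <- cs$kernel_size
      nm <- sprintf("col%d_conv%d", ci, li)
      bn <- sprintf("col%d_bn%d", ci, li)
      # NOTE: the conv bias is omitted from the forward pass on purpose —
      # batch normalization immediately follows every column conv, and a
      # per-channel constant cancels exactly in the normalization, so the
      # bias is mathematically inert (zero gradient). It remains a declared,
      # counted parameter of the layer.
      z <- conv_fw(a, p[[paste0(nm, "_W")]], h, w, k, nimg)
      if (training) {
        ns <- nimg * h * w
        sums <- colsums_pair(z, z)
        mu <- sums$sum / ns
        v <- pmax(sums$sum_prod / ns - mu^2, 0)
        mom <- net$bn_momentum
        new_state[[paste0(bn, "_mean")]] <-
          mom * new_state[[paste0(bn, "_mean")]] + (1 - mom) * mu
        new_state[[paste0(bn, "_var")]] <-
          mom * new_state[[paste0(bn, "_var")]] + (1 - mom) * v
      } else {
        mu <- st[[paste0(bn, "_mean")]]
        v <- st[[paste0(bn, "_var")]]
      }
      istd <- 1 / sqrt(v + net$bn_eps)
      g <- p[[paste0(bn, "_gamma")]]; be <- p[[paste0(bn, "_beta")]]
      A <- g * istd; B <- be - mu * A
      conv_in <- a
      a <- scale_shift(z, A, B, relu = TRUE)
      pooled <- li %in% cs$pool_after
      pool_arg <- NULL
      if (pooled) {
        pl <- maxpool2(a, h, w, nimg)
        a <- pl$y
        pool_arg <- pl$argmax
      }
      if (keep_cache) {
        ccache[[li]] <- list(conv_in = conv_in, h = h, w = w, k = k,
                             z = z, istd = istd, mu = mu,
                             pooled = pooled, pool_arg = pool_arg)
      }
      if (pooled) { h <- h %/% 2L; w <- w %/% 2L }
    }
    col_out[[ci]] <- a
    col_dims[[ci]] <- c(h, w)
    if (keep_cache) cache$cols[[ci]] <- ccache
  }

  hh <- col_dims[[1]][1]; ww <- col_dims[[1]][2]
  z_cat <- do.call(cbind, col_out)
  f <- arch$upsample_factor
  ones <- rep(1, arch$head_channels)
  z_up <- NULL
  if (arch$upsample_mode == "nearest") {
    # a 1x1 head commutes with nearest-neighbour upsampling, so the head is
    # applied at the pooled resolution and only its (thin) output upsampled
    z_head <- upsample_nn(z_cat %*% p$head_W, hh, ww, f, nimg)
    up_info <- list(mode = "nearest", hin = hh, win = ww)
  } else {
    bw <- bilinear_upsample_weights(hh, ww, f)
    hwin <- hh * ww; hwout <- hwin * f * f
    z_up <- matrix(0, hwout * nimg, ncol(z_cat))
    for (n in seq_len(nimg)) {
      sub <- z_cat[((n - 1) * hwin + 1):(n * hwin), , drop = FALSE]
      z_up[((n - 1) * hwout + 1):(n * hwout), ] <-
        bw$w[, 1] * sub[bw$idx[, 1], , drop = FALSE] +
        bw$w[, 2] * sub[bw$idx[, 2], , drop = FALSE] +
        bw$w[, 3] * sub[bw$idx[, 3], , drop = FALSE] +
        bw$w[, 4] * sub[bw$idx[, 4], , drop = FALSE]
    }
    z_head <- z_up %*% p$head_W
    up_info <- list(mode = "bilinear", bw = bw, hin = hh, win = ww)
  }
  out <- scale_shift(z_head, ones, p$head_b,
                     relu = arch$final_activation == "relu")
  if (keep_cache) {
    cache$z_cat <- z_cat
    cache$z_up <- z_up
    cache$z_head <- z_head
    cache$up <- up_info
    cache$concat_dims <- vapply(arch$columns, function(cs) {
      cs$channel_dims[length(cs$channel_dims)]
    }, integer(1))
    cache$nimg <- nimg
  }
  list(out = out, cache = cache, state = new_state)
}

net_backward <- function(net, cache, dout) {
  arch <- net$arch
  p <- net$params
  nimg <- cache$nimg
  grads <- lapply(p, function(x) if (is.matrix(x)) {
    matrix(0, nrow(x), ncol(x))
  } else numeric(length(x)))

  if (arch$final_activation == "relu") {
    dout <- relu_backward_affine(dout, cache$z_head,
                                 rep(1, arch$head_channels), p$head_b)
  }
  grads$head_b <- colSums(dout)
  up <- cache$up
  if (up$mode == "nearest") {
    # adjoint of (head at pooled resolution, then nearest upsample)
    d_small <- upsample_nn_backward(dout, up$hin, up$win,
                                    arch$upsample_factor, nimg)
    grads$head_W <- crossprod(cache$z_cat, d_small)
    dz <- tcrossprod(d_small, p$head_W)
  } else {
    grads$head_W <- crossprod(cache$z_up, dout)
    dz_up <- tcrossprod(dout, p$head_W)
    bw <- up$bw
    f <- arch$upsample_factor
    hwin <- up$hin * up$win; hwout <- hwin * f * f
    dz <- matrix(0, hwin * nimg, ncol(dz_up))
    for (n in seq_len(nimg)) {
      sub <- dz_up[((n - 1) * hwout + 1):(n * hwout), , drop = FALSE]
      acc <- matrix(0, hwin, ncol(dz_up))
      for (t in 1:4) {
        r <- rowsum(bw$w[, t] * sub, bw$idx[, t], reorder = TRUE)
        ri <- as.integer(rownames(r))
        acc[ri, ] <- acc[ri, ] + r
      }
      dz[((n - 1) * hwin + 1):(n * hwin), ] <- acc
    }
  }

  # split the concatenation back into columns
  cd <- cache$concat_dims
  col_ends <- cumsum(cd); col_starts <- col_ends - cd + 1
  for (ci in rev(seq_along(arch$columns))) {
    cs <- arch$columns[[ci]]
    d <- dz[, col_starts[ci]:col_ends[ci], drop = FALSE]
    for (li in rev(seq_along(cs$channel_dims))) {
      cc <- cache$cols[[ci]][[li]]
      bn <- sprintf("col%d_bn%d", ci, li)
      g <- p[[paste0(bn, "_gamma")]]
      be <- p[[paste0(bn, "_beta")]]
      if (cc$pooled) d <- maxpool2_backward(d, cc$pool_arg, cc$h, cc$w, nimg)
      bb <- bn_relu_backward(d, cc$z, g, be, cc$mu, cc$istd,
                             nimg * cc$h * cc$w)
      grads[[paste0(bn, "_beta")]] <- bb$dbeta
      grads[[paste0(bn, "_gamma")]] <- bb$dgamma
      nm <- sprintf("col%d_conv%d", ci, li)
      cb <- conv_bw(cc$conv_in, p[[paste0(nm, "_W")]], bb$dx,
                    cc$h, cc$w, cc$k, nimg, need_dx = li > 1)
      grads[[paste0(nm, "_W")]] <- cb$dW
      # conv bias: inert through the following batch norm (gradient 0)
      if (li > 1) d <- cb$dX
    }
  }
  grads
}

# Normalize an input image to the engine's (H*W) x 3 matrix form, pixels
# scaled to [0, 1].
as_input_matrix <- function(x, input_hw = NULL) {
  if (inherits(x, "image_record")) x <- x$pixels
  d <- dim(x)
  if (is.matrix(x) && !is.null(input_hw) && nrow(x) == prod(input_hw) &&
      ncol(x) == 3) {
    m <- x
  } else if (length(d) == 3 && d[3] == 3) {
    m <- cbind(as.vector(x[, , 1]), as.vector(x[, , 2]), as.vector(x[, , 3]))
    input_hw <- d[1:2]
  } else {
    fail_validation("expected an H x W x 3 array (got dims %s)",
                    paste(d, collapse = "x"))
  }
  if (max(m) > 1.5) m <- m / 255
  list(m = m, hw = input_hw)
}

#' Predict a density map for one image
#'
#' Runs the network in inference mode (batch-norm running statistics) and
#' returns the density channel (channel 1 of the head).
#'
#' @param net a `sorghum_net`.
#' @param image an H x W x 3 array (0..255 or 0..1; scaled to `[0, 1]`
#'   internally) or an [image_record()]. H and W must be divisible by the
#'   architecture's pooling factor.
#' @return H x W numeric matrix; non-negative under the ReLU head.
#' @export
predict_density <- function(net, image) {
  stopifnot(inherits(net, "sorghum_net"))
  inp <- as_input_matrix(image)
  hw <- inp$hw
  f <- net$arch$upsample_factor
  if (any(hw %% f != 0)) {
    fail_validation("input size %s not divisible by the pooling factor %d",
                    paste(hw, collapse = "x"), f)
  }
  fw <- net_forward(net, inp$m, hw[1], hw[2], nimg = 1L, training = FALSE)
  matrix(fw$out[, 1], hw[1], hw[2])
}

#' @param object a `sorghum_net`.
#' @param newdata one image (array or [image_record()]) or a list of images.
#' @param ... unused.
#' @rdname predict_density
#' @export
predict.sorghum_net <- function(object, newdata, ...) {
  if (is.list(newdata) && !inherits(newdata, "image_record")) {
    lapply(newdata, function(x) predict_density(object, x))
  } else {
    predict_density(object, newdata)
  }
}

#' @export
plot.sorghum_net <- function(x, ...) {
  if (is.null(x$history)) {
    fail_validation("network has no training history to plot")
  }
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "pixel-mean MSE loss", col = "steelblue",
                 ylim = range(c(h$train_loss, h$val_loss)), ...)
  graphics::lines(h$epoch, h$val_loss, col = "firebrick")
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

arch_to_list <- function(arch) {
  list(input_size = arch$input_size,
       columns = lapply(arch$columns, function(cs) {
         list(kernel_size = cs$kernel_size, channel_dims = cs$channel_dims,
              pool_after = cs$pool_after)
       }),
       upsample_mode = arch$upsample_mode,
       head_channels = arch$head_channels,
       final_activation = arch$final_activation)
}

arch_from_list <- function(x) {
  arch_config(input_size = unlist(x$input_size),
              columns = lapply(x$columns, function(cs) {
                column_spec(cs$kernel_size, unlist(cs$channel_dims),
                            unlist(cs$pool_after))
              }),
              upsample_mode = x$upsample_mode,
              head_channels = x$head_channels,
              final_activation = x$final_activation)
}

#' Save / load a network checkpoint
#'
#' The checkpoint is an RDS file with weights and running statistics; an
#' `<path>.json` sidecar describes the architecture so the parameter report
#' is reproducible without loading the weights.
#'
#' @param net a `sorghum_net`.
#' @param path checkpoint path.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "sorghum_net"))
  saveRDS(net, path)
  jsonlite::write_json(arch_to_list(net$arch), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  if (!file.exists(path)) fail_io("checkpoint not found: %s", path)
  net <- readRDS(path)
  if (!inherits(net, "sorghum_net")) fail_io("%s is not a sorghum_net checkpoint", path)
  net
}
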