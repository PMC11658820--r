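# Training regimen: Adam on pixel-mean MSE between the predicted density
# channel and the ground-truth map, early stopping on validation loss with
# best-weights restoration.

#' Training configuration
#'
#' Defaults follow the study protocol: Adam, learning rate 0.001, batch size
#' 8, at most 200 epochs with early stopping patience 20.
#'
#' @param max_epochs maximum number of epochs.
#' @param patience epochs without validation-loss improvement tolerated
#'   before stopping (min-delta 0); the best weights are restored.
#' @param batch_size images per optimization step.
#' @param learning_rate Adam step size.
#' @param validation_fraction fraction of the training pairs carved off for
#'   validation when no explicit validation set is supplied.
#' @param seed integer seed controlling shuffling and the validation carve.
#' @param shuffle reshuffle the training order every epoch.
#' @param verbose log per-epoch losses.
#' @return object of class `train_config`.
#' @export
train_config <- function(max_epochs = 200L, patience = 20L, batch_size = 8L,
                         learning_rate = 0.001, validation_fraction = 0.15,
                         seed = 1L, shuffle = TRUE, verbose = FALSE) {
  if (batch_size < 1) fail_validation("batch_size must be >= 1")
  if (learning_rate <= 0) fail_validation("learning_rate must be > 0")
  if (max_epochs < 1) fail_validation("max_epochs must be >= 1")
  if (patience >= max_epochs && max_epochs > 1) patience <- max_epochs - 1L
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), shuffle = isTRUE(shuffle),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# One (image, density map) pair in engine form.
as_pair <- function(p, input_hw) {
  x <- as_input_matrix(p$x, input_hw)
  y <- if (inherits(p$y, "density_map")) p$y$values else p$y
  if (!is.matrix(y)) fail_validation("pair target must be a matrix or density_map")
  list(x = x$m, y = as.vector(y), hw = x$hw)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0), v = lapply(params, function(x) x * 0),
       t = 0)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

eval_loss <- function(net, pairs, hw, batch_size) {
  # all pairs share the input size, so the mean over images of per-image
  # pixel-mean MSE equals the overall pixel mean
  total <- 0
  idx <- seq_along(pairs)
  for (b in split(idx, ceiling(seq_along(idx) / batch_size))) {
    X <- do.call(rbind, lapply(pairs[b], `[[`, "x"))
    fw <- net_forward(net, X, hw[1], hw[2], nimg = length(b),
                      training = FALSE)
    yv <- unlist(lapply(pairs[b], `[[`, "y"), use.names = FALSE)
    total <- total + sum((fw$out[, 1] - yv)^2) / prod(hw)
  }
  total / length(pairs)
}

#' Train a Sorghum-Net on (image, density map) pairs
#'
#' Mini-batch Adam on pixel-mean MSE with per-epoch shuffling, early stopping
#' on the validation loss and best-weights restoration. Fully deterministic
#' for a fixed `cfg$seed` (single-threaded BLAS assumed).
#'
#' @param net a freshly built or previously trained `sorghum_net`.
#' @param train_pairs list of pairs, each `list(x = , y = )` where `x` is an
#'   H x W x 3 image (H, W matching `net$arch$input_size`) and `y` the H x W
#'   ground-truth density map (matrix or `density_map`).
#' @param val_pairs optional validation pairs in the same form; when `NULL`,
#'   `cfg$validation_fraction` of the training pairs is carved off.
#' @param cfg a [train_config()].
#' @return the trained `sorghum_net` with `$history` (data.frame of epoch,
#'   train_loss, val_loss) and `$best_epoch` set.
#' @export
train_network <- function(net, train_pairs, val_pairs = NULL,
                          cfg = train_config()) {
  stopifnot(inherits(net, "sorghum_net"), inherits(cfg, "train_config"))
  if (length(train_pairs) == 0) fail_validation("empty training set")
  hw <- net$arch$input_size[1:2]
  train_pairs <- lapply(train_pairs, as_pair, input_hw = hw)
  bad <- which(vapply(train_pairs, function(p) !identical(as.integer(p$hw),
                                                          hw), logical(1)))
  if (length(bad) > 0) {
    fail_validation("training pair(s) not at the network input size %s: %s",
                    paste(hw, collapse = "x"), paste(head(bad, 5), collapse = ", "))
  }
  if (is.null(val_pairs)) {
    nv <- max(1L, floor(length(train_pairs) * cfg$validation_fraction))
    if (length(train_pairs) - nv < 1) {
      fail_validation("too few pairs (%d) to carve a validation set",
                      length(train_pairs))
    }
    vi <- with_seed(derive_seed(cfg$seed, 77L),
                    sample.int(length(train_pairs), nv))
    val_pairs <- train_pairs[vi]
    train_pairs <- train_pairs[-vi]
  } else {
    val_pairs <- lapply(val_pairs, as_pair, input_hw = hw)
  }

  opt <- adam_init(net$params)
  best <- list(loss = Inf, params = net$params, state = net$state, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  wait <- 0L
  npx <- prod(hw)

  with_seed(derive_seed(cfg$seed, 13L), {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- if (cfg$shuffle) sample.int(length(train_pairs)) else
        seq_along(train_pairs)
      ep_loss <- 0
      for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        X <- do.call(rbind, lapply(train_pairs[b], `[[`, "x"))
        yv <- unlist(lapply(train_pairs[b], `[[`, "y"), use.names = FALSE)
        fw <- net_forward(net, X, hw[1], hw[2], nimg = length(b),
                          training = TRUE, keep_cache = TRUE)
        net$state <- fw$state
        resid <- fw$out[, 1] - yv
        loss <- sum(resid^2) / (npx * length(b))
        if (!is.finite(loss)) {
          stop(sprintf("NaN/Inf loss at epoch %d after %d update(s); try a lower learning rate",
                       epoch, opt$t))
        }
        ep_loss <- ep_loss + loss * length(b)
        dout <- matrix(0, npx * length(b), net$arch$head_channels)
        dout[, 1] <- 2 * resid / (npx * length(b))
        grads <- net_backward(net, fw$cache, dout)
        upd <- adam_step(net$params, grads, opt, cfg$learning_rate)
        net$params <- upd$params
        opt <- upd$opt
        net$n_updates <- net$n_updates + 1L
      }
      train_loss <- ep_loss / length(train_pairs)
      val_loss <- eval_loss(net, val_pairs, hw, cfg$batch_size)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                     val_loss = val_loss))
      if (cfg$verbose) {
        sn_log("epoch %3d  train %.6g  val %.6g", epoch, train_loss, val_loss)
      }
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = net$params, state = net$state,
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience && epoch < cfg$max_epochs) break
      }
    }
  })
  net$params <- best$params
  net$state <- best$state
  net$best_epoch <- best$epoch
  net$history <- hist
  net
}

#' Count-accuracy metric suite
#'
#' Mean absolute error, mean squared error, mean absolute percentage error
#' (0-100 scale), root mean squared error and the coefficient of
#' determination between observed and predicted counts.
#'
#' @param y_obs observed (ground-truth) counts; must be positive when
#'   `mape = TRUE`.
#' @param y_pred predicted counts, same length.
#' @param mape compute MAPE (requires strictly positive `y_obs`).
#' @return object of class `count_metrics` with fields `n`, `mae`, `mse`,
#'   `rmse`, `mape`, `r2`.
#' @export
evaluate_counts <- function(y_obs, y_pred, mape = TRUE) {
  y_obs <- as.numeric(y_obs); y_pred <- as.numeric(y_pred)
  if (length(y_obs) != length(y_pred)) {
    fail_validation("length mismatch: %d observed vs %d predicted",
                    length(y_obs), length(y_pred))
  }
  if (length(y_obs) == 0) fail_validation("empty input")
  err <- y_obs - y_pred
  mape_val <- NA_real_
  if (mape) {
    zi <- which(y_obs <= 0)
    if (length(zi) > 0) {
      fail_validation("MAPE undefined: non-positive observed value(s) at index %s",
                      paste(head(zi, 10), collapse = ", "))
    }
    mape_val <- mean(abs(err) / y_obs) * 100
  }
  mse <- mean(err^2)
  ss_tot <- sum((y_obs - mean(y_obs))^2)
  structure(list(n = length(y_obs),
                 mae = mean(abs(err)),
                 mse = mse,
                 rmse = sqrt(mse),
                 mape = mape_val,
                 r2 = if (ss_tot > 0) 1 - sum(err^2) / ss_tot else NA_real_),
            class = "count_metrics")
}

#' @export
print.count_metrics <- function(x, ...) {
  cat(sprintf("count metrics (n = %d):\n", x$n))
  cat(sprintf("  MAE  %10.3f grains\n", x$mae))
  cat(sprintf("  MSE  %10.3f grains^2\n", x$mse))
  cat(sprintf("  RMSE %10.3f grains\n", x$rmse))
  if (!is.na(x$mape)) cat(sprintf("  MAPE %10.2f %%\n", x$mape))
  if (!is.na(x$r2)) cat(sprintf("  R^2  %10.4f\n", x$r2))
  invisible(x)
}

#' Write a training history as CSV
#' @param net a trained `sorghum_net`.
#' @param path output CSV path (columns epoch, train_loss, val_loss).
#' @export
write_history <- function(net, path) {
  if (is.null(net$history)) fail_validation("network has no training history")
  utils::write.csv(net$history, path, row.names = FALSE)
  invisible(path)
}
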