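# Polynomial calibration from the one-side visible count (density-map
# estimate) to the machine-counted whole-panicle grain number: an ordinary
# least-squares polynomial regression, fitted on a random 70% of the
# panicles and scored on the held-out 30%.

#' Fit the visible-to-total polynomial calibration model
#'
#' Least-squares polynomial fit of the observed whole-panicle count
#' (dependent) on the one-side visible-count estimate (independent), with a
#' random train/test split and held-out metrics (R^2, MSE, RMSE, MAPE).
#'
#' @param records data.frame with columns `total_visible` and
#'   `observed_total`, or a list of [panicle_record()]s (side A is used).
#' @param degree polynomial degree (default 2).
#' @param train_fraction fraction of records used for fitting (default 0.7).
#' @param seed integer seed for the random split; `NULL` uses the current
#'   RNG state.
#' @return object of class `panicle_poly` with `coefficients` (ascending
#'   powers, intercept first) and `fit_metrics` (held-out `count_metrics`).
#' @export
fit_panicle_model <- function(records, degree = 2L, train_fraction = 0.7,
                              seed = NULL) {
  if (!is.data.frame(records)) {
    records <- data.frame(
      total_visible = vapply(records, function(r) r$visible_A, numeric(1)),
      observed_total = vapply(records, function(r) r$observed_total, numeric(1)))
  }
  x <- as.numeric(records$total_visible)
  y <- as.numeric(records$observed_total)
  n <- length(x)
  degree <- as.integer(degree)
  if (degree < 0) fail_validation("degree must be >= 0")
  ntr <- floor(n * train_fraction)
  if (ntr < degree + 2) {
    fail_validation("need at least %d training points for degree %d (have %d)",
                    degree + 2, degree, ntr)
  }
  tr <- with_seed(seed, sample.int(n, ntr))
  te <- setdiff(seq_len(n), tr)
  if (length(unique(x[tr])) < degree + 1) {
    fail_validation("degenerate design: too few distinct x values for degree %d",
                    degree)
  }
  fit <- if (degree == 0) {
    lm(y ~ 1, data = data.frame(x = x[tr], y = y[tr]))
  } else {
    lm(y ~ poly(x, degree, raw = TRUE), data = data.frame(x = x[tr], y = y[tr]))
  }
  coefs <- unname(coef(fit))
  metrics <- if (length(te) > 0) {
    pred <- eval_poly(coefs, x[te])
    evaluate_counts(y[te], pred, mape = all(y[te] > 0))
  } else NULL
  structure(list(degree = degree, coefficients = coefs,
                 fit_metrics = metrics,
                 n_train = ntr, n_test = length(te), seed = seed,
                 train_data = data.frame(x = x[tr], y = y[tr]),
                 test_data = data.frame(x = x[te], y = y[te])),
            class = "panicle_poly")
}

eval_poly <- function(coefs, x) {
  # Horner evaluation, highest power first
  acc <- rep(coefs[length(coefs)], length(x))
  if (length(coefs) > 1) {
    for (i in (length(coefs) - 1):1) acc <- acc * x + coefs[i]
  }
  acc
}

#' Predict the whole-panicle grain number from a one-side visible count
#'
#' Evaluates the fitted polynomial and clips negative predictions at 0.
#'
#' @param model a fitted `panicle_poly`.
#' @param total_visible numeric vector of one-side visible-count estimates.
#' @return predicted whole-panicle grain numbers (>= 0).
#' @export
predict_total <- function(model, total_visible) {
  stopifnot(inherits(model, "panicle_poly"))
  pmax(0, eval_poly(model$coefficients, as.numeric(total_visible)))
}

#' @param object a `panicle_poly`.
#' @param newdata numeric vector of visible counts (defaults to the
#'   training data).
#' @param ... unused.
#' @rdname predict_total
#' @export
predict.panicle_poly <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$train_data$x
  predict_total(object, newdata)
}

#' @export
coef.panicle_poly <- function(object, ...) {
  stats::setNames(object$coefficients, paste0("x^", 0:object$degree))
}

#' @export
print.panicle_poly <- function(x, ...) {
  terms <- sprintf("%.6g*x^%d", x$coefficients, 0:x$degree)
  cat(sprintf("<panicle_poly> degree %d: total = %s\n", x$degree,
              paste(terms, collapse = " + ")))
  if (!is.null(x$fit_metrics)) {
    cat(sprintf("  held-out (n = %d): R^2 %.3f, RMSE %.1f grains%s\n",
                x$n_test, x$fit_metrics$r2, x$fit_metrics$rmse,
                if (is.na(x$fit_metrics$mape)) "" else
                  sprintf(", MAPE %.1f%%", x$fit_metrics$mape)))
  }
  invisible(x)
}

#' @export
summary.panicle_poly <- function(object, ...) {
  cat(sprintf("Polynomial calibration, degree %d; %d train / %d test panicles\n",
              object$degree, object$n_train, object$n_test))
  print(coef(object))
  if (!is.null(object$fit_metrics)) print(object$fit_metrics)
  invisible(object)
}

#' @export
plot.panicle_poly <- function(x, ...) {
  xx <- c(x$train_data$x, x$test_data$x)
  yy <- c(x$train_data$y, x$test_data$y)
  graphics::plot(xx, yy, xlab = "one-side visible count (density estimate)",
                 ylab = "observed whole-panicle grains",
                 col = c(rep("steelblue", nrow(x$train_data)),
                         rep("firebrick", nrow(x$test_data))), ...)
  xs <- seq(min(xx), max(xx), length.out = 200)
  graphics::lines(xs, predict_total(x, xs), lwd = 2, col = "red")
  graphics::legend("topleft", c("train", "test", "fitted model"),
                   col = c("steelblue", "firebrick", "red"),
                   pch = c(1, 1, NA), lty = c(NA, NA, 1), bty = "n")
  invisible(x)
}

#' Persist / restore a fitted calibration model as JSON
#'
#' @param model a `panicle_poly`.
#' @param path JSON path.
#' @export
write_panicle_model <- function(model, path) {
  stopifnot(inherits(model, "panicle_poly"))
  m <- model$fit_metrics
  jsonlite::write_json(
    list(degree = model$degree, coefficients = model$coefficients,
         n_train = model$n_train, n_test = model$n_test,
         seed = model$seed,
         metrics = if (!is.null(m)) list(n = m$n, mae = m$mae, mse = m$mse,
                                         rmse = m$rmse, mape = m$mape,
                                         r2 = m$r2)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_panicle_model
#' @export
read_panicle_model <- function(path) {
  if (!file.exists(path)) fail_io("model file not found: %s", path)
  js <- jsonlite::fromJSON(path)
  structure(list(degree = js$degree, coefficients = js$coefficients,
                 fit_metrics = NULL, n_train = js$n_train, n_test = js$n_test,
                 seed = js$seed,
                 train_data = data.frame(x = numeric(0), y = numeric(0)),
                 test_data = data.frame(x = numeric(0), y = numeric(0))),
            class = "panicle_poly")
}
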