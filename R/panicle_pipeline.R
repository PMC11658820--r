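# Whole-panicle estimation: mask the background, cut the panicle into three
# equal-height patches, predict a density map per patch and integrate, sum
# the three patch counts into the one-side visible count, and calibrate a
# polynomial model from visible count to the machine-counted whole-panicle
# total. Panicle symmetry is assessed by comparing the two opposite-side
# visible counts.

#' Zero out the background of a masked image
#'
#' @param img an [image_record()] carrying a mask.
#' @return an [image_record()] with background pixels set to 0 in all
#'   channels; foreground pixels untouched.
#' @export
apply_mask <- function(img) {
  stopifnot(inherits(img, "image_record"))
  if (is.null(img$mask)) fail_validation("image %s has no mask", img$image_id)
  px <- img$pixels
  for (ch in 1:3) px[, , ch] <- px[, , ch] * img$mask
  image_record(img$image_id, px, img$mask)
}

#' Cut an image into three equal-height patches
#'
#' Heights are `(floor(H/3), floor(H/3), H - 2*floor(H/3))`: any remainder
#' rows go to the bottom patch. Patches are returned both at original
#' resolution (for exact reassembly) and resized to `target_size`.
#'
#' @param img an [image_record()] (or H x W x 3 array).
#' @param target_size `(H, W)` for the resized patches, default 224 x 224.
#' @return object of class `patch_set`: `patches` (3 resized arrays), `raw`
#'   (3 original-resolution arrays), `heights`, `width`.
#' @export
split_patches <- function(img, target_size = c(224L, 224L)) {
  px <- if (inherits(img, "image_record")) img$pixels else img
  H <- dim(px)[1]; W <- dim(px)[2]
  if (H < 3) fail_validation("image height %d < 3: cannot cut into thirds", H)
  h1 <- H %/% 3L
  heights <- c(h1, h1, H - 2L * h1)
  starts <- c(1L, h1 + 1L, 2L * h1 + 1L)
  raw <- lapply(1:3, function(i) {
    px[starts[i]:(starts[i] + heights[i] - 1L), , , drop = FALSE]
  })
  patches <- lapply(raw, resize_image, out_h = target_size[1],
                    out_w = target_size[2])
  structure(list(patches = patches, raw = raw, heights = heights, width = W,
                 image_id = if (inherits(img, "image_record")) img$image_id else NA),
            class = "patch_set")
}

#' Split point annotations along the three-patch cut
#'
#' @param ps a [point_set()] on the full image.
#' @param heights the three patch heights (from [split_patches()]).
#' @return list of three [point_set()]s in patch-local coordinates.
#' @export
split_patch_annotations <- function(ps, heights) {
  stopifnot(inherits(ps, "point_set"), length(heights) == 3)
  offs <- c(0, cumsum(heights))[1:3]
  lapply(1:3, function(i) {
    if (nrow(ps$points) > 0) {
      keep <- ps$points[, 2] >= offs[i] & ps$points[, 2] < offs[i] + heights[i]
      pts <- ps$points[keep, , drop = FALSE]
      pts[, 2] <- pts[, 2] - offs[i]
    } else {
      pts <- ps$points
    }
    point_set(sprintf("%s_p%d", ps$image_id, i), ps$width, heights[i], pts)
  })
}

#' Estimate the visible grain count of one panicle side
#'
#' Masks the image, cuts it into three patches, predicts a density map per
#' patch with the network and integrates each; the side's visible count is
#' the sum of the three patch integrals.
#'
#' @param img an [image_record()] with a mask.
#' @param net a trained `sorghum_net`.
#' @param side side label recorded in the estimate (`"A"` or `"B"`).
#' @return object of class `grain_count_estimate` with `per_patch` (3
#'   floats) and `total_visible` (their sum).
#' @export
count_panicle_side <- function(img, net, side = "A") {
  stopifnot(inherits(net, "sorghum_net"))
  masked <- apply_mask(img)
  hw <- net$arch$input_size[1:2]
  pset <- split_patches(masked, target_size = hw)
  per_patch <- vapply(pset$patches, function(p) {
    count_from_density(predict_density(net, p))
  }, numeric(1))
  structure(list(image_id = img$image_id, side = side,
                 per_patch = per_patch, total_visible = sum(per_patch)),
            class = "grain_count_estimate")
}

#' @export
print.grain_count_estimate <- function(x, ...) {
  cat(sprintf("<grain_count_estimate> %s side %s: %.1f + %.1f + %.1f = %.1f grains\n",
              x$image_id, x$side, x$per_patch[1], x$per_patch[2],
              x$per_patch[3], x$total_visible))
  invisible(x)
}

#' One panicle with both sides and the observed total
#'
#' @param panicle_id identifier.
#' @param estimate_A,estimate_B [count_panicle_side()] results (or numeric
#'   visible totals) for the two opposite sides.
#' @param observed_total machine-counted whole-panicle grain number (> 0).
#' @return object of class `panicle_record`.
#' @export
panicle_record <- function(panicle_id, estimate_A, estimate_B, observed_total) {
  tv <- function(e) if (inherits(e, "grain_count_estimate")) e$total_visible else
    as.numeric(e)
  if (is.na(observed_total) || observed_total <= 0) {
    fail_validation("panicle %s: observed_total must be > 0", panicle_id)
  }
  structure(list(panicle_id = as.character(panicle_id),
                 visible_A = tv(estimate_A), visible_B = tv(estimate_B),
                 observed_total = as.numeric(observed_total)),
            class = "panicle_record")
}

#' Panicle symmetry report
#'
#' MAE, MSE and RMSE between the side-A and side-B visible-count estimates
#' over a set of panicles; small values mean the two faces of the panicle
#' carry similar grain numbers.
#'
#' @param records list of [panicle_record()]s, or a data.frame with columns
#'   `panicle_id`, `visible_A`, `visible_B`.
#' @return a `count_metrics` object (A as reference, B as comparison).
#' @export
symmetry_report <- function(records) {
  if (is.data.frame(records)) {
    a <- records$visible_A; b <- records$visible_B; ids <- records$panicle_id
  } else {
    a <- vapply(records, function(r) r$visible_A %||% NA_real_, numeric(1))
    b <- vapply(records, function(r) r$visible_B %||% NA_real_, numeric(1))
    ids <- vapply(records, function(r) r$panicle_id, character(1))
  }
  miss <- which(is.na(a) | is.na(b))
  if (length(miss) > 0) {
    fail_validation("missing side estimate(s) for panicle(s): %s",
                    paste(head(ids[miss], 10), collapse = ", "))
  }
  evaluate_counts(a, b, mape = all(a > 0))
}
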