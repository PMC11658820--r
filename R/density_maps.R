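# Ground-truth density maps: unit impulses at annotated grain centres,
# smoothed with a normalized Gaussian. With the reflect boundary the map's
# integral equals the number of points exactly, so counting reduces to
# summing pixels.

#' Density-map configuration
#'
#' @param target_size `(H, W)` of the density grid, default 224 x 224.
#' @param sigma Gaussian standard deviation in pixels (default 5).
#' @param boundary_mode `"reflect"` (mass-conserving, default) or
#'   `"constant"` (zero padding; kernel mass can leak at edges).
#' @return object of class `density_map_config`.
#' @export
density_map_config <- function(target_size = c(224L, 224L), sigma = 5,
                               boundary_mode = c("reflect", "constant")) {
  boundary_mode <- match.arg(boundary_mode)
  if (sigma <= 0) fail_validation("sigma must be > 0")
  if (length(target_size) != 2 || any(target_size <= 0)) {
    fail_validation("target_size must be two positive integers")
  }
  structure(list(target_size = as.integer(target_size), sigma = sigma,
                 boundary_mode = boundary_mode),
            class = "density_map_config")
}

#' Rescale point annotations to a new image size
#'
#' Coordinates are scaled by the per-axis size ratio and clamped into
#' `[0, target - 1]`; the point set's dimensions are updated.
#'
#' @param ps a [point_set()].
#' @param target_size `(H, W)` target size in pixels.
#' @return a rescaled [point_set()].
#' @export
rescale_points <- function(ps, target_size = c(224L, 224L)) {
  stopifnot(inherits(ps, "point_set"))
  if (ps$width <= 0 || ps$height <= 0) {
    fail_validation("source image has zero dimension")
  }
  th <- target_size[1]; tw <- target_size[2]
  pts <- ps$points
  if (nrow(pts) > 0) {
    pts[, 1] <- clamp(pts[, 1] * (tw / ps$width), 0, tw - 1)
    pts[, 2] <- clamp(pts[, 2] * (th / ps$height), 0, th - 1)
  }
  point_set(ps$image_id, tw, th, pts)
}

#' Build a ground-truth density map from point annotations
#'
#' Each point contributes a unit impulse at its nearest pixel (collisions
#' accumulate); the impulse grid is then filtered with a normalized Gaussian
#' of `cfg$sigma`, truncated at 4 sigma. Points must already be in the target
#' coordinate system (see [rescale_points()]).
#'
#' @param ps a [point_set()] with coordinates on the target grid.
#' @param cfg a [density_map_config()].
#' @return object of class `density_map` with fields `values`
#'   (H x W, non-negative), `source_image_id` and `n_points`.
#' @export
build_density_map <- function(ps, cfg = density_map_config()) {
  stopifnot(inherits(ps, "point_set"))
  H <- cfg$target_size[1]; W <- cfg$target_size[2]
  n <- nrow(ps$points)
  if (n > 0) {
    px <- round(ps$points[, 1]); py <- round(ps$points[, 2])
    # a coordinate in [W - 0.5, W) is a valid point whose impulse lands on
    # the last pixel; only genuinely out-of-grid points are an error
    px[ps$points[, 1] < W & px > W - 1] <- W - 1
    py[ps$points[, 2] < H & py > H - 1] <- H - 1
    bad <- which(px < 0 | px > W - 1 | py < 0 | py > H - 1)
    if (length(bad) > 0) {
      fail_validation("point(s) fall outside the %d x %d grid after rounding: %s",
                      H, W, paste(head(bad, 20), collapse = ", "))
    }
    lin <- py + 1 + H * px           # 1-based column-major index
    impulses <- matrix(tabulate(lin, H * W), H, W)
  } else {
    impulses <- matrix(0, H, W)
  }
  values <- if (n > 0) {
    gaussian_filter_2d(impulses, cfg$sigma, mode = cfg$boundary_mode)
  } else impulses
  values[values < 0] <- 0   # clip tiny negative rounding residue
  structure(list(values = values, source_image_id = ps$image_id, n_points = n),
            class = "density_map")
}

#' Count grains by integrating a density map
#'
#' @param dm a `density_map` or a bare numeric matrix.
#' @return the sum of all pixel values (a float; fractional counts are
#'   expected from model predictions).
#' @export
count_from_density <- function(dm) {
  v <- if (inherits(dm, "density_map")) dm$values else dm
  if (!is.numeric(v)) fail_validation("count_from_density expects a numeric grid")
  if (any(!is.finite(v))) fail_validation("density grid contains NaN/Inf")
  sum(v)
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %s: %d x %d, %d point(s), integral %.4f\n",
              x$source_image_id, nrow(x$values), ncol(x$values),
              x$n_points, sum(x$values)))
  invisible(x)
}

#' @export
plot.density_map <- function(x, ...) {
  v <- x$values
  graphics::image(t(v)[, nrow(v):1], col = grDevices::hcl.colors(64, "inferno"),
                  axes = FALSE, asp = nrow(v) / ncol(v),
                  main = sprintf("%s (integral %.1f)", x$source_image_id, sum(v)), ...)
  invisible(x)
}

#' Persist a density map (32-bit floats plus JSON sidecar)
#'
#' @param dm a `density_map`.
#' @param path output path for the raw float32 array (little-endian,
#'   column-major); a `<path>.json` sidecar stores id, dimensions and count.
#' @param sigma value recorded in the sidecar for provenance.
#' @export
write_density_map <- function(dm, path, sigma = NA) {
  stopifnot(inherits(dm, "density_map"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(dm$values), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(image_id = dm$source_image_id, n_points = dm$n_points,
         height = nrow(dm$values), width = ncol(dm$values), sigma = sigma),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a density map written by [write_density_map()]
#' @param path path of the raw float32 file.
#' @return a `density_map`.
#' @export
read_density_map <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(meta_path)) {
    fail_io("density map or sidecar missing: %s(.json)", path)
  }
  meta <- jsonlite::fromJSON(meta_path)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = meta$height * meta$width, size = 4,
               endian = "little")
  structure(list(values = matrix(v, meta$height, meta$width),
                 source_image_id = meta$image_id, n_points = meta$n_points),
            class = "density_map")
}
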