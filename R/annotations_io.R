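# I/O for images, LabelMe-style point annotations, masks, dataset manifests
# and run configuration.
#
# Coordinate convention throughout the package (LabelMe's): 0-based, x is the
# pixel column, y the pixel row, origin at the top-left corner.

#' Point-annotation set
#'
#' One coordinate per visible grain of a single image, plus the image size.
#'
#' @param image_id character scalar identifying the image.
#' @param width,height image dimensions in pixels.
#' @param points numeric n x 2 matrix of (x, y) coordinates, 0-based,
#'   x = column, y = row, origin top-left. Duplicates are allowed.
#' @return an object of class `point_set`.
#' @export
point_set <- function(image_id, width, height, points = NULL) {
  if (is.null(points) || length(points) == 0) {
    points <- matrix(numeric(0), ncol = 2)
  }
  points <- as.matrix(points)
  if (ncol(points) != 2) fail_validation("points must be an n x 2 matrix")
  colnames(points) <- c("x", "y")
  width <- as.numeric(width); height <- as.numeric(height)
  if (width <= 0 || height <= 0) {
    fail_validation("image dimensions must be positive (got %g x %g)", width, height)
  }
  if (nrow(points) > 0) {
    bad <- which(points[, 1] < 0 | points[, 1] >= width |
                 points[, 2] < 0 | points[, 2] >= height)
    if (length(bad) > 0) {
      fail_validation("point(s) outside image bounds at indices: %s",
                      paste(head(bad, 20), collapse = ", "))
    }
  }
  structure(list(image_id = as.character(image_id), width = width,
                 height = height, points = points),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %s: %d point(s) in %g x %g px\n",
              x$image_id, nrow(x$points), x$width, x$height))
  invisible(x)
}

#' Read point annotations from a LabelMe-dialect JSON file
#'
#' Shapes with `shape_type == "point"` become annotation points; any other
#' shape types are ignored with a warning. Image dimensions come from the
#' file's `imageWidth`/`imageHeight` fields.
#'
#' @param path path to the JSON file.
#' @return a [point_set()].
#' @export
read_point_annotations <- function(path) {
  if (!file.exists(path)) fail_io("annotation file not found: %s", path)
  js <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) {
                   fail_io("malformed JSON in %s: %s", path, conditionMessage(e))
                 })
  if (is.null(js$imageWidth) || is.null(js$imageHeight)) {
    fail_validation("%s: missing imageWidth/imageHeight", path)
  }
  shapes <- js$shapes %||% list()
  types <- vapply(shapes, function(s) s$shape_type %||% "", character(1))
  skipped <- sum(types != "point")
  if (skipped > 0) {
    warning(sprintf("%s: ignoring %d non-point shape(s)", path, skipped))
  }
  pts <- shapes[types == "point"]
  coords <- if (length(pts) > 0) {
    t(vapply(pts, function(s) as.numeric(unlist(s$points)[1:2]), numeric(2)))
  } else NULL
  image_id <- if (!is.null(js$imagePath)) {
    tools::file_path_sans_ext(basename(js$imagePath))
  } else {
    tools::file_path_sans_ext(basename(path))
  }
  point_set(image_id, js$imageWidth, js$imageHeight, coords)
}

#' Write point annotations as LabelMe-dialect JSON
#'
#' @param ps a [point_set()].
#' @param path output path; the result round-trips through
#'   [read_point_annotations()] with coordinates preserved to full precision.
#' @export
write_point_annotations <- function(ps, path) {
  stopifnot(inherits(ps, "point_set"))
  shapes <- lapply(seq_len(nrow(ps$points)), function(i) {
    list(label = "grain",
         points = list(as.numeric(ps$points[i, ])),
         group_id = NULL,
         shape_type = "point",
         flags = structure(list(), names = character(0)))
  })
  js <- list(version = "5.0.1",
             flags = structure(list(), names = character(0)),
             shapes = shapes,
             imagePath = paste0(ps$image_id, ".png"),
             imageData = NULL,
             imageHeight = ps$height,
             imageWidth = ps$width)
  ok <- tryCatch({
    jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, null = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) fail_io("cannot write annotation file: %s", path)
  invisible(path)
}

#' Image record
#'
#' @param image_id character identifier.
#' @param pixels H x W x 3 integer array with values in 0..255.
#' @param mask optional H x W binary matrix (1 = panicle foreground).
#' @return an object of class `image_record`.
#' @export
image_record <- function(image_id, pixels, mask = NULL) {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) fail_validation("pixels must be H x W x 3")
  if (min(pixels) < 0 || max(pixels) > 255) {
    fail_validation("pixel values must lie in [0, 255]")
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), d[1:2])) {
      fail_validation("mask dimensions (%s) do not match image (%s)",
                      paste(dim(mask), collapse = "x"), paste(d[1:2], collapse = "x"))
    }
    mask <- (mask > 0) * 1L
  }
  structure(list(image_id = as.character(image_id), pixels = pixels, mask = mask),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_record> %s: %d x %d px%s\n", x$image_id, d[1], d[2],
              if (is.null(x$mask)) "" else " (with mask)"))
  invisible(x)
}

read_image_array <- function(path) {
  if (!file.exists(path)) fail_io("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      fail_io("JPEG support requires the EBImage package; convert %s to PNG", path)
    }
    img <- EBImage::readImage(path)
    a <- EBImage::imageData(img)
    px <- if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
  } else {
    fail_io("unsupported image format '%s' (use PNG or JPEG): %s", ext, path)
  }
  if (is.null(dim(px)) || length(dim(px)) == 2) {
    px <- array(px, c(dim(px), 1L))
  }
  if (dim(px)[3] == 1) px <- px[, , c(1, 1, 1), drop = FALSE]  # grayscale -> RGB
  if (dim(px)[3] == 2) px <- px[, , c(1, 1, 1), drop = FALSE]  # gray+alpha
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]          # drop alpha
  px
}

#' Load an image (and optionally its mask) from disk
#'
#' PNG natively, JPEG through EBImage when available. Grayscale inputs are
#' replicated to three channels; an alpha channel is dropped.
#'
#' @param path image path (PNG or JPEG).
#' @param mask_path optional path of a single-channel mask image; any nonzero
#'   pixel counts as panicle foreground.
#' @param image_id identifier; defaults to the file name without extension.
#' @return an [image_record()] with integer pixels in 0..255.
#' @export
load_image <- function(path, mask_path = NULL, image_id = NULL) {
  px <- read_image_array(path)
  pixels <- array(as.integer(round(px * 255)), dim(px))
  mask <- if (!is.null(mask_path) && !is.na(mask_path) && nzchar(mask_path)) {
    load_mask(mask_path)
  } else NULL
  image_record(image_id %||% tools::file_path_sans_ext(basename(path)),
               pixels, mask)
}

#' Load a binary mask image
#'
#' @param path path to a mask image; binarized at threshold > 0 so both 0/1
#'   and 0/255 dialects work. Multi-channel inputs use the per-pixel maximum.
#' @return H x W integer matrix of 0/1.
#' @export
load_mask <- function(path) {
  px <- read_image_array(path)
  m <- do.call(pmax, lapply(seq_len(dim(px)[3]), function(ch) px[, , ch]))
  (m > 0) * 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

manifest_columns <- c("image_id", "image", "annotation", "mask", "side",
                      "panicle_id", "observed_total")

#' Read a dataset manifest (CSV)
#'
#' Columns: `image_id,image,annotation,mask,side,panicle_id,observed_total`.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @param check_paths verify that every referenced file exists.
#' @return a data.frame of class `dataset_manifest`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) fail_io("manifest not found: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(manifest_columns, names(m))
  if (length(missing) > 0) {
    fail_validation("manifest %s lacks column(s): %s", path,
                    paste(missing, collapse = ", "))
  }
  m$observed_total <- suppressWarnings(as.numeric(m$observed_total))
  root <- dirname(normalizePath(path))
  for (col in c("image", "annotation", "mask")) {
    has <- !is.na(m[[col]]) & nzchar(m[[col]])
    rel <- has & !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(root, m[[col]][rel])
    m[[col]][!has] <- NA_character_
  }
  if (anyDuplicated(m$image_id)) {
    fail_validation("manifest %s: duplicate image_id values", path)
  }
  if (check_paths) {
    for (col in c("image", "annotation", "mask")) {
      p <- m[[col]][!is.na(m[[col]])]
      bad <- p[!file.exists(p)]
      if (length(bad) > 0) {
        fail_io("manifest %s references missing %s file(s), e.g. %s",
                path, col, bad[1])
      }
    }
  }
  class(m) <- c("dataset_manifest", "data.frame")
  m
}

#' Write a dataset manifest (CSV)
#'
#' @param manifest data.frame with the manifest columns.
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  missing <- setdiff(manifest_columns, names(manifest))
  if (length(missing) > 0) {
    fail_validation("manifest lacks column(s): %s", paste(missing, collapse = ", "))
  }
  out <- as.data.frame(manifest)[, union(manifest_columns, names(manifest))]
  # store file paths relative to the manifest's own directory so the
  # dataset folder stays relocatable
  root <- paste0(normalizePath(dirname(path), mustWork = FALSE), "/")
  for (col in c("image", "annotation", "mask")) {
    out[[col]] <- as.character(out[[col]])
    has <- !is.na(out[[col]]) & nzchar(out[[col]])
    p <- suppressWarnings(normalizePath(out[[col]][has], mustWork = FALSE))
    rel <- startsWith(p, root)
    p[rel] <- substring(p[rel], nchar(root) + 1)
    out[[col]][has] <- p
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Default run configuration
#'
#' Defaults follow the study protocol: density-map sigma 5 px on a 224 x 224
#' grid, batch size 8, learning rate 0.001, at most 200 epochs with early
#' stopping patience 20, 40 augmentation variants per source image.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    sigma = 5,
    target_size = c(224L, 224L),
    boundary_mode = "reflect",
    batch_size = 8L,
    learning_rate = 0.001,
    max_epochs = 200L,
    patience = 20L,
    variants_per_image = 40L,
    degree = 2L,
    split_fraction = 0.8,
    split_level = "source",
    train_fraction = 0.7,
    input_size = c(224L, 224L),
    upsample_mode = "nearest",
    final_activation = "relu",
    seed = 1L
  )
}

#' Load a run configuration from a YAML key-value file
#'
#' Unset keys take the defaults of [default_config()]; unknown keys raise an
#' error listing the valid ones.
#'
#' @param path path to a YAML (key: value) text file.
#' @return named list of class `run_config`.
#' @export
load_config <- function(path) {
  defaults <- default_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) fail_io("config file not found: %s", path)
    user <- yaml::read_yaml(path) %||% list()
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    fail_validation("unknown config key(s): %s\nvalid keys: %s",
                    paste(unknown, collapse = ", "),
                    paste(names(defaults), collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, user)
  if (cfg$sigma <= 0) fail_validation("config: sigma must be > 0")
  if (any(cfg$target_size <= 0) || any(cfg$input_size <= 0)) {
    fail_validation("config: sizes must be positive")
  }
  if (cfg$batch_size < 1) fail_validation("config: batch_size must be >= 1")
  if (cfg$learning_rate <= 0) fail_validation("config: learning_rate must be > 0")
  if (cfg$patience >= cfg$max_epochs && cfg$max_epochs > 1) {
    cfg$patience <- min(cfg$patience, cfg$max_epochs - 1L)
  }
  if (!cfg$split_level %in% c("source", "record")) {
    fail_validation("config: split_level must be 'source' or 'record'")
  }
  structure(cfg, class = c("run_config", "list"))
}
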