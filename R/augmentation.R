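# Annotation-consistent data augmentation. Photometric operations (hue and
# saturation shifts, Gaussian noise, blur, channel inversion, contrast,
# additive value) touch pixels only; geometric operations (rotation about the
# image centre, horizontal/vertical flips) are applied identically to pixels,
# mask and point coordinates. Density maps are regenerated from transformed
# points afterwards, never warped as images, so the count/integral identity
# survives augmentation.

#' Augmentation configuration
#'
#' @param variants_per_image number of augmented variants generated per
#'   source image (default 40, which expands 120 sources into 4,800 images).
#' @param rotation_range maximum absolute rotation in degrees (default 25).
#' @param flip which flips may be drawn: any of `"horizontal"`, `"vertical"`.
#' @param p_rotate,p_flip probability of applying a rotation / each flip.
#' @param photometric named list of photometric op settings; each entry has a
#'   probability `p` and a magnitude field. Defaults: hue shift +-0.1,
#'   saturation scale +-10%, Gaussian noise sd <= 10 intensity units, blur
#'   sigma <= 2 px, channel inversion p = 0.05, contrast x\[0.8, 1.2\],
#'   additive value +-20.
#' @param seed integer seed making dataset expansion deterministic.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(variants_per_image = 40L,
                           rotation_range = 25,
                           flip = c("horizontal", "vertical"),
                           p_rotate = 0.7,
                           p_flip = 0.5,
                           photometric = list(
                             hue = list(p = 0.5, range = 0.1),
                             saturation = list(p = 0.5, range = 0.1),
                             noise = list(p = 0.3, sd = 10),
                             blur = list(p = 0.3, sigma = 2),
                             invert = list(p = 0.05),
                             contrast = list(p = 0.5, range = c(0.8, 1.2)),
                             value = list(p = 0.5, range = 20)),
                           seed = 1L) {
  if (variants_per_image < 1) fail_validation("variants_per_image must be >= 1")
  probs <- c(p_rotate, p_flip, vapply(photometric, function(o) o$p, numeric(1)))
  if (any(probs < 0 | probs > 1)) fail_validation("probabilities must lie in [0, 1]")
  flip <- match.arg(flip, c("horizontal", "vertical"), several.ok = TRUE)
  structure(list(variants_per_image = as.integer(variants_per_image),
                 rotation_range = rotation_range, flip = flip,
                 p_rotate = p_rotate, p_flip = p_flip,
                 photometric = photometric, seed = as.integer(seed)),
            class = "augment_config")
}

# Rotate an image array by `theta` radians about its centre (output canvas
# unchanged, nearest-neighbour resampling, fill value 0).
rotate_image_array <- function(px, theta) {
  d <- dim(px); H <- d[1]; W <- d[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  xs <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  ys <- matrix(seq_len(H), H, W) - cy
  # inverse map: source = R(-theta) . dest
  sx <- round(cos(theta) * xs + sin(theta) * ys + cx)
  sy <- round(-sin(theta) * xs + cos(theta) * ys + cy)
  ok <- sx >= 1 & sx <= W & sy >= 1 & sy <= H
  idx <- ifelse(ok, sy + H * (sx - 1), NA)
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    plane <- px[, , ch]
    o <- plane[idx]
    o[!ok] <- 0
    out[, , ch] <- o
  }
  out
}

# Rotate 0-based point coordinates by `theta` about the pixel-centre of the
# image; forward transform matching rotate_image_array's inverse map.
rotate_points_xy <- function(pts, theta, width, height) {
  if (nrow(pts) == 0) return(pts)
  cx <- (width - 1) / 2; cy <- (height - 1) / 2
  dx <- pts[, 1] - cx; dy <- pts[, 2] - cy
  cbind(x = cos(theta) * dx - sin(theta) * dy + cx,
        y = sin(theta) * dx + cos(theta) * dy + cy)
}

apply_photometric <- function(px, cfg) {
  ph <- cfg$photometric
  if (!is.null(ph$hue) || !is.null(ph$saturation)) {
    do_h <- !is.null(ph$hue) && runif(1) < ph$hue$p
    do_s <- !is.null(ph$saturation) && runif(1) < ph$saturation$p
    if (do_h || do_s) {
      d <- dim(px)
      rgbm <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
      hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 255)
      if (do_h) hsv[1, ] <- (hsv[1, ] + runif(1, -ph$hue$range, ph$hue$range)) %% 1
      if (do_s) hsv[2, ] <- clamp(hsv[2, ] * (1 + runif(1, -ph$saturation$range,
                                                        ph$saturation$range)), 0, 1)
      rgb2 <- hsv_to_rgb(hsv[1, ], hsv[2, ], hsv[3, ]) * 255
      px <- array(rgb2, c(d[1], d[2], 3))
    }
  }
  if (!is.null(ph$noise) && runif(1) < ph$noise$p) {
    px <- px + array(rnorm(length(px), 0, runif(1, 0, ph$noise$sd)), dim(px))
  }
  if (!is.null(ph$blur) && runif(1) < ph$blur$p) {
    s <- runif(1, 0.3, ph$blur$sigma)
    for (ch in 1:3) px[, , ch] <- gaussian_filter_2d(px[, , ch], s)
  }
  if (!is.null(ph$invert) && runif(1) < ph$invert$p) {
    px <- 255 - px
  }
  if (!is.null(ph$contrast) && runif(1) < ph$contrast$p) {
    f <- runif(1, ph$contrast$range[1], ph$contrast$range[2])
    px <- (px - 127.5) * f + 127.5
  }
  if (!is.null(ph$value) && runif(1) < ph$value$p) {
    px <- px + runif(1, -ph$value$range, ph$value$range)
  }
  clamp(px, 0, 255)
}

#' Augment an image/annotation pair consistently
#'
#' Draws one random variant. Photometric ops alter only pixels; geometric
#' ops transform pixels, the mask (if present) and point coordinates with the
#' same parameters. Points rotated out of the canvas are dropped.
#'
#' @param img an [image_record()].
#' @param ps the matching [point_set()].
#' @param cfg an [augment_config()].
#' @param seed optional integer; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return list with elements `img` (new [image_record()]), `ps` (new
#'   [point_set()]) and `ops` (character vector of the ops applied).
#' @export
augment_pair <- function(img, ps, cfg = augment_config(), seed = NULL) {
  stopifnot(inherits(img, "image_record"), inherits(ps, "point_set"))
  with_seed(seed, {
    px <- apply_photometric(array(as.numeric(img$pixels), dim(img$pixels)), cfg)
    mask <- img$mask
    pts <- ps$points
    H <- dim(px)[1]; W <- dim(px)[2]
    ops <- character(0)

    if (cfg$rotation_range > 0 && runif(1) < cfg$p_rotate) {
      theta <- runif(1, -cfg$rotation_range, cfg$rotation_range) * pi / 180
      px <- rotate_image_array(px, theta)
      if (!is.null(mask)) {
        mask <- rotate_image_array(array(mask, c(H, W, 1)), theta)[, , 1]
      }
      pts <- rotate_points_xy(pts, theta, W, H)
      keep <- pts[, 1] >= 0 & pts[, 1] <= W - 1 & pts[, 2] >= 0 & pts[, 2] <= H - 1
      pts <- pts[keep, , drop = FALSE]
      ops <- c(ops, sprintf("rotate(%.2f deg)", theta * 180 / pi))
    }
    if ("horizontal" %in% cfg$flip && runif(1) < cfg$p_flip) {
      px <- px[, W:1, , drop = FALSE]
      if (!is.null(mask)) mask <- mask[, W:1, drop = FALSE]
      # coordinates live in [0, W): reflecting about the pixel-centre axis
      # can overshoot by under one pixel at the right edge, so clamp
      if (nrow(pts) > 0) pts[, 1] <- clamp(W - 1 - pts[, 1], 0, W - 1)
      ops <- c(ops, "hflip")
    }
    if ("vertical" %in% cfg$flip && runif(1) < cfg$p_flip) {
      px <- px[H:1, , , drop = FALSE]
      if (!is.null(mask)) mask <- mask[H:1, , drop = FALSE]
      if (nrow(pts) > 0) pts[, 2] <- clamp(H - 1 - pts[, 2], 0, H - 1)
      ops <- c(ops, "vflip")
    }
    if (nrow(pts) == 0 && nrow(ps$points) > 0) {
      sn_log("augment_pair: all %d point(s) left the frame for %s",
             nrow(ps$points), ps$image_id)
    }
    list(img = image_record(img$image_id, array(as.integer(round(px)), dim(px)),
                            mask),
         ps = point_set(ps$image_id, W, H, pts),
         ops = ops)
  })
}

#' Expand a dataset by augmentation
#'
#' Each source record yields `cfg$variants_per_image` augmented records; the
#' originals are not kept (40 variants turn 120 sources into 4,800 images).
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param manifest a `dataset_manifest` whose records all have annotations.
#' @param cfg an [augment_config()].
#' @param out_dir directory for augmented PNGs and JSON annotations.
#' @return the manifest of augmented records (also written to
#'   `out_dir/manifest.csv`), with a `source_id` column naming each record's
#'   source image.
#' @export
expand_dataset <- function(manifest, cfg = augment_config(), out_dir) {
  no_ann <- is.na(manifest$annotation) | !nzchar(manifest$annotation)
  if (any(no_ann)) {
    fail_validation("record(s) without annotation: %s",
                    paste(head(manifest$image_id[no_ann], 5), collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(manifest) * cfg$variants_per_image)
  k <- 0
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    img <- load_image(rec$image, if (!is.na(rec$mask)) rec$mask,
                      image_id = rec$image_id)
    ps <- read_point_annotations(rec$annotation)
    for (v in seq_len(cfg$variants_per_image)) {
      out <- augment_pair(img, ps, cfg, seed = derive_seed(cfg$seed, i, v))
      aid <- sprintf("%s_aug%03d", rec$image_id, v)
      img_path <- file.path(out_dir, paste0(aid, ".png"))
      ann_path <- file.path(out_dir, paste0(aid, ".json"))
      png::writePNG(out$img$pixels / 255, img_path)
      aps <- out$ps; aps$image_id <- aid
      write_point_annotations(aps, ann_path)
      mask_path <- NA_character_
      if (!is.null(out$img$mask)) {
        mask_path <- file.path(out_dir, paste0(aid, "_mask.png"))
        png::writePNG(out$img$mask + 0.0, mask_path)
      }
      k <- k + 1
      rows[[k]] <- data.frame(image_id = aid, image = img_path,
                              annotation = ann_path, mask = mask_path,
                              side = rec$side, panicle_id = rec$panicle_id,
                              observed_total = rec$observed_total,
                              source_id = rec$image_id,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dataset_manifest", "data.frame")
  write_manifest(out, file.path(out_dir, "manifest.csv"))
  out
}

#' Split a dataset into train and test partitions
#'
#' `level = "record"` samples individual records (the study's protocol);
#' `level = "source"` keeps all augmented variants of one source image on the
#' same side, preventing augmented-twin leakage, and is the default.
#'
#' @param manifest a `dataset_manifest` (data.frame).
#' @param fraction training fraction in (0, 1), default 0.8.
#' @param level `"source"` or `"record"`.
#' @param seed integer seed for the random draw.
#' @return list with `train` and `test` manifests (disjoint, exhaustive).
#' @export
split_dataset <- function(manifest, fraction = 0.8,
                          level = c("source", "record"), seed = 1L) {
  level <- match.arg(level)
  if (fraction <= 0 || fraction >= 1) fail_validation("fraction must be in (0, 1)")
  n <- nrow(manifest)
  with_seed(seed, {
    if (level == "record") {
      if (n < 2) fail_validation("need at least 2 records to split")
      idx <- sample.int(n, floor(n * fraction))
    } else {
      groups <- manifest$source_id %||% manifest$image_id
      if (is.null(manifest$source_id) && !is.null(manifest$panicle_id) &&
          any(duplicated(manifest$panicle_id))) {
        groups <- manifest$panicle_id
      }
      ug <- unique(groups)
      if (length(ug) < 2) {
        fail_validation("need at least 2 groups at level='source' (got %d)",
                        length(ug))
      }
      tr_groups <- sample(ug, floor(length(ug) * fraction))
      idx <- which(groups %in% tr_groups)
    }
    list(train = manifest[idx, , drop = FALSE],
         test = manifest[setdiff(seq_len(n), idx), , drop = FALSE])
  })
}
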