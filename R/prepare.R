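# Dataset preparation glue: turn full-panicle scenes into the three-patch
# density-training dataset (mask, cut, carry annotations along), and load a
# patch manifest into (image, density map) training pairs.

#' Cut every scene of a manifest into three annotated patches
#'
#' For each record: load image (+ mask), zero the background, cut into three
#' equal-height patches, split the point annotation accordingly, and write
#' patch PNGs and LabelMe JSONs with a new manifest. Patches are written at
#' original resolution; resizing happens when training pairs are built.
#'
#' @param manifest a `dataset_manifest` of full scenes with annotations.
#' @param out_dir output directory.
#' @return the patch-level `dataset_manifest` (3 records per source record,
#'   with `source_id` tracking provenance), also written to
#'   `out_dir/manifest.csv`.
#' @export
patchify_manifest <- function(manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", 3 * nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    if (is.na(rec$annotation) || !nzchar(rec$annotation)) {
      fail_validation("record %s has no annotation", rec$image_id)
    }
    img <- load_image(rec$image, if (!is.na(rec$mask)) rec$mask,
                      image_id = rec$image_id)
    if (!is.null(img$mask)) img <- apply_mask(img)
    ps <- read_point_annotations(rec$annotation)
    pset <- split_patches(img)
    psl <- split_patch_annotations(ps, pset$heights)
    for (p in 1:3) {
      pid <- sprintf("%s_p%d", rec$image_id, p)
      img_path <- file.path(out_dir, paste0(pid, ".png"))
      ann_path <- file.path(out_dir, paste0(pid, ".json"))
      png::writePNG(pset$raw[[p]] / 255, img_path)
      pps <- psl[[p]]; pps$image_id <- pid
      write_point_annotations(pps, ann_path)
      rows[[3 * (i - 1) + p]] <- data.frame(
        image_id = pid, image = img_path, annotation = ann_path,
        mask = NA_character_, side = rec$side, panicle_id = rec$panicle_id,
        observed_total = rec$observed_total, source_id = rec$image_id,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dataset_manifest", "data.frame")
  write_manifest(out, file.path(out_dir, "manifest.csv"))
  out
}

#' Build (image, density map) training pairs from a patch manifest
#'
#' Images are resized to `input_size` and scaled to `[0, 1]`; annotations
#' are rescaled to the same grid and turned into ground-truth density maps.
#'
#' @param manifest a patch-level `dataset_manifest`.
#' @param input_size `(H, W)` network input size.
#' @param sigma density-map Gaussian sd in pixels.
#' @param boundary_mode density-map boundary handling.
#' @return list of pairs `list(x = H x W x 3 array in [0,1], y = density
#'   matrix, n_points = , image_id = )`.
#' @export
build_training_pairs <- function(manifest, input_size = c(224L, 224L),
                                 sigma = 5, boundary_mode = "reflect") {
  dcfg <- density_map_config(target_size = input_size, sigma = sigma,
                             boundary_mode = boundary_mode)
  lapply(seq_len(nrow(manifest)), function(i) {
    rec <- manifest[i, ]
    img <- load_image(rec$image, image_id = rec$image_id)
    ps <- read_point_annotations(rec$annotation)
    x <- resize_image(img$pixels, input_size[1], input_size[2]) / 255
    dm <- build_density_map(rescale_points(ps, input_size), dcfg)
    list(x = x, y = dm$values, n_points = dm$n_points, image_id = rec$image_id)
  })
}

#' Build and persist ground-truth density maps for a manifest
#'
#' @param manifest a patch-level `dataset_manifest` with annotations.
#' @param out_dir output directory for `.f32` arrays + JSON sidecars.
#' @param cfg a [density_map_config()].
#' @return invisibly, the vector of density-map paths.
#' @export
build_density_dataset <- function(manifest, out_dir,
                                  cfg = density_map_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    ps <- read_point_annotations(rec$annotation)
    dm <- build_density_map(rescale_points(ps, cfg$target_size), cfg)
    paths[i] <- file.path(out_dir, paste0(rec$image_id, ".f32"))
    write_density_map(dm, paths[i], sigma = cfg$sigma)
  }
  invisible(paths)
}
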