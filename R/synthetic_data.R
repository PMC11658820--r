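# Synthetic panicle scenes with exactly known grain annotations. A scene is
# a tapered, spindle-shaped panicle mask on a cluttered background; grains
# are rendered as small anti-aliased elliptical blobs (~8 px across, with
# size/colour jitter) at minimum-separation positions inside the mask, and
# the annotation is the exact list of blob centres. Panicles come in
# opposite-side pairs sharing a machine-counted total; the per-side visible
# count follows a quadratic visibility relation with controllable asymmetry.
# Clutter never overlaps the mask, so the visible ground truth stays exact.

#' Synthetic-scene configuration
#'
#' Defaults emulate the study conditions: whole-panicle totals between 672
#' and 4,156 grains with mean 2,363 (drawn from a truncated normal), grains
#' about 8 px across, and a quadratic visible-to-total relation
#' `total = a*visible^2 + b*visible + c` with Gaussian noise.
#'
#' @param canvas `(H, W)` scene size in pixels.
#' @param grain_diameter nominal grain size in pixels (+-25% jitter).
#' @param total_range inclusive range of whole-panicle totals.
#' @param total_mean,total_sd mean and spread of the truncated-normal total
#'   distribution.
#' @param relation named vector `c(a, b, c)` of the visibility relation
#'   (ascending powers of the visible count are c, b, a).
#' @param sigma_rel relative noise of the visibility relation: the Gaussian
#'   noise sd is `sigma_rel * total`.
#' @param asymmetry relative spread between the two sides' visible counts
#'   (sd of the symmetric +-delta/2 split).
#' @param clutter background clutter level in `[0, 1]` (0 = plain).
#' @param seed default seed for generation helpers.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(canvas = c(896L, 448L), grain_diameter = 8,
                         total_range = c(672L, 4156L), total_mean = 2363,
                         total_sd = 580,
                         relation = c(a = 2e-4, b = 2, c = 100),
                         sigma_rel = 0.05, asymmetry = 0.1, clutter = 0.5,
                         seed = 1L) {
  if (any(canvas < 32)) fail_validation("canvas must be at least 32 px")
  if (grain_diameter <= 1) fail_validation("grain_diameter must exceed 1 px")
  if (total_range[1] >= total_range[2]) fail_validation("invalid total_range")
  if (sigma_rel < 0 || asymmetry < 0) fail_validation("noise levels must be >= 0")
  structure(list(canvas = as.integer(canvas), grain_diameter = grain_diameter,
                 total_range = as.numeric(total_range),
                 total_mean = total_mean, total_sd = total_sd,
                 relation = c(a = unname(relation["a"] %||% relation[1]),
                              b = unname(relation["b"] %||% relation[2]),
                              c = unname(relation["c"] %||% relation[3])),
                 sigma_rel = sigma_rel, asymmetry = asymmetry,
                 clutter = clutter, seed = as.integer(seed)),
            class = "scene_config")
}

#' Sample whole-panicle totals
#'
#' Truncated-normal draw matching the configured min/mean/max.
#'
#' @param cfg a [scene_config()].
#' @param n number of totals.
#' @param seed optional seed.
#' @return integer vector of totals within `cfg$total_range`.
#' @export
sample_panicle_totals <- function(cfg, n, seed = NULL) {
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      x <- rnorm(max(n, 10), cfg$total_mean, cfg$total_sd)
      out <- c(out, x[x >= cfg$total_range[1] & x <= cfg$total_range[2]])
    }
    round(out[seq_len(n)])
  })
}

# Positive root of a*v^2 + b*v + c = total.
visible_from_total <- function(cfg, total) {
  a <- cfg$relation["a"]; b <- cfg$relation["b"]; cc <- cfg$relation["c"]
  if (abs(a) < 1e-12) return(pmax(1, (total - cc) / b))
  pmax(1, (-b + sqrt(pmax(b^2 - 4 * a * (cc - total), 0))) / (2 * a))
}

#' Sample panicle count records from the visibility relation
#'
#' Draws whole-panicle totals, applies the quadratic visibility relation
#' with Gaussian noise (`sd = sigma_rel * total`) to obtain the mean
#' visible count, and splits it into two sides with the configured
#' asymmetry. The observed total satisfies
#' `observed_total = a*visible^2 + b*visible + c + noise` in terms of the
#' mean visible count.
#'
#' @param cfg a [scene_config()].
#' @param n number of panicles.
#' @param seed optional seed.
#' @return data.frame with columns `panicle_id`, `observed_total`,
#'   `visible_mean`, `visible_A`, `visible_B`.
#' @export
sample_visibility_records <- function(cfg, n, seed = NULL) {
  with_seed(seed, {
    # draw the noise-free relation value from the totals distribution and
    # invert it for the visible count, then add the relation noise on top:
    # the noise is then independent of the visible count, so regressing
    # total on visible recovers the relation without attenuation bias
    signal <- sample_panicle_totals(cfg, n)
    vmean <- visible_from_total(cfg, signal)
    eps <- rnorm(n, 0, cfg$sigma_rel * signal)
    totals <- round(clamp(signal + eps, cfg$total_range[1], cfg$total_range[2]))
    delta <- rnorm(n, 0, cfg$asymmetry)
    va <- pmax(1, round(vmean * (1 + delta / 2)))
    vb <- pmax(1, round(vmean * (1 - delta / 2)))
    data.frame(panicle_id = sprintf("pan%04d", seq_len(n)),
               observed_total = totals, visible_mean = vmean,
               visible_A = va, visible_B = vb, stringsAsFactors = FALSE)
  })
}

# Spindle-shaped panicle mask with mild wobble; returns H x W 0/1 matrix.
make_panicle_mask <- function(H, W) {
  y <- seq_len(H)
  t <- clamp((y - 0.05 * H) / (0.9 * H), 0, 1)
  phi1 <- runif(1, 0, 2 * pi); phi2 <- runif(1, 0, 2 * pi)
  halfw <- 0.5 * 0.75 * W * sin(pi * t)^0.6 * (1 + 0.08 * sin(3 * pi * t + phi1))
  halfw[t <= 0 | t >= 1] <- 0
  cx <- W / 2 + 0.05 * W * sin(2 * pi * t + phi2)
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  m <- (abs(xs - cx) <= halfw) * 1L
  dim(m) <- c(H, W)
  m
}

# Minimum-separation point placement inside a mask: mask pixels are binned
# into a grid of pitch ~0.5 * grain diameter and at most one grain occupies
# a cell, giving Poisson-disk-like spacing.
place_grains <- function(mask, n, pitch) {
  H <- nrow(mask); W <- ncol(mask)
  inside <- which(mask > 0)
  ys <- (inside - 1) %% H + 1
  xs <- (inside - 1) %/% H + 1
  # keep cells whose centre area lies inside the mask
  cell <- (ys %/% pitch) + 100000 * (xs %/% pitch)
  cells <- unique(cell)
  if (length(cells) < n) {
    fail_validation(paste0("requested %d grains but the mask supports only ",
                           "~%d at this density; use a larger canvas"),
                    n, length(cells))
  }
  chosen <- cells[sample.int(length(cells), n)]
  # representative pixel per chosen cell, plus jitter (reverted when the
  # jittered position would leave the mask)
  first_idx <- match(chosen, cell)
  px <- clamp(xs[first_idx] + runif(n, -pitch / 4, pitch / 4), 1, W)
  py <- clamp(ys[first_idx] + runif(n, -pitch / 4, pitch / 4), 1, H)
  ok <- mask[cbind(round(py), round(px))] > 0
  px <- ifelse(ok, px, xs[first_idx])
  py <- ifelse(ok, py, ys[first_idx])
  # 0-based annotation coordinates
  cbind(x = px - 1, y = py - 1)
}

# Paint anti-aliased elliptical grain blobs onto the image (in place).
render_grains <- function(px, centers, diameter) {
  if (nrow(centers) == 0) return(px)
  H <- dim(px)[1]; W <- dim(px)[2]
  base_col <- c(205, 150, 95)
  for (i in seq_len(nrow(centers))) {
    r <- (diameter / 2) * (1 + runif(1, -0.25, 0.25))
    aspect <- runif(1, 0.7, 1)
    ang <- runif(1, 0, pi)
    colr <- clamp(base_col + rnorm(3, 0, 18) + runif(1, -25, 25), 30, 255)
    cx <- centers[i, 1] + 1; cy <- centers[i, 2] + 1   # 1-based
    rr <- ceiling(r) + 1L
    x0 <- max(1L, floor(cx - rr)); x1 <- min(W, ceiling(cx + rr))
    y0 <- max(1L, floor(cy - rr)); y1 <- min(H, ceiling(cy + rr))
    if (x0 > x1 || y0 > y1) next
    gx <- seq(x0, x1) - cx
    gy <- seq(y0, y1) - cy
    u <- outer(gy * 0, gx, "+"); v <- outer(gy, gx * 0, "+")
    ur <- u * cos(ang) + v * sin(ang)
    vr <- -u * sin(ang) + v * cos(ang)
    d <- sqrt((ur / 1)^2 + (vr / aspect)^2)
    cov <- clamp(r - d + 0.5, 0, 1)
    shade <- 1 - 0.35 * clamp((v + r) / (2 * r), 0, 1)   # simple top lighting
    for (ch in 1:3) {
      block <- px[y0:y1, x0:x1, ch]
      px[y0:y1, x0:x1, ch] <- block * (1 - cov) + colr[ch] * shade * cov
    }
  }
  px
}

render_background <- function(H, W, mask, clutter) {
  base <- c(95, 88, 62)
  px <- array(0, c(H, W, 3))
  lowres <- matrix(rnorm(ceiling(H / 8) * ceiling(W / 8), 0, 18),
                   ceiling(H / 8), ceiling(W / 8))
  noise <- resize_image(lowres, H, W)
  for (ch in 1:3) px[, , ch] <- base[ch] + noise + rnorm(H * W, 0, 4)
  if (clutter > 0) {
    # distractor blobs kept clear of the panicle: sample centres where a
    # dilated mask is empty
    dil <- gaussian_filter_2d(mask + 0, 6) > 1e-3
    free <- which(!dil)
    nblob <- round(clutter * 30)
    if (length(free) > 0 && nblob > 0) {
      pick <- free[sample.int(length(free), min(nblob, length(free)))]
      ys <- (pick - 1) %% H + 1; xs <- (pick - 1) %/% H + 1
      for (j in seq_along(pick)) {
        r <- runif(1, 3, 12)
        if (xs[j] - r < 1 || xs[j] + r > W || ys[j] - r < 1 || ys[j] + r > H) next
        # skip blobs that would touch the dilated mask
        xr <- max(1, floor(xs[j] - r)):min(W, ceiling(xs[j] + r))
        yr <- max(1, floor(ys[j] - r)):min(H, ceiling(ys[j] + r))
        if (any(dil[yr, xr])) next
        colb <- clamp(c(70, 110, 55) + rnorm(3, 0, 25), 0, 255)
        u <- outer(yr - ys[j], (xr - xs[j]) * 0, "+")
        v <- outer((yr - ys[j]) * 0, xr - xs[j], "+")
        cov <- clamp(r - sqrt(u^2 + v^2) + 0.5, 0, 1) * 0.8
        for (ch in 1:3) {
          px[yr, xr, ch] <- px[yr, xr, ch] * (1 - cov) + colb[ch] * cov
        }
      }
    }
  }
  px
}

#' Generate one synthetic panicle scene
#'
#' @param cfg a [scene_config()].
#' @param panicle_id identifier stored in the scene.
#' @param side side label, `"A"` or `"B"`.
#' @param visible_count number of grains to render (and annotate); when
#'   `NULL` a fresh visibility record is drawn.
#' @param true_total whole-panicle total recorded with the scene (optional).
#' @param seed optional seed; the same seed reproduces the scene exactly.
#' @return object of class `synthetic_scene` with fields `image`
#'   ([image_record()] with mask), `points` ([point_set()] of exact grain
#'   centres), `side`, `panicle_id`, `true_visible`, `true_total`.
#' @export
generate_scene <- function(cfg = scene_config(), panicle_id = "pan0001",
                           side = "A", visible_count = NULL,
                           true_total = NA, seed = NULL) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(seed, {
    if (is.null(visible_count)) {
      rec <- sample_visibility_records(cfg, 1)
      visible_count <- if (side == "A") rec$visible_A else rec$visible_B
      true_total <- rec$observed_total
    }
    H <- cfg$canvas[1]; W <- cfg$canvas[2]
    mask <- make_panicle_mask(H, W)
    px <- render_background(H, W, mask, cfg$clutter)
    # panicle body: dark reddish brown under the grains
    body <- clamp(c(75, 45, 35) + rnorm(3, 0, 8), 0, 255)
    tex <- matrix(rnorm(H * W, 0, 10), H, W)
    for (ch in 1:3) {
      px[, , ch] <- px[, , ch] * (1 - mask) + (body[ch] + tex) * mask
    }
    centers <- if (visible_count > 0) {
      place_grains(mask, visible_count, pitch = max(2, cfg$grain_diameter / 2))
    } else {
      matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
    }
    px <- render_grains(px, centers, cfg$grain_diameter)
    px <- array(as.integer(round(clamp(px, 0, 255))), c(H, W, 3))
    img_id <- sprintf("%s_%s", panicle_id, side)
    structure(list(image = image_record(img_id, px, mask),
                   points = point_set(img_id, W, H, centers),
                   side = side, panicle_id = panicle_id,
                   true_visible = as.integer(visible_count),
                   true_total = as.numeric(true_total)),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %s (side %s): %d visible grain(s), total %s\n",
              x$panicle_id, x$side, x$true_visible,
              ifelse(is.na(x$true_total), "?", x$true_total)))
  invisible(x)
}

#' Generate a pair of opposite-side scenes of one panicle
#'
#' Both sides share the machine-counted total; their visible counts are
#' split around the visibility relation with the configured asymmetry.
#'
#' @param cfg a [scene_config()].
#' @param panicle_id identifier.
#' @param seed optional seed.
#' @return list with `A`, `B` (two `synthetic_scene`s) and `observed_total`.
#' @export
generate_panicle_pair <- function(cfg = scene_config(), panicle_id = "pan0001",
                                  seed = NULL) {
  with_seed(seed, {
    rec <- sample_visibility_records(cfg, 1)
    A <- generate_scene(cfg, panicle_id, "A", visible_count = rec$visible_A,
                        true_total = rec$observed_total)
    B <- generate_scene(cfg, panicle_id, "B", visible_count = rec$visible_B,
                        true_total = rec$observed_total)
    list(A = A, B = B, observed_total = rec$observed_total)
  })
}

write_scene <- function(scene, out_dir) {
  id <- scene$image$image_id
  img_path <- file.path(out_dir, paste0(id, ".png"))
  mask_path <- file.path(out_dir, paste0(id, "_mask.png"))
  ann_path <- file.path(out_dir, paste0(id, ".json"))
  png::writePNG(scene$image$pixels / 255, img_path)
  png::writePNG(scene$image$mask + 0.0, mask_path)
  write_point_annotations(scene$points, ann_path)
  data.frame(image_id = id, image = img_path, annotation = ann_path,
             mask = mask_path, side = scene$side,
             panicle_id = scene$panicle_id,
             observed_total = scene$true_total, stringsAsFactors = FALSE)
}

#' Generate a synthetic benchmark dataset on disk
#'
#' Writes paired opposite-side scenes (images, masks, LabelMe JSON
#' annotations) plus a manifest CSV; the output is a drop-in input for every
#' other stage of the pipeline. Deterministic for a fixed seed.
#'
#' @param cfg a [scene_config()].
#' @param n_panicles number of panicles (2 images each).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return the `dataset_manifest` (also written to `out_dir/manifest.csv`).
#' @export
generate_benchmark <- function(cfg = scene_config(), n_panicles, out_dir,
                               seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", 2 * n_panicles)
  for (i in seq_len(n_panicles)) {
    pair <- generate_panicle_pair(cfg, sprintf("pan%04d", i),
                                  seed = derive_seed(seed, i))
    rows[[2 * i - 1]] <- write_scene(pair$A, out_dir)
    rows[[2 * i]] <- write_scene(pair$B, out_dir)
  }
  manifest <- do.call(rbind, rows)
  class(manifest) <- c("dataset_manifest", "data.frame")
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
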