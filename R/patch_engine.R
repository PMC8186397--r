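# Patch engine: amplifies a handful of annotated wells into an effectively
# unbounded training set by sampling random sub-patches (10-15% of the
# well side by default) with photometric and geometric augmentation.

#' Construct a patch specification
#'
#' @param x,y Top-left corner in pixels (0-based well coordinates).
#' @param w,h Patch size in pixels.
#' @param image_w,image_h Parent image size, for bounds checking.
#' @return Named numeric vector of class `patch_spec`.
#' @export
patch_spec <- function(x, y, w, h, image_w = Inf, image_h = Inf) {
  if (w < 1 || h < 1 || x < 0 || y < 0 || x + w > image_w || y + h > image_h) {
    stop("invalid patch spec: (", x, ",", y, ") ", w, "x", h,
         " does not fit in ", image_w, "x", image_h)
  }
  structure(c(x = unname(x), y = unname(y), w = unname(w), h = unname(h)),
            class = "patch_spec")
}

admissible_sides <- function(dim, f_min, f_max) {
  lo <- ceiling(f_min * dim)
  hi <- floor(f_max * dim)
  if (lo < 1 || lo > hi) {
    stop("image dimension ", dim, " admits no patch side in [",
         f_min, ", ", f_max, "] of the image")
  }
  c(lo, hi)
}

#' Sample a random training patch
#'
#' Draws a patch whose width and height are independently uniform over the
#' admissible integer sides (`f_min` to `f_max` of the image width and
#' height; default 10-15%), and whose top-left corner is uniform over all
#' valid positions.
#'
#' @param image_w,image_h Well image size in pixels.
#' @param f_min,f_max Side fractions (defaults 0.10, 0.15).
#' @return A [patch_spec()].
#' @export
sample_random_patch <- function(image_w, image_h, f_min = 0.10, f_max = 0.15) {
  stopifnot(f_min > 0, f_min <= f_max, f_max <= 1)
  ws <- admissible_sides(image_w, f_min, f_max)
  hs <- admissible_sides(image_h, f_min, f_max)
  w <- sample.int(ws[2] - ws[1] + 1L, 1L) + ws[1] - 1L
  h <- sample.int(hs[2] - hs[1] + 1L, 1L) + hs[1] - 1L
  x <- sample.int(image_w - w + 1L, 1L) - 1L
  y <- sample.int(image_h - h + 1L, 1L) - 1L
  patch_spec(x, y, w, h, image_w, image_h)
}

#' Count the patch sampling space
#'
#' Exact number of distinct (width, height, x, y) patches the random
#' sampler can produce: `sum_w (W - w + 1) * sum_h (H - h + 1)` over the
#' admissible integer sides. For a 1,000 x 1,000 well at 10-15% this
#' exceeds 1.8e9, the combinatorial basis of training-set amplification.
#'
#' @inheritParams sample_random_patch
#' @return Exact count (double).
#' @examples
#' count_patch_space(1000, 1000, 0.10, 0.15)  # > 1.8e9
#' @export
count_patch_space <- function(image_w, image_h, f_min = 0.10, f_max = 0.15) {
  stopifnot(f_min > 0, f_min <= f_max, f_max <= 1)
  ws <- admissible_sides(image_w, f_min, f_max)
  hs <- admissible_sides(image_h, f_min, f_max)
  sw <- sum(image_w - seq(ws[1], ws[2]) + 1)
  sh <- sum(image_h - seq(hs[1], hs[2]) + 1)
  sw * sh
}

#' Crop a patch with its annotations
#'
#' Clips ground-truth boxes to the patch and re-offsets them to patch
#' coordinates. A clipped box is kept iff its remaining area is at least
#' `keep_threshold` of the original area, which avoids training on slivers
#' of cells cut by the patch boundary while keeping most split cells.
#'
#' @param image Well image (H x W x 3 array).
#' @param boxes Data frame `x_min,y_min,x_max,y_max,class` in well
#'   coordinates (see [well_boxes()]).
#' @param spec A [patch_spec()].
#' @param keep_threshold Minimum clipped/original area ratio (default 0.25).
#' @return A `patch_sample`: list with `image` (the crop), `boxes` (patch
#'   coordinates), and `spec`.
#' @export
crop_with_annotations <- function(image, boxes, spec, keep_threshold = 0.25) {
  sp <- unclass(spec)
  crop <- crop_image(image, sp["x"], sp["y"], sp["w"], sp["h"])
  kept <- clip_boxes(boxes, sp, keep_threshold)
  structure(list(image = crop, boxes = kept, spec = spec),
            class = "patch_sample")
}

clip_boxes <- function(boxes, sp, keep_threshold) {
  if (nrow(boxes) == 0) return(boxes)
  x0 <- sp[["x"]]; y0 <- sp[["y"]]
  x1 <- x0 + sp[["w"]]; y1 <- y0 + sp[["h"]]
  cx_min <- pmax(boxes$x_min, x0)
  cy_min <- pmax(boxes$y_min, y0)
  cx_max <- pmin(boxes$x_max, x1)
  cy_max <- pmin(boxes$y_max, y1)
  cw <- pmax(0, cx_max - cx_min)
  ch <- pmax(0, cy_max - cy_min)
  orig <- (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
  keep <- cw * ch / orig >= keep_threshold & cw > 0 & ch > 0
  out <- boxes[keep, , drop = FALSE]
  out$x_min <- cx_min[keep] - x0
  out$y_min <- cy_min[keep] - y0
  out$x_max <- cx_max[keep] - x0
  out$y_max <- cy_max[keep] - y0
  rownames(out) <- NULL
  out
}

#' Augmentation configuration
#'
#' Photometric distortions (brightness, hue, saturation), vertical flips,
#' and rotations by multiples of 90 degrees. Photometric changes leave
#' boxes untouched; geometric changes remap them exactly; class labels
#' never change.
#'
#' @param brightness_delta Range of additive value change (HSV value
#'   channel), e.g. `c(-0.1, 0.1)`; `NULL` disables.
#' @param hue_delta Range of additive hue rotation (fraction of the hue
#'   circle); `NULL` disables.
#' @param saturation_factor Range of multiplicative saturation change;
#'   `NULL` disables.
#' @param vertical_flip_prob Probability of a vertical flip.
#' @param rotation_set Subset of `c(0, 90, 180, 270)` sampled uniformly.
#' @return List of class `augmentation_config`.
#' @export
augmentation_config <- function(brightness_delta = c(-0.08, 0.08),
                                hue_delta = c(-0.03, 0.03),
                                saturation_factor = c(0.8, 1.2),
                                vertical_flip_prob = 0.5,
                                rotation_set = c(0, 90, 180, 270)) {
  stopifnot(vertical_flip_prob >= 0, vertical_flip_prob <= 1,
            all(rotation_set %in% c(0, 90, 180, 270)))
  structure(list(brightness_delta = brightness_delta, hue_delta = hue_delta,
                 saturation_factor = saturation_factor,
                 vertical_flip_prob = vertical_flip_prob,
                 rotation_set = rotation_set),
            class = "augmentation_config")
}

#' No-op augmentation configuration
#' @return An [augmentation_config()] with every augmentation disabled.
#' @export
no_augmentation <- function() {
  augmentation_config(NULL, NULL, NULL, 0, 0)
}

#' Augment a patch sample
#'
#' Applies (in order) photometric distortion, a random vertical flip, and
#' a random rotation from the configured set. Rotations of 90/270 degrees
#' on non-square patches swap the patch dimensions; boxes are remapped
#' accordingly.
#'
#' @param sample A `patch_sample` from [crop_with_annotations()].
#' @param cfg An [augmentation_config()].
#' @return The augmented `patch_sample`; `$augmentation` records what was
#'   applied.
#' @export
augment <- function(sample, cfg) {
  img <- sample$image
  boxes <- sample$boxes
  rec <- list()
  if (!is.null(cfg$brightness_delta) || !is.null(cfg$hue_delta) ||
      !is.null(cfg$saturation_factor)) {
    dv <- if (is.null(cfg$brightness_delta)) 0 else
      runif(1, cfg$brightness_delta[1], cfg$brightness_delta[2])
    dh <- if (is.null(cfg$hue_delta)) 0 else
      runif(1, cfg$hue_delta[1], cfg$hue_delta[2])
    fs <- if (is.null(cfg$saturation_factor)) 1 else
      runif(1, cfg$saturation_factor[1], cfg$saturation_factor[2])
    img <- photometric_distort(img, dv, dh, fs)
    rec$photometric <- c(brightness = dv, hue = dh, saturation = fs)
  }
  if (runif(1) < cfg$vertical_flip_prob) {
    fl <- flip_vertical(img, boxes)
    img <- fl$image; boxes <- fl$boxes
    rec$vflip <- TRUE
  }
  if (length(cfg$rotation_set) > 0) {
    ang <- cfg$rotation_set[sample.int(length(cfg$rotation_set), 1)]
    if (ang > 0) {
      rt <- rotate90(img, boxes, ang / 90)
      img <- rt$image; boxes <- rt$boxes
    }
    rec$rotation <- ang
  }
  sample$image <- img
  sample$boxes <- boxes
  sample$augmentation <- rec
  sample
}

photometric_distort <- function(img, dv, dh, fs) {
  cpp_photometric(img, dv, dh, fs)
}

# Vertical flip = mirror top-to-bottom (y -> H - y).
flip_vertical <- function(img, boxes) {
  H <- dim(img)[1]
  img <- img[H:1, , , drop = FALSE]
  if (nrow(boxes) > 0) {
    y0 <- boxes$y_min
    boxes$y_min <- H - boxes$y_max
    boxes$y_max <- H - y0
  }
  list(image = img, boxes = boxes)
}

# Rotate image and boxes by k * 90 degrees clockwise.
# 90 deg CW maps a point (x, y) in an H-row image to (H - y, x).
rotate90 <- function(img, boxes, k) {
  k <- k %% 4
  for (i in seq_len(k)) {
    H <- dim(img)[1]
    img <- aperm(img[H:1, , , drop = FALSE], c(2, 1, 3))
    if (nrow(boxes) > 0) {
      x0 <- boxes$x_min; x1 <- boxes$x_max
      boxes$x_min <- H - boxes$y_max
      boxes$x_max <- H - boxes$y_min
      boxes$y_min <- x0
      boxes$y_max <- x1
    }
  }
  list(image = img, boxes = boxes)
}

#' Build a streaming training set from annotated wells
#'
#' Amplifies the wells into `n_patches` training samples: a well is chosen
#' uniformly, a random patch is sampled, ground-truth boxes are clipped,
#' and augmentation is applied. Samples are produced lazily by the
#' returned iterator, and the whole stream is reproducible from `seed`.
#' Random streams are split per stage (well choice/position vs
#' augmentation), so toggling augmentation does not perturb patch
#' positions.
#'
#' @param wells List of `list(image =, boxes =)` with `boxes` as from
#'   [well_boxes()] (well coordinates).
#' @param n_patches Total number of samples the stream yields.
#' @param cfg An [augmentation_config()].
#' @param seed Integer seed.
#' @param f_min,f_max Patch side fractions (defaults 0.10, 0.15).
#' @param keep_threshold Clipped-box keep rule (see
#'   [crop_with_annotations()]).
#' @return A function `nxt()` returning the next `patch_sample` (with
#'   `$well` the source well index) or `NULL` when exhausted; attribute
#'   `n_patches` records the stream length.
#' @export
build_training_set <- function(wells, n_patches, cfg = augmentation_config(),
                               seed = 1L, f_min = 0.10, f_max = 0.15,
                               keep_threshold = 0.25) {
  stopifnot(length(wells) >= 1, n_patches >= 0)
  i <- 0L
  pos_seed <- derive_seed(seed, "patch-position")
  aug_seed <- derive_seed(seed, "patch-augment")
  nxt <- function() {
    if (i >= n_patches) return(NULL)
    i <<- i + 1L
    sample_one_patch(wells,
                     (as.double(pos_seed) + i) %% 2147483563,
                     (as.double(aug_seed) + i) %% 2147483563,
                     cfg, f_min, f_max, keep_threshold)
  }
  attr(nxt, "n_patches") <- n_patches
  nxt
}

sample_one_patch <- function(wells, pos_seed, aug_seed, cfg,
                             f_min, f_max, keep_threshold) {
  smp <- with_seed(pos_seed, {
    wi <- sample.int(length(wells), 1L)
    wl <- wells[[wi]]
    d <- image_dims(wl$image)
    sp <- sample_random_patch(d["width"], d["height"], f_min, f_max)
    s <- crop_with_annotations(wl$image, wl$boxes, sp, keep_threshold)
    s$well <- wi
    s
  })
  with_seed(aug_seed, augment(smp, cfg))
}

#' Write a dataset manifest
#'
#' Drains a training stream, recording one CSV row per sample (well, patch
#' geometry, augmentation descriptor, number of boxes) for audit and
#' reproduction. Intended for modest audit runs, not the full stream.
#'
#' @param stream Iterator from [build_training_set()].
#' @param path Output CSV path.
#' @return The manifest data frame, invisibly.
#' @export
write_dataset_manifest <- function(stream, path) {
  rows <- list()
  repeat {
    s <- stream()
    if (is.null(s)) break
    sp <- unclass(s$spec)
    rows[[length(rows) + 1]] <- data.frame(
      well_id = s$well, x = sp[["x"]], y = sp[["y"]], w = sp[["w"]],
      h = sp[["h"]],
      augmentation = paste(
        c(if (!is.null(s$augmentation$photometric))
            sprintf("photo(%.3f,%.3f,%.3f)",
                    s$augmentation$photometric[1],
                    s$augmentation$photometric[2],
                    s$augmentation$photometric[3]),
          if (isTRUE(s$augmentation$vflip)) "vflip",
          if (!is.null(s$augmentation$rotation))
            paste0("rot", s$augmentation$rotation)),
        collapse = "+"),
      n_boxes = nrow(s$boxes), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
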