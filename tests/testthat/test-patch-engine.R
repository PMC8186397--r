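test_that("patch-space count matches exhaustive enumeration and closed form", {
  # brute-force enumeration oracle on small images
  enumerate_patches <- function(W, H, f_min, f_max) {
    n <- 0
    for (w in seq_len(W)) {
      if (w < ceiling(f_min * W) || w > floor(f_max * W)) next
      for (h in seq_len(H)) {
        if (h < ceiling(f_min * H) || h > floor(f_max * H)) next
        n <- n + (W - w + 1) * (H - h + 1)
      }
    }
    n
  }
  cases <- list(c(20, 30, 0.1, 0.2), c(40, 40, 0.10, 0.15),
                c(33, 17, 0.2, 0.5), c(10, 10, 0.5, 0.5))
  for (cs in cases) {
    expect_equal(count_patch_space(cs[1], cs[2], cs[3], cs[4]),
                 enumerate_patches(cs[1], cs[2], cs[3], cs[4]))
  }
  # single admissible side: 6 positions per axis on a 10 x 10 image
  expect_equal(count_patch_space(10, 10, 0.5, 0.5), 36)
})

test_that("random patches have uniform sides and valid positions", {
  set.seed(31)
  n <- 1e5
  specs <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    specs[i, ] <- unclass(sample_random_patch(1000, 1000, 0.10, 0.15))
  }
  w <- specs[, 3]; x <- specs[, 1]
  expect_true(all(w >= 100 & w <= 150))
  expect_true(all(x >= 0 & x + w <= 1000))
  # empirical side distribution uniform over [100, 150]
  tab <- table(factor(w, levels = 100:150))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
  # f_min = f_max = 1 yields the full image
  full <- sample_random_patch(50, 40, 1, 1)
  expect_equal(unname(unclass(full)), c(0, 0, 50, 40))
  # image smaller than the minimum side errors
  expect_error(sample_random_patch(5, 5, 0.1, 0.15), "no patch side")
})

test_that("box clipping honors the keep-area-ratio rule", {
  img <- array(0.5, c(100, 100, 3))
  sp <- patch_spec(20, 20, 40, 40, 100, 100)
  inside <- data.frame(x_min = 25, y_min = 25, x_max = 35, y_max = 35,
                       class = "osteoclast_i", stringsAsFactors = FALSE)
  s <- crop_with_annotations(img, inside, sp)
  expect_equal(s$boxes[, 1:4],
               data.frame(x_min = 5, y_min = 5, x_max = 15, y_max = 15))
  outside <- data.frame(x_min = 70, y_min = 70, x_max = 90, y_max = 90,
                        class = "ghost", stringsAsFactors = FALSE)
  expect_equal(nrow(crop_with_annotations(img, outside, sp)$boxes), 0)
  # 30% inside: kept at threshold 0.25, dropped at 0.5
  straddle <- data.frame(x_min = 14, y_min = 30, x_max = 34, y_max = 40,
                         class = "preosteoclast", stringsAsFactors = FALSE)
  # clipped width 14 of 20 -> ratio 0.7; craft an exact 0.3 case instead
  straddle <- data.frame(x_min = 6, y_min = 30, x_max = 26, y_max = 40,
                         class = "preosteoclast", stringsAsFactors = FALSE)
  # clipped [20,26) x [30,40) = 60 of 200 -> 0.3
  expect_equal(nrow(crop_with_annotations(img, straddle, sp, 0.25)$boxes), 1)
  expect_equal(nrow(crop_with_annotations(img, straddle, sp, 0.5)$boxes), 0)
})

test_that("geometric augmentations form the expected group actions", {
  set.seed(5)
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  boxes <- random_boxes(5, 38, 38)
  s <- structure(list(image = img, boxes = boxes,
                      spec = patch_spec(0, 0, 40, 40)),
                 class = "patch_sample")
  oq <- asNamespace("osteoquant")
  # four 90-degree rotations are the identity on image and boxes
  r <- list(image = img, boxes = boxes)
  for (i in 1:4) r <- oq$rotate90(r$image, r$boxes, 1)
  expect_equal(r$image, img)
  expect_equal(r$boxes, boxes)
  # two vertical flips are the identity
  f <- oq$flip_vertical(img, boxes)
  f <- oq$flip_vertical(f$image, f$boxes)
  expect_equal(f$image, img)
  expect_equal(f$boxes, boxes)
  # augmentation preserves the number of boxes and the label multiset
  cfg <- augmentation_config()
  for (rep in 1:10) {
    a <- augment(s, cfg)
    expect_equal(nrow(a$boxes), nrow(boxes))
    expect_equal(sort(a$boxes$class), sort(boxes$class))
  }
})

test_that("rotated boxes equal the bounding box of the rotated mask", {
  set.seed(11)
  H <- 30; W <- 30
  img <- array(0, c(H, W, 3))
  b <- data.frame(x_min = 4, y_min = 7, x_max = 13, y_max = 21,
                  class = "osteoclast_i", stringsAsFactors = FALSE)
  mask <- matrix(0, H, W)
  mask[(b$y_min + 1):b$y_max, (b$x_min + 1):b$x_max] <- 1
  oq <- asNamespace("osteoquant")
  m3 <- array(rep(mask, 3), c(H, W, 3))
  for (k in 1:3) {
    r <- oq$rotate90(m3, b, k)
    rb <- r$boxes
    rm <- r$image[, , 1]
    ys <- range(which(rowSums(rm) > 0))
    xs <- range(which(colSums(rm) > 0))
    expect_equal(c(rb$x_min, rb$x_max), c(xs[1] - 1, xs[2]))
    expect_equal(c(rb$y_min, rb$y_max), c(ys[1] - 1, ys[2]))
  }
})

test_that("photometric distortion leaves geometry untouched", {
  set.seed(9)
  img <- array(runif(20 * 20 * 3, 0.2, 0.8), c(20, 20, 3))
  oq <- asNamespace("osteoquant")
  out <- oq$photometric_distort(img, 0.05, 0.1, 1.1)
  expect_equal(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 1))
  # zero distortion is the identity (rgb<->hsv round trip)
  expect_equal(oq$photometric_distort(img, 0, 0, 1), img, tolerance = 1e-12)
})

test_that("inference tiling partitions the well into 64 ordered tiles", {
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  tiles <- tile_image(img)
  expect_length(tiles, 64)
  cover <- matrix(0, 96, 96)
  for (tl in tiles) {
    sp <- unclass(tl$spec)
    cover[(sp["y"] + 1):(sp["y"] + sp["h"]),
          (sp["x"] + 1):(sp["x"] + sp["w"])] <-
      cover[(sp["y"] + 1):(sp["y"] + sp["h"]),
            (sp["x"] + 1):(sp["x"] + sp["w"])] + 1
    expect_identical(tl$image,
                     img[(sp["y"] + 1):(sp["y"] + sp["h"]),
                         (sp["x"] + 1):(sp["x"] + sp["w"]), , drop = FALSE])
  }
  expect_true(all(cover == 1))
  # row-major ordering
  sp1 <- unclass(tiles[[1]]$spec)
  sp2 <- unclass(tiles[[2]]$spec)
  expect_true(sp2["x"] > sp1["x"] && sp2["y"] == sp1["y"])
  expect_length(tile_image(img, 1, 1), 1)
})

test_that("training stream is seed-reproducible and balanced across wells", {
  cfg <- tiny_synthetic_config()
  wells <- lapply(1:2, function(i) {
    w <- generate_well(cfg, seed = i)
    list(image = w$image, boxes = well_boxes(w$annotation))
  })
  s1 <- build_training_set(wells, 30, seed = 21)
  s2 <- build_training_set(wells, 30, seed = 21)
  for (i in 1:30) {
    a <- s1(); b <- s2()
    expect_identical(a, b)
    # PatchSample invariants: boxes within the (augmented) patch image
    d <- dim(a$image)
    if (nrow(a$boxes) > 0) {
      expect_true(all(a$boxes$x_min >= 0 & a$boxes$x_max <= d[2] &
                        a$boxes$y_min >= 0 & a$boxes$y_max <= d[1]))
      expect_true(all(a$boxes$x_min < a$boxes$x_max))
    }
  }
  expect_null(s1())
  # well choice is uniform within binomial noise
  s3 <- build_training_set(wells, 2000, seed = 22, cfg = no_augmentation())
  picks <- integer(0)
  repeat {
    s <- s3()
    if (is.null(s)) break
    picks <- c(picks, s$well)
  }
  p1 <- mean(picks == 1)
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("patch positions are unchanged when augmentation is toggled", {
  cfg <- tiny_synthetic_config()
  w <- generate_well(cfg, seed = 4)
  wells <- list(list(image = w$image, boxes = well_boxes(w$annotation)))
  with_aug <- build_training_set(wells, 10, seed = 33)
  without <- build_training_set(wells, 10, seed = 33, cfg = no_augmentation())
  for (i in 1:10) {
    a <- with_aug()
    b <- without()
    expect_identical(a$spec, b$spec)
  }
})

test_that("the dataset manifest records one auditable row per sample", {
  cfg <- tiny_synthetic_config()
  w <- generate_well(cfg, seed = 4)
  wells <- list(list(image = w$image, boxes = well_boxes(w$annotation)))
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_dataset_manifest(build_training_set(wells, 12, seed = 1), path)
  expect_equal(nrow(df), 12)
  expect_true(all(c("well_id", "x", "y", "w", "h", "augmentation",
                    "n_boxes") %in% names(df)))
  expect_identical(nrow(read.csv(path)), 12L)
})
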