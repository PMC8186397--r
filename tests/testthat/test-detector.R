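test_that("IoU matches hand-computed overlaps", {
  a <- bbox(0, 0, 2, 2)
  expect_equal(iou(a, a), 1.0)
  expect_equal(iou(a, bbox(5, 5, 6, 6)), 0.0)
  expect_equal(iou(a, bbox(1, 1, 3, 3)), 1 / 7)
  # symmetry on random boxes
  set.seed(2)
  b <- random_boxes(20)
  for (i in 1:10) {
    x <- as.numeric(b[i, 1:4]); y <- as.numeric(b[i + 10, 1:4])
    expect_equal(iou(x, y), iou(y, x))
  }
})

test_that("anchor count follows the closed form and anchors stay in bounds", {
  cfg <- detector_config("reference")
  a <- generate_anchors(cfg)
  oq <- asNamespace("osteoquant")
  fms <- oq$feature_map_sizes(cfg)
  expect_equal(fms, c(38, 19, 10, 5))
  A <- length(cfg$aspect_ratios) + 1
  expect_equal(nrow(a), A * sum(fms^2))
  corners <- oq$centers_to_corners(a)
  expect_true(all(corners >= 0 & corners <= 1))
  # anchor set is a pure function of the configuration
  expect_identical(generate_anchors(cfg), generate_anchors(cfg))
})

test_that("default anchor sizes cover the 51-383 um cell range", {
  rng <- anchor_size_range_um(detector_config("reference"))
  expect_lte(rng[["min_um"]], 51)
  expect_gte(rng[["max_um"]], 383)
  cfg_noscale <- detector_config("reference")
  cfg_noscale$pixel_scale_um <- NULL
  expect_error(anchor_size_range_um(cfg_noscale), "pixel_scale_um")
})

test_that("box codec is exact on round trips and matches the formulas", {
  set.seed(8)
  n <- 1000
  anchors <- cbind(runif(n, 0.2, 0.8), runif(n, 0.2, 0.8),
                   runif(n, 0.05, 0.3), runif(n, 0.05, 0.3))
  cx <- runif(n, 0.2, 0.8); cy <- runif(n, 0.2, 0.8)
  w <- runif(n, 0.02, 0.3); h <- runif(n, 0.02, 0.3)
  boxes <- cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  enc <- box_codec(boxes, anchors, "encode")
  dec <- box_codec(enc, anchors, "decode")
  expect_lt(max(abs(dec - boxes)), 1e-6)
  # a box equal to its anchor encodes to zero offsets
  self <- osteoquant:::centers_to_corners(anchors[1:5, , drop = FALSE])
  expect_equal(max(abs(box_codec(self, anchors[1:5, ], "encode"))), 0)
  # hand-checked single pair: standard center/log-size parameterization
  a1 <- matrix(c(0.5, 0.5, 0.2, 0.1), 1)
  b1 <- matrix(c(0.45, 0.48, 0.65, 0.56), 1)  # center (0.55,0.52), 0.2x0.08
  e1 <- box_codec(b1, a1, "encode")
  expect_equal(as.numeric(e1),
               c((0.55 - 0.5) / (0.2 * 0.1), (0.52 - 0.5) / (0.1 * 0.1),
                 log(0.2 / 0.2) / 0.2, log(0.08 / 0.1) / 0.2),
               tolerance = 1e-12)
  expect_error(box_codec(matrix(c(0.5, 0.5, 0.4, 0.6), 1), a1, "encode"),
               "positive")
})

test_that("anchor matching equals a brute-force matcher", {
  brute_match <- function(anchors, gt, thr) {
    oq <- asNamespace("osteoquant")
    ac <- oq$centers_to_corners(anchors)
    n <- nrow(anchors)
    out <- integer(n)
    if (nrow(gt) == 0) return(out)
    im <- matrix(0, n, nrow(gt))
    for (i in seq_len(n)) for (j in seq_len(nrow(gt))) {
      im[i, j] <- iou(ac[i, ], gt[j, ])
    }
    for (i in seq_len(n)) {
      j <- which.max(im[i, ])
      if (im[i, j] >= thr) out[i] <- j
    }
    claimed <- logical(n)
    for (j in seq_len(nrow(gt))) {
      i <- which.max(im[, j])
      if (!claimed[i]) {
        out[i] <- j
        claimed[i] <- TRUE
      }
    }
    out
  }
  set.seed(3)
  for (rep in 1:20) {
    na <- sample(5:50, 1)
    ng <- sample(0:6, 1)
    anchors <- cbind(runif(na, 0.1, 0.9), runif(na, 0.1, 0.9),
                     runif(na, 0.05, 0.4), runif(na, 0.05, 0.4))
    gt <- if (ng > 0) {
      x0 <- runif(ng, 0, 0.7); y0 <- runif(ng, 0, 0.7)
      cbind(x0, y0, x0 + runif(ng, 0.05, 0.3), y0 + runif(ng, 0.05, 0.3))
    } else matrix(0, 0, 4)
    expect_equal(match_anchors(anchors, gt), brute_match(anchors, gt, 0.5))
  }
  # zero ground truth: all background
  a <- cbind(0.5, 0.5, 0.1, 0.1)
  expect_equal(match_anchors(a, matrix(0, 0, 4)), 0L)
  # a single strongly overlapping anchor is positive
  g <- matrix(c(0.44, 0.44, 0.56, 0.56), 1)
  expect_equal(match_anchors(cbind(0.5, 0.5, 0.12, 0.12), g), 1L)
})

test_that("multibox loss equals a naive per-anchor summation", {
  naive_loss <- function(logits, offs, assign, toffs, tcls, ratio = 3) {
    n <- nrow(logits)
    ce <- numeric(n)
    for (i in seq_len(n)) {
      p <- exp(logits[i, ] - max(logits[i, ]))
      p <- p / sum(p)
      tgt <- if (assign[i] > 0) tcls[i] else 1
      ce[i] <- -log(p[tgt])
    }
    pos <- which(assign > 0)
    np <- max(length(pos), 1)
    neg <- setdiff(seq_len(n), pos)
    neg <- neg[order(-ce[neg])]
    neg <- head(neg, ceiling(ratio * np))
    lloc <- 0
    for (i in pos) {
      for (k in 1:4) {
        d <- offs[i, k] - toffs[i, k]
        lloc <- lloc + if (abs(d) < 1) 0.5 * d^2 else abs(d) - 0.5
      }
    }
    (sum(ce[pos]) + sum(ce[neg]) + lloc) / np
  }
  set.seed(12)
  for (rep in 1:10) {
    n <- 10
    logits <- matrix(rnorm(n * 5), n)
    offs <- matrix(rnorm(n * 4), n)
    assign <- sample(0:2, n, replace = TRUE)
    toffs <- matrix(rnorm(n * 4), n)
    tcls <- sample(2:5, n, replace = TRUE)
    expect_equal(
      as.numeric(multibox_loss(logits, offs, assign, toffs, tcls)),
      naive_loss(logits, offs, assign, toffs, tcls))
  }
})

test_that("multibox loss is zero-localization at perfect prediction and
           decreases as the true logit grows", {
  n <- 8
  logits <- matrix(0, n, 5)
  assign <- c(1L, rep(0L, n - 1))
  toffs <- matrix(rnorm(n * 4), n)
  offs <- toffs                      # perfect localization
  tcls <- rep(2L, n)
  l <- multibox_loss(logits, offs, assign, toffs, tcls)
  expect_equal(attr(l, "loc"), 0)
  # raising the positive anchor's true-class logit lowers the loss
  logits2 <- logits
  logits2[1, 2] <- 2
  expect_lt(as.numeric(multibox_loss(logits2, offs, assign, toffs, tcls)),
            as.numeric(l))
  # no positives: confidence term over capped negatives only
  l0 <- multibox_loss(logits, offs, rep(0L, n), toffs, tcls)
  expect_equal(attr(l0, "loc"), 0)
  expect_gt(as.numeric(l0), 0)
})

test_that("loss gradients agree with finite differences", {
  set.seed(4)
  oq <- asNamespace("osteoquant")
  n <- 12
  logits <- matrix(rnorm(n * 5), n)
  offs <- matrix(rnorm(n * 4), n)
  assign <- c(1L, 2L, rep(0L, n - 2))
  toffs <- matrix(rnorm(n * 4), n)
  tcls <- rep(3L, n)
  g <- oq$multibox_loss_grad(logits, offs, assign, toffs, tcls)
  eps <- 1e-6
  for (idx in list(c(1, 2), c(5, 1), c(2, 3))) {
    lp <- logits; lp[idx[1], idx[2]] <- lp[idx[1], idx[2]] + eps
    lm <- logits; lm[idx[1], idx[2]] <- lm[idx[1], idx[2]] - eps
    fd <- (multibox_loss(lp, offs, assign, toffs, tcls) -
             multibox_loss(lm, offs, assign, toffs, tcls)) / (2 * eps)
    expect_equal(g$dlogits[idx[1], idx[2]], as.numeric(fd), tolerance = 1e-4)
  }
  for (idx in list(c(1, 1), c(2, 4))) {
    op <- offs; op[idx[1], idx[2]] <- op[idx[1], idx[2]] + eps
    om <- offs; om[idx[1], idx[2]] <- om[idx[1], idx[2]] - eps
    fd <- (multibox_loss(logits, op, assign, toffs, tcls) -
             multibox_loss(logits, om, assign, toffs, tcls)) / (2 * eps)
    expect_equal(g$dloc[idx[1], idx[2]], as.numeric(fd), tolerance = 1e-4)
  }
})

test_that("NMS equals the quadratic greedy reference", {
  set.seed(6)
  for (rep in 1:30) {
    det <- random_boxes(sample(2:60, 1), classes = "osteoclast_i")
    thr <- runif(1, 0.2, 0.7)
    got <- nms(det, thr)
    ref <- nms_reference(det, thr)
    expect_equal(got[order(got$x_min, got$score), ],
                 ref[order(ref$x_min, ref$score), ], ignore_attr = TRUE)
  }
  # two identical boxes: the higher score survives
  two <- data.frame(x_min = 0, y_min = 0, x_max = 2, y_max = 2,
                    class = "ghost", score = c(0.9, 0.5))
  expect_equal(nrow(nms(two, 0.45)), 1)
  expect_equal(nms(two, 0.45)$score, 0.9)
  # disjoint boxes all survive
  disj <- data.frame(x_min = c(0, 10), y_min = 0, x_max = c(2, 12),
                     y_max = 2, class = "ghost", score = c(0.3, 0.8))
  expect_equal(nrow(nms(disj, 0.45)), 2)
  # classes suppress independently
  mix <- data.frame(x_min = 0, y_min = 0, x_max = 2, y_max = 2,
                    class = c("ghost", "osteoclast_i"), score = c(0.9, 0.8))
  expect_equal(nrow(nms(mix, 0.45)), 2)
})

test_that("training is seed-reproducible and learns easy synthetic patches", {
  cfg <- tiny_synthetic_config()
  w <- generate_well(cfg, seed = 2)
  wells <- list(list(image = w$image, boxes = well_boxes(w$annotation)))
  dcfg <- detector_config("desk", channels = c(6, 10, 12, 12, 12))
  run <- function() {
    stream <- build_training_set(wells, 200, seed = 14,
                                 f_min = 0.3, f_max = 0.4)
    tcfg <- training_config("desk", iterations = 10, batch_size = 4,
                            seed = 14)
    train_detector(stream, dcfg, tcfg)
  }
  m1 <- run()
  m2 <- run()
  expect_identical(m1$log$loss, m2$log$loss)
  expect_identical(m1$params, m2$params)
  # learnability smoke test: smoothed loss decreases over 150 iterations
  stream <- build_training_set(wells, 4 * 150 + 5, seed = 15,
                               f_min = 0.3, f_max = 0.4)
  tcfg <- training_config("desk", iterations = 150, batch_size = 4,
                          seed = 15)
  m3 <- train_detector(stream, dcfg, tcfg)
  expect_lt(mean(tail(m3$log$loss, 20)), mean(head(m3$log$loss, 20)))
  # empty dataset errors
  expect_error(train_detector(list(), dcfg,
                              training_config("desk", seed = 1)), "empty")
})

test_that("an overfitted model memorizes its two training patches", {
  cfg <- tiny_synthetic_config(cells_per_well = 6)
  w <- generate_well(cfg, seed = 9)
  wells <- list(list(image = w$image, boxes = well_boxes(w$annotation)))
  base <- build_training_set(wells, 2, seed = 21, f_min = 0.35, f_max = 0.4,
                             cfg = no_augmentation())
  two <- list(base(), base())
  # the fixture seed yields annotated patches; the recall check needs them
  expect_gt(nrow(two[[1]]$boxes), 0)
  expect_gt(nrow(two[[2]]$boxes), 0)
  dcfg <- detector_config("desk", channels = c(6, 10, 12, 12, 12))
  tcfg <- training_config("desk", iterations = 500, batch_size = 2,
                          learning_rate = 2e-3, seed = 16)
  m <- train_detector(two, dcfg, tcfg)
  for (s in two) {
    det <- detect_patch(m, s$image, conf_threshold = 0.5)
    expect_true(all(det$score >= 0.5))
    sp <- unclass(s$spec)
    expect_true(all(det$x_min >= 0 & det$x_max <= sp["w"] &
                      det$y_min >= 0 & det$y_max <= sp["h"]))
    # every ground-truth box is recovered at IoU >= 0.5
    for (i in seq_len(nrow(s$boxes))) {
      gtb <- as.numeric(s$boxes[i, 1:4])
      ious <- vapply(seq_len(nrow(det)), function(j)
        iou(gtb, as.numeric(det[j, 1:4])), numeric(1))
      expect_gte(max(c(ious, 0)), 0.5)
    }
  }
})
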