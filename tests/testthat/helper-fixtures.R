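# Shared fixtures: all synthetic, built in code at test time.

# A small, quick synthetic well for unit tests.
tiny_synthetic_config <- function(...) {
  args <- utils::modifyList(list(image_size = 384, cells_per_well = 10,
                                 max_overlap = 0.25),
                            list(...))
  do.call(synthetic_config, args)
}

# Random simple (star-shaped) polygon around a center: star-shaped in the
# geometric sense, hence guaranteed simple.
random_simple_polygon <- function(n = 12, cx = 0, cy = 0, r_min = 2,
                                  r_max = 10) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, r_min, r_max)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Random boxes data frame on a W x H canvas.
random_boxes <- function(n, W = 60, H = 60, classes = CELL_TYPES) {
  x0 <- runif(n, 0, W - 2)
  y0 <- runif(n, 0, H - 2)
  data.frame(x_min = x0, y_min = y0,
             x_max = x0 + runif(n, 1, W / 3),
             y_max = y0 + runif(n, 1, H / 3),
             class = sample(classes, n, replace = TRUE),
             score = runif(n),
             stringsAsFactors = FALSE)
}

# Larger pixel-grid extent of a polygon (for box-minimality checks).
polygon_bbox_side <- function(p) {
  max(ceiling(max(p[, 1])) - floor(min(p[, 1])),
      ceiling(max(p[, 2])) - floor(min(p[, 2])))
}

# Independent quadratic greedy NMS reference (single class).
nms_reference <- function(det, thr) {
  ord <- order(-det$score)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (iou(as.numeric(det[i, c("x_min", "y_min", "x_max", "y_max")]),
              as.numeric(det[j, c("x_min", "y_min", "x_max", "y_max")])) >
          thr) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  det[kept, , drop = FALSE]
}

# Per-pixel membership oracle for union area of boxes (half-open pixels).
union_area_reference <- function(boxes, W, H) {
  n <- 0L
  for (py in seq_len(H) - 1) {
    for (px in seq_len(W) - 1) {
      cx <- px + 0.5
      cy <- py + 0.5
      inside <- FALSE
      for (i in seq_len(nrow(boxes))) {
        if (cx >= boxes$x_min[i] && cx < boxes$x_max[i] &&
            cy >= boxes$y_min[i] && cy < boxes$y_max[i]) {
          inside <- TRUE
          break
        }
      }
      if (inside) n <- n + 1L
    }
  }
  n
}
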