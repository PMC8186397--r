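# Anchor (default box) generation, the box offset codec, and
# anchor-to-ground-truth matching.

#' Generate the anchor set
#'
#' One anchor per aspect ratio plus one extra square anchor at the
#' geometric mean of the head's scale and the next, at every position of
#' every head feature map. Anchors are normalized (cx, cy, w, h) in the
#' unit square; anchor order matches the network head layout (positions
#' column-major per head, anchors fastest).
#'
#' @param cfg A [detector_config()].
#' @return Matrix n x 4 (`cx, cy, w, h`), clipped to the unit square, with
#'   attribute `head` giving each anchor's head index.
#' @export
generate_anchors <- function(cfg) {
  fms <- feature_map_sizes(cfg)
  ars <- cfg$aspect_ratios
  out <- vector("list", length(fms))
  for (hidx in seq_along(fms)) {
    f <- fms[hidx]
    s <- cfg$anchor_scales[hidx]
    s_extra <- sqrt(s * cfg$anchor_scales[hidx + 1])
    ww <- c(s * sqrt(ars), s_extra)
    hh <- c(s / sqrt(ars), s_extra)
    # positions column-major over the f x f map (row/y fastest), to match
    # the column-major layout of the head output tensors
    ij <- expand.grid(i = seq_len(f) - 1, j = seq_len(f) - 1)
    cx <- rep((ij$j + 0.5) / f, each = length(ww))
    cy <- rep((ij$i + 0.5) / f, each = length(ww))
    m <- cbind(cx = cx, cy = cy,
               w = rep(ww, nrow(ij)), h = rep(hh, nrow(ij)))
    attr(m, "head") <- rep(hidx, nrow(m))
    out[[hidx]] <- m
  }
  anchors <- do.call(rbind, out)
  heads <- unlist(lapply(out, attr, "head"))
  # clip to the unit square in corner form, back to center form
  corners <- centers_to_corners(anchors)
  corners <- pmin(pmax(corners, 0), 1)
  anchors <- corners_to_centers(corners)
  attr(anchors, "head") <- heads
  anchors
}

centers_to_corners <- function(m) {
  cbind(x_min = m[, 1] - m[, 3] / 2, y_min = m[, 2] - m[, 4] / 2,
        x_max = m[, 1] + m[, 3] / 2, y_max = m[, 2] + m[, 4] / 2)
}

corners_to_centers <- function(m) {
  cbind(cx = (m[, 1] + m[, 3]) / 2, cy = (m[, 2] + m[, 4]) / 2,
        w = m[, 3] - m[, 1], h = m[, 4] - m[, 2])
}

#' Physical size range covered by the anchor set
#'
#' Smallest and largest anchor side expressed in micrometers, assuming the
#' network input spans `input_size` native pixels at `pixel_scale_um`
#' micrometers per pixel. The default configuration covers the 51-383 um
#' cell-size range.
#'
#' @param cfg A [detector_config()].
#' @return Named numeric `c(min_um, max_um)`.
#' @export
anchor_size_range_um <- function(cfg) {
  if (is.null(cfg$pixel_scale_um)) {
    stop("pixel_scale_um is not set; physical coverage cannot be checked")
  }
  a <- generate_anchors(cfg)
  px <- cfg$input_size * cfg$pixel_scale_um
  c(min_um = min(a[, 3:4]) * px, max_um = max(a[, 3:4]) * px)
}

#' Encode or decode boxes against anchors
#'
#' Standard single-shot-detector parameterization: center offsets scaled
#' by anchor size and variance 0.1, log size ratios scaled by variance
#' 0.2. `decode(encode(b, a), a) = b` to floating-point accuracy.
#'
#' @param boxes n x 4 corner boxes (`x_min,y_min,x_max,y_max`, normalized)
#'   for `mode = "encode"`, or n x 4 offset rows for `mode = "decode"`.
#' @param anchors n x 4 center-form anchors (`cx,cy,w,h`), row-matched.
#' @param mode `"encode"` or `"decode"`.
#' @param variances Codec variances (center, size).
#' @return n x 4 matrix of offsets (encode) or corner boxes (decode).
#' @export
box_codec <- function(boxes, anchors, mode = c("encode", "decode"),
                      variances = c(0.1, 0.2)) {
  mode <- match.arg(mode)
  boxes <- as.matrix(boxes)
  anchors <- as.matrix(anchors)
  stopifnot(nrow(boxes) == nrow(anchors))
  if (mode == "encode") {
    ctr <- corners_to_centers(boxes)
    if (any(ctr[, 3] <= 0) || any(ctr[, 4] <= 0)) {
      stop("box_codec: boxes must have positive width and height")
    }
    cbind((ctr[, 1] - anchors[, 1]) / (anchors[, 3] * variances[1]),
          (ctr[, 2] - anchors[, 2]) / (anchors[, 4] * variances[1]),
          log(ctr[, 3] / anchors[, 3]) / variances[2],
          log(ctr[, 4] / anchors[, 4]) / variances[2])
  } else {
    cx <- anchors[, 1] + boxes[, 1] * variances[1] * anchors[, 3]
    cy <- anchors[, 2] + boxes[, 2] * variances[1] * anchors[, 4]
    w <- anchors[, 3] * exp(boxes[, 3] * variances[2])
    h <- anchors[, 4] * exp(boxes[, 4] * variances[2])
    centers_to_corners(cbind(cx, cy, w, h))
  }
}

#' Match anchors to ground-truth boxes
#'
#' Two-step matching: every ground-truth box claims its best-IoU anchor
#' (ties broken by lowest anchor index; an anchor already claimed by an
#' earlier ground truth keeps its first assignment), then every remaining
#' anchor with IoU at least `iou_threshold` to some ground truth is
#' assigned to its best-IoU ground truth. All other anchors are
#' background.
#'
#' @param anchors n x 4 center-form anchors (normalized).
#' @param gt_boxes m x 4 corner boxes (normalized; may have 0 rows).
#' @param iou_threshold Positive-match threshold (default 0.5).
#' @return Integer vector of length n: 0 for background, else the matched
#'   ground-truth row index.
#' @export
match_anchors <- function(anchors, gt_boxes, iou_threshold = 0.5) {
  anchors <- as.matrix(anchors)
  n <- nrow(anchors)
  gt_boxes <- as.matrix(gt_boxes)
  if (length(gt_boxes) == 0 || nrow(gt_boxes) == 0) {
    return(integer(n))
  }
  ac <- centers_to_corners(anchors)
  im <- iou_matrix(ac, gt_boxes)
  assign <- integer(n)
  # threshold step first, forced bipartite step overrides
  best_gt <- max.col(im, ties.method = "first")
  best_iou <- im[cbind(seq_len(n), best_gt)]
  assign[best_iou >= iou_threshold] <- best_gt[best_iou >= iou_threshold]
  forced <- logical(n)
  for (m in seq_len(ncol(im))) {
    a <- which.max(im[, m])      # lowest index on ties
    if (!forced[a]) {
      assign[a] <- m
      forced[a] <- TRUE
    }
  }
  assign
}
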