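# Whole-well inference: the patch-trained detector is applied to each tile
# of a non-overlapping grid and the outputs are unioned (translated by the
# tile origin and concatenated). No cross-tile merging is done by default:
# cells split across tiles are a measured, small error mode (the
# split-cell audit quantifies it), and a duplicate box over one cell
# cannot change the union covered area.

#' Detect cells in a full well image
#'
#' @param model A `detector_model`.
#' @param image Well image (H x W x 3 array, native resolution).
#' @param grid_rows,grid_cols Inference tiling (default 8 x 8 = 64 tiles).
#' @param cross_tile_nms Apply a final NMS pass across tile boundaries.
#'   Off by default: the published scheme is the naive union.
#' @param conf_threshold Optional confidence override.
#' @return Detections data frame (`x_min,y_min,x_max,y_max,class,score`)
#'   in well pixel coordinates, with a `tile` column recording the source
#'   tile (row-major index).
#' @export
detect_well <- function(model, image, grid_rows = 8, grid_cols = 8,
                        cross_tile_nms = FALSE, conf_threshold = NULL) {
  tiles <- tile_image(image, grid_rows, grid_cols)
  parts <- lapply(seq_along(tiles), function(k) {
    tl <- tiles[[k]]
    det <- detect_patch(model, tl$image, conf_threshold = conf_threshold)
    if (nrow(det) == 0) return(cbind(det, tile = integer(0)))
    sp <- unclass(tl$spec)
    det$x_min <- det$x_min + sp[["x"]]
    det$x_max <- det$x_max + sp[["x"]]
    det$y_min <- det$y_min + sp[["y"]]
    det$y_max <- det$y_max + sp[["y"]]
    det$tile <- k
    det
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  if (cross_tile_nms && nrow(out) > 0) {
    out <- nms(out, model$config$nms_iou, classwise = TRUE)
  }
  out
}

#' Audit cells split by the inference tiling
#'
#' Counts annotated cells whose tightest-square box intersects two or more
#' tiles of the inference grid. Such cells can be detected twice (once per
#' tile), inflating counts but never the union covered area.
#'
#' @param well A [well_annotation()] (ground truth).
#' @param grid_rows,grid_cols Inference tiling (default 8 x 8).
#' @return List `n_cells`, `n_crossing`, `fraction`.
#' @export
split_cell_audit <- function(well, grid_rows = 8, grid_cols = 8) {
  boxes <- well_boxes(well)
  rects <- grid_rects(well$width, well$height, grid_rows, grid_cols)
  tile_boxes <- cbind(rects[, "x"], rects[, "y"],
                      rects[, "x"] + rects[, "w"],
                      rects[, "y"] + rects[, "h"])
  n <- nrow(boxes)
  crossing <- 0L
  if (n > 0) {
    bm <- as.matrix(boxes[, c("x_min", "y_min", "x_max", "y_max")])
    for (i in seq_len(n)) {
      iw <- pmax(0, pmin(bm[i, 3], tile_boxes[, 3]) -
                    pmax(bm[i, 1], tile_boxes[, 1]))
      ih <- pmax(0, pmin(bm[i, 4], tile_boxes[, 4]) -
                    pmax(bm[i, 2], tile_boxes[, 2]))
      if (sum(iw * ih > 0) >= 2) crossing <- crossing + 1L
    }
  }
  list(n_cells = n, n_crossing = crossing,
       fraction = if (n > 0) crossing / n else 0)
}

#' Write detections to CSV
#'
#' @param detections Detections data frame.
#' @param path Output path.
#' @param well_id Identifier stored in the first column.
#' @return The written data frame, invisibly.
#' @export
write_detections <- function(detections, path, well_id = "well") {
  df <- cbind(well_id = well_id, detections)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Render detection boxes onto an image
#'
#' Draws 2 px box outlines color-coded by class (preosteoclast yellow,
#' type I blue, type II red, ghost gray) for visual QC.
#'
#' @param image H x W x 3 array.
#' @param detections Detections data frame (well or patch coordinates
#'   matching `image`).
#' @return The annotated image array.
#' @export
render_detections <- function(image, detections) {
  cols <- list(preosteoclast = c(0.95, 0.85, 0.1),
               osteoclast_i = c(0.1, 0.3, 0.95),
               osteoclast_ii = c(0.9, 0.1, 0.1),
               ghost = c(0.5, 0.5, 0.5))
  d <- dim(image)
  for (i in seq_len(nrow(detections))) {
    b <- detections[i, ]
    col <- cols[[b$class]]
    x0 <- max(1, floor(b$x_min) + 1); x1 <- min(d[2], ceiling(b$x_max))
    y0 <- max(1, floor(b$y_min) + 1); y1 <- min(d[1], ceiling(b$y_max))
    for (ch in 1:3) {
      image[y0:min(y0 + 1, y1), x0:x1, ch] <- col[ch]
      image[max(y1 - 1, y0):y1, x0:x1, ch] <- col[ch]
      image[y0:y1, x0:min(x0 + 1, x1), ch] <- col[ch]
      image[y0:y1, max(x1 - 1, x0):x1, ch] <- col[ch]
    }
  }
  image
}
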