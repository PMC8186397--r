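#' Non-maximum suppression
#'
#' Greedy suppression in descending score order: a box is kept iff its IoU
#' with every previously kept box is at most `iou_threshold`. Applied per
#' class; detections of different classes never suppress each other.
#'
#' @param detections Data frame with columns
#'   `x_min,y_min,x_max,y_max,score` and optionally `class`.
#' @param iou_threshold Suppression threshold (default 0.45).
#' @param classwise If `TRUE` (default) suppress within each `class`
#'   independently.
#' @return The surviving rows, scores descending (within class groups
#'   interleaved by score).
#' @export
nms <- function(detections, iou_threshold = 0.45, classwise = TRUE) {
  if (nrow(detections) == 0) return(detections)
  if (classwise && "class" %in% names(detections)) {
    parts <- split(seq_len(nrow(detections)), detections$class)
    kept <- unlist(lapply(parts, function(idx) {
      idx[nms_single(detections[idx, , drop = FALSE], iou_threshold)]
    }), use.names = FALSE)
    out <- detections[kept, , drop = FALSE]
  } else {
    out <- detections[nms_single(detections, iou_threshold), , drop = FALSE]
  }
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Indices (into det) surviving greedy NMS, score-descending.
nms_single <- function(det, thr) {
  ord <- order(-det$score)
  boxes <- as.matrix(det[ord, c("x_min", "y_min", "x_max", "y_max")])
  n <- length(ord)
  keep <- logical(n)
  area <- (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2])
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i == n) break
    rest <- which(alive & seq_len(n) > i)
    if (length(rest) == 0) break
    iw <- pmax(0, pmin(boxes[rest, 3], boxes[i, 3]) -
                  pmax(boxes[rest, 1], boxes[i, 1]))
    ih <- pmax(0, pmin(boxes[rest, 4], boxes[i, 4]) -
                  pmax(boxes[rest, 2], boxes[i, 2]))
    inter <- iw * ih
    ov <- inter / (area[rest] + area[i] - inter)
    alive[rest[ov > thr]] <- FALSE
  }
  ord[keep]
}
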