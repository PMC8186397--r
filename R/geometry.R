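# Polygon and box geometry. Coordinate convention (used package-wide):
# 0-based pixel coordinates, origin at the top-left, x across columns,
# y down rows. Boxes are half-open: column x belongs to a box iff
# x_min <= x < x_max.

#' Construct a polygon
#'
#' A polygon is an n x 2 numeric matrix of ordered vertices (columns `x`,
#' `y`, in pixels). Orientation is normalized to counter-clockwise in image
#' coordinates (positive shoelace sum).
#'
#' @param xy An n x 2 matrix or data frame of vertices (n >= 3).
#' @return An n x 2 numeric matrix with columns `x`, `y`.
#' @export
polygon_vertices <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3 || ncol(xy) != 2) {
    stop("invalid polygon: need at least 3 vertices as an n x 2 matrix")
  }
  storage.mode(xy) <- "double"
  colnames(xy) <- c("x", "y")
  # orientation normalized to counter-clockwise; fully degenerate
  # polygons are tolerated (area 0, tightest square falls back to 1 px)
  if (signed_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  xy
}

signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area by the shoelace formula
#'
#' @param p A polygon ([polygon_vertices()] or any n x 2 matrix, n >= 3).
#' @return Absolute enclosed area in square pixels. Invariant under vertex
#'   rotation and orientation reversal.
#' @examples
#' polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3)))  # 6
#' @export
polygon_area <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) < 3 || ncol(p) != 2) {
    stop("invalid polygon: need at least 3 vertices")
  }
  abs(signed_area(p))
}

polygon_centroid <- function(p) {
  p <- as.matrix(p)
  a <- signed_area(p)
  if (abs(a) < 1e-12) {
    return(c(mean(p[, 1]), mean(p[, 2])))
  }
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Construct a bounding box
#'
#' @param x_min,y_min,x_max,y_max Box corners in pixels, half-open
#'   (`x_min <= x < x_max`).
#' @return A named numeric vector of class `bbox`.
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  if (!(x_min < x_max && y_min < y_max)) {
    stop("invalid bbox: require x_min < x_max and y_min < y_max")
  }
  structure(c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
            class = "bbox")
}

# Boxes in bulk are plain m x 4 matrices with columns x_min,y_min,x_max,y_max.
as_box_matrix <- function(b) {
  if (inherits(b, "bbox")) b <- matrix(unclass(b), nrow = 1)
  b <- as.matrix(b)
  if (ncol(b) != 4) stop("boxes must have 4 columns (x_min, y_min, x_max, y_max)")
  colnames(b) <- c("x_min", "y_min", "x_max", "y_max")
  storage.mode(b) <- "double"
  b
}

polygon_bbox <- function(p) {
  p <- as.matrix(p)
  c(x_min = min(p[, 1]), y_min = min(p[, 2]),
    x_max = max(p[, 1]), y_max = max(p[, 2]))
}

#' Tightest square box containing a polygon
#'
#' Converts a cell polygon to the tightest pixel-aligned square containing
#' the whole cell, the box representation the detector trains on. The side
#' equals the larger of the polygon's pixel-grid extents; the square is
#' centered on the extent and then shifted (never shrunk) to lie inside the
#' image. Only when the side exceeds an image dimension is squareness given
#' up on that axis (the box is clipped to the image).
#'
#' @param p Polygon (n x 2 matrix).
#' @param image_w,image_h Image dimensions in pixels (bounds for the shift
#'   /clip policy). `Inf` disables clipping.
#' @return A [bbox()] with integer corners.
#' @export
tightest_square_bbox <- function(p, image_w = Inf, image_h = Inf) {
  p <- as.matrix(p)
  if (nrow(p) < 3 || ncol(p) != 2) stop("invalid polygon: need >= 3 vertices")
  e <- polygon_bbox(p)
  x_lo <- floor(e["x_min"]); x_hi <- ceiling(e["x_max"])
  y_lo <- floor(e["y_min"]); y_hi <- ceiling(e["y_max"])
  if (x_hi == x_lo) x_hi <- x_lo + 1   # degenerate extent -> 1 px
  if (y_hi == y_lo) y_hi <- y_lo + 1
  w <- x_hi - x_lo
  h <- y_hi - y_lo
  side <- max(w, h)
  x0 <- x_lo - floor((side - w) / 2)
  y0 <- y_lo - floor((side - h) / 2)
  # shift into the image, then clip only if the side does not fit at all
  sx <- shift_clip_1d(x0, side, image_w)
  sy <- shift_clip_1d(y0, side, image_h)
  bbox(sx[1], sy[1], sx[2], sy[2])
}

shift_clip_1d <- function(lo, side, limit) {
  if (side > limit) {
    return(c(0, limit))       # squareness yields to containment
  }
  lo <- max(0, min(lo, limit - side))
  c(lo, lo + side)
}

#' Intersection-over-union of two boxes
#'
#' @param a,b Boxes ([bbox()] or length-4 vectors `x_min,y_min,x_max,y_max`).
#' @return IoU in `[0, 1]`; 1 iff identical, 0 iff disjoint.
#' @examples
#' iou(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  if (inter <= 0) return(0)
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  unname(inter / ua)
}

# Pairwise IoU between two box matrices (n x 4, m x 4) -> n x m matrix.
iou_matrix <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- nrow(a); m <- nrow(b)
  iw <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  ih <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- iw * ih
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  un <- outer(area_a, area_b, `+`) - inter
  out <- inter / un
  out[inter <= 0] <- 0
  matrix(out, n, m)
}
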