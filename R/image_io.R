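# Image I/O and helpers. Images are H x W x 3 numeric arrays in [0, 1],
# row = y (top-down), column = x, matching the package's 0-based pixel
# coordinate convention.

#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' @param path Image path; format chosen by extension.
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (use PNG or TIFF)"))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image (PNG or TIFF)
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "' (use PNG or TIFF)"))
  invisible(path)
}

image_dims <- function(img) {
  d <- dim(img)
  c(width = d[2], height = d[1])
}

# Crop [x, x+w) x [y, y+h) in 0-based pixel coordinates.
crop_image <- function(img, x, y, w, h) {
  img[(y + 1):(y + h), (x + 1):(x + w), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Grid partitioning shared by the 4x4 annotation split and the 8x8
# inference tiler. Remainder pixels go to the last row/column.

grid_rects <- function(width, height, grid_rows, grid_cols) {
  width <- unname(width)
  height <- unname(height)
  stopifnot(grid_rows >= 1, grid_cols >= 1)
  if (grid_cols > width || grid_rows > height) {
    stop("grid ", grid_rows, "x", grid_cols,
         " exceeds image dimensions ", width, "x", height)
  }
  bw <- floor(width / grid_cols)
  bh <- floor(height / grid_rows)
  out <- vector("list", grid_rows * grid_cols)
  k <- 1
  for (r in seq_len(grid_rows)) {          # row-major ordering
    for (cc in seq_len(grid_cols)) {
      x <- (cc - 1) * bw
      y <- (r - 1) * bh
      w <- if (cc == grid_cols) width - x else bw
      h <- if (r == grid_rows) height - y else bh
      out[[k]] <- c(x = x, y = y, w = w, h = h)
      k <- k + 1
    }
  }
  do.call(rbind, out)
}

#' Split a well image into annotation regions
#'
#' Divides a culture well into a grid of equally sized regions (default the
#' 4 x 4 = 16-region split used for manual annotation). Remainder pixels
#' from non-divisible dimensions are assigned to the last row/column, so
#' the regions are disjoint and cover every pixel exactly once.
#'
#' @param image H x W x 3 array.
#' @param grid_rows,grid_cols Grid shape (default 4 x 4).
#' @return List of `list(image =, offset = c(x, y), width =, height =)`,
#'   row-major.
#' @export
split_well_into_regions <- function(image, grid_rows = 4, grid_cols = 4) {
  d <- image_dims(image)
  rects <- grid_rects(d["width"], d["height"], grid_rows, grid_cols)
  lapply(seq_len(nrow(rects)), function(k) {
    rc <- rects[k, ]
    list(image = crop_image(image, rc["x"], rc["y"], rc["w"], rc["h"]),
         offset = c(x = unname(rc["x"]), y = unname(rc["y"])),
         width = unname(rc["w"]), height = unname(rc["h"]))
  })
}

#' Tile an image for patch-level inference
#'
#' Deterministic non-overlapping tiling (default 8 x 8 = 64 tiles per
#' well), row-major. The tiles partition the image exactly.
#'
#' @param image H x W x 3 array.
#' @param grid_rows,grid_cols Grid shape (default 8 x 8).
#' @return List of `list(spec = patch_spec, image = crop)`.
#' @export
tile_image <- function(image, grid_rows = 8, grid_cols = 8) {
  d <- image_dims(image)
  rects <- grid_rects(d["width"], d["height"], grid_rows, grid_cols)
  lapply(seq_len(nrow(rects)), function(k) {
    rc <- rects[k, ]
    list(spec = patch_spec(rc["x"], rc["y"], rc["w"], rc["h"],
                           d["width"], d["height"]),
         image = crop_image(image, rc["x"], rc["y"], rc["w"], rc["h"]))
  })
}

# ---------------------------------------------------------------------------
# Numeric rgb <-> hsv (vectorized; h, s, v in [0, 1]).

rgb_to_hsv_num <- function(r, g, b) {
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  nz <- d > 0
  i_r <- nz & mx == r
  i_g <- nz & !i_r & mx == g
  i_b <- nz & !i_r & !i_g
  h[i_r] <- ((g[i_r] - b[i_r]) / d[i_r]) %% 6
  h[i_g] <- (b[i_g] - r[i_g]) / d[i_g] + 2
  h[i_b] <- (r[i_b] - g[i_b]) / d[i_b] + 4
  h <- h / 6
  s <- ifelse(mx > 0, d / mx, 0)
  list(h = h, s = s, v = mx)
}

hsv_to_rgb_num <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  for (k in 0:5) {
    m <- i == k
    if (!any(m)) next
    vals <- switch(as.character(k),
      "0" = list(v, t, p), "1" = list(q, v, p), "2" = list(p, v, t),
      "3" = list(p, q, v), "4" = list(t, p, v), "5" = list(v, p, q))
    r[m] <- vals[[1]][m]; g[m] <- vals[[2]][m]; b[m] <- vals[[3]][m]
  }
  list(r = r, g = g, b = b)
}
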