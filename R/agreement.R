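# Agreement statistics: per-region measurement vectors, pairwise Pearson
# correlation between measurement sources (human annotators and/or the
# model), and a residual-normality check for the correlation analyses.

#' Per-region measurement vector
#'
#' Splits the well into a grid of regions and measures one value per
#' region for one cell type: either the cell count or the covered area.
#' Cells are assigned to the region containing their center (box center
#' for detections, polygon centroid for annotations), so a cell is never
#' double counted; area is the union mask restricted to each region, so
#' region areas sum exactly to the whole-well union area.
#'
#' @param source Detections data frame or [well_annotation()].
#' @param width,height Well size in px (defaults from a
#'   [well_annotation()]).
#' @param grid_rows,grid_cols Region grid (default the 4 x 4 annotation
#'   split).
#' @param measure `"count"` or `"area"`.
#' @param cell_type One of [CELL_TYPES], or a character vector to pool.
#' @return Numeric vector, one value per region (row-major).
#' @export
per_region_vector <- function(source, width = NULL, height = NULL,
                              grid_rows = 4, grid_cols = 4,
                              measure = c("count", "area"),
                              cell_type = "osteoclast_i") {
  measure <- match.arg(measure)
  cell_type <- as_cell_type(cell_type)
  if (inherits(source, "well_annotation")) {
    width <- width %||% source$width
    height <- height %||% source$height
  }
  if (is.null(width) || is.null(height)) {
    stop("width and height are required for detection sources")
  }
  rects <- grid_rects(width, height, grid_rows, grid_cols)
  if (measure == "count") {
    centers <- item_centers(source, cell_type)
    v <- numeric(nrow(rects))
    if (nrow(centers) > 0) {
      col <- pmin(pmax(floor(centers[, 1] / floor(width / grid_cols)), 0),
                  grid_cols - 1)
      row <- pmin(pmax(floor(centers[, 2] / floor(height / grid_rows)), 0),
                  grid_rows - 1)
      idx <- row * grid_cols + col + 1
      tab <- table(factor(idx, levels = seq_len(nrow(rects))))
      v <- as.numeric(tab)
    }
    v
  } else {
    mask <- union_mask(source, cell_type, width, height)
    vapply(seq_len(nrow(rects)), function(k) {
      rc <- rects[k, ]
      sum(mask[(rc["y"] + 1):(rc["y"] + rc["h"]),
               (rc["x"] + 1):(rc["x"] + rc["w"])])
    }, numeric(1))
  }
}

item_centers <- function(source, cell_types) {
  if (inherits(source, "well_annotation")) {
    cells <- well_cells(source)
    cells <- cells[vapply(cells, function(cl) cl$cell_type %in% cell_types,
                          TRUE)]
    if (length(cells) == 0) return(matrix(0, 0, 2))
    t(vapply(cells, function(cl) polygon_centroid(cl$polygon), numeric(2)))
  } else {
    keep <- source$class %in% cell_types
    cbind((source$x_min[keep] + source$x_max[keep]) / 2,
          (source$y_min[keep] + source$y_max[keep]) / 2)
  }
}

#' Pearson product-moment correlation
#'
#' Thin, checked front end to the standard estimator: requires equal
#' lengths of at least 3 and non-degenerate variance in both vectors (a
#' zero-variance input is an explicit error, never a silent 0).
#'
#' @param x,y Numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_r: unequal lengths")
  if (length(x) < 3) stop("pearson_r: need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("pearson_r: undefined correlation (zero variance input)")
  }
  stats::cor(x, y, method = "pearson")
}

#' Pairwise agreement matrix
#'
#' Pearson correlation between every pair of measurement sources (e.g.
#' three human annotators and the model) over identical regions. Regions
#' empty in every source are dropped before correlating, mirroring the
#' practice of discarding regions without any cells; a region counted by
#' at least one source is kept for all.
#'
#' @param vectors Named list of equal-length per-region vectors (from
#'   [per_region_vector()]).
#' @param drop_empty Drop regions that are zero in all sources (default
#'   `TRUE`).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
agreement_matrix <- function(vectors, drop_empty = TRUE) {
  stopifnot(length(vectors) >= 2)
  len <- unique(vapply(vectors, length, 0L))
  if (length(len) != 1) stop("all sources must cover the same regions")
  m <- do.call(cbind, vectors)
  if (drop_empty) {
    m <- m[rowSums(m != 0) > 0, , drop = FALSE]
  }
  k <- ncol(m)
  out <- diag(1, k)
  dimnames(out) <- list(colnames(m), colnames(m))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      out[i, j] <- out[j, i] <- pearson_r(m[, i], m[, j])
    }
  }
  out
}

#' Residual-normality check for a correlation analysis
#'
#' Fits the least-squares line of `y` on `x` and applies the D'Agostino &
#' Pearson omnibus K-squared test (combined skewness and kurtosis
#' z-statistics, chi-squared with 2 df) to the residuals. The correlation
#' analyses are considered well behaved when the residuals pass at the
#' given level.
#'
#' @param x,y Numeric vectors (n >= 8; the kurtosis z-transform is not
#'   defined below that).
#' @param alpha Significance level (default 0.05).
#' @return List `statistic` (K-squared), `p`, `pass` (`p > alpha`).
#' @export
residual_normality <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("unequal lengths")
  if (length(x) < 8) stop("residual_normality: need n >= 8")
  r <- residuals(lm(y ~ x))
  if (sd(r) < 1e-10 * max(sd(y), 1e-300)) {
    stop("residual_normality: residuals are degenerate (perfect fit)")
  }
  k2 <- dagostino_k2(r)
  list(statistic = k2$statistic, p = k2$p, pass = k2$p > alpha)
}

# D'Agostino & Pearson omnibus test: Z1 from the sample skewness
# (D'Agostino 1970 transform), Z2 from the sample kurtosis
# (Anscombe & Glynn 1983 transform), K2 = Z1^2 + Z2^2 ~ chi^2(2).
dagostino_k2 <- function(x) {
  n <- length(x)
  if (n < 8) stop("dagostino_k2: need n >= 8")
  x <- x - mean(x)
  m2 <- mean(x^2)
  m3 <- mean(x^3)
  m4 <- mean(x^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2
  # skewness transform
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (g2 - eb2) / sqrt(vb2)
  sb2 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb2 * (2 / sb2 + sqrt(1 + 4 / sb2^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p = pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Scatter plot for an agreement pair
#'
#' Mirrors the study's agreement figures: one source against another with
#' the least-squares line and the Pearson r in the title.
#'
#' @param x,y Per-region vectors.
#' @param xlab,ylab Axis labels (source names).
#' @param ... Passed to [graphics::plot()].
#' @return The Pearson r, invisibly.
#' @export
#' @importFrom graphics abline plot title
plot_agreement <- function(x, y, xlab = "source 1", ylab = "source 2", ...) {
  r <- pearson_r(x, y)
  plot(x, y, xlab = xlab, ylab = ylab, pch = 19, ...)
  abline(lm(y ~ x), col = "steelblue")
  title(main = sprintf("Pearson r = %.3f", r))
  invisible(r)
}
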