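# Quantification endpoints: per-class cell counts and covered area. Area
# uses the geometric UNION of shapes, rasterized at native resolution --
# a cell covered by two boxes contributes its area once, so duplicate
# detections cannot inflate the area estimate (they can only inflate
# counts).

# Items accepted throughout: a detections data frame (boxes) or a
# well_annotation (polygons).
item_classes <- function(items) {
  if (inherits(items, "well_annotation")) {
    vapply(well_cells(items), `[[`, "", "cell_type")
  } else if (is.data.frame(items)) {
    items$class
  } else {
    stop("items must be a detections data frame or a well_annotation")
  }
}

#' Count cells of a class
#'
#' @param items Detections data frame or [well_annotation()].
#' @param cell_type One of [CELL_TYPES]. Classes are never pooled:
#'   preosteoclasts and ghosts are not osteoclasts.
#' @return Integer count.
#' @export
count_cells <- function(items, cell_type) {
  cell_type <- as_cell_type(cell_type)
  sum(item_classes(items) %in% cell_type)
}

# Rasterize the union of the given items into a logical H x W mask.
union_mask <- function(items, cell_types, width, height) {
  mask <- matrix(FALSE, nrow = height, ncol = width)
  if (inherits(items, "well_annotation")) {
    for (cell in well_cells(items)) {
      if (!cell$cell_type %in% cell_types) next
      p <- cell$polygon
      mask <- mask | cpp_fill_polygon(p[, 1], p[, 2], height, width)
    }
  } else {
    keep <- items$class %in% cell_types
    b <- items[keep, , drop = FALSE]
    # pixel-center rasterization, consistent with the polygon scanline fill
    for (i in seq_len(nrow(b))) {
      x0 <- max(0, ceiling(b$x_min[i] - 0.5))
      x1 <- min(width, ceiling(b$x_max[i] - 0.5))
      y0 <- max(0, ceiling(b$y_min[i] - 0.5))
      y1 <- min(height, ceiling(b$y_max[i] - 0.5))
      if (x1 > x0 && y1 > y0) mask[(y0 + 1):y1, (x0 + 1):x1] <- TRUE
    }
  }
  mask
}

#' Covered area (union) of cells
#'
#' Area of the geometric union of the selected cells' shapes (polygons for
#' annotations, boxes for detections), computed by rasterization at native
#' resolution. Adding a duplicate or fully contained shape never changes
#' the result.
#'
#' @param items Detections data frame or [well_annotation()].
#' @param cell_types Character vector of classes to include (default: the
#'   three TRAP+ classes).
#' @param width,height Canvas size in pixels. Defaults to the well size
#'   when `items` is a [well_annotation()].
#' @return Covered area in px^2.
#' @export
covered_area <- function(items, cell_types = setdiff(CELL_TYPES, "ghost"),
                         width = NULL, height = NULL) {
  cell_types <- as_cell_type(cell_types)
  if (inherits(items, "well_annotation")) {
    width <- width %||% items$width
    height <- height %||% items$height
  }
  if (is.null(width) || is.null(height)) {
    stop("width and height are required for box items")
  }
  sum(union_mask(items, cell_types, width, height))
}

#' Area fraction of a well
#'
#' @param covered Covered area in px^2.
#' @param well_w,well_h Well size in pixels.
#' @return `covered / (well_w * well_h)` in `[0, 1]`.
#' @export
area_fraction <- function(covered, well_w, well_h) {
  total <- well_w * well_h
  if (covered > total) {
    stop("covered area ", covered, " exceeds the well area ", total,
         " -- check units (px^2 expected)")
  }
  covered / total
}

#' Quantify a well
#'
#' The two study endpoints for one well: per-class cell count and union
#' covered area (px^2, um^2 and as a fraction of the well), plus a total
#' row for the TRAP+ classes combined. The area basis (polygons for human
#' annotations, boxes for detections) is recorded in the `basis` column.
#'
#' @param items Detections data frame or [well_annotation()].
#' @param width,height Well size in px (defaults from a
#'   [well_annotation()]).
#' @param pixel_scale_um Micrometers per pixel.
#' @param well_id Identifier for the report.
#' @return Data frame, one row per class plus `trap_total`, columns
#'   `well_id, class, count, area_px2, area_um2, area_fraction, basis`.
#' @export
quantify_well <- function(items, width = NULL, height = NULL,
                          pixel_scale_um = 1, well_id = "well") {
  if (inherits(items, "well_annotation")) {
    width <- width %||% items$width
    height <- height %||% items$height
    well_id <- if (identical(well_id, "well")) items$well_id else well_id
    basis <- "polygon"
  } else {
    basis <- "box"
  }
  if (is.null(width) || is.null(height)) {
    stop("width and height are required for box items")
  }
  rows <- lapply(CELL_TYPES, function(ct) {
    a <- covered_area(items, ct, width, height)
    data.frame(well_id = well_id, class = ct,
               count = count_cells(items, ct),
               area_px2 = a, area_um2 = a * pixel_scale_um^2,
               area_fraction = area_fraction(a, width, height),
               basis = basis, stringsAsFactors = FALSE)
  })
  trap <- setdiff(CELL_TYPES, "ghost")
  a <- covered_area(items, trap, width, height)
  rows[[length(rows) + 1]] <- data.frame(
    well_id = well_id, class = "trap_total",
    count = sum(item_classes(items) %in% trap),
    area_px2 = a, area_um2 = a * pixel_scale_um^2,
    area_fraction = area_fraction(a, width, height),
    basis = basis, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Write a quantification report
#'
#' @param report Data frame from [quantify_well()] (rows from several
#'   wells may be concatenated).
#' @param path Output CSV path.
#' @return The report, invisibly.
#' @export
write_quantification <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(report)
}
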