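# Well annotation containers and LabelMe-compatible JSON I/O.
#
# A WellAnnotation references one culture-well image and holds its polygon
# annotations grouped into rectangular regions (the unit human annotators
# work on). Cell coordinates inside a region are region-local; region
# offsets place them in well coordinates.

#' Construct a cell annotation
#'
#' @param polygon Polygon in (region-local) pixel coordinates.
#' @param cell_type One of [CELL_TYPES].
#' @param n_nuclei Nucleus count, or `NA` when unknown (always allowed for
#'   ghost cells). When present for a TRAP+ class it must agree with
#'   [classify_cell_type()].
#' @return A list of class `cell_annotation`.
#' @export
cell_annotation <- function(polygon, cell_type, n_nuclei = NA_integer_) {
  cell_type <- as_cell_type(cell_type)
  polygon <- polygon_vertices(polygon)
  if (!is.na(n_nuclei) && cell_type != "ghost") {
    implied <- classify_cell_type(n_nuclei)
    if (implied != cell_type) {
      stop("inconsistent annotation: ", n_nuclei, " nuclei implies ",
           implied, ", not ", cell_type)
    }
  }
  structure(list(polygon = polygon, cell_type = cell_type,
                 n_nuclei = as.integer(n_nuclei)),
            class = "cell_annotation")
}

#' Construct a region annotation
#'
#' @param region_id Identifier (scalar).
#' @param offset Length-2 numeric, (x, y) of the region origin in well
#'   coordinates.
#' @param width,height Region size in pixels.
#' @param cells List of [cell_annotation()] in region-local coordinates.
#' @return A list of class `region_annotation`.
#' @export
region_annotation <- function(region_id, offset, width, height, cells = list()) {
  stopifnot(length(offset) == 2, width >= 1, height >= 1)
  for (i in seq_along(cells)) {
    p <- cells[[i]]$polygon
    if (any(p[, 1] < 0) || any(p[, 1] > width) ||
        any(p[, 2] < 0) || any(p[, 2] > height)) {
      stop("cell ", i, " in region ", region_id,
           " has vertices outside [0,", width, ") x [0,", height, ")")
    }
  }
  structure(list(region_id = region_id, offset = as.numeric(offset),
                 width = width, height = height, cells = cells),
            class = "region_annotation")
}

#' Construct a well annotation
#'
#' @param well_id Identifier.
#' @param image_path Path of the well image (may be empty for synthetic
#'   in-memory wells).
#' @param width,height Well image size in pixels.
#' @param regions List of [region_annotation()]; their rectangles must be
#'   pairwise disjoint and cover the image exactly.
#' @return A list of class `well_annotation`.
#' @export
well_annotation <- function(well_id, image_path, width, height, regions) {
  covered <- sum(vapply(regions, function(r) r$width * r$height, 0))
  if (covered != width * height) {
    stop("region rectangles must cover the well exactly (",
         covered, " px^2 covered, well is ", width * height, ")")
  }
  rects <- t(vapply(regions, function(r)
    c(r$offset[1], r$offset[2], r$offset[1] + r$width, r$offset[2] + r$height),
    numeric(4)))
  if (nrow(rects) > 1) {
    ov <- iou_matrix(rects, rects)
    diag(ov) <- 0
    if (any(ov > 0)) stop("region rectangles overlap")
  }
  structure(list(well_id = well_id, image_path = image_path,
                 width = width, height = height, regions = regions),
            class = "well_annotation")
}

#' @export
print.well_annotation <- function(x, ...) {
  cells <- well_cells(x)
  cat("<well_annotation> ", x$well_id, ": ", x$width, "x", x$height, " px, ",
      length(x$regions), " region(s), ", length(cells), " cell(s)\n", sep = "")
  if (length(cells) > 0) {
    print(table(factor(vapply(cells, `[[`, "", "cell_type"),
                       levels = CELL_TYPES)))
  }
  invisible(x)
}

#' All cells of a well in well coordinates
#'
#' Flattens the region structure, translating each polygon by its region's
#' offset.
#'
#' @param well A [well_annotation()].
#' @return List of [cell_annotation()] with polygons in well coordinates.
#' @export
well_cells <- function(well) {
  out <- list()
  for (r in well$regions) {
    for (cell in r$cells) {
      p <- cell$polygon
      p[, 1] <- p[, 1] + r$offset[1]
      p[, 2] <- p[, 2] + r$offset[2]
      cell$polygon <- p
      out[[length(out) + 1]] <- cell
    }
  }
  out
}

#' Ground-truth boxes of a well
#'
#' Tightest-square boxes for every cell, in well coordinates.
#'
#' @param well A [well_annotation()].
#' @param types Cell types to include (default all).
#' @return Data frame with columns `x_min,y_min,x_max,y_max,class`.
#' @export
well_boxes <- function(well, types = CELL_TYPES) {
  cells <- well_cells(well)
  keep <- vapply(cells, function(cl) cl$cell_type %in% types, TRUE)
  cells <- cells[keep]
  if (length(cells) == 0) {
    return(data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  bx <- t(vapply(cells, function(cl)
    unclass(tightest_square_bbox(cl$polygon, well$width, well$height)),
    numeric(4)))
  data.frame(x_min = bx[, 1], y_min = bx[, 2], x_max = bx[, 3],
             y_max = bx[, 4],
             class = vapply(cells, `[[`, "", "cell_type"),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# LabelMe-compatible JSON dialect.
# Top level: imagePath, imageWidth, imageHeight, shapes.
# Shape: {label, points [[x, y], ...], shape_type: "polygon"} plus an
# optional "description" carrying "nuclei=<n>".

#' Default mapping from annotation labels to cell types
#'
#' The annotation tool's label strings are a local convention; this table
#' maps them to the canonical taxonomy and is configurable everywhere a
#' file is read.
#'
#' @return Named character vector, label -> cell type.
#' @export
default_label_map <- function() {
  c(preosteoclast = "preosteoclast",
    osteoclast_type1 = "osteoclast_i",
    osteoclast_type2 = "osteoclast_ii",
    ghost_cell = "ghost")
}

#' Read a LabelMe-compatible annotation file
#'
#' @param path JSON file path.
#' @param label_map Named character vector mapping the file's label strings
#'   to [CELL_TYPES]; defaults to [default_label_map()]. Unknown labels are
#'   an error that lists every offending label and shape index.
#' @param well_id Well identifier; defaults to the file name sans extension.
#' @return A [well_annotation()] with a single region covering the image.
#' @export
read_annotation <- function(path, label_map = default_label_map(),
                            well_id = NULL) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed annotation JSON in ",
                                           path, ": ", conditionMessage(e)))
  for (key in c("imagePath", "imageWidth", "imageHeight", "shapes")) {
    if (is.null(obj[[key]])) stop("annotation file ", path,
                                  " lacks required key '", key, "'")
  }
  w <- as.numeric(obj$imageWidth)
  h <- as.numeric(obj$imageHeight)
  cells <- list()
  unknown <- character(0)
  for (i in seq_along(obj$shapes)) {
    sh <- obj$shapes[[i]]
    if (!identical(sh$shape_type, "polygon")) {
      stop("shape ", i, " in ", path, " has unsupported shape_type '",
           sh$shape_type %||% "<missing>", "' (only 'polygon' is supported)")
    }
    pts <- do.call(rbind, lapply(sh$points, function(pt) as.numeric(pt)))
    if (is.null(pts) || nrow(pts) < 3) {
      stop("shape ", i, " in ", path, " has fewer than 3 points")
    }
    if (any(pts[, 1] < 0) || any(pts[, 1] > w) ||
        any(pts[, 2] < 0) || any(pts[, 2] > h)) {
      stop("shape ", i, " in ", path, " has vertices outside the image ",
           "bounds ", w, "x", h)
    }
    lbl <- as.character(sh$label)
    if (!lbl %in% names(label_map)) {
      unknown <- c(unknown, sprintf("shape %d: '%s'", i, lbl))
      next
    }
    n_nuc <- parse_nuclei(sh$description)
    cells[[length(cells) + 1]] <-
      cell_annotation(pts, label_map[[lbl]], n_nuc)
  }
  if (length(unknown) > 0) {
    stop("unknown label(s) in ", path, " (not in label_map): ",
         paste(unknown, collapse = "; "))
  }
  well_annotation(
    well_id = well_id %||% sub("\\.[^.]*$", "", basename(path)),
    image_path = obj$imagePath, width = w, height = h,
    regions = list(region_annotation("r1", c(0, 0), w, h, cells)))
}

parse_nuclei <- function(desc) {
  if (is.null(desc) || !nzchar(desc)) return(NA_integer_)
  m <- regmatches(desc, regexec("nuclei=([0-9]+)", desc))[[1]]
  if (length(m) == 2) as.integer(m[2]) else NA_integer_
}

#' Write a LabelMe-compatible annotation file
#'
#' Writes the dialect [read_annotation()] reads; `read_annotation()` of the
#' result reproduces the annotation (cells flattened to well coordinates)
#' up to float formatting.
#'
#' @param well A [well_annotation()].
#' @param path Output JSON path.
#' @param label_map Mapping used in reverse (cell type -> label).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(well, path, label_map = default_label_map()) {
  rev_map <- stats::setNames(names(label_map), unname(label_map))
  cells <- well_cells(well)
  shapes <- lapply(cells, function(cl) {
    sh <- list(
      label = rev_map[[cl$cell_type]],
      points = lapply(seq_len(nrow(cl$polygon)),
                      function(i) as.numeric(cl$polygon[i, ])),
      shape_type = "polygon")
    if (!is.na(cl$n_nuclei)) sh$description <- paste0("nuclei=", cl$n_nuclei)
    sh
  })
  obj <- list(imagePath = well$image_path %||% "",
              imageWidth = well$width, imageHeight = well$height,
              shapes = shapes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
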