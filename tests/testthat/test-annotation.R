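test_that("nucleus counts partition into the three TRAP+ classes", {
  expect_identical(classify_cell_type(1), "preosteoclast")
  expect_identical(classify_cell_type(2), "preosteoclast")
  expect_identical(classify_cell_type(3), "osteoclast_i")
  expect_identical(classify_cell_type(14), "osteoclast_i")
  expect_identical(classify_cell_type(15), "osteoclast_ii")
  expect_identical(classify_cell_type(40), "osteoclast_ii")
  # ghost flag dominates any count
  expect_identical(classify_cell_type(7, is_ghost = TRUE), "ghost")
  expect_identical(classify_cell_type(NA, is_ghost = TRUE), "ghost")
  # no anucleate TRAP+ cell
  expect_error(classify_cell_type(0), "invalid annotation")
  # totality: every count maps to exactly one class
  for (n in 1:60) {
    expect_true(classify_cell_type(n) %in% CELL_TYPES[1:3])
  }
})

test_that("shoelace area matches known shapes and is orientation invariant", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1.0)
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(polygon_area(tri), 6.0)
  # rotation of vertex order and reversal leave the area unchanged
  p <- random_simple_polygon(9)
  a <- polygon_area(p)
  expect_equal(polygon_area(p[c(4:9, 1:3), ]), a)
  expect_equal(polygon_area(p[9:1, ]), a)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "invalid polygon")
})

test_that("shoelace area agrees with a Monte-Carlo point-in-polygon oracle", {
  set.seed(42)
  p <- random_simple_polygon(12, cx = 10, cy = 10, r_min = 3, r_max = 9)
  a <- polygon_area(p)
  # rejection sampling over the bounding box
  n <- 1e6
  bx <- range(p[, 1]); by <- range(p[, 2])
  px <- runif(n, bx[1], bx[2])
  py <- runif(n, by[1], by[2])
  # even-odd crossing test, vectorized over sample points
  inside <- rep(FALSE, n)
  nv <- nrow(p)
  for (i in seq_len(nv)) {
    j <- if (i == 1) nv else i - 1
    cross <- ((p[i, 2] > py) != (p[j, 2] > py)) &
      (px < (p[j, 1] - p[i, 1]) * (py - p[i, 2]) /
         (p[j, 2] - p[i, 2]) + p[i, 1])
    inside <- xor(inside, cross)
  }
  mc <- mean(inside) * diff(bx) * diff(by)
  expect_lt(abs(mc - a) / a, 0.01)
})

test_that("tightest square box contains, is square, and shifts at borders", {
  # integer extent 20 x 10 -> side 20 centered on the extent
  p <- rbind(c(10, 10), c(30, 10), c(30, 20), c(10, 20))
  b <- tightest_square_bbox(p, 1000, 1000)
  expect_equal(unname(b["x_max"] - b["x_min"]), 20)
  expect_equal(unname(b["y_max"] - b["y_min"]), 20)
  expect_equal(unname(b), c(10, 5, 30, 25))
  # an axis-aligned square polygon is its own box
  sqp <- rbind(c(3, 4), c(9, 4), c(9, 10), c(3, 10))
  expect_equal(unname(unclass(tightest_square_bbox(sqp, 100, 100))),
               c(3, 4, 9, 10))
  # extent taller than the image is wide: clipped on x, still contains
  tall <- rbind(c(1, 0), c(5, 0), c(3, 90))
  b2 <- tightest_square_bbox(tall, 10, 100)
  expect_equal(unname(b2[c("x_min", "x_max")]), c(0, 10))
  expect_true(b2["y_min"] <= 0 && b2["y_max"] >= 90)
  # degenerate polygon -> minimum side 1
  degen <- rbind(c(5, 5), c(5, 5), c(5, 5))
  b3 <- tightest_square_bbox(degen, 10, 10)
  expect_equal(unname(b3["x_max"] - b3["x_min"]), 1)
})

test_that("tightest square is minimal on the pixel grid (brute force)", {
  set.seed(7)
  for (rep in 1:50) {
    p <- random_simple_polygon(sample(3:12, 1), cx = runif(1, 15, 45),
                               cy = runif(1, 15, 45), r_min = 1, r_max = 12)
    b <- tightest_square_bbox(p, 60, 60)
    side <- unname(b["x_max"] - b["x_min"])
    expect_equal(side, unname(b["y_max"] - b["y_min"]))
    # contains every vertex (pixel-grid sense: vertex in [x_min, x_max])
    expect_true(all(p[, 1] >= b["x_min"] & p[, 1] <= b["x_max"]))
    expect_true(all(p[, 2] >= b["y_min"] & p[, 2] <= b["y_max"]))
    # no smaller pixel-aligned square covers the pixel extent
    ext <- polygon_bbox_side(p)
    expect_equal(side, max(ext, 1))
  }
})

test_that("annotation files round trip and reject unknown labels", {
  cfg <- tiny_synthetic_config()
  w <- generate_well(cfg, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_annotation(w$annotation, path)
  back <- read_annotation(path, well_id = w$annotation$well_id)
  cells_a <- well_cells(w$annotation)
  cells_b <- well_cells(back)
  expect_length(cells_b, length(cells_a))
  for (i in seq_along(cells_a)) {
    expect_equal(cells_b[[i]]$polygon, cells_a[[i]]$polygon,
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_identical(cells_b[[i]]$cell_type, cells_a[[i]]$cell_type)
    expect_identical(cells_b[[i]]$n_nuclei, cells_a[[i]]$n_nuclei)
  }
  # write(read(f)) is field-identical
  path2 <- withr::local_tempfile(fileext = ".json")
  write_annotation(back, path2)
  expect_identical(jsonlite::fromJSON(path2), jsonlite::fromJSON(path))

  # a single labeled polygon parses to the mapped class
  one <- list(imagePath = "x.png", imageWidth = 100, imageHeight = 100,
              shapes = list(list(label = "osteoclast_type1",
                                 points = list(c(1, 1), c(20, 3), c(18, 25),
                                               c(5, 22), c(2, 10)),
                                 shape_type = "polygon")))
  p1 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(one, p1, auto_unbox = TRUE)
  ann <- read_annotation(p1)
  expect_identical(well_cells(ann)[[1]]$cell_type, "osteoclast_i")

  # unknown labels are reported, not dropped
  one$shapes[[1]]$label <- "unknown_cell"
  p2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(one, p2, auto_unbox = TRUE)
  expect_error(read_annotation(p2), "unknown_cell")

  # out-of-bounds vertices name the shape
  one$shapes[[1]]$label <- "ghost_cell"
  one$shapes[[1]]$points <- list(c(-5, 1), c(20, 3), c(18, 25))
  p3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(one, p3, auto_unbox = TRUE)
  expect_error(read_annotation(p3), "shape 1")
})

test_that("region splitting is an exact partition and reassembles", {
  img <- array(runif(60 * 48 * 3), c(48, 60, 3))   # W=60, H=48
  regs <- split_well_into_regions(img, 4, 4)
  expect_length(regs, 16)
  # coverage histogram: every pixel covered exactly once
  cover <- matrix(0, 48, 60)
  for (r in regs) {
    ys <- (r$offset["y"] + 1):(r$offset["y"] + r$height)
    xs <- (r$offset["x"] + 1):(r$offset["x"] + r$width)
    cover[ys, xs] <- cover[ys, xs] + 1
  }
  expect_true(all(cover == 1))
  # reassembly is pixel-exact
  rec <- array(0, dim(img))
  for (r in regs) {
    ys <- (r$offset["y"] + 1):(r$offset["y"] + r$height)
    xs <- (r$offset["x"] + 1):(r$offset["x"] + r$width)
    rec[ys, xs, ] <- r$image
  }
  expect_identical(rec, img)
  # 1x1 is the identity
  one <- split_well_into_regions(img, 1, 1)
  expect_identical(one[[1]]$image, img)
  expect_equal(one[[1]]$offset, c(x = 0, y = 0))
  # non-divisible dims: remainder in the last column
  img2 <- array(0, c(100, 101, 3))
  regs2 <- split_well_into_regions(img2, 4, 4)
  widths <- vapply(regs2, `[[`, 0, "width")
  expect_equal(sort(unique(widths)), c(25, 26))
  expect_equal(sum(widths[seq(4, 16, by = 4)] == 26), 4)
  # grid larger than the image errors
  expect_error(split_well_into_regions(array(0, c(2, 2, 3)), 4, 4), "grid")
})
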