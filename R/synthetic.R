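# Seeded synthetic TRAP-culture generator. Renders culture-well-like RGB
# images -- magenta/purple multinucleated cells on a pale background, plus
# faint ghost-cell silhouettes -- with exact polygon/class/nucleus ground
# truth, standing in for real annotated wells in training, testing and
# validation. Cells are smoothed random-star polygons (radial harmonics on
# an ellipse), not circles, so the box-conversion and IoU paths are
# exercised on irregular shapes.

#' Synthetic culture configuration
#'
#' Defaults emulate a 4x-magnification TRAP-stained culture well imaged at
#' about 1,000 px: a ~6 mm well at 6 um/px, several hundred cells per
#' well (tens per annotation region), cell diameters inside the 51-383 um
#' detectable range -- so a typical cell spans a tenth to a half of an
#' inference tile, and only giant type II cells approach tile size --
#' class mixture and per-class nucleus distributions consistent with the
#' cell-type taxonomy, stronger staining for more mature (larger) cells,
#' and near-background ghost silhouettes that are genuinely hard to see.
#'
#' @param image_size Square well side in px.
#' @param pixel_scale_um Micrometers per pixel.
#' @param cells_per_well Expected number of cells (Poisson).
#' @param class_mixture Probabilities over
#'   `preosteoclast, osteoclast_i, osteoclast_ii, ghost`; must sum to 1.
#' @param nucleus_range Named list of `c(min, max)` nucleus counts per
#'   TRAP+ class (uniform); must be consistent with
#'   [classify_cell_type()].
#' @param diameter_um Named list of `c(min, max)` cell diameters (um) per
#'   class, support within `[51, 383]`.
#' @param stain_hue Hue range of the TRAP stain (fraction of the hue
#'   circle; magenta/purple).
#' @param stain_saturation Named vector of per-class saturation of the
#'   TRAP+ classes (maturity-dependent staining).
#' @param contrast Global stain-contrast multiplier (difficulty knob).
#' @param background_rgb Pale background color.
#' @param noise_sd Additive Gaussian pixel noise.
#' @param max_overlap Maximum allowed center-distance overlap fraction
#'   between two cells.
#' @param density_heterogeneity Strength of the smooth spatial density
#'   field cells are placed from (0 = uniform). The default reproduces
#'   the wide spread of per-region cell counts seen in real cultures,
#'   where region counts range from a handful to a few times the mean.
#' @param seed Default seed for [generate_well()].
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(image_size = 1024,
                             pixel_scale_um = 6.0,
                             cells_per_well = 900,
                             class_mixture = c(preosteoclast = 0.35,
                                               osteoclast_i = 0.35,
                                               osteoclast_ii = 0.10,
                                               ghost = 0.20),
                             nucleus_range = list(
                               preosteoclast = c(1, 2),
                               osteoclast_i = c(3, 14),
                               osteoclast_ii = c(15, 40)),
                             diameter_um = list(
                               preosteoclast = c(51, 85),
                               osteoclast_i = c(90, 200),
                               osteoclast_ii = c(210, 383),
                               ghost = c(70, 180)),
                             stain_hue = c(0.84, 0.92),
                             stain_saturation = c(preosteoclast = 0.30,
                                                  osteoclast_i = 0.50,
                                                  osteoclast_ii = 0.65),
                             contrast = 1.0,
                             background_rgb = c(0.94, 0.91, 0.93),
                             noise_sd = 0.012,
                             max_overlap = 0.15,
                             density_heterogeneity = 1.0,
                             seed = 1L) {
  stopifnot(abs(sum(class_mixture) - 1) < 1e-9,
            all(names(class_mixture) == CELL_TYPES))
  for (ct in names(nucleus_range)) {
    rg <- nucleus_range[[ct]]
    if (classify_cell_type(rg[1]) != ct || classify_cell_type(rg[2]) != ct) {
      stop("nucleus_range for ", ct, " is inconsistent with the taxonomy")
    }
  }
  for (ct in names(diameter_um)) {
    if (any(diameter_um[[ct]] <= 0)) stop("diameters must be positive")
  }
  structure(list(image_size = image_size, pixel_scale_um = pixel_scale_um,
                 cells_per_well = cells_per_well,
                 class_mixture = class_mixture,
                 nucleus_range = nucleus_range, diameter_um = diameter_um,
                 stain_hue = stain_hue,
                 stain_saturation = stain_saturation, contrast = contrast,
                 background_rgb = background_rgb, noise_sd = noise_sd,
                 max_overlap = max_overlap,
                 density_heterogeneity = density_heterogeneity,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Smoothed random-star polygon around the origin; rescaled so the larger
# axis-aligned extent equals `diameter` px.
random_star_polygon <- function(diameter, n_vertices = 14) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  th <- th + runif(n_vertices, -0.4, 0.4) * (2 * pi / n_vertices)
  amp <- runif(3, 0, c(0.12, 0.08, 0.05))
  ph <- runif(3, 0, 2 * pi)
  r <- 1 + amp[1] * sin(th + ph[1]) + amp[2] * sin(2 * th + ph[2]) +
    amp[3] * sin(3 * th + ph[3])
  q <- runif(1, 0.75, 1)                 # ellipse ratio
  rot <- runif(1, 0, pi)
  x <- r * cos(th) * q
  y <- r * sin(th)
  xr <- x * cos(rot) - y * sin(rot)
  yr <- x * sin(rot) + y * cos(rot)
  ext <- max(diff(range(xr)), diff(range(yr)))
  s <- diameter / ext
  cbind(x = xr * s, y = yr * s)
}

#' Generate a synthetic annotated well
#'
#' Deterministic given `(cfg, seed)`: the same pair always yields a
#' bitwise-identical image and annotation. Cells are placed by rejection
#' sampling under the overlap constraint (largest first, so giant type II
#' cells find room); a cell that cannot be placed after 150 attempts is
#' skipped. Every rendered cell carries its exact polygon, class, and
#' nucleus count (nuclei are drawn inside the cell body); ghost cells get
#' a near-background silhouette and no nucleus count.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed (default `cfg$seed`).
#' @return List `image` (H x W x 3 array) and `annotation`
#'   ([well_annotation()] with one region). The annotation carries a
#'   `tally` attribute with the generator's internal per-class counts and
#'   union-area bookkeeping.
#' @export
generate_well <- function(cfg, seed = cfg$seed) {
  with_seed(seed, generate_well_impl(cfg, seed))
}

generate_well_impl <- function(cfg, seed) {
  sz <- cfg$image_size
  n <- rpois(1, cfg$cells_per_well)
  classes <- sample(CELL_TYPES, n, replace = TRUE, prob = cfg$class_mixture)
  # smooth spatial density: base level plus a few Gaussian blobs, as in
  # real cultures where cell density varies severalfold across the well
  h <- cfg$density_heterogeneity %||% 0
  if (h > 0) {
    nb <- 3
    bx <- runif(nb, 0.15, 0.85) * sz
    by <- runif(nb, 0.15, 0.85) * sz
    bs <- runif(nb, 0.15, 0.35) * sz
    bw <- runif(nb, 0.4, 1)
    density_at <- function(x, y) {
      g <- 0
      for (k in seq_len(nb)) {
        g <- g + bw[k] * exp(-((x - bx[k])^2 + (y - by[k])^2) /
                               (2 * bs[k]^2))
      }
      (1 - h * 0.8) + h * 0.8 * min(g, 1)
    }
  } else {
    density_at <- function(x, y) 1
  }
  diam_px <- vapply(classes, function(ct) {
    runif(1, cfg$diameter_um[[ct]][1], cfg$diameter_um[[ct]][2]) /
      cfg$pixel_scale_um
  }, numeric(1))
  ord <- order(-diam_px)                  # place big cells first
  placed <- list()
  centers <- matrix(0, 0, 2)
  radii <- numeric(0)
  for (k in ord) {
    D <- diam_px[k]
    if (D + 4 >= sz) next
    rad <- D / 2
    ok <- FALSE
    for (att in seq_len(150)) {
      cx <- runif(1, rad + 2, sz - rad - 2)
      cy <- runif(1, rad + 2, sz - rad - 2)
      if (runif(1) > density_at(cx, cy)) next
      if (nrow(centers) > 0) {
        dd <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        if (any(dd < (radii + rad) * (1 - cfg$max_overlap))) next
      }
      ok <- TRUE
      break
    }
    if (!ok) next
    poly <- random_star_polygon(D)
    poly[, 1] <- pmin(pmax(poly[, 1] + cx, 0), sz)
    poly[, 2] <- pmin(pmax(poly[, 2] + cy, 0), sz)
    ct <- classes[k]
    n_nuc <- if (ct == "ghost") NA_integer_ else {
      rg <- cfg$nucleus_range[[ct]]
      sample(seq(rg[1], rg[2]), 1)
    }
    placed[[length(placed) + 1]] <-
      list(polygon = poly, cell_type = ct, n_nuclei = n_nuc,
           center = c(cx, cy), radius = rad)
    centers <- rbind(centers, c(cx, cy))
    radii <- c(radii, rad)
  }
  img <- render_culture(cfg, placed, sz)
  cells <- lapply(placed, function(pl)
    cell_annotation(pl$polygon, pl$cell_type, pl$n_nuclei))
  ann <- well_annotation(well_id = paste0("synthetic_", seed),
                         image_path = "", width = sz, height = sz,
                         regions = list(
                           region_annotation("r1", c(0, 0), sz, sz, cells)))
  all_mask <- matrix(FALSE, sz, sz)
  trap_mask <- matrix(FALSE, sz, sz)
  for (pl in placed) {
    # fill in the polygon's local window, then offset into the well masks
    x0 <- max(0, floor(min(pl$polygon[, 1])))
    y0 <- max(0, floor(min(pl$polygon[, 2])))
    x1 <- min(sz, ceiling(max(pl$polygon[, 1])))
    y1 <- min(sz, ceiling(max(pl$polygon[, 2])))
    m <- cpp_fill_polygon(pl$polygon[, 1] - x0, pl$polygon[, 2] - y0,
                          y1 - y0, x1 - x0)
    idx <- which(m)
    rows <- ((idx - 1) %% (y1 - y0)) + y0 + 1
    cols <- ((idx - 1) %/% (y1 - y0)) + x0 + 1
    flat <- cbind(rows, cols)
    all_mask[flat] <- TRUE
    if (pl$cell_type != "ghost") trap_mask[flat] <- TRUE
  }
  attr(ann, "tally") <- list(
    counts = vapply(CELL_TYPES, function(ct)
      sum(vapply(placed, function(pl) pl$cell_type == ct, TRUE)), 0),
    n_drawn = n, n_placed = length(placed),
    area_px2_all = sum(all_mask), area_px2_trap = sum(trap_mask))
  list(image = img, annotation = ann)
}

render_culture <- function(cfg, placed, sz) {
  ch <- lapply(cfg$background_rgb, function(v) matrix(v, sz, sz))
  nuc_rgb <- hsv_to_rgb_num(0.78, 0.55, 0.33)
  hue0 <- mean(cfg$stain_hue)
  bg_hsv <- rgb_to_hsv_num(cfg$background_rgb[1], cfg$background_rgb[2],
                           cfg$background_rgb[3])
  for (pl in placed) {
    poly <- pl$polygon
    x0 <- max(0, floor(min(poly[, 1])) - 1)
    y0 <- max(0, floor(min(poly[, 2])) - 1)
    x1 <- min(sz, ceiling(max(poly[, 1])) + 1)
    y1 <- min(sz, ceiling(max(poly[, 2])) + 1)
    w <- x1 - x0; h <- y1 - y0
    lm <- cpp_fill_polygon(poly[, 1] - x0, poly[, 2] - y0, h, w)
    idx <- which(lm)
    if (length(idx) == 0) next
    # inner region (shrunk polygon) for the rim effect and nuclei
    ctr <- polygon_centroid(poly)
    inner <- cbind((poly[, 1] - ctr[1]) * 0.82 + ctr[1] - x0,
                   (poly[, 2] - ctr[2]) * 0.82 + ctr[2] - y0)
    im <- cpp_fill_polygon(inner[, 1], inner[, 2], h, w)
    rim <- lm & !im
    np <- length(idx)
    if (pl$cell_type == "ghost") {
      # faint silhouette: a whisper below background, rim slightly darker
      dv <- 0.035 * cfg$contrast
      hsv <- list(h = rep(hue0, np),
                  s = pmin(bg_hsv$s + 0.03 * cfg$contrast +
                             rnorm(np, 0, 0.01), 1),
                  v = pmax(bg_hsv$v - dv - rnorm(np, 0, 0.008), 0))
      hsv$v[rim[idx]] <- pmax(hsv$v[rim[idx]] - 0.04 * cfg$contrast, 0)
    } else {
      sat <- cfg$stain_saturation[[pl$cell_type]] * cfg$contrast
      hsv <- list(h = (runif(np, cfg$stain_hue[1], cfg$stain_hue[2])) %% 1,
                  s = pmin(pmax(sat + rnorm(np, 0, 0.04), 0), 1),
                  v = pmin(pmax(0.72 - 0.25 * sat + rnorm(np, 0, 0.03),
                                0), 1))
      hsv$v[rim[idx]] <- hsv$v[rim[idx]] * 0.82
    }
    rgb <- hsv_to_rgb_num(hsv$h, hsv$s, hsv$v)
    rows <- ((idx - 1) %% h) + y0 + 1
    cols <- ((idx - 1) %/% h) + x0 + 1
    flat <- cbind(rows, cols)
    ch[[1]][flat] <- rgb$r
    ch[[2]][flat] <- rgb$g
    ch[[3]][flat] <- rgb$b
    if (pl$cell_type != "ghost" && !is.na(pl$n_nuclei)) {
      # assign here rather than in the helper: passing the channel
      # matrices through a function would copy them for every cell
      nf <- nucleus_pixels(pl, im, x0, y0, h, w, nrow(ch[[1]]),
                           ncol(ch[[1]]), cfg)
      if (nrow(nf) > 0) {
        ch[[1]][nf] <- nuc_rgb$r
        ch[[2]][nf] <- nuc_rgb$g
        ch[[3]][nf] <- nuc_rgb$b
      }
    }
  }
  img <- array(c(ch[[1]], ch[[2]], ch[[3]]), c(sz, sz, 3))
  img <- cpp_blur3(img)
  img <- img + array(rnorm(length(img), 0, cfg$noise_sd), dim(img))
  pmin(pmax(img, 0), 1)
}

# Pixel coordinates of the nucleus disks of one cell: positions drawn by
# vectorized rejection against the inner (shrunk-polygon) mask.
nucleus_pixels <- function(pl, inner_mask, x0, y0, h, w, H, W, cfg) {
  nuc_r <- max(7 / cfg$pixel_scale_um, 1)     # ~14 um nucleus, min 1 px
  n <- pl$n_nuclei
  n_try <- n * 25
  a <- runif(n_try, 0, 2 * pi)
  rr <- sqrt(runif(n_try)) * pl$radius * 0.78
  ix <- round(pl$center[1] + rr * cos(a) - x0)
  iy <- round(pl$center[2] + rr * sin(a) - y0)
  ok <- ix >= 1 & ix <= w & iy >= 1 & iy <= h
  ok[ok] <- inner_mask[cbind(iy[ok], ix[ok])]
  sel <- which(ok)
  sel <- sel[seq_len(min(n, length(sel)))]
  if (length(sel) == 0) return(matrix(0L, 0, 2))
  rg <- ceiling(nuc_r)
  off <- expand.grid(dy = -rg:rg, dx = -rg:rg)
  off <- off[off$dx^2 + off$dy^2 <= nuc_r^2, ]
  py <- rep(iy[sel] + y0, each = nrow(off)) + off$dy
  px <- rep(ix[sel] + x0, each = nrow(off)) + off$dx
  keep <- py >= 1 & py <= H & px >= 1 & px <= W
  cbind(py[keep], px[keep])
}

#' Difficulty suite of synthetic configurations
#'
#' Returns configurations that differ from `base` only in the difficulty
#' knobs, ordered easy to hard: stain contrast decreases while density
#' and allowed overlap increase. Detector metrics are expected to degrade
#' monotonically across the suite.
#'
#' @param base A [synthetic_config()].
#' @param levels Number of levels (level 1 = `base`).
#' @return List of `synthetic_config`, length `levels`.
#' @export
generate_difficulty_suite <- function(base, levels = 3) {
  stopifnot(levels >= 1)
  lapply(seq_len(levels) - 1, function(l) {
    cfg <- base
    cfg$contrast <- base$contrast * 0.65^l
    cfg$cells_per_well <- round(base$cells_per_well * (1 + 0.3 * l))
    cfg$max_overlap <- min(base$max_overlap + 0.12 * l, 0.6)
    cfg
  })
}

#' Write a synthetic well to disk
#'
#' Emits a PNG image and the LabelMe-compatible JSON annotation, i.e.
#' exactly what [read_annotation()] and [read_image()] consume -- a
#' drop-in replacement for a real annotated well.
#'
#' @param well Result of [generate_well()].
#' @param dir Output directory.
#' @param name Base file name (default the well id).
#' @return Named character vector with the two paths, invisibly.
#' @export
write_synthetic_well <- function(well, dir, name = NULL) {
  name <- name %||% well$annotation$well_id
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".png"))
  json_path <- file.path(dir, paste0(name, ".json"))
  write_image(well$image, img_path)
  ann <- well$annotation
  ann$image_path <- basename(img_path)
  write_annotation(ann, json_path)
  invisible(c(image = img_path, annotation = json_path))
}
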