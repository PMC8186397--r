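# Confidence-threshold calibration. A patch-trained detector fires not
# only on whole cells but also on the partial cells that tiling creates
# at patch borders; fragment detections carry systematically lower
# confidence than whole-cell detections. Choosing the per-class operating
# threshold on the *training* wells -- the threshold at which predicted
# whole-well counts match the known counts -- suppresses duplicate
# fragment detections without touching held-out data.

#' Calibrate per-class confidence thresholds on training wells
#'
#' Runs tiled inference on annotated wells at a permissive confidence
#' floor, then for each cell type picks the threshold (over `grid`) whose
#' per-region detection counts best match the annotated per-region counts
#' (smallest summed squared error over all regions of all wells, ties to
#' the lower threshold). Calibrating against the per-region counts — the
#' statistic the agreement analyses report — rather than whole-well
#' totals penalizes compensating errors in different regions. The
#' returned model carries the per-class thresholds in its configuration;
#' [detect_patch()] and [detect_well()] use them automatically.
#'
#' @param model A `detector_model` from [train_detector()].
#' @param wells List of `list(image =, annotation =)` with
#'   [well_annotation()] ground truth (training wells).
#' @param grid Candidate thresholds (default 0.12 to 0.96 by 0.02; wide
#'   enough that the optimum is interior, not clipped at the floor).
#' @param floor Confidence floor used for the single inference pass.
#' @param grid_rows,grid_cols Inference tiling.
#' @param region_rows,region_cols Region grid the counts are matched on.
#' @return The model with `config$conf_threshold` replaced by a named
#'   per-class vector; attribute `calibration` records the error curves.
#' @export
calibrate_confidence <- function(model, wells,
                                 grid = seq(0.12, 0.96, by = 0.02),
                                 floor = 0.12, grid_rows = 8,
                                 grid_cols = 8, region_rows = 4,
                                 region_cols = 4) {
  stopifnot(length(wells) >= 1)
  raw <- lapply(wells, function(w)
    detect_well(model, w$image, grid_rows, grid_cols,
                conf_threshold = floor))
  thresholds <- stats::setNames(numeric(length(CELL_TYPES)), CELL_TYPES)
  curves <- list()
  for (ct in CELL_TYPES) {
    gt <- lapply(wells, function(w)
      per_region_vector(w$annotation, grid_rows = region_rows,
                        grid_cols = region_cols, measure = "count",
                        cell_type = ct))
    err <- vapply(grid, function(t) {
      sum(vapply(seq_along(wells), function(i) {
        d <- raw[[i]]
        keep <- d$class == ct & d$score >= t
        w <- wells[[i]]$annotation
        pred <- per_region_vector(d[keep, , drop = FALSE],
                                  w$width, w$height,
                                  region_rows, region_cols,
                                  "count", ct)
        sum((pred - gt[[i]])^2)
      }, numeric(1)))
    }, numeric(1))
    thresholds[ct] <- grid[which.min(err)]
    curves[[ct]] <- data.frame(threshold = grid, sq_error = err)
  }
  model$config$conf_threshold <- thresholds
  attr(model, "calibration") <- curves
  model
}
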