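# Detector and training configuration. Two named profiles are provided:
# "reference" is the full-scale configuration (input 300, VGG-like
# channels, 120,000 iterations, batch 32, Adam lr 1e-5) and "desk" is a
# small randomly initialized backbone for CPU-scale experiments and tests
# (input 128, 2,000 iterations, batch 8).

#' Detector configuration
#'
#' The detector is a single-shot multibox network with four detection
#' heads (the two coarsest feature scales of the classic six-head layout
#' are removed, which drops anchor boxes spanning large sections of the
#' input -- cells never do). Feature maps halve (ceiling division) after
#' every backbone block; heads attach to the last four blocks.
#'
#' @param profile `"reference"` or `"desk"`; sets all defaults below.
#' @param input_size Square network input in px.
#' @param channels Output channels of each backbone block.
#' @param head_blocks Indices of the blocks carrying detection heads
#'   (always 4 of them).
#' @param anchor_scales Normalized anchor scales, one per head plus one
#'   extra for the geometric-mean anchor of the last head.
#' @param aspect_ratios Anchor aspect ratios at every position.
#' @param nms_iou IoU threshold for non-maximum suppression.
#' @param conf_threshold Confidence threshold for emitted detections.
#' @param top_k Maximum detections kept per patch.
#' @param pixel_scale_um Physical pixel size of the native imagery, in
#'   micrometers per pixel. Required for physical-size checks; there is no
#'   silent default at the command line.
#' @param variances Box-codec variances (center, size).
#' @return List of class `detector_config`.
#' @export
detector_config <- function(profile = c("reference", "desk"),
                            input_size = NULL, channels = NULL,
                            head_blocks = NULL, anchor_scales = NULL,
                            aspect_ratios = c(1, 2, 0.5),
                            nms_iou = 0.45, conf_threshold = 0.5,
                            top_k = 200, pixel_scale_um = NULL,
                            variances = c(0.1, 0.2)) {
  profile <- match.arg(profile)
  def <- switch(profile,
    reference = list(input_size = 300,
                 channels = c(64, 128, 256, 512, 512, 512),
                 head_blocks = 3:6,
                 anchor_scales = c(0.10, 0.26, 0.45, 0.65, 0.85),
                 pixel_scale_um = 1.6),
    desk = list(input_size = 128,
                channels = c(8, 16, 24, 32, 32),
                head_blocks = 2:5,
                anchor_scales = c(0.06, 0.14, 0.28, 0.45, 0.65),
                pixel_scale_um = 6.0))
  cfg <- list(
    profile = profile,
    input_size = input_size %||% def$input_size,
    channels = channels %||% def$channels,
    head_blocks = head_blocks %||% def$head_blocks,
    anchor_scales = anchor_scales %||% def$anchor_scales,
    aspect_ratios = aspect_ratios,
    n_classes = length(CELL_TYPES),
    nms_iou = nms_iou,
    conf_threshold = conf_threshold,
    top_k = top_k,
    pixel_scale_um = pixel_scale_um %||% def$pixel_scale_um,
    variances = variances)
  if (length(cfg$head_blocks) != 4) {
    stop("the detector uses exactly 4 detection heads")
  }
  if (length(cfg$anchor_scales) != 5 || any(diff(cfg$anchor_scales) <= 0)) {
    stop("anchor_scales must be 5 strictly increasing values")
  }
  if (max(cfg$head_blocks) > length(cfg$channels)) {
    stop("head_blocks reference blocks beyond the backbone")
  }
  class(cfg) <- "detector_config"
  cfg
}

# Feature-map side of each backbone block: input halves (ceiling) after
# every block's pooling stage.
feature_map_sizes <- function(cfg) {
  s <- cfg$input_size
  sizes <- integer(length(cfg$channels))
  for (b in seq_along(cfg$channels)) {
    s <- ceiling(s / 2)
    sizes[b] <- s
  }
  sizes[cfg$head_blocks]
}

anchors_per_position <- function(cfg) {
  length(cfg$aspect_ratios) + 1L   # + geometric-mean extra scale
}

#' Training configuration
#'
#' @param profile `"reference"` (120,000 iterations, batch 32, Adam learning
#'   rate 1e-5, for a pretrained large backbone) or `"desk"` (2,000
#'   iterations, batch 8, learning rate 1e-3, for the small randomly
#'   initialized backbone).
#' @param iterations,batch_size,learning_rate Override the profile.
#' @param lr_decay_at,lr_decay_factor Step learning-rate schedule: after
#'   `lr_decay_at` of the iterations, the rate is multiplied by
#'   `lr_decay_factor`. The desk profile decays to a tenth for the final
#'   fifth of training (the usual step schedule for short from-scratch
#'   runs); the reference profile keeps its constant rate.
#' @param swa_from Fraction of training after which weights are averaged
#'   (stochastic weight averaging over the low-learning-rate tail;
#'   snapshots every 10 iterations). 1 disables. The desk profile
#'   averages the final tenth; the reference profile disables it.
#' @param seed Integer seed; mandatory.
#' @param checkpoint_interval Iterations between checkpoints (0 = none).
#' @param checkpoint_dir Directory for checkpoints (required if interval
#'   > 0).
#' @return List of class `training_config`.
#' @export
training_config <- function(profile = c("desk", "reference"),
                            iterations = NULL, batch_size = NULL,
                            learning_rate = NULL, lr_decay_at = NULL,
                            lr_decay_factor = NULL, swa_from = NULL,
                            seed = NULL, checkpoint_interval = 0,
                            checkpoint_dir = NULL) {
  profile <- match.arg(profile)
  def <- switch(profile,
    reference = list(iterations = 120000L, batch_size = 32L,
                 learning_rate = 1e-5, lr_decay_at = 1,
                 lr_decay_factor = 1, swa_from = 1),
    desk = list(iterations = 2000L, batch_size = 8L, learning_rate = 1e-3,
                lr_decay_at = 0.8, lr_decay_factor = 0.1, swa_from = 0.9))
  if (is.null(seed)) stop("training_config: a seed is mandatory")
  cfg <- list(profile = profile,
              iterations = as.integer(iterations %||% def$iterations),
              batch_size = as.integer(batch_size %||% def$batch_size),
              learning_rate = learning_rate %||% def$learning_rate,
              lr_decay_at = lr_decay_at %||% def$lr_decay_at,
              lr_decay_factor = lr_decay_factor %||% def$lr_decay_factor,
              swa_from = swa_from %||% def$swa_from,
              optimizer = "adam",
              seed = as.integer(seed),
              checkpoint_interval = checkpoint_interval,
              checkpoint_dir = checkpoint_dir)
  stopifnot(cfg$iterations > 0, cfg$batch_size > 0, cfg$learning_rate > 0)
  class(cfg) <- "training_config"
  cfg
}
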