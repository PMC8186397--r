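# The detection network: a small convolutional backbone of 3x3
# conv + ReLU + 2x2 max-pool blocks, with classification and localization
# convolution heads attached to the last four blocks (four detection
# scales). Convolutions run through im2col GEMM kernels (src/ops.cpp);
# the training loop, loss gradients and Adam live here in R.
#
# Anchor/tensor ordering contract (shared with generate_anchors): within a
# head, positions are column-major over the feature map (y fastest),
# anchors fastest within a position; head output slice (a-1)*K + k holds
# output k of anchor a.

net_init <- function(cfg, seed) {
  with_seed(seed, {
    nb <- length(cfg$channels)
    A <- anchors_per_position(cfg)
    K <- cfg$n_classes + 1L
    blocks <- vector("list", nb)
    cin <- 3L
    for (b in seq_len(nb)) {
      cout <- cfg$channels[b]
      blocks[[b]] <- list(
        w = matrix(rnorm(cout * 9 * cin, sd = sqrt(2 / (9 * cin))),
                   nrow = cout),
        b = rep(0, cout))
      cin <- cout
    }
    heads <- vector("list", length(cfg$head_blocks))
    for (h in seq_along(cfg$head_blocks)) {
      ch <- cfg$channels[cfg$head_blocks[h]]
      cls_b <- rep(0, A * K)
      # bias the background class up so the untrained net predicts mostly
      # background, which stabilizes hard negative mining early on
      cls_b[seq(1, A * K, by = K)] <- 2
      heads[[h]] <- list(
        cls_w = matrix(rnorm(A * K * 9 * ch, sd = sqrt(1 / (9 * ch))),
                       nrow = A * K),
        cls_b = cls_b,
        loc_w = matrix(rnorm(A * 4 * 9 * ch, sd = sqrt(1 / (9 * ch))),
                       nrow = A * 4),
        loc_b = rep(0, A * 4))
    }
    list(blocks = blocks, heads = heads)
  })
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# (f, f, A*K) head tensor -> (A*f*f) x K matrix in anchor order.
head_to_matrix <- function(arr, A, K) {
  f1 <- dim(arr)[1]; f2 <- dim(arr)[2]
  P <- f1 * f2
  m <- matrix(arr, nrow = P, ncol = A * K)
  arr3 <- array(m, c(P, K, A))
  matrix(aperm(arr3, c(3, 1, 2)), nrow = A * P, ncol = K)
}

matrix_to_head <- function(M, f1, f2, A, K) {
  P <- f1 * f2
  arr3 <- array(M, c(A, P, K))
  m <- matrix(aperm(arr3, c(2, 3, 1)), nrow = P, ncol = K * A)
  # column of m is (k, a) with k fastest after aperm order (P, K, A)
  array(m, c(f1, f2, A * K))
}

net_forward <- function(params, cfg, x, keep_cache = FALSE) {
  A <- anchors_per_position(cfg)
  K <- cfg$n_classes + 1L
  nb <- length(params$blocks)
  cache <- if (keep_cache) vector("list", nb) else NULL
  cur <- x
  feats <- vector("list", nb)
  for (b in seq_len(nb)) {
    conv <- cpp_conv2d_fwd(cur, params$blocks[[b]]$w, params$blocks[[b]]$b,
                           3L, 1L, 1L)
    act <- relu(conv)
    pl <- cpp_maxpool2_fwd(act, TRUE)
    if (keep_cache) {
      cache[[b]] <- list(input = cur, conv = conv, idx = pl$idx,
                         conv_dim = dim(conv))
    }
    cur <- pl$out
    feats[[b]] <- cur
  }
  cls <- vector("list", length(cfg$head_blocks))
  loc <- vector("list", length(cfg$head_blocks))
  for (h in seq_along(cfg$head_blocks)) {
    fb <- feats[[cfg$head_blocks[h]]]
    hp <- params$heads[[h]]
    co <- cpp_conv2d_fwd(fb, hp$cls_w, hp$cls_b, 3L, 1L, 1L)
    lo <- cpp_conv2d_fwd(fb, hp$loc_w, hp$loc_b, 3L, 1L, 1L)
    cls[[h]] <- head_to_matrix(co, A, K)
    loc[[h]] <- head_to_matrix(lo, A, 4L)
  }
  list(cls = do.call(rbind, cls), loc = do.call(rbind, loc),
       feats = if (keep_cache) feats else NULL, cache = cache)
}

net_backward <- function(params, cfg, fwd, dcls, dloc) {
  A <- anchors_per_position(cfg)
  K <- cfg$n_classes + 1L
  nb <- length(params$blocks)
  grads <- list(blocks = vector("list", nb),
                heads = vector("list", length(cfg$head_blocks)))
  # split row blocks of dcls/dloc per head
  fms <- feature_map_sizes(cfg)
  counts <- A * fms^2
  offs <- c(0, cumsum(counts))
  dfeat <- vector("list", nb)
  for (h in seq_along(cfg$head_blocks)) {
    b <- cfg$head_blocks[h]
    rows <- (offs[h] + 1):offs[h + 1]
    f <- fms[h]
    dco <- matrix_to_head(dcls[rows, , drop = FALSE], f, f, A, K)
    dlo <- matrix_to_head(dloc[rows, , drop = FALSE], f, f, A, 4L)
    fb <- fwd$feats[[b]]
    hp <- params$heads[[h]]
    rc <- cpp_conv2d_bwd(fb, hp$cls_w, dco, 3L, 1L, 1L)
    rl <- cpp_conv2d_bwd(fb, hp$loc_w, dlo, 3L, 1L, 1L)
    grads$heads[[h]] <- list(cls_w = rc$dw, cls_b = as.numeric(rc$db),
                             loc_w = rl$dw, loc_b = as.numeric(rl$db))
    dfeat[[b]] <- add_or_init(dfeat[[b]], rc$dx + rl$dx)
  }
  dcur <- NULL
  for (b in rev(seq_len(nb))) {
    dcur <- add_or_init(dcur, dfeat[[b]])
    if (is.null(dcur)) {
      dcur <- array(0, dim(fwd$feats[[b]]))
    }
    ch <- fwd$cache[[b]]
    dact <- cpp_maxpool2_bwd(ch$idx, dcur, ch$conv_dim[1], ch$conv_dim[2])
    dact <- dact * (ch$conv > 0)
    r <- cpp_conv2d_bwd(ch$input, params$blocks[[b]]$w, dact, 3L, 1L, 1L)
    grads$blocks[[b]] <- list(w = r$dw, b = as.numeric(r$db))
    dcur <- r$dx
  }
  grads
}

add_or_init <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.null(a)) return(b)
  a + b
}

# ---------------------------------------------------------------------------
# Flat parameter walking for the optimizer.

walk_params <- function(p, f) {
  if (is.list(p)) {
    for (i in seq_along(p)) p[[i]] <- walk_params(p[[i]], f)
    p
  } else {
    f(p)
  }
}

walk_params2 <- function(a, b, f) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- walk_params2(a[[i]], b[[i]], f)
    a
  } else {
    f(a, b)
  }
}

scale_grads <- function(g, s) walk_params(g, function(x) x * s)

accumulate_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  walk_params2(acc, g, `+`)
}

adam_init <- function(params) {
  list(m = walk_params(params, function(x) x * 0),
       v = walk_params(params, function(x) x * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- walk_params2(state$m, grads,
                          function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- walk_params2(state$v, grads,
                          function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- scale_grads(state$m, 1 / bc1)
  vh <- walk_params(state$v, function(v) v / bc2)
  upd <- walk_params2(mh, vh, function(m, v) m / (sqrt(v) + eps))
  params <- walk_params2(params, upd, function(p, u) p - lr * u)
  list(params = params, state = state)
}

# ---------------------------------------------------------------------------

# Normalize a sample's boxes to the unit square of its (possibly
# augmented, hence possibly dimension-swapped) patch image and build
# matching targets against the anchor set.
prepare_targets <- function(sample, anchors, cfg) {
  d <- dim(sample$image)
  w <- d[2]; h <- d[1]
  boxes <- sample$boxes
  if (nrow(boxes) > 0) {
    gt <- cbind(boxes$x_min / w, boxes$y_min / h,
                boxes$x_max / w, boxes$y_max / h)
    cls_col <- match(boxes$class, CELL_TYPES) + 1L
  } else {
    gt <- matrix(0, 0, 4)
    cls_col <- integer(0)
  }
  assign <- match_anchors(anchors, gt, 0.5)
  n <- nrow(anchors)
  tgt_off <- matrix(0, n, 4)
  tgt_cls <- integer(n)
  pos <- which(assign > 0)
  if (length(pos) > 0) {
    tgt_off[pos, ] <- box_codec(gt[assign[pos], , drop = FALSE],
                                anchors[pos, , drop = FALSE],
                                "encode", cfg$variances)
    tgt_cls[pos] <- cls_col[assign[pos]]
  }
  list(assign = assign, tgt_off = tgt_off, tgt_cls = tgt_cls)
}

resize_to_input <- function(img, input_size) {
  d <- dim(img)
  if (d[1] == input_size && d[2] == input_size) return(img)
  cpp_resize_bilinear(img, input_size, input_size)
}

#' Train the detector
#'
#' Streams patch samples from `dataset`, matches ground-truth boxes to the
#' anchor set, and minimizes the multibox loss with Adam. Fully
#' reproducible from the training seed; aborts with a diagnostic on a
#' non-finite loss.
#'
#' @param dataset An iterator from [build_training_set()] (a function
#'   returning `patch_sample`s, `NULL` when exhausted) or a list of
#'   `patch_sample`s, which is cycled.
#' @param dcfg A [detector_config()].
#' @param tcfg A [training_config()].
#' @param verbose Print a progress line every 100 iterations.
#' @return A `detector_model`: list with `params`, `config`, `anchors`,
#'   and `log` (per-iteration loss components).
#' @export
train_detector <- function(dataset, dcfg, tcfg, verbose = FALSE) {
  if (is.list(dataset)) {
    pool <- dataset
    if (length(pool) == 0) stop("empty training dataset")
    k <- 0L
    dataset <- function() {
      k <<- k + 1L
      pool[[(k - 1L) %% length(pool) + 1L]]
    }
  }
  anchors <- generate_anchors(dcfg)
  params <- net_init(dcfg, derive_seed(tcfg$seed, "net-init"))
  state <- adam_init(params)
  swa_start <- ceiling((tcfg$swa_from %||% 1) * tcfg$iterations)
  swa_sum <- NULL
  swa_n <- 0L
  log <- data.frame(iteration = integer(tcfg$iterations),
                    loss = numeric(tcfg$iterations),
                    conf = numeric(tcfg$iterations),
                    loc = numeric(tcfg$iterations))
  for (it in seq_len(tcfg$iterations)) {
    batch <- vector("list", tcfg$batch_size)
    for (j in seq_len(tcfg$batch_size)) {
      s <- dataset()
      if (is.null(s)) stop("training dataset exhausted at iteration ", it)
      batch[[j]] <- s
    }
    acc <- NULL
    tot <- conf <- locl <- 0
    for (s in batch) {
      x <- resize_to_input(s$image, dcfg$input_size)
      tg <- prepare_targets(s, anchors, dcfg)
      fwd <- net_forward(params, dcfg, x, keep_cache = TRUE)
      lg <- multibox_loss_grad(fwd$cls, fwd$loc, tg$assign, tg$tgt_off,
                               tg$tgt_cls)
      tot <- tot + as.numeric(lg$loss)
      conf <- conf + attr(lg$loss, "conf")
      locl <- locl + attr(lg$loss, "loc")
      g <- net_backward(params, dcfg, fwd, lg$dlogits, lg$dloc)
      acc <- accumulate_grads(acc, g)
    }
    nb <- tcfg$batch_size
    if (!is.finite(tot)) {
      stop("non-finite loss at iteration ", it,
           " (conf = ", conf / nb, ", loc = ", locl / nb,
           "); lower the learning rate or inspect the data")
    }
    acc <- scale_grads(acc, 1 / nb)
    lr <- tcfg$learning_rate
    if (it > (tcfg$lr_decay_at %||% 1) * tcfg$iterations) {
      lr <- lr * (tcfg$lr_decay_factor %||% 1)
    }
    st <- adam_step(params, acc, state, lr)
    params <- st$params
    state <- st$state
    # average weights over the low-learning-rate tail of training
    if (it >= swa_start && it < tcfg$iterations &&
        (it - swa_start) %% 10 == 0) {
      swa_sum <- accumulate_grads(swa_sum, params)
      swa_n <- swa_n + 1L
    }
    log$iteration[it] <- it
    log$loss[it] <- tot / nb
    log$conf[it] <- conf / nb
    log$loc[it] <- locl / nb
    if (verbose && it %% 100 == 0) {
      message(sprintf("iter %d: loss %.4f (conf %.4f, loc %.4f)",
                      it, tot / nb, conf / nb, locl / nb))
    }
    if (tcfg$checkpoint_interval > 0 && it %% tcfg$checkpoint_interval == 0) {
      save_detector(
        structure(list(params = params, config = dcfg, anchors = anchors,
                       log = log[seq_len(it), ]), class = "detector_model"),
        file.path(tcfg$checkpoint_dir, sprintf("checkpoint_%06d.rds", it)))
    }
  }
  if (!is.null(swa_sum)) {
    swa_sum <- accumulate_grads(swa_sum, params)   # include final weights
    params <- scale_grads(swa_sum, 1 / (swa_n + 1L))
  }
  structure(list(params = params, config = dcfg, anchors = anchors,
                 log = log),
            class = "detector_model")
}

#' Save / load a detector checkpoint
#'
#' A checkpoint is a single file containing the weights, the embedded
#' detector configuration and the package version.
#'
#' @param model A `detector_model`.
#' @param path Checkpoint file path.
#' @return `path` invisibly; `load_detector()` returns the model.
#' @export
save_detector <- function(model, path) {
  model$version <- as.character(utils::packageVersion("osteoquant"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  readRDS(path)
}

#' Run the detector on one patch
#'
#' Resizes the patch to the network input, decodes anchor offsets into
#' boxes, filters by confidence, applies class-wise non-maximum
#' suppression, and maps the surviving boxes back to the patch's native
#' pixel scale.
#'
#' @param model A `detector_model` from [train_detector()].
#' @param patch H x W x 3 array (native resolution).
#' @param conf_threshold,top_k Optional overrides of the model config;
#'   `conf_threshold` may be a scalar or a named per-class vector (see
#'   [calibrate_confidence()]).
#' @return Detections data frame: `x_min,y_min,x_max,y_max,class,score`
#'   in patch pixel coordinates.
#' @export
detect_patch <- function(model, patch, conf_threshold = NULL, top_k = NULL) {
  cfg <- model$config
  conf_threshold <- conf_threshold %||% cfg$conf_threshold
  top_k <- top_k %||% cfg$top_k
  d <- dim(patch)
  x <- resize_to_input(patch, cfg$input_size)
  fwd <- net_forward(model$params, cfg, x, keep_cache = FALSE)
  p <- softmax_rows(fwd$cls)
  out <- empty_detections()
  for (k in seq_len(cfg$n_classes)) {
    thr <- if (length(conf_threshold) > 1) {
      conf_threshold[[CELL_TYPES[k]]]   # per-class calibrated threshold
    } else {
      conf_threshold
    }
    sc <- p[, k + 1]
    sel <- which(sc >= thr)
    if (length(sel) == 0) next
    dec <- box_codec(fwd$loc[sel, , drop = FALSE],
                     model$anchors[sel, , drop = FALSE],
                     "decode", cfg$variances)
    dec <- pmin(pmax(dec, 0), 1)
    keep <- dec[, 3] > dec[, 1] & dec[, 4] > dec[, 2]
    if (!any(keep)) next
    dec <- dec[keep, , drop = FALSE]
    out <- rbind(out, data.frame(
      x_min = dec[, 1] * d[2], y_min = dec[, 2] * d[1],
      x_max = dec[, 3] * d[2], y_max = dec[, 4] * d[1],
      class = CELL_TYPES[k], score = sc[sel][keep],
      stringsAsFactors = FALSE))
  }
  out <- nms(out, cfg$nms_iou, classwise = TRUE)
  if (nrow(out) > top_k) out <- out[seq_len(top_k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_detections <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
             y_max = numeric(0), class = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}
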