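# Multibox loss: smooth-L1 localization on positive anchors plus
# cross-entropy classification with hard negative mining (negatives capped
# at neg_pos_ratio x positives, picked by highest confidence loss),
# normalized by the number of positives.
#
# Class columns: 1 = background, 1 + k = CELL_TYPES[k].

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

smooth_l1 <- function(d) {
  a <- abs(d)
  ifelse(a < 1, 0.5 * d^2, a - 0.5)
}

#' Multibox detection loss
#'
#' @param class_logits n x (1 + n_classes) matrix of raw class scores
#'   (column 1 = background).
#' @param box_offsets n x 4 matrix of predicted offsets.
#' @param assignment Integer vector from [match_anchors()] (0 =
#'   background).
#' @param target_offsets n x 4 matrix of encoded ground-truth offsets
#'   (rows for background anchors are ignored).
#' @param target_class Integer vector of ground-truth class columns for
#'   positive anchors (values in `2:(1 + n_classes)`; ignored for
#'   background rows).
#' @param neg_pos_ratio Hard-negative cap as a multiple of the positive
#'   count (default 3).
#' @return Scalar loss; attributes `conf` and `loc` carry the two
#'   normalized components.
#' @export
multibox_loss <- function(class_logits, box_offsets, assignment,
                          target_offsets, target_class,
                          neg_pos_ratio = 3) {
  multibox_loss_grad(class_logits, box_offsets, assignment, target_offsets,
                     target_class, neg_pos_ratio, want_grad = FALSE)$loss
}

# Loss plus gradients w.r.t. logits and offsets (used by the trainer).
multibox_loss_grad <- function(class_logits, box_offsets, assignment,
                               target_offsets, target_class,
                               neg_pos_ratio = 3, want_grad = TRUE) {
  n <- nrow(class_logits)
  pos <- which(assignment > 0)
  n_pos <- length(pos)
  norm <- max(n_pos, 1)
  p <- softmax_rows(class_logits)
  ce <- -log(pmax(p[, 1], 1e-12))              # CE against background
  if (n_pos > 0) {
    ce[pos] <- -log(pmax(p[cbind(pos, target_class[pos])], 1e-12))
  }
  # hard negative mining (partial sort: only the top slice is needed)
  neg_cand <- if (n_pos > 0) seq_len(n)[-pos] else seq_len(n)
  n_neg <- min(length(neg_cand), ceiling(neg_pos_ratio * norm))
  ce_neg <- ce[neg_cand]
  if (n_neg < length(neg_cand)) {
    thr <- -sort.int(-ce_neg, partial = n_neg)[n_neg]
    cand <- neg_cand[ce_neg >= thr]
    neg <- cand[order(-ce[cand])][seq_len(n_neg)]
  } else {
    neg <- neg_cand
  }
  l_conf <- sum(ce[pos]) + sum(ce[neg])
  if (n_pos > 0) {
    d <- box_offsets[pos, , drop = FALSE] -
      target_offsets[pos, , drop = FALSE]
    l_loc <- sum(smooth_l1(d))
  } else {
    l_loc <- 0
  }
  loss <- (l_conf + l_loc) / norm
  out <- list(loss = structure(loss, conf = l_conf / norm,
                               loc = l_loc / norm),
              n_pos = n_pos)
  if (want_grad) {
    dlogits <- matrix(0, n, ncol(class_logits))
    sel <- c(pos, neg)
    tgt <- rep(1L, length(sel))
    if (n_pos > 0) tgt[seq_len(n_pos)] <- target_class[pos]
    dlogits[sel, ] <- p[sel, , drop = FALSE]
    dlogits[cbind(sel, tgt)] <- dlogits[cbind(sel, tgt)] - 1
    dlogits <- dlogits / norm
    dloc <- matrix(0, n, 4)
    if (n_pos > 0) {
      dd <- box_offsets[pos, , drop = FALSE] -
        target_offsets[pos, , drop = FALSE]
      g <- ifelse(abs(dd) < 1, dd, sign(dd))
      dloc[pos, ] <- g / norm
    }
    out$dlogits <- dlogits
    out$dloc <- dloc
  }
  out
}
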