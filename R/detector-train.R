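# Target assignment and the toy training loop.

# wh-only IoU used for anchor matching (boxes aligned at a common centre)
anchor_wh_iou <- function(wh, anchors) {
  inter <- pmin(wh[1], anchors[, 1]) * pmin(wh[2], anchors[, 2])
  inter / (wh[1] * wh[2] + anchors[, 1] * anchors[, 2] - inter)
}

# Build regression/objectness/class targets for one batch.
# labels: list (one per image) of data.frames with class, cx, cy, w, h.
#
# Assignment follows the practice of this detector family: a ground
# truth matches every anchor whose width/height IoU exceeds 0.35 (always
# including the best), lands in its centre cell plus the two nearest
# neighbour cells (offsets decoded as 2*sigmoid - 0.5, so targets stay
# in (0, 1)), and cells covered by the box that are not positives are
# excluded from the negative objectness loss (the features there are
# indistinguishable from the positive cell on an elongated marker).
build_targets <- function(cfg, labels, grid_shallow, grid_deep) {
  A <- cfg$anchors_per_head
  N <- length(labels)
  mk <- function(G) list(
    txy = array(0, c(G, G, 2L * A, N)),
    twh = array(0, c(G, G, 2L * A, N)),
    mask = array(0, c(G, G, 2L * A, N)),
    tobj = array(0, c(G, G, A, N)),
    gtbox = array(0, c(G, G, 4L * A, N)),
    negw = array(1, c(G, G, A, N)),
    tcls = array(0, c(G, G, cfg$n_classes, N)),
    mcls = array(0, c(G, G, cfg$n_classes, N)))
  tg <- list(shallow = mk(grid_shallow), deep = mk(grid_deep))
  npos <- 0L
  for (n in seq_len(N)) {
    lab <- labels[[n]]
    if (is.null(lab) || !nrow(lab)) next
    for (r in seq_len(nrow(lab))) {
      wh <- c(lab$w[r], lab$h[r])
      iou6 <- anchor_wh_iou(wh, cfg$anchors)
      matches <- which(iou6 > 0.35)
      if (!length(matches)) matches <- which.max(iou6)
      # small targets are the shallow head's job: a box under 5% of the
      # image area is localised at stride 8, never at stride 32, whose
      # cells are too coarse for it
      if (wh[1] * wh[2] < 0.05) {
        matches <- matches[matches <= A]
        if (!length(matches)) matches <- which.max(iou6[seq_len(A)])
      }
      for (best in matches) {
        hn <- if (best <= A) "shallow" else "deep"
        a <- if (best <= A) best else best - A
        G <- if (hn == "shallow") grid_shallow else grid_deep
        gx <- lab$cx[r] * G; gy <- lab$cy[r] * G
        j0 <- min(max(floor(gx), 0), G - 1)   # col = x
        i0 <- min(max(floor(gy), 0), G - 1)   # row = y
        # centre cell only: on an elongated uniform marker, neighbouring
        # cells see near-identical features and cannot be asked for
        # different offsets; the covered ring is ignored instead
        cells <- matrix(c(i0, j0), 1, 2)
        anc <- cfg$anchors[best, ]
        t <- tg[[hn]]
        # ignore the whole covered region for this head's negatives
        ir <- max(0, floor(gy - lab$h[r] * G / 2)):
          min(G - 1, ceiling(gy + lab$h[r] * G / 2) - 1L)
        jr <- max(0, floor(gx - lab$w[r] * G / 2)):
          min(G - 1, ceiling(gx + lab$w[r] * G / 2) - 1L)
        t$negw[ir + 1, jr + 1, , n] <- 0
        for (cc in seq_len(nrow(cells))) {
          i <- cells[cc, 1]; j <- cells[cc, 2]
          if (i < 0 || i >= G || j < 0 || j >= G) next
          ox <- gx - j; oy <- gy - i
          if (ox <= -0.5 || ox >= 1.5 || oy <= -0.5 || oy >= 1.5) next
          t$txy[i + 1, j + 1, 2L * (a - 1L) + 1L, n] <- (ox + 0.5) / 2
          t$txy[i + 1, j + 1, 2L * (a - 1L) + 2L, n] <- (oy + 0.5) / 2
          t$twh[i + 1, j + 1, 2L * (a - 1L) + 1L, n] <- log(wh[1] / anc[1])
          t$twh[i + 1, j + 1, 2L * (a - 1L) + 2L, n] <- log(wh[2] / anc[2])
          t$mask[i + 1, j + 1, 2L * (a - 1L) + 1:2, n] <- 1
          t$tobj[i + 1, j + 1, a, n] <- 1
          t$gtbox[i + 1, j + 1, 4L * (a - 1L) + 1:4, n] <-
            c(lab$cx[r], lab$cy[r], wh)
          t$negw[i + 1, j + 1, a, n] <- 0
          t$tcls[i + 1, j + 1, lab$class[r] + 1L, n] <- 1
          t$mcls[i + 1, j + 1, , n] <- 1
          npos <- npos + 1L
        }
        tg[[hn]] <- t
      }
    }
  }
  tg$npos <- npos
  tg
}

# Compose the scalar loss node on an existing training tape.
# Box terms: MSE on sigmoid(tx, ty) vs the cell fraction and on raw
# (tw, th) vs log anchor ratios, at assigned anchors only; objectness
# and class terms: weighted binary cross-entropy with logits.
detector_loss <- function(model, fw, tg) {
  tp <- fw$tape
  cfg <- model$cfg
  A <- cfg$anchors_per_head
  xyidx <- as.vector(vapply(seq_len(A),
                            function(a) 4L * (a - 1L) + 1:2, integer(2)))
  whidx <- as.vector(vapply(seq_len(A),
                            function(a) 4L * (a - 1L) + 3:4, integer(2)))
  npos <- max(1, tg$npos)
  ids <- integer(0); coefs <- numeric(0)
  A_ <- cfg$anchors_per_head
  for (hn in c("shallow", "deep")) {
    h <- fw$nodes[[hn]]
    t <- tg[[hn]]
    xy <- op_sigmoid(tp, op_channels(tp, h$reg, xyidx))
    wh <- op_channels(tp, h$reg, whidx)
    # IoU-aware objectness: the target at a positive is the IoU of the
    # currently decoded box with its ground truth (no gradient through
    # the target), so a head that cannot localise precisely learns a
    # proportionally lower confidence and does not outrank precise boxes
    reg_now <- tn_val(tp, h$reg)
    G <- dim(reg_now)[1]
    anc_h <- if (hn == "shallow") cfg$anchors[seq_len(A_), , drop = FALSE]
             else cfg$anchors[A_ + seq_len(A_), , drop = FALSE]
    tobj_soft <- t$tobj
    pos <- which(t$tobj == 1, arr.ind = TRUE)
    if (nrow(pos)) {
      sg <- function(z) 1 / (1 + exp(-z))
      for (k in seq_len(nrow(pos))) {
        i <- pos[k, 1]; j <- pos[k, 2]; a <- pos[k, 3]; n <- pos[k, 4]
        rg <- reg_now[i, j, 4L * (a - 1L) + 1:4, n]
        pb <- c((2 * sg(rg[1]) - 0.5 + (j - 1)) / G,
                (2 * sg(rg[2]) - 0.5 + (i - 1)) / G,
                anc_h[a, 1] * exp(min(rg[3], 4)),
                anc_h[a, 2] * exp(min(rg[4], 4)))
        gb <- t$gtbox[i, j, 4L * (a - 1L) + 1:4, n]
        tobj_soft[i, j, a, n] <- box_iou_matrix(matrix(pb, 1), matrix(gb, 1))[1, 1]
      }
    }
    # positives pull objectness up strongly; true background is pushed
    # down; box-covered non-positive cells carry zero negative weight.
    # The class channel is also supervised (lightly) on background so an
    # untrained class logit cannot inflate background scores.
    ids <- c(ids, op_mse(tp, xy, t$txy, t$mask, npos),
             op_mse(tp, wh, t$twh, t$mask, npos),
             op_bce_logits(tp, h$obj, tobj_soft,
                           5 * t$tobj + 2 * t$negw, npos),
             op_bce_logits(tp, h$cls, t$tcls,
                           t$mcls + 0.1 * (1 - t$mcls), npos))
    # box-offset precision dominates IoU for a thin, wide marker, so
    # the centre-offset term carries the largest weight; objectness and
    # class keep enough weight not to be starved by the box terms
    coefs <- c(coefs, 25, 10, 5, 2)
  }
  op_wsum(tp, ids, coefs)
}

#' Train the detector on a small labelled dataset
#'
#' Desk-scale training with Adam: meant for overfitting sanity checks on
#' synthetic scenes and for exercising the full computation graph, not
#' for producing deployable weights. The loop is deterministic given the
#' seed and aborts with diagnostics if the loss diverges.
#'
#' @param model a \code{"cpr_detector"} (modified in place).
#' @param dataset list with \code{images} (list of \code{(H, W, 3)}
#'   arrays in \[0, 1\]) and \code{labels} (list of data frames with
#'   \code{class}, \code{cx}, \code{cy}, \code{w}, \code{h} normalised).
#' @param epochs,lr,batch training schedule (defaults 60 / 0.001 / 16).
#' @param seed RNG seed controlling shuffling.
#' @param checkpoint path for the final checkpoint; a temporary file by
#'   default.
#' @param verbose print the epoch loss.
#' @return Invisibly, a list with the \code{model}, per-epoch
#'   \code{loss_history}, and the \code{checkpoint} path.
#' @export
train_toy <- function(model, dataset, epochs = 60L, lr = 1e-3, batch = 16L,
                      seed = 1L, checkpoint = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "cpr_detector"))
  n <- length(dataset$images)
  if (n == 0L) stop("empty dataset", call. = FALSE)
  if (length(dataset$labels) != n)
    stop("images and labels must align", call. = FALSE)
  set.seed(seed)
  opt <- new.env(parent = emptyenv())
  opt$t <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    # step decay: final fifth of the schedule at a tenth of the rate
    lr_ep <- if (ep > 0.8 * epochs) lr * 0.1 else lr
    perm <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch)) {
      sel <- perm[start:min(start + batch - 1L, n)]
      xb <- simplify2array(dataset$images[sel])   # (H, W, 3, |sel|)
      if (length(dim(xb)) == 3L) dim(xb) <- c(dim(xb), 1L)
      fw <- detector_forward(model, xb, training = TRUE)
      gs <- dim(fw$shallow$reg)[1]
      gd <- dim(fw$deep$reg)[1]
      tg <- build_targets(model$cfg, dataset$labels[sel], gs, gd)
      loss_id <- detector_loss(model, fw, tg)
      lv <- tn_val(fw$tape, loss_id)
      if (!is.finite(lv))
        stop(sprintf(
          "training diverged: non-finite loss at epoch %d (batch starting %d); last finite epoch loss %.4f",
          ep, start, if (ep > 1) history[ep - 1] else NA_real_), call. = FALSE)
      grads <- tape_backward(fw$tape, loss_id)
      pg <- tape_param_grads(fw$tape, grads)
      if (lr > 0) {
        opt$t <- opt$t + 1
        corr <- sqrt(1 - b2^opt$t) / (1 - b1^opt$t)
        for (nm in names(pg)) {
          g <- pg[[nm]]
          if (is.null(g)) next
          mkey <- paste0(nm, ".m"); vkey <- paste0(nm, ".v")
          mo <- opt[[mkey]]; vo <- opt[[vkey]]
          if (is.null(mo)) { mo <- g * 0; vo <- g * 0 }
          mo <- b1 * mo + (1 - b1) * g
          vo <- b2 * vo + (1 - b2) * g * g
          opt[[mkey]] <- mo; opt[[vkey]] <- vo
          model$params[[nm]] <- model$params[[nm]] -
            lr_ep * corr * mo / (sqrt(vo) + eps)
        }
      }
      ep_loss <- ep_loss + lv; nb <- nb + 1L
    }
    history[ep] <- ep_loss / nb
    if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, history[ep]))
  }
  # settle the batch-norm running statistics on the final weights so
  # evaluation-mode activations match what the loss was trained on
  model$bn_momentum <- 0.5
  for (rep in 1:2) for (start in seq(1L, n, by = batch)) {
    sel <- start:min(start + batch - 1L, n)
    xb <- simplify2array(dataset$images[sel])
    if (length(dim(xb)) == 3L) dim(xb) <- c(dim(xb), 1L)
    detector_forward(model, xb, training = TRUE)
  }
  model$bn_momentum <- NULL
  if (is.null(checkpoint)) checkpoint <- tempfile("cpr_detector_",
                                                  fileext = ".rds")
  save_detector(model, checkpoint)
  invisible(list(model = model, loss_history = history,
                 checkpoint = checkpoint))
}

#' Detect the marker wristband in images
#'
#' @param model a trained \code{"cpr_detector"}.
#' @param images a single \code{(H, W, 3)} array or list of them.
#' @param conf_thr,iou_thr optional decoding threshold overrides.
#' @return A \code{"detections"} data frame (see [decode_and_nms()]).
#' @export
detect_marker <- function(model, images, conf_thr = NULL, iou_thr = NULL) {
  if (!is.list(images)) images <- list(images)
  xb <- simplify2array(images)
  if (length(dim(xb)) == 3L) dim(xb) <- c(dim(xb), 1L)
  fw <- detector_forward(model, xb, training = FALSE)
  decode_and_nms(fw, model$cfg, conf_thr, iou_thr)
}
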