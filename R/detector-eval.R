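#' Detection evaluation counts
#'
#' @param TP,FP,FN,TN non-negative integer counts of true positives,
#'   false positives, false negatives and true negatives.
#' @return An object of class \code{"eval_counts"}.
#' @export
eval_counts <- function(TP, FP = 0L, FN = 0L, TN = 0L) {
  v <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(v < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(as.list(v), class = "eval_counts")
}

#' Detection precision and recall
#'
#' Precision is \code{TP / (TP + FP)}; recall is \code{TP / (TP + FN)}.
#' A zero denominator yields 0 with a warning.
#'
#' @param counts an [eval_counts()].
#' @return A value in \[0, 1\].
#' @export
precision <- function(counts) {
  stopifnot(inherits(counts, "eval_counts"))
  den <- counts$TP + counts$FP
  if (den == 0) { warning("precision undefined (TP + FP = 0); returning 0"); return(0) }
  counts$TP / den
}

#' @rdname precision
#' @export
recall <- function(counts) {
  stopifnot(inherits(counts, "eval_counts"))
  den <- counts$TP + counts$FN
  if (den == 0) { warning("recall undefined (TP + FN = 0); returning 0"); return(0) }
  counts$TP / den
}

# IoU between two sets of normalised (cx, cy, w, h) boxes: n x m matrix
box_iou_matrix <- function(a, b) {
  a <- matrix(a, ncol = 4); b <- matrix(b, ncol = 4)
  ax1 <- a[, 1] - a[, 3] / 2; ax2 <- a[, 1] + a[, 3] / 2
  ay1 <- a[, 2] - a[, 4] / 2; ay2 <- a[, 2] + a[, 4] / 2
  bx1 <- b[, 1] - b[, 3] / 2; bx2 <- b[, 1] + b[, 3] / 2
  by1 <- b[, 2] - b[, 4] / 2; by2 <- b[, 2] + b[, 4] / 2
  iw <- outer(ax2, bx2, pmin) - outer(ax1, bx1, pmax)
  ih <- outer(ay2, by2, pmin) - outer(ay1, by1, pmax)
  iw[iw < 0] <- 0; ih[ih < 0] <- 0
  inter <- iw * ih
  ua <- outer((ax2 - ax1) * (ay2 - ay1), (bx2 - bx1) * (by2 - by1), "+") - inter
  out <- inter / ua
  out[ua <= 0] <- 0
  out
}

# greedy score-ordered NMS; returns indices kept
nms_keep <- function(boxes, scores, iou_thr) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    rest <- ord[-1]
    iou <- box_iou_matrix(boxes[i, , drop = FALSE],
                          boxes[rest, , drop = FALSE])[1, ]
    ord <- rest[iou <= iou_thr]
  }
  keep
}

#' Decode raw head outputs and apply non-maximum suppression
#'
#' Anchor decoding: \code{bx = (2 sigmoid(tx) - 0.5 + cell_x) / grid},
#' \code{bw = anchor_w * exp(tw)}; the detection score is
#' \code{sigmoid(objectness) * sigmoid(class)}. Boxes are normalised to
#' \[0, 1\], sorted by score, and greedily suppressed at the configured
#' IoU threshold.
#'
#' @param fw output of [detector_forward()].
#' @param cfg the model's [detector_config()].
#' @param conf_thr,iou_thr optional overrides of the config thresholds.
#' @return A data frame of class \code{"detections"}: \code{image},
#'   \code{cx}, \code{cy}, \code{w}, \code{h}, \code{score},
#'   \code{class_id}.
#' @export
decode_and_nms <- function(fw, cfg, conf_thr = NULL, iou_thr = NULL) {
  if (is.null(conf_thr)) conf_thr <- cfg$conf_thr
  if (is.null(iou_thr)) iou_thr <- cfg$nms_iou
  A <- cfg$anchors_per_head
  sig <- function(z) 1 / (1 + exp(-z))
  rows <- list()
  for (hn in c("shallow", "deep")) {
    h <- fw[[hn]]
    anc <- if (hn == "shallow") cfg$anchors[seq_len(A), , drop = FALSE]
           else cfg$anchors[A + seq_len(A), , drop = FALSE]
    d <- dim(h$reg)   # (G, G, 4A, N)
    G <- d[1]; N <- d[4]
    for (n in seq_len(N)) {
      for (a in seq_len(A)) {
        tx <- h$reg[, , 4L * (a - 1L) + 1L, n]
        ty <- h$reg[, , 4L * (a - 1L) + 2L, n]
        tw <- h$reg[, , 4L * (a - 1L) + 3L, n]
        th <- h$reg[, , 4L * (a - 1L) + 4L, n]
        obj <- sig(h$obj[, , a, n])
        clsmat <- sig(h$cls[, , , n, drop = FALSE])
        cbest <- apply(array(clsmat, c(G, d[2], cfg$n_classes)), c(1, 2), max)
        cid <- if (cfg$n_classes == 1L) matrix(0L, G, d[2]) else
          apply(array(clsmat, c(G, d[2], cfg$n_classes)), c(1, 2),
                which.max) - 1L
        score <- obj * cbest
        sel <- which(score >= conf_thr, arr.ind = TRUE)
        if (!nrow(sel)) next
        i <- sel[, 1]; j <- sel[, 2]   # i = row = y, j = col = x
        cx <- (2 * sig(tx[sel]) - 0.5 + (j - 1)) / d[2]
        cy <- (2 * sig(ty[sel]) - 0.5 + (i - 1)) / G
        bw <- pmin(1, anc[a, 1] * exp(pmin(tw[sel], 4)))
        bh <- pmin(1, anc[a, 2] * exp(pmin(th[sel], 4)))
        rows[[length(rows) + 1L]] <- data.frame(
          image = n, cx = pmin(1, pmax(0, cx)), cy = pmin(1, pmax(0, cy)),
          w = bw, h = bh, score = score[sel], class_id = cid[sel])
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(image = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0), score = numeric(0),
                      class_id = integer(0))
    class(out) <- c("detections", "data.frame")
    return(out)
  }
  det <- do.call(rbind, rows)
  kept <- list()
  for (n in unique(det$image)) for (cl in unique(det$class_id)) {
    sub <- det[det$image == n & det$class_id == cl, , drop = FALSE]
    keep <- nms_keep(as.matrix(sub[, c("cx", "cy", "w", "h")]), sub$score,
                     iou_thr)
    kept[[length(kept) + 1L]] <- sub[keep, , drop = FALSE]
  }
  out <- do.call(rbind, kept)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("detections", "data.frame")
  out
}

# average precision at one IoU threshold, 101-point interpolation
average_precision <- function(detections, truths, iou_thr) {
  ngt <- nrow(truths)
  if (!nrow(detections)) return(0)
  det <- detections[order(-detections$score), , drop = FALSE]
  matched <- rep(FALSE, ngt)
  tp <- fp <- numeric(nrow(det))
  for (k in seq_len(nrow(det))) {
    cand <- which(truths$image == det$image[k] & !matched)
    if (length(cand)) {
      iou <- box_iou_matrix(as.matrix(det[k, c("cx", "cy", "w", "h")]),
                            as.matrix(truths[cand, c("cx", "cy", "w", "h")]))[1, ]
      best <- which.max(iou)
      if (iou[best] >= iou_thr) {
        matched[cand[best]] <- TRUE
        tp[k] <- 1
        next
      }
    }
    fp[k] <- 1
  }
  ctp <- cumsum(tp); cfp <- cumsum(fp)
  rec <- ctp / ngt
  prec <- ctp / (ctp + cfp)
  rgrid <- seq(0, 1, by = 0.01)
  mean(vapply(rgrid, function(r) {
    p <- prec[rec >= r]
    if (length(p)) max(p) else 0
  }, numeric(1)))
}

#' Mean average precision over IoU thresholds
#'
#' AP at each IoU threshold is the 101-point-interpolated area under the
#' precision-recall curve with greedy score-ordered matching;
#' \code{mAP0.5:0.95} averages thresholds 0.5 to 0.95 in steps of 0.05.
#'
#' @param detections data frame with \code{image}, \code{score},
#'   \code{cx}, \code{cy}, \code{w}, \code{h} (normalised).
#' @param truths data frame with \code{image}, \code{cx}, \code{cy},
#'   \code{w}, \code{h}; must be non-empty.
#' @param iou_thresholds IoU thresholds (default 0.5 to 0.95 step 0.05).
#' @return A list: \code{ap} (named per threshold), \code{mAP50},
#'   \code{mAP50_95}.
#' @export
mean_average_precision <- function(detections, truths,
                                   iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (is.null(truths) || !nrow(truths))
    stop("mAP undefined: no ground-truth boxes", call. = FALSE)
  ap <- vapply(iou_thresholds,
               function(t) average_precision(detections, truths, t),
               numeric(1))
  names(ap) <- sprintf("%.2f", iou_thresholds)
  list(ap = ap,
       mAP50 = if ("0.50" %in% names(ap)) ap[["0.50"]] else NA_real_,
       mAP50_95 = mean(ap))
}

#' Anchor priors by k-means over training boxes
#'
#' Clusters the normalised (w, h) of the training boxes into \code{k}
#' anchors, sorted by area; the smaller half serves the shallow
#' (small-object) head. Degenerate inputs (fewer distinct boxes than
#' clusters) fall back to jittered replication.
#'
#' @param wh two-column matrix of normalised box widths/heights.
#' @param k number of anchors (default 6).
#' @param seed RNG seed.
#' @return A \code{k x 2} anchor matrix.
#' @export
kmeans_anchors <- function(wh, k = 6L, seed = 1L) {
  wh <- matrix(as.numeric(wh), ncol = 2)
  set.seed(seed)
  uq <- unique(round(wh, 6))
  if (nrow(uq) < k) {
    base <- uq[rep(seq_len(nrow(uq)), length.out = k), , drop = FALSE]
    centers <- base * (1 + matrix(stats::rnorm(2 * k, 0, 0.05), k, 2))
  } else {
    centers <- stats::kmeans(wh, centers = k, nstart = 5)$centers
  }
  centers <- pmax(centers, 1e-3)
  centers[order(centers[, 1] * centers[, 2]), , drop = FALSE]
}
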