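# Shared fixtures for the test suite. Everything is generated in code.

# camera used throughout the geometry tests: square pixels, principal
# point at the centre of a 352 x 352 frame
test_cam <- function(f = 500, res = c(352, 352))
  camera_model(fx = f, ideal_resolution = res)

# independent oracle for the projection chain: a single homogeneous
# 3x4 matrix product zc * (u, v, 1)' = K [R | T] (xw, yw, zw, 1)'
project_oracle <- function(pw, R, T, K) {
  P <- K %*% cbind(R, T)
  uvw <- P %*% c(pw, 1)
  uvw[1:2] / uvw[3]
}

# a noise-free scene whose compression rate samples the stroke extrema
# exactly on the 30 fps frame grid (period 0.6 s = 18 frames)
noiseless_spec <- function(rate_cpm = 100, range_cm = 60, depth_cm = 5,
                           fx = 600)
  scene_spec(cam = camera_model(fx = fx, ideal_resolution = c(704, 704)),
             range_cm = range_cm, depth_cm = depth_cm, rate_cpm = rate_cpm,
             depth_jitter_cm = 0, period_jitter_frac = 0,
             center_noise_px = 0, marker_len_noise_frac = 0,
             dropout_prob = 0, settle_amp_cm = 0)

# tiny detector configuration used wherever only shapes/plumbing matter
tiny_cfg <- function(input = 64L, ...)
  detector_config(input_size = input, stem_channels = 8L,
                  stage_channels = c(16L, 32L, 64L),
                  stage_repeats = c(1L, 1L, 1L),
                  fpn_channels = 16L, base_fpn_channels = 16L,
                  head_blocks = 1L, ...)

# brute-force greedy NMS written independently of the implementation:
# repeatedly take the highest-score box and drop everything overlapping it
brute_force_nms <- function(boxes, scores, thr) {
  to_xyxy <- function(b) c(b[1] - b[3] / 2, b[2] - b[4] / 2,
                           b[1] + b[3] / 2, b[2] + b[4] / 2)
  iou1 <- function(a, b) {
    a <- to_xyxy(a); b <- to_xyxy(b)
    iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- iw * ih
    ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
    if (ua <= 0) 0 else inter / ua
  }
  alive <- seq_along(scores)
  kept <- integer(0)
  while (length(alive)) {
    i <- alive[which.max(scores[alive])]
    kept <- c(kept, i)
    alive <- alive[vapply(alive, function(j)
      j != i && iou1(boxes[i, ], boxes[j, ]) <= thr, logical(1))]
  }
  kept
}

# brute-force average precision: direct PR scan over score cutoffs with
# greedy best-IoU matching, then max-precision-to-the-right integration
# on the 101-point recall grid
brute_force_ap <- function(det, gt, iou_thr) {
  to_xyxy <- function(cx, cy, w, h) cbind(cx - w / 2, cy - h / 2,
                                          cx + w / 2, cy + h / 2)
  iou1 <- function(a, b) {
    iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- iw * ih
    ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
    if (ua <= 0) 0 else inter / ua
  }
  ngt <- nrow(gt)
  if (!nrow(det)) return(0)
  det <- det[order(-det$score), , drop = FALSE]
  db <- to_xyxy(det$cx, det$cy, det$w, det$h)
  gb <- to_xyxy(gt$cx, gt$cy, gt$w, gt$h)
  used <- rep(FALSE, ngt)
  is_tp <- logical(nrow(det))
  for (k in seq_len(nrow(det))) {
    ious <- vapply(seq_len(ngt), function(g)
      if (gt$image[g] == det$image[k] && !used[g]) iou1(db[k, ], gb[g, ])
      else -1, numeric(1))
    g <- which.max(ious)
    if (length(g) && ious[g] >= iou_thr) { used[g] <- TRUE; is_tp[k] <- TRUE }
  }
  prec <- cumsum(is_tp) / seq_along(is_tp)
  rec <- cumsum(is_tp) / ngt
  mean(vapply(seq(0, 1, 0.01), function(r) {
    p <- prec[rec >= r]
    if (length(p)) max(p) else 0
  }, numeric(1)))
}
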