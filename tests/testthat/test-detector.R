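test_that("backbone stages sit at strides 8, 16 and 32", {
  mdl <- init_detector(tiny_cfg(352L), seed = 1)
  x <- array(stats::runif(352 * 352 * 3 * 2), c(352, 352, 3, 2))
  S <- build_backbone(mdl, x)
  expect_equal(dim(S$S1)[1:2], c(44, 44))
  expect_equal(dim(S$S2)[1:2], c(22, 22))
  expect_equal(dim(S$S3)[1:2], c(11, 11))
  expect_equal(dim(S$S1)[4], 2)   # batch preserved
  mdl320 <- init_detector(tiny_cfg(320L), seed = 1)
  S320 <- build_backbone(mdl320, array(0, c(320, 320, 3, 1)))
  expect_equal(vapply(S320, function(s) dim(s)[1], numeric(1)),
               c(S1 = 40, S2 = 20, S3 = 10))
  expect_error(detector_config(input_size = 100L), "divisible by 32")
})

test_that("partial convolution touches only the configured channel slice", {
  set.seed(8)
  x <- array(stats::rnorm(16 * 16 * 64), c(16, 16, 64))
  y <- pconv(x, ratio = 1 / 4, seed = 2)
  expect_equal(dim(y), dim(x))
  # untouched channels are bitwise identical
  expect_identical(y[, , 17:64], x[, , 17:64])
  expect_false(isTRUE(all.equal(y[, , 1:16], x[, , 1:16])))
  expect_error(pconv(x, ratio = 0), "ratio")
  expect_error(pconv(x, ratio = 1.5), "ratio")
  # MAC ratio of pconv to a full same-width convolution is ratio^2
  count_conv_macs <- function(cin, cout) {
    tp <- cprmeter:::tape_new()
    xi <- cprmeter:::tn_input(tp, array(0, c(16, 16, cin, 1)))
    w <- cprmeter:::tn_input(tp, array(0, c(3, 3, cin, cout)))
    cprmeter:::op_conv(tp, xi, w)
    tp$flops
  }
  expect_equal(count_conv_macs(16, 16) / count_conv_macs(64, 64), 1 / 16)
})

test_that("mixed local channel attention gates without reshaping", {
  z <- array(0, c(8, 8, 16))
  expect_equal(mlca(z), z, ignore_attr = TRUE)
  u <- array(1, c(8, 8, 16, 2))
  yu <- mlca(u, local_grid = 2)
  att <- attr(yu, "attention")
  expect_true(all(att > 0 & att < 1))
  # spatially uniform input: local and global branches agree, so the
  # attention map is spatially uniform per channel
  expect_equal(max(apply(att, c(3, 4), function(m) diff(range(m)))), 0,
               tolerance = 1e-12)
  expect_equal(dim(yu), dim(u))
  # parameter overhead of MLCA is far below 0.1% of the model
  n_off <- count_parameters(init_detector(
    detector_config(use_mlca = FALSE, use_pconv = FALSE, use_std_fpn = FALSE),
    seed = 1))
  n_on <- count_parameters(init_detector(
    detector_config(use_mlca = TRUE, use_pconv = FALSE, use_std_fpn = FALSE),
    seed = 1))
  expect_gt(n_on, n_off)
  expect_lt((n_on - n_off) / n_off, 0.001)
})

test_that("the small-target pyramid fuses stride-8 and stride-32 maps", {
  mdl <- init_detector(tiny_cfg(352L), seed = 2)
  x <- array(stats::runif(352 * 352 * 3), c(352, 352, 3, 1))
  fw <- detector_forward(mdl, x)
  expect_equal(dim(fw$P_deep)[1:2], c(11, 11))
  expect_equal(dim(fw$P_shallow)[1:2], c(44, 44))
  expect_equal(dim(fw$deep$reg)[1:2], c(11, 11))
  expect_equal(dim(fw$shallow$reg)[1:2], c(44, 44))
  expect_equal(unname(fw$deep$stride), 32L)
  expect_equal(unname(fw$shallow$stride), 8L)
  expect_true(all(is.finite(fw$deep$reg)), all(is.finite(fw$shallow$obj)))
  # disabling the small-target pyramid reverts to the two-level baseline
  mdlb <- init_detector(tiny_cfg(352L, use_std_fpn = FALSE), seed = 2)
  fwb <- detector_forward(mdlb, x)
  expect_equal(dim(fwb$shallow$reg)[1:2], c(22, 22))
  expect_equal(unname(fwb$shallow$stride), 16L)
})

test_that("detection heads expose per-anchor boxes and a single class", {
  cfg <- tiny_cfg(96L)
  mdl <- init_detector(cfg, seed = 1)
  fw <- detector_forward(mdl, array(0.5, c(96, 96, 3, 1)))
  A <- cfg$anchors_per_head
  expect_equal(dim(fw$deep$reg)[3], 4L * A)
  expect_equal(dim(fw$deep$obj)[3], A)
  expect_equal(dim(fw$deep$cls)[3], 1L)   # single class: the wristband
  # swapping pconv for depthwise-separable blocks changes the parameter
  # count by the closed-form delta
  C <- cfg$fpn_channels
  cp <- floor(C * cfg$pconv_ratio)
  per_block_pconv <- 9 * cp * cp + 2 * C           # kernel + BN
  per_block_dws <- 9 * C + 2 * C + C * C + 2 * C   # dw + BN + pw + BN
  delta_expected <- 2 * cfg$head_blocks * (per_block_dws - per_block_pconv)
  n_p <- count_parameters(init_detector(tiny_cfg(96L, use_pconv = TRUE), seed = 1))
  n_d <- count_parameters(init_detector(tiny_cfg(96L, use_pconv = FALSE), seed = 1))
  expect_equal(n_d - n_p, delta_expected)
})

test_that("decoding and suppression behave like the brute-force oracle", {
  cfg <- tiny_cfg(96L)
  A <- cfg$anchors_per_head
  G <- 3L
  # hand-built raw head output: everything silent except chosen cells
  mk_head <- function(stride) {
    list(reg = array(0, c(G, G, 4 * A, 1)),
         obj = array(-20, c(G, G, A, 1)),
         cls = array(20, c(G, G, 1, 1)), stride = stride)
  }
  fw <- list(deep = mk_head(32L), shallow = mk_head(8L))
  # two anchors with identical priors firing at the same cell: after
  # decoding they are identical boxes; NMS keeps exactly one
  cfg$anchors[4, ] <- c(0.4, 0.12); cfg$anchors[5, ] <- c(0.4, 0.12)
  fw$deep$obj[2, 2, 1, 1] <- 8
  fw$deep$obj[2, 2, 2, 1] <- 6
  det <- decode_and_nms(fw, cfg, conf_thr = 0.25, iou_thr = 0.45)
  expect_equal(nrow(det), 1)
  expect_equal(det$score[1], 1 / (1 + exp(-8)), tolerance = 1e-6)
  # all scores below the confidence threshold: empty result
  fw$deep$obj[] <- -20
  expect_equal(nrow(decode_and_nms(fw, cfg, conf_thr = 0.25)), 0)
  # random boxes: greedy NMS equals the brute-force oracle
  set.seed(21)
  for (rep in 1:20) {
    n <- 8
    boxes <- cbind(stats::runif(n, 0.3, 0.7), stats::runif(n, 0.3, 0.7),
                   stats::runif(n, 0.1, 0.4), stats::runif(n, 0.1, 0.4))
    scores <- stats::runif(n)
    expect_setequal(cprmeter:::nms_keep(boxes, scores, 0.4),
                    brute_force_nms(boxes, scores, 0.4))
  }
})

test_that("parameter counting matches closed-form convolution formulas", {
  m <- new.env(parent = emptyenv())
  m$params <- new.env(parent = emptyenv())
  m$param_order <- character(0)
  class(m) <- "cpr_detector"
  tp <- cprmeter:::tape_new()
  cprmeter:::getp(tp, m, "conv.W", c(3L, 3L, 16L, 32L), "he", fan_in = 144)
  cprmeter:::getp(tp, m, "conv.b", 32L, "zeros")
  expect_equal(count_parameters(m), 3 * 3 * 16 * 32 + 32)   # 4640
  # a pconv layer always has fewer parameters than the full convolution
  expect_lt(9 * 16 * 16, 9 * 64 * 64)
})

test_that("precision and recall follow their defining ratios", {
  expect_equal(precision(eval_counts(TP = 9, FP = 1)), 0.9)
  expect_equal(recall(eval_counts(TP = 8, FN = 2)), 0.8)
  ec <- eval_counts(TP = 5, FP = 0, FN = 0)
  expect_equal(precision(ec), 1)
  expect_equal(recall(ec), 1)
  expect_warning(p0 <- precision(eval_counts(TP = 0, FP = 0)), "undefined")
  expect_equal(p0, 0)
  expect_warning(r0 <- recall(eval_counts(TP = 0, FN = 0)), "undefined")
  expect_equal(r0, 0)
  expect_error(eval_counts(TP = -1), "non-negative")
})

test_that("mean average precision matches a brute-force PR integration", {
  # perfect detections
  gt <- data.frame(image = 1:3, cx = c(0.3, 0.5, 0.7), cy = 0.5,
                   w = 0.2, h = 0.1)
  perfect <- cbind(gt, score = c(0.9, 0.8, 0.7), class_id = 0)
  mp <- mean_average_precision(perfect, gt)
  expect_equal(unname(mp$ap), rep(1, 10))
  expect_equal(mp$mAP50, 1)
  # no detections
  none <- perfect[0, ]
  expect_equal(mean_average_precision(none, gt)$mAP50, 0)
  expect_error(mean_average_precision(perfect, gt[0, ]), "ground-truth")
  # 5-image hand-built mix of hits, misses and false positives
  gt5 <- data.frame(image = c(1, 2, 3, 4, 5, 5),
                    cx = c(0.3, 0.5, 0.4, 0.6, 0.3, 0.7),
                    cy = c(0.4, 0.5, 0.6, 0.4, 0.3, 0.7),
                    w = c(0.2, 0.3, 0.2, 0.25, 0.2, 0.2),
                    h = c(0.1, 0.15, 0.1, 0.1, 0.12, 0.1))
  det5 <- data.frame(
    image = c(1, 1, 2, 3, 4, 5, 5, 2),
    cx = c(0.31, 0.8, 0.51, 0.1, 0.61, 0.31, 0.71, 0.52),
    cy = c(0.41, 0.8, 0.52, 0.1, 0.41, 0.29, 0.69, 0.51),
    w = c(0.2, 0.1, 0.28, 0.1, 0.24, 0.21, 0.2, 0.3),
    h = c(0.1, 0.1, 0.14, 0.1, 0.1, 0.12, 0.11, 0.15),
    score = c(0.95, 0.9, 0.85, 0.8, 0.75, 0.7, 0.65, 0.6))
  for (thr in c(0.5, 0.75)) {
    expect_equal(cprmeter:::average_precision(det5, gt5, thr),
                 brute_force_ap(det5, gt5, thr), tolerance = 1e-12)
  }
  mp5 <- mean_average_precision(det5, gt5)
  expect_lte(mp5$mAP50, 1)
  expect_gte(mp5$mAP50, mp5$mAP50_95)
})

test_that("anchor clustering handles rich and degenerate box sets", {
  set.seed(3)
  wh <- cbind(stats::runif(60, 0.2, 0.6), stats::runif(60, 0.03, 0.1))
  anc <- kmeans_anchors(wh, 6, seed = 1)
  expect_equal(dim(anc), c(6, 2))
  areas <- anc[, 1] * anc[, 2]
  expect_true(all(diff(areas) >= 0))   # sorted by area
  # fewer distinct boxes than clusters: jittered replication
  anc2 <- kmeans_anchors(matrix(c(0.4, 0.05), 3, 2, byrow = TRUE), 6, seed = 1)
  expect_equal(dim(anc2), c(6, 2))
  expect_true(all(anc2 > 0))
})

test_that("toy training is deterministic, inert at lr 0, and reduces loss", {
  sp <- scene_spec()
  ds <- render_frames(sp, 8, seed = 13, size = 64)
  cfg <- tiny_cfg(64L, anchors = kmeans_anchors(
    do.call(rbind, lapply(ds$labels, function(l) cbind(l$w, l$h))), 6, seed = 1))
  # lr = 0 leaves every parameter untouched
  m0 <- init_detector(cfg, seed = 5)
  before <- lapply(as.list(m0$params), identity)
  train_toy(m0, ds, epochs = 2, lr = 0, batch = 4, seed = 1)
  for (nm in names(before)) expect_identical(m0$params[[nm]], before[[nm]])
  # same seed twice: identical loss history
  m1 <- init_detector(cfg, seed = 5)
  h1 <- train_toy(m1, ds, epochs = 3, lr = 1e-3, batch = 4, seed = 9)$loss_history
  m2 <- init_detector(cfg, seed = 5)
  h2 <- train_toy(m2, ds, epochs = 3, lr = 1e-3, batch = 4, seed = 9)$loss_history
  expect_identical(h1, h2)
  # loss decreases over a short run and a checkpoint is written
  m3 <- init_detector(cfg, seed = 5)
  res <- train_toy(m3, ds, epochs = 10, lr = 1e-3, batch = 4, seed = 1)
  expect_lt(res$loss_history[10], res$loss_history[1])
  expect_true(file.exists(res$checkpoint))
  m4 <- load_detector(res$checkpoint)
  expect_equal(count_parameters(m4), count_parameters(m3))
  d4 <- detect_marker(m4, ds$images[[1]], conf_thr = 0.01)
  expect_s3_class(d4, "detections")
})
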