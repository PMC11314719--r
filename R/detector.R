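#' Configuration of the marker-wristband detector
#'
#' Describes the lightweight anchor-based detector: a ShuffleNetV2-style
#' backbone with three stages (strides 8/16/32), a small-target feature
#' pyramid (STD-FPN) that fuses the shallow stride-8 and deep stride-32
#' maps, mixed local channel attention (MLCA) on each stage output, and
#' decoupled detection heads whose convolutions use partial convolution
#' (PConv). Each of the three additions can be toggled off, reverting to
#' the plain two-level pyramid / depthwise-separable-convolution baseline.
#'
#' @param input_size square input size in pixels; must be divisible by 32
#'   (default 352).
#' @param stem_channels,stage_channels,stage_repeats backbone widths and
#'   block counts; defaults follow the 0.5x ShuffleNetV2 configuration.
#' @param fpn_channels channel width of the fused pyramid levels.
#' @param base_fpn_channels width of the baseline two-level pyramid.
#' @param head_blocks number of convolution blocks in each detection head.
#' @param pconv_ratio fraction of channels convolved by PConv, in (0, 1].
#' @param mlca_grid local-pooling grid size of MLCA.
#' @param mlca_kernel cross-channel 1-D convolution kernel size (fixed 3).
#' @param anchors 6x2 matrix of normalised anchor (w, h); rows 1-3 serve
#'   the shallow (small-object) head, rows 4-6 the deep head.
#' @param anchors_per_head anchors per detection head.
#' @param n_classes number of object classes (default 1: the wristband).
#' @param conf_thr,nms_iou decoding confidence and NMS IoU thresholds.
#' @param use_pconv,use_mlca,use_std_fpn ablation toggles.
#' @return An object of class \code{"detector_config"}.
#' @export
detector_config <- function(input_size = 352L,
                            stem_channels = 24L,
                            stage_channels = c(48L, 96L, 192L),
                            stage_repeats = c(4L, 8L, 4L),
                            fpn_channels = 80L,
                            base_fpn_channels = 56L,
                            head_blocks = 2L,
                            pconv_ratio = 0.25,
                            mlca_grid = 2L,
                            mlca_kernel = 3L,
                            anchors = NULL,
                            anchors_per_head = 3L,
                            n_classes = 1L,
                            conf_thr = 0.25,
                            nms_iou = 0.45,
                            use_pconv = TRUE,
                            use_mlca = TRUE,
                            use_std_fpn = TRUE) {
  if (input_size %% 32L != 0L)
    stop("config error: input_size must be divisible by 32", call. = FALSE)
  if (pconv_ratio <= 0 || pconv_ratio > 1)
    stop("config error: pconv_ratio must be in (0, 1]", call. = FALSE)
  if (length(stage_channels) != 3L || length(stage_repeats) != 3L)
    stop("config error: need three backbone stages", call. = FALSE)
  if (is.null(anchors))
    anchors <- matrix(c(0.10, 0.04,
                        0.18, 0.06,
                        0.28, 0.09,
                        0.40, 0.12,
                        0.55, 0.16,
                        0.75, 0.22), ncol = 2, byrow = TRUE)
  anchors <- as.matrix(anchors)
  if (nrow(anchors) != 2L * anchors_per_head)
    stop("config error: need anchors for two heads", call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 stem_channels = as.integer(stem_channels),
                 stage_channels = as.integer(stage_channels),
                 stage_repeats = as.integer(stage_repeats),
                 fpn_channels = as.integer(fpn_channels),
                 base_fpn_channels = as.integer(base_fpn_channels),
                 head_blocks = as.integer(head_blocks),
                 pconv_ratio = pconv_ratio,
                 mlca_grid = as.integer(mlca_grid),
                 mlca_kernel = as.integer(mlca_kernel),
                 anchors = anchors,
                 anchors_per_head = as.integer(anchors_per_head),
                 n_classes = as.integer(n_classes),
                 conf_thr = conf_thr, nms_iou = nms_iou,
                 use_pconv = isTRUE(use_pconv),
                 use_mlca = isTRUE(use_mlca),
                 use_std_fpn = isTRUE(use_std_fpn)),
            class = "detector_config")
}

## ---- parameter store --------------------------------------------------

# lazily create a parameter on first use; creation order is recorded so
# optimisation and serialisation are deterministic
getp <- function(tp, m, name, shape, init = c("he", "ones", "zeros"),
                 fan_in = NULL) {
  if (is.null(m$params[[name]])) {
    init <- match.arg(init)
    n <- prod(shape)
    v <- switch(init,
                he = stats::rnorm(n, 0, sqrt(2 / fan_in)),
                ones = rep(1, n),
                zeros = rep(0, n))
    m$params[[name]] <- if (length(shape) > 1L) array(v, shape) else v
    m$param_order <- c(m$param_order, name)
  }
  tn_param(tp, m, name)
}

nchan <- function(tp, x) dim(tn_val(tp, x))[3]

## ---- building blocks --------------------------------------------------

# convolution + batch norm + ReLU
cbr_block <- function(tp, m, x, name, cout, k = 1L, stride = 1L, training = FALSE) {
  cin <- nchan(tp, x)
  w <- getp(tp, m, paste0(name, ".W"), c(k, k, cin, cout), "he",
            fan_in = k * k * cin)
  y <- op_conv(tp, x, w, stride = stride)
  y <- bn_block(tp, m, y, name, cout, training)
  op_relu(tp, y)
}

bn_block <- function(tp, m, x, name, cout, training) {
  g <- getp(tp, m, paste0(name, ".gamma"), cout, "ones")
  b <- getp(tp, m, paste0(name, ".beta"), cout, "zeros")
  op_bn(tp, x, g, b, m, paste0(name, ".bn"), training)
}

# depthwise 3x3 + BN (no activation, as in ShuffleNetV2)
dw_block <- function(tp, m, x, name, stride = 1L, training = FALSE) {
  c_ <- nchan(tp, x)
  w <- getp(tp, m, paste0(name, ".W"), c(3L, 3L, c_), "he", fan_in = 9)
  y <- op_conv_dw(tp, x, w, stride = stride)
  bn_block(tp, m, y, name, c_, training)
}

# partial convolution: 3x3 regular convolution on the first
# floor(C * ratio) channels, identity on the rest
pconv_core <- function(tp, m, x, name, ratio, training = FALSE) {
  C <- nchan(tp, x)
  cp <- floor(C * ratio)
  if (cp < 1L) stop("config error: pconv ratio leaves no channels", call. = FALSE)
  xa <- op_channels(tp, x, seq_len(cp))
  w <- getp(tp, m, paste0(name, ".W"), c(3L, 3L, cp, cp), "he",
            fan_in = 9 * cp)
  ya <- op_conv(tp, xa, w)
  if (cp == C) return(ya)
  xb <- op_channels(tp, x, (cp + 1L):C)
  op_concat_c(tp, ya, xb)
}

# mixed local channel attention: local g x g pooled branch and global
# pooled branch, each passed through a kernel-3 cross-channel 1-D
# convolution, restored by nearest-neighbour unpooling, fused by
# addition, squashed to (0,1) and applied multiplicatively
mlca_core <- function(tp, m, x, name, grid, training = FALSE) {
  d <- dim(tn_val(tp, x))
  wl <- getp(tp, m, paste0(name, ".wl"), 3L, "he", fan_in = 3)
  wg <- getp(tp, m, paste0(name, ".wg"), 3L, "he", fan_in = 3)
  loc <- op_adaptive_avgpool(tp, x, grid)
  loc <- op_conv1d_c(tp, loc, wl)
  loc <- op_unpool_to(tp, loc, d[1], d[2])
  glo <- op_adaptive_avgpool(tp, x, 1L)
  glo <- op_conv1d_c(tp, glo, wg)
  glo <- op_unpool_to(tp, glo, d[1], d[2])
  att <- op_sigmoid(tp, op_add(tp, loc, glo))
  op_mul(tp, x, att)
}

# ShuffleNetV2 unit: channel split + shuffle (stride 1) or dual-branch
# downsampling (stride 2)
shuffle_unit <- function(tp, m, x, name, cout, stride, training) {
  cin <- nchan(tp, x)
  if (stride == 1L) {
    half <- cin %/% 2L
    x1 <- op_channels(tp, x, seq_len(half))
    x2 <- op_channels(tp, x, (half + 1L):cin)
    b <- cbr_block(tp, m, x2, paste0(name, ".pw1"), half, 1L, 1L, training)
    b <- dw_block(tp, m, b, paste0(name, ".dw"), 1L, training)
    b <- cbr_block(tp, m, b, paste0(name, ".pw2"), half, 1L, 1L, training)
    y <- op_concat_c(tp, x1, b)
  } else {
    half <- cout %/% 2L
    b1 <- dw_block(tp, m, x, paste0(name, ".b1dw"), 2L, training)
    b1 <- cbr_block(tp, m, b1, paste0(name, ".b1pw"), half, 1L, 1L, training)
    b2 <- cbr_block(tp, m, x, paste0(name, ".b2pw1"), half, 1L, 1L, training)
    b2 <- dw_block(tp, m, b2, paste0(name, ".b2dw"), 2L, training)
    b2 <- cbr_block(tp, m, b2, paste0(name, ".b2pw2"), half, 1L, 1L, training)
    y <- op_concat_c(tp, b1, b2)
  }
  op_shuffle_c(tp, y, 2L)
}

## ---- network graph ----------------------------------------------------

backbone_graph <- function(tp, m, x, training) {
  cfg <- m$cfg
  y <- cbr_block(tp, m, x, "stem", cfg$stem_channels, 3L, 2L, training)
  y <- op_maxpool(tp, y, 3L, 2L, 1L)
  S <- vector("list", 3L)
  for (s in 1:3) {
    cout <- cfg$stage_channels[s]
    y <- shuffle_unit(tp, m, y, sprintf("stage%d.b1", s), cout, 2L, training)
    r <- cfg$stage_repeats[s]
    if (r > 1L) for (b in 2:r)
      y <- shuffle_unit(tp, m, y, sprintf("stage%d.b%d", s, b), cout, 1L,
                        training)
    S[[s]] <- y
  }
  S
}

fpn_graph <- function(tp, m, S, training) {
  cfg <- m$cfg
  C <- S
  if (cfg$use_mlca)
    for (s in 1:3)
      C[[s]] <- mlca_core(tp, m, S[[s]], sprintf("mlca%d", s), cfg$mlca_grid,
                          training)
  if (cfg$use_std_fpn) {
    fc <- cfg$fpn_channels
    # deep path: pool C1 by 4, concat with C3, CBR, then 1x1 conv
    c1p <- op_avgpool(tp, C[[1]], 4L, 4L)
    cat3 <- op_concat_c(tp, c1p, C[[3]])
    pd <- cbr_block(tp, m, cat3, "fpn.deep_cbr", fc, 1L, 1L, training)
    wd <- getp(tp, m, "fpn.deep_out.W", c(1L, 1L, fc, fc), "he", fan_in = fc)
    bd <- getp(tp, m, "fpn.deep_out.b", fc, "zeros")
    p_deep <- op_conv(tp, pd, wd, bd)
    # shallow path: CBR C2 to match C1 channels, upsample, add, CBR, 1x1
    c1ch <- nchan(tp, C[[1]])
    c2p <- cbr_block(tp, m, C[[2]], "fpn.c2_cbr", c1ch, 1L, 1L, training)
    c2u <- op_upsample2(tp, c2p)
    sadd <- op_add(tp, c2u, C[[1]])
    ps <- cbr_block(tp, m, sadd, "fpn.shallow_cbr", fc, 1L, 1L, training)
    ws <- getp(tp, m, "fpn.shallow_out.W", c(1L, 1L, fc, fc), "he", fan_in = fc)
    bs <- getp(tp, m, "fpn.shallow_out.b", fc, "zeros")
    p_shallow <- op_conv(tp, ps, ws, bs)
    list(deep = p_deep, shallow = p_shallow,
         strides = c(deep = 32L, shallow = 8L))
  } else {
    # baseline two-level pyramid: lateral 1x1 on stages 2-3, 3x3 smoothing,
    # upsample-and-add fusion
    fc <- cfg$base_fpn_channels
    l3 <- cbr_block(tp, m, C[[3]], "bfpn.l3", fc, 1L, 1L, training)
    p_deep <- cbr_block(tp, m, l3, "bfpn.deep", fc, 3L, 1L, training)
    l2 <- cbr_block(tp, m, C[[2]], "bfpn.l2", fc, 1L, 1L, training)
    fuse <- op_add(tp, l2, op_upsample2(tp, l3))
    p_shallow <- cbr_block(tp, m, fuse, "bfpn.shallow", fc, 3L, 1L, training)
    list(deep = p_deep, shallow = p_shallow,
         strides = c(deep = 32L, shallow = 16L))
  }
}

head_graph <- function(tp, m, p, name, training) {
  cfg <- m$cfg
  x <- p
  for (i in seq_len(cfg$head_blocks)) {
    bn <- sprintf("%s.blk%d", name, i)
    if (cfg$use_pconv) {
      x <- pconv_core(tp, m, x, paste0(bn, ".pconv"), cfg$pconv_ratio, training)
      x <- bn_block(tp, m, x, paste0(bn, ".pbn"), nchan(tp, x), training)
      x <- op_relu(tp, x)
    } else {
      x <- dw_block(tp, m, x, paste0(bn, ".dw"), 1L, training)
      x <- op_relu(tp, x)
      x <- cbr_block(tp, m, x, paste0(bn, ".pw"), nchan(tp, x), 1L, 1L,
                     training)
    }
  }
  cin <- nchan(tp, x)
  A <- cfg$anchors_per_head
  mk_out <- function(sfx, cout) {
    w <- getp(tp, m, sprintf("%s.%s.W", name, sfx), c(1L, 1L, cin, cout),
              "he", fan_in = cin)
    b <- getp(tp, m, sprintf("%s.%s.b", name, sfx), cout, "zeros")
    op_conv(tp, x, w, b)
  }
  list(reg = mk_out("reg", 4L * A),
       obj = mk_out("obj", A),
       cls = mk_out("cls", cfg$n_classes))
}

## ---- public model interface -------------------------------------------

#' Initialise a detector model
#'
#' Builds the parameter store by tracing one forward pass on a dummy
#' input, so every toggled-on module materialises its weights (He
#' initialisation, seeded).
#'
#' @param cfg a [detector_config()].
#' @param seed RNG seed for weight initialisation.
#' @return An object of class \code{"cpr_detector"}.
#' @export
init_detector <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "detector_config"))
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  m$params <- new.env(parent = emptyenv())
  m$bn_state <- new.env(parent = emptyenv())
  m$param_order <- character(0)
  class(m) <- "cpr_detector"
  set.seed(seed)
  x <- array(0, c(cfg$input_size, cfg$input_size, 3L, 1L))
  invisible(detector_forward(m, x, training = FALSE))
  m
}

#' @export
print.cpr_detector <- function(x, ...) {
  cfg <- x$cfg
  cat("CPR marker-wristband detector\n")
  cat(sprintf("  input %dx%d | pconv:%s mlca:%s std_fpn:%s\n",
              cfg$input_size, cfg$input_size,
              cfg$use_pconv, cfg$use_mlca, cfg$use_std_fpn))
  cat(sprintf("  parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Run the detector forward pass
#'
#' @param model a \code{"cpr_detector"} from [init_detector()].
#' @param x input array \code{(H, W, 3, N)} (or \code{(H, W, 3)}) with
#'   values in \[0, 1\].
#' @param training logical; training mode uses batch statistics in the
#'   batch-norm layers and keeps the autodiff tape.
#' @return A list with raw head outputs (\code{deep}, \code{shallow},
#'   each with \code{reg}, \code{obj}, \code{cls} arrays and
#'   \code{stride}), the tape, and node ids (used internally by the
#'   training loop).
#' @export
detector_forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "cpr_detector"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] != model$cfg$input_size || d[2] != model$cfg$input_size ||
      d[3] != 3L)
    stop("config error: input must be (", model$cfg$input_size, ", ",
         model$cfg$input_size, ", 3[, N])", call. = FALSE)
  tp <- tape_new()
  xin <- tn_input(tp, x)
  S <- backbone_graph(tp, model, xin, training)
  P <- fpn_graph(tp, model, S, training)
  hd <- head_graph(tp, model, P$deep, "head_deep", training)
  hs <- head_graph(tp, model, P$shallow, "head_shallow", training)
  out_of <- function(h, stride) list(reg = tn_val(tp, h$reg),
                                     obj = tn_val(tp, h$obj),
                                     cls = tn_val(tp, h$cls),
                                     stride = stride)
  list(deep = out_of(hd, P$strides["deep"]),
       shallow = out_of(hs, P$strides["shallow"]),
       S = lapply(S, function(id) tn_val(tp, id)),
       P_deep = tn_val(tp, P$deep),
       P_shallow = tn_val(tp, P$shallow),
       tape = tp,
       nodes = list(deep = hd, shallow = hs))
}

#' Backbone stage outputs
#'
#' Runs only the ShuffleNetV2-style backbone and returns the three stage
#' feature maps at strides 8, 16 and 32.
#'
#' @inheritParams detector_forward
#' @return List of arrays \code{S1}, \code{S2}, \code{S3}.
#' @export
build_backbone <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "cpr_detector"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1] %% 32L != 0L || dim(x)[2] %% 32L != 0L)
    stop("config error: input size must be divisible by 32", call. = FALSE)
  tp <- tape_new()
  S <- backbone_graph(tp, model, tn_input(tp, x), training)
  stats::setNames(lapply(S, function(id) tn_val(tp, id)),
                  c("S1", "S2", "S3"))
}

#' Standalone partial convolution
#'
#' Convolves the first \code{floor(C * ratio)} channels of a feature map
#' with a 3x3 same-padding kernel and passes the remaining channels
#' through unchanged.
#'
#' @param x array \code{(H, W, C)} or \code{(H, W, C, N)}.
#' @param ratio fraction of channels to convolve, in (0, 1].
#' @param weights optional \code{(3, 3, cp, cp)} kernel; random (seeded)
#'   if omitted.
#' @param seed RNG seed for the default kernel.
#' @return Array of the same shape as \code{x}.
#' @export
pconv <- function(x, ratio = 0.25, weights = NULL, seed = 1L) {
  if (ratio <= 0 || ratio > 1)
    stop("config error: ratio must be in (0, 1]", call. = FALSE)
  squeeze <- length(dim(x)) == 3L
  if (squeeze) dim(x) <- c(dim(x), 1L)
  C <- dim(x)[3]
  cp <- floor(C * ratio)
  if (cp < 1L) stop("config error: ratio leaves no channels", call. = FALSE)
  if (is.null(weights)) {
    set.seed(seed)
    weights <- array(stats::rnorm(9 * cp * cp, 0, sqrt(2 / (9 * cp))),
                     c(3L, 3L, cp, cp))
  }
  tp <- tape_new()
  xa <- tn_input(tp, x[, , seq_len(cp), , drop = FALSE])
  w <- tn_input(tp, weights)
  ya <- tn_val(tp, op_conv(tp, xa, w))
  out <- x
  out[, , seq_len(cp), ] <- ya
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}

#' Standalone mixed local channel attention
#'
#' Applies the MLCA gating to a feature map: local \code{g x g} and
#' global pooled channel descriptors, kernel-3 cross-channel 1-D
#' convolutions, nearest-neighbour unpooling, additive fusion, sigmoid
#' squashing and multiplicative application.
#'
#' @param x array \code{(H, W, C)} or \code{(H, W, C, N)}.
#' @param local_grid local pooling grid size (default 2).
#' @param kernel cross-channel kernel (only 3 supported).
#' @param weights optional list \code{(wl, wg)} of length-3 kernels.
#' @param seed RNG seed for default kernels.
#' @return Array of the same shape as \code{x}, plus attribute
#'   \code{"attention"} holding the applied weights in (0, 1).
#' @export
mlca <- function(x, local_grid = 2L, kernel = 3L, weights = NULL, seed = 1L) {
  if (kernel != 3L) stop("only kernel 3 is supported", call. = FALSE)
  squeeze <- length(dim(x)) == 3L
  if (squeeze) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] < local_grid || d[2] < local_grid)
    stop("spatial dims must be >= local_grid", call. = FALSE)
  if (is.null(weights)) {
    set.seed(seed)
    weights <- list(wl = stats::rnorm(3, 0, sqrt(2 / 3)),
                    wg = stats::rnorm(3, 0, sqrt(2 / 3)))
  }
  tp <- tape_new()
  xi <- tn_input(tp, x)
  wl <- tn_input(tp, weights$wl); wg <- tn_input(tp, weights$wg)
  loc <- op_unpool_to(tp, op_conv1d_c(tp, op_adaptive_avgpool(tp, xi, local_grid), wl),
                      d[1], d[2])
  glo <- op_unpool_to(tp, op_conv1d_c(tp, op_adaptive_avgpool(tp, xi, 1L), wg),
                      d[1], d[2])
  att <- op_sigmoid(tp, op_add(tp, loc, glo))
  y <- tn_val(tp, op_mul(tp, xi, att))
  attv <- tn_val(tp, att)
  if (squeeze) { dim(y) <- d[1:3]; dim(attv) <- d[1:3] }
  attr(y, "attention") <- attv
  y
}

#' Count trainable parameters
#' @param model a \code{"cpr_detector"}.
#' @return Integer-valued parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "cpr_detector"))
  sum(vapply(model$param_order,
             function(nm) length(model$params[[nm]]), numeric(1)))
}

#' Count convolution multiply-accumulates for one forward pass
#' @param model a \code{"cpr_detector"}.
#' @param input_size optional square input size (defaults to the config).
#' @return Numeric MAC count for a single image.
#' @export
count_flops <- function(model, input_size = NULL) {
  stopifnot(inherits(model, "cpr_detector"))
  if (is.null(input_size)) input_size <- model$cfg$input_size
  x <- array(0, c(input_size, input_size, 3L, 1L))
  fw <- detector_forward(model, x, training = FALSE)
  fw$tape$flops
}

#' Save / load a detector checkpoint
#'
#' The checkpoint embeds the configuration, parameter arrays,
#' batch-norm running statistics and creation order.
#'
#' @param model a \code{"cpr_detector"}.
#' @param path file path.
#' @return [load_detector()] returns the restored model.
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "cpr_detector"))
  saveRDS(list(cfg = model$cfg,
               params = as.list(model$params),
               bn_state = as.list(model$bn_state),
               param_order = model$param_order),
          path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  s <- readRDS(path)
  m <- new.env(parent = emptyenv())
  m$cfg <- s$cfg
  m$params <- list2env(s$params, parent = emptyenv())
  m$bn_state <- list2env(s$bn_state, parent = emptyenv())
  m$param_order <- s$param_order
  class(m) <- "cpr_detector"
  m
}
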