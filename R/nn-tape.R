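# Minimal define-by-run reverse-mode autodiff over base-R arrays.
#
# Feature maps are numeric arrays with dim (H, W, C, N). A tape records
# each operation's value, parent node ids and a backward closure mapping
# the output gradient to parent gradients. Convolutions go through
# im2col + BLAS matmul; depthwise convolutions use nine shifted
# elementwise products. This exists because the detector is trained and
# evaluated entirely inside R; it is deliberately small and only
# implements the ops the network needs.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp$flops <- 0
  tp$param_ids <- list()   # param name -> node ids
  tp
}

tn_push <- function(tp, val, parents = integer(0), backward = NULL) {
  tp$n <- tp$n + 1L
  tp$nodes[[tp$n]] <- list(val = val, parents = parents, backward = backward)
  tp$n
}

tn_val <- function(tp, id) {
  force(id)   # the id expression may itself push nodes onto the tape
  tp$nodes[[id]]$val
}

# leaf node for a model parameter; ids recorded so gradients can be
# collected per parameter name after the backward pass
tn_param <- function(tp, model, name) {
  v <- model$params[[name]]
  if (is.null(v)) stop("unknown parameter: ", name)
  id <- tn_push(tp, v)
  tp$param_ids[[name]] <- c(tp$param_ids[[name]], id)
  id
}

tn_input <- function(tp, val) tn_push(tp, val)

# reverse sweep from scalar node `id`; returns list of gradients indexed
# by node id (non-NULL only where needed)
tape_backward <- function(tp, id) {
  grads <- vector("list", tp$n)
  grads[[id]] <- 1
  for (k in seq.int(id, 1L)) {
    g <- grads[[k]]
    if (is.null(g)) next
    nd <- tp$nodes[[k]]
    if (is.null(nd$backward) || !length(nd$parents)) next
    pg <- nd$backward(g)
    for (j in seq_along(nd$parents)) {
      if (is.null(pg[[j]])) next
      p <- nd$parents[j]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
    if (k != id) grads[k] <- list(NULL)  # free intermediate gradient
  }
  grads
}

# collect per-parameter gradients by name (summing over reuse)
tape_param_grads <- function(tp, grads) {
  out <- list()
  for (nm in names(tp$param_ids)) {
    tot <- NULL
    for (id in tp$param_ids[[nm]]) {
      g <- grads[[id]]
      if (is.null(g)) next
      tot <- if (is.null(tot)) g else tot + g
    }
    out[[nm]] <- tot
  }
  out
}

## ---- im2col machinery -------------------------------------------------

.idx_cache <- new.env(parent = emptyenv())

conv_out_dim <- function(H, k, stride, pad) (H + 2L * pad - k) %/% stride + 1L

# gather-index matrix for im2col: rows enumerate (oh, ow, n) with oh
# fastest; columns enumerate (ki, kj, c) with ki fastest, matching the
# column-major flattening of a (kh, kw, Cin, Cout) weight array.
conv_idx <- function(H, W, C, N, kh, kw, stride, pad) {
  key <- paste("c", H, W, C, N, kh, kw, stride, pad, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  OH <- conv_out_dim(H, kh, stride, pad); OW <- conv_out_dim(W, kw, stride, pad)
  P <- OH * OW * N; K <- kh * kw * C
  oh <- rep(seq_len(OH), times = OW * N)
  ow <- rep(rep(seq_len(OW), each = OH), times = N)
  nn <- rep(seq_len(N), each = OH * OW)
  base_i <- (oh - 1L) * stride
  base_j <- (ow - 1L) * stride
  plane <- Hp * Wp
  nc_off <- ((nn - 1L) * C) * plane
  idx <- matrix(0L, P, K)
  k <- 0L
  for (c in seq_len(C)) {
    c_off <- (c - 1L) * plane
    for (kj in seq_len(kw)) {
      jcol <- (base_j + kj - 1L) * Hp
      for (ki in seq_len(kh)) {
        k <- k + 1L
        idx[, k] <- base_i + ki + jcol + c_off + nc_off
      }
    }
  }
  out <- list(idx = idx, OH = OH, OW = OW, Hp = Hp, Wp = Wp, P = P, K = K)
  .idx_cache[[key]] <- out
  out
}

# per-channel pooling index: rows enumerate (oh, ow, c, n) oh fastest,
# columns enumerate (ki, kj)
pool_idx <- function(H, W, C, N, k, stride, pad = 0L) {
  key <- paste("p", H, W, C, N, k, stride, pad, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  OH <- conv_out_dim(H, k, stride, pad); OW <- conv_out_dim(W, k, stride, pad)
  P <- OH * OW * C * N; K <- k * k
  oh <- rep(seq_len(OH), times = OW * C * N)
  ow <- rep(rep(seq_len(OW), each = OH), times = C * N)
  cn <- rep(seq_len(C * N), each = OH * OW)   # combined (c, n) plane index
  base_i <- (oh - 1L) * stride
  base_j <- (ow - 1L) * stride
  plane_off <- (cn - 1L) * (Hp * Wp)
  idx <- matrix(0L, P, K)
  kk <- 0L
  for (kj in seq_len(k)) {
    jcol <- (base_j + kj - 1L) * Hp
    for (ki in seq_len(k)) {
      kk <- kk + 1L
      idx[, kk] <- base_i + ki + jcol + plane_off
    }
  }
  out <- list(idx = idx, OH = OH, OW = OW, Hp = Hp, Wp = Wp, P = P, K = K)
  .idx_cache[[key]] <- out
  out
}

pad_array <- function(X, pad, fill = 0) {
  if (pad == 0L) return(X)
  d <- dim(X)
  Xp <- array(fill, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  Xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- X
  Xp
}

## ---- core ops ---------------------------------------------------------

# full convolution; weight array dim (kh, kw, Cin, Cout); optional bias
op_conv <- function(tp, x, w, b = NULL, stride = 1L, pad = NULL) {
  X <- tn_val(tp, x); Wt <- tn_val(tp, w)
  d <- dim(X); dw <- dim(Wt)
  kh <- dw[1]; kw <- dw[2]; Cin <- dw[3]; Cout <- dw[4]
  if (d[3] != Cin) stop("conv channel mismatch: input ", d[3], " vs weight ", Cin)
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  H <- d[1]; W_ <- d[2]; N <- d[4]
  bias <- !is.null(b)
  if (kh == 1L && kw == 1L && stride == 1L && pad == 0L) {
    P <- H * W_ * N
    Xm <- matrix(aperm(X, c(1, 2, 4, 3)), P, Cin)
    Wm <- matrix(Wt, Cin, Cout)
    Y <- Xm %*% Wm
    if (bias) Y <- Y + matrix(tn_val(tp, b), P, Cout, byrow = TRUE)
    yv <- aperm(array(Y, c(H, W_, N, Cout)), c(1, 2, 4, 3))
    tp$flops <- tp$flops + as.numeric(Cin) * Cout * H * W_ * N
    backward <- function(g) {
      dym <- matrix(aperm(g, c(1, 2, 4, 3)), P, Cout)
      dW <- array(crossprod(Xm, dym), dim(Wt))
      dX <- aperm(array(dym %*% t(Wm), c(H, W_, N, Cin)), c(1, 2, 4, 3))
      out <- list(dX, dW)
      if (bias) out[[3]] <- colSums(dym)
      out
    }
    return(tn_push(tp, yv, c(x, w, if (bias) b), backward))
  }
  ci <- conv_idx(H, W_, Cin, N, kh, kw, as.integer(stride), as.integer(pad))
  Xp <- pad_array(X, pad)
  cols <- matrix(Xp[ci$idx], ci$P, ci$K)
  Wm <- matrix(Wt, ci$K, Cout)
  Y <- cols %*% Wm
  if (bias) Y <- Y + matrix(tn_val(tp, b), ci$P, Cout, byrow = TRUE)
  yv <- aperm(array(Y, c(ci$OH, ci$OW, N, Cout)), c(1, 2, 4, 3))
  tp$flops <- tp$flops + as.numeric(ci$K) * Cout * ci$OH * ci$OW * N
  backward <- function(g) {
    dym <- matrix(aperm(g, c(1, 2, 4, 3)), ci$P, Cout)
    dW <- array(crossprod(cols, dym), dim(Wt))
    dcols <- dym %*% t(Wm)
    dxp <- numeric(ci$Hp * ci$Wp * Cin * N)
    for (k in seq_len(ci$K)) {
      ii <- ci$idx[, k]
      dxp[ii] <- dxp[ii] + dcols[, k]
    }
    dxp <- array(dxp, c(ci$Hp, ci$Wp, Cin, N))
    dX <- if (pad > 0L)
      dxp[pad + seq_len(H), pad + seq_len(W_), , , drop = FALSE] else dxp
    out <- list(dX, dW)
    if (bias) out[[3]] <- colSums(dym)
    out
  }
  tn_push(tp, yv, c(x, w, if (bias) b), backward)
}

# depthwise convolution; weight dim (kh, kw, C)
op_conv_dw <- function(tp, x, w, stride = 1L, pad = NULL) {
  X <- tn_val(tp, x); Wt <- tn_val(tp, w)
  d <- dim(X); dw <- dim(Wt)
  kh <- dw[1]; kw <- dw[2]; C <- d[3]; N <- d[4]
  if (dw[3] != C) stop("depthwise conv channel mismatch")
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  OH <- conv_out_dim(d[1], kh, stride, pad)
  OW <- conv_out_dim(d[2], kw, stride, pad)
  Xp <- pad_array(X, pad)
  rows_of <- function(ki) seq.int(ki, by = stride, length.out = OH)
  cols_of <- function(kj) seq.int(kj, by = stride, length.out = OW)
  Y <- array(0, c(OH, OW, C, N))
  for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    xs <- Xp[rows_of(ki), cols_of(kj), , , drop = FALSE]
    Y <- Y + xs * rep(Wt[ki, kj, ], each = OH * OW)
  }
  tp$flops <- tp$flops + as.numeric(kh) * kw * C * OH * OW * N
  backward <- function(g) {
    dW <- array(0, dim(Wt))
    dxp <- array(0, dim(Xp))
    for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
      ri <- rows_of(ki); cj <- cols_of(kj)
      xs <- Xp[ri, cj, , , drop = FALSE]
      s <- g * xs
      percn <- colSums(matrix(s, OH * OW, C * N))
      dW[ki, kj, ] <- rowSums(matrix(percn, C, N))
      dxp[ri, cj, , ] <- dxp[ri, cj, , , drop = FALSE] +
        g * rep(Wt[ki, kj, ], each = OH * OW)
    }
    dX <- if (pad > 0L)
      dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE] else dxp
    list(dX, dW)
  }
  tn_push(tp, Y, c(x, w), backward)
}

# batch normalisation over (H, W, N) per channel
op_bn <- function(tp, x, gamma, beta, model, key, training,
                  momentum = 0.1, eps = 1e-5) {
  X <- tn_val(tp, x); gam <- tn_val(tp, gamma); bet <- tn_val(tp, beta)
  d <- dim(X); C <- d[3]
  P <- d[1] * d[2] * d[4]
  Xm <- matrix(aperm(X, c(1, 2, 4, 3)), P, C)
  st <- model$bn_state
  if (!is.null(model$bn_momentum)) momentum <- model$bn_momentum
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm * Xm) - mu * mu
    v[v < 0] <- 0
    rs <- st[[key]]
    if (is.null(rs)) rs <- list(mean = mu * 0, var = mu * 0 + 1)
    st[[key]] <- list(mean = (1 - momentum) * rs$mean + momentum * mu,
                      var = (1 - momentum) * rs$var + momentum * v)
  } else {
    rs <- st[[key]]
    if (is.null(rs)) rs <- list(mean = rep(0, C), var = rep(1, C))
    mu <- rs$mean; v <- rs$var
  }
  invstd <- 1 / sqrt(v + eps)
  Xhat <- (Xm - matrix(mu, P, C, byrow = TRUE)) *
    matrix(invstd, P, C, byrow = TRUE)
  Ym <- Xhat * matrix(gam, P, C, byrow = TRUE) +
    matrix(bet, P, C, byrow = TRUE)
  yv <- aperm(array(Ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  backward <- function(g) {
    dym <- matrix(aperm(g, c(1, 2, 4, 3)), P, C)
    dgamma <- colSums(dym * Xhat)
    dbeta <- colSums(dym)
    gm <- matrix(gam, P, C, byrow = TRUE)
    if (training) {
      dxhat <- dym * gm
      m1 <- matrix(colMeans(dxhat), P, C, byrow = TRUE)
      m2 <- matrix(colMeans(dxhat * Xhat), P, C, byrow = TRUE)
      dXm <- (dxhat - m1 - Xhat * m2) * matrix(invstd, P, C, byrow = TRUE)
    } else {
      dXm <- dym * gm * matrix(invstd, P, C, byrow = TRUE)
    }
    dX <- aperm(array(dXm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
    list(dX, dgamma, dbeta)
  }
  tn_push(tp, yv, c(x, gamma, beta), backward)
}

op_relu <- function(tp, x) {
  X <- tn_val(tp, x)
  mask <- X > 0
  tn_push(tp, X * mask, x, function(g) list(g * mask))
}

op_sigmoid <- function(tp, x) {
  X <- tn_val(tp, x)
  S <- 1 / (1 + exp(-X))
  tn_push(tp, S, x, function(g) list(g * S * (1 - S)))
}

op_add <- function(tp, a, b) {
  A <- tn_val(tp, a); B <- tn_val(tp, b)
  if (!identical(dim(A), dim(B)))
    stop("wiring error: elementwise add of shapes (",
         paste(dim(A), collapse = "x"), ") and (",
         paste(dim(B), collapse = "x"), ")")
  tn_push(tp, A + B, c(a, b), function(g) list(g, g))
}

op_mul <- function(tp, a, b) {
  A <- tn_val(tp, a); B <- tn_val(tp, b)
  tn_push(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

op_concat_c <- function(tp, a, b) {
  A <- tn_val(tp, a); B <- tn_val(tp, b)
  da <- dim(A); db <- dim(B)
  if (!identical(da[c(1, 2, 4)], db[c(1, 2, 4)]))
    stop("wiring error: concat spatial/batch mismatch")
  Y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  Y[, , seq_len(da[3]), ] <- A
  Y[, , da[3] + seq_len(db[3]), ] <- B
  tn_push(tp, Y, c(a, b), function(g)
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE]))
}

op_channels <- function(tp, x, idx) {
  X <- tn_val(tp, x)
  Y <- X[, , idx, , drop = FALSE]
  d <- dim(X)
  tn_push(tp, Y, x, function(g) {
    dX <- array(0, d)
    dX[, , idx, ] <- g
    list(dX)
  })
}

op_shuffle_c <- function(tp, x, groups = 2L) {
  X <- tn_val(tp, x)
  C <- dim(X)[3]
  if (C %% groups != 0L) stop("channel shuffle: channels not divisible by groups")
  perm <- as.vector(t(matrix(seq_len(C), ncol = groups)))
  iperm <- integer(C); iperm[perm] <- seq_len(C)
  tn_push(tp, X[, , perm, , drop = FALSE], x,
          function(g) list(g[, , iperm, , drop = FALSE]))
}

op_maxpool <- function(tp, x, k = 3L, stride = 2L, pad = 1L) {
  X <- tn_val(tp, x)
  d <- dim(X)
  pi <- pool_idx(d[1], d[2], d[3], d[4], k, stride, pad)
  Xp <- pad_array(X, pad, fill = -Inf)
  vals <- matrix(Xp[pi$idx], pi$P, pi$K)
  cur <- vals[, 1]; arg <- rep(1L, pi$P)
  for (k2 in seq_len(pi$K)[-1]) {
    upd <- vals[, k2] > cur
    cur[upd] <- vals[upd, k2]
    arg[upd] <- k2
  }
  Y <- array(cur, c(pi$OH, pi$OW, d[3], d[4]))
  backward <- function(g) {
    gv <- as.vector(g)
    dxp <- numeric(pi$Hp * pi$Wp * d[3] * d[4])
    for (k2 in seq_len(pi$K)) {
      sel <- arg == k2
      if (!any(sel)) next
      ii <- pi$idx[sel, k2]
      dxp[ii] <- dxp[ii] + gv[sel]
    }
    dxp <- array(dxp, c(pi$Hp, pi$Wp, d[3], d[4]))
    dX <- if (pad > 0L)
      dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE] else dxp
    list(dX)
  }
  tn_push(tp, Y, x, backward)
}

op_avgpool <- function(tp, x, k, stride = k) {
  X <- tn_val(tp, x)
  d <- dim(X)
  pi <- pool_idx(d[1], d[2], d[3], d[4], k, stride, 0L)
  vals <- matrix(X[pi$idx], pi$P, pi$K)
  Y <- array(rowMeans(vals), c(pi$OH, pi$OW, d[3], d[4]))
  backward <- function(g) {
    gv <- as.vector(g) / pi$K
    dx <- numeric(prod(d))
    for (k2 in seq_len(pi$K)) {
      ii <- pi$idx[, k2]
      dx[ii] <- dx[ii] + gv
    }
    list(array(dx, d))
  }
  tn_push(tp, Y, x, backward)
}

# adaptive average pooling to a g x g grid (blocks by floor boundaries)
op_adaptive_avgpool <- function(tp, x, g) {
  X <- tn_val(tp, x)
  d <- dim(X)
  if (d[1] < g || d[2] < g)
    stop("adaptive pool: spatial dims smaller than target grid")
  sh <- floor((0:(g - 1)) * d[1] / g) + 1L; eh <- floor((1:g) * d[1] / g)
  sw <- floor((0:(g - 1)) * d[2] / g) + 1L; ew <- floor((1:g) * d[2] / g)
  Y <- array(0, c(g, g, d[3], d[4]))
  for (a in seq_len(g)) for (b in seq_len(g)) {
    blk <- X[sh[a]:eh[a], sw[b]:ew[b], , , drop = FALSE]
    Y[a, b, , ] <- colMeans(matrix(blk, length(sh[a]:eh[a]) * length(sw[b]:ew[b]),
                                   d[3] * d[4]))
  }
  backward <- function(gr) {
    dX <- array(0, d)
    for (a in seq_len(g)) for (b in seq_len(g)) {
      nh <- eh[a] - sh[a] + 1L; nw <- ew[b] - sw[b] + 1L
      gab <- as.vector(gr[a, b, , ]) / (nh * nw)
      dX[sh[a]:eh[a], sw[b]:ew[b], , ] <-
        dX[sh[a]:eh[a], sw[b]:ew[b], , , drop = FALSE] +
        array(rep(gab, each = nh * nw), c(nh, nw, d[3], d[4]))
    }
    list(dX)
  }
  tn_push(tp, Y, x, backward)
}

# nearest-neighbour restore of a g x g grid to (H, W), inverse of the
# adaptive pooling blocks
op_unpool_to <- function(tp, x, H, W) {
  Xs <- tn_val(tp, x)
  d <- dim(Xs); g <- d[1]
  sh <- floor((0:(g - 1)) * H / g) + 1L; eh <- floor((1:g) * H / g)
  sw <- floor((0:(g - 1)) * W / g) + 1L; ew <- floor((1:g) * W / g)
  bi <- rep(seq_len(g), times = eh - sh + 1L)
  bj <- rep(seq_len(g), times = ew - sw + 1L)
  Y <- Xs[bi, bj, , , drop = FALSE]
  backward <- function(gr) {
    dXs <- array(0, d)
    for (a in seq_len(g)) for (b in seq_len(g)) {
      blk <- gr[sh[a]:eh[a], sw[b]:ew[b], , , drop = FALSE]
      dXs[a, b, , ] <- colSums(matrix(blk, (eh[a] - sh[a] + 1L) *
                                        (ew[b] - sw[b] + 1L), d[3] * d[4]))
    }
    list(dXs)
  }
  tn_push(tp, Y, x, backward)
}

op_upsample2 <- function(tp, x) {
  X <- tn_val(tp, x)
  d <- dim(X)
  Y <- X[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
         drop = FALSE]
  backward <- function(g) {
    od <- seq.int(1L, 2L * d[1], by = 2L); ev <- od + 1L
    odw <- seq.int(1L, 2L * d[2], by = 2L); evw <- odw + 1L
    list(g[od, odw, , , drop = FALSE] + g[ev, odw, , , drop = FALSE] +
           g[od, evw, , , drop = FALSE] + g[ev, evw, , , drop = FALSE])
  }
  tn_push(tp, Y, x, backward)
}

# 1-D convolution along the channel axis (kernel length 3, zero padding,
# no bias); used for cross-channel interaction in the attention module
op_conv1d_c <- function(tp, x, w) {
  X <- tn_val(tp, x); wt <- tn_val(tp, w)
  d <- dim(X); C <- d[3]
  shift <- function(A, by) {   # by = +1 brings channel c-1 into slot c
    Z <- array(0, dim(A))
    if (by == 1L) Z[, , 2:C, ] <- A[, , 1:(C - 1), , drop = FALSE]
    else Z[, , 1:(C - 1), ] <- A[, , 2:C, , drop = FALSE]
    Z
  }
  Xl <- shift(X, 1L); Xr <- shift(X, -1L)
  Y <- wt[1] * Xl + wt[2] * X + wt[3] * Xr
  backward <- function(g) {
    dw <- c(sum(g * Xl), sum(g * X), sum(g * Xr))
    dX <- wt[1] * shift(g, -1L) + wt[2] * g + wt[3] * shift(g, 1L)
    list(dX, dw)
  }
  tn_push(tp, Y, c(x, w), backward)
}

## ---- loss ops (scalar outputs) ----------------------------------------

# weighted binary cross-entropy with logits: sum(weight * bce) / norm
op_bce_logits <- function(tp, x, target, weight = 1, norm = 1) {
  X <- tn_val(tp, x)
  l <- pmax(X, 0) - X * target + log1p(exp(-abs(X)))
  val <- sum(weight * l) / norm
  backward <- function(g) {
    s <- 1 / (1 + exp(-X))
    list(g * weight * (s - target) / norm)
  }
  tn_push(tp, val, x, backward)
}

# weighted squared error: sum(weight * (x - target)^2) / norm
op_mse <- function(tp, x, target, weight = 1, norm = 1) {
  X <- tn_val(tp, x)
  r <- X - target
  val <- sum(weight * r * r) / norm
  tn_push(tp, val, x, function(g) list(g * weight * 2 * r / norm))
}

# weighted sum of scalar nodes
op_wsum <- function(tp, ids, coefs = rep(1, length(ids))) {
  val <- 0
  for (j in seq_along(ids)) val <- val + coefs[j] * tn_val(tp, ids[j])
  tn_push(tp, val, ids, function(g) as.list(g * coefs))
}
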