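# Rendered synthetic frames with Yolo-format labels, augmentation and
# dataset splitting.

marker_rgb <- c(0.35, 0.95, 0.25)   # fluorescent green

rect_bounds <- function(cx, cy, w, h, H, W) {
  r1 <- max(1L, round(cy - h / 2)); r2 <- min(H, round(cy + h / 2) - 1L)
  c1 <- max(1L, round(cx - w / 2)); c2 <- min(W, round(cx + w / 2) - 1L)
  if (r2 < r1) r2 <- r1
  if (c2 < c1) c2 <- c1
  c(r1, r2, c1, c2)
}

draw_rect <- function(img, cx, cy, w, h, col) {
  H <- dim(img)[1]; W <- dim(img)[2]
  b <- rect_bounds(cx, cy, w, h, H, W)
  if (any(!is.finite(b))) return(img)
  for (ch in 1:3) img[b[1]:b[2], b[3]:b[4], ch] <- col[ch]
  img
}

#' Render synthetic marker frames with Yolo labels
#'
#' Each frame contains a fluorescent-green marker rectangle whose pixel
#' size follows the pinhole projection at a camera range drawn from the
#' scene's deployment band (50-75 cm by default), plus background
#' clutter rectangles -- some sharing the marker colour -- and
#' illumination jitter. The marker is drawn last (on top) and its label
#' box tightly encloses it. Frames whose marker would fall outside the
#' image are resampled (and counted in the \code{resampled} attribute).
#'
#' @param spec a [scene_spec()].
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param size square image size in pixels (default: the scene's window
#'   resolution).
#' @return A list of class \code{"yolo_dataset"}: \code{images} (arrays
#'   \code{(size, size, 3)} in \[0, 1\]), \code{labels} (data frames
#'   with \code{class}, \code{cx}, \code{cy}, \code{w}, \code{h}
#'   normalised), \code{size}.
#' @export
render_frames <- function(spec, n_frames, seed = 1L, size = NULL) {
  stopifnot(inherits(spec, "scene_spec"), n_frames > 0)
  set.seed(seed)
  if (is.null(size)) size <- spec$rmap$window_resolution[1]
  cam <- spec$cam
  s <- size / cam$ideal_resolution[1]
  images <- vector("list", n_frames)
  labels <- vector("list", n_frames)
  resampled <- 0L
  for (f in seq_len(n_frames)) {
    illum <- 1 + stats::runif(1, -spec$illum_jitter, spec$illum_jitter)
    bg <- pmin(1, pmax(0, 0.45 * illum))
    img <- array(bg, c(size, size, 3))
    img <- img + array(stats::rnorm(size * size * 3, 0, 0.02),
                       c(size, size, 3))
    nclut <- spec$clutter
    for (k in seq_len(nclut)) {
      col <- if (k <= spec$clutter_marker_like)
        pmin(1, pmax(0, marker_rgb + stats::runif(3, -0.12, 0.12)))
      else stats::runif(3)
      img <- draw_rect(img,
                       stats::runif(1, 1, size), stats::runif(1, 1, size),
                       stats::runif(1, 0.05, 0.4) * size,
                       stats::runif(1, 0.03, 0.25) * size,
                       col * illum)
    }
    for (try in 1:50) {
      L <- stats::runif(1, 50, 75)
      w <- cam$fx * spec$marker_length_cm / L * s
      h <- cam$fy * spec$marker_width_cm / L * s
      cx <- stats::runif(1, w / 2 + 1, size - w / 2 - 1)
      cy <- stats::runif(1, h / 2 + 1, size - h / 2 - 1)
      if (cx - w / 2 >= 0 && cx + w / 2 <= size &&
          cy - h / 2 >= 0 && cy + h / 2 <= size) break
      resampled <- resampled + 1L
    }
    img <- draw_rect(img, cx, cy, w, h, pmin(1, marker_rgb * illum))
    images[[f]] <- pmin(pmax(img, 0), 1)
    # label = the drawn pixel footprint, in continuous box coordinates
    b <- rect_bounds(cx, cy, w, h, size, size)
    labels[[f]] <- data.frame(class = 0L,
                              cx = (b[3] - 1 + b[4]) / 2 / size,
                              cy = (b[1] - 1 + b[2]) / 2 / size,
                              w = (b[4] - b[3] + 1) / size,
                              h = (b[2] - b[1] + 1) / size)
  }
  structure(list(images = images, labels = labels, size = size),
            class = "yolo_dataset", resampled = resampled)
}

# nearest-neighbour warp; ainv maps output (x, y) to source (x, y),
# a 2x3 matrix in pixel coordinates (x = column, y = row)
warp_nn <- function(img, ainv, fill) {
  H <- dim(img)[1]; W <- dim(img)[2]
  xg <- matrix(rep(seq_len(W), each = H), H, W)
  yg <- matrix(rep(seq_len(H), times = W), H, W)
  sx <- ainv[1, 1] * xg + ainv[1, 2] * yg + ainv[1, 3]
  sy <- ainv[2, 1] * xg + ainv[2, 2] * yg + ainv[2, 3]
  si <- round(sy); sj <- round(sx)
  ok <- si >= 1 & si <= H & sj >= 1 & sj <= W
  out <- array(fill, dim(img))
  idx <- cbind(si[ok], sj[ok])
  for (ch in 1:3) {
    m <- matrix(fill, H, W)
    m[ok] <- img[, , ch][idx]
    out[, , ch] <- m
  }
  out
}

rotate_sample <- function(img, lab, theta) {
  H <- dim(img)[1]; W <- dim(img)[2]
  cx0 <- (W + 1) / 2; cy0 <- (H + 1) / 2
  ct <- cos(theta); st <- sin(theta)
  # inverse map: rotate output coords by -theta about the centre
  ainv <- matrix(c(ct, st, cx0 - ct * cx0 - st * cy0,
                   -st, ct, cy0 + st * cx0 - ct * cy0),
                 2, 3, byrow = TRUE)
  out <- warp_nn(img, ainv, fill = mean(img))
  # forward-rotate the box corners, take the axis-aligned hull
  bx <- lab$cx * W; by <- lab$cy * H
  hw <- lab$w * W / 2; hh <- lab$h * H / 2
  nl <- lab
  for (r in seq_len(nrow(lab))) {
    xs <- bx[r] + c(-1, 1, 1, -1) * hw[r] - cx0
    ys <- by[r] + c(-1, -1, 1, 1) * hh[r] - cy0
    xr <- ct * xs - st * ys + cx0
    yr <- st * xs + ct * ys + cy0
    nl$cx[r] <- mean(range(xr)) / W
    nl$cy[r] <- mean(range(yr)) / H
    nl$w[r] <- diff(range(xr)) / W
    nl$h[r] <- diff(range(yr)) / H
  }
  list(image = out, label = nl)
}

scale_sample <- function(img, lab, s) {
  H <- dim(img)[1]; W <- dim(img)[2]
  cx0 <- (W + 1) / 2; cy0 <- (H + 1) / 2
  ainv <- matrix(c(1 / s, 0, cx0 - cx0 / s,
                   0, 1 / s, cy0 - cy0 / s), 2, 3, byrow = TRUE)
  out <- warp_nn(img, ainv, fill = mean(img))
  nl <- lab
  nl$cx <- 0.5 + (lab$cx - 0.5) * s
  nl$cy <- 0.5 + (lab$cy - 0.5) * s
  nl$w <- lab$w * s
  nl$h <- lab$h * s
  list(image = out, label = nl)
}

label_in_frame <- function(lab) {
  all(lab$cx - lab$w / 2 >= 0, lab$cx + lab$w / 2 <= 1,
      lab$cy - lab$h / 2 >= 0, lab$cy + lab$h / 2 <= 1)
}

#' Augment a labelled dataset
#'
#' Every original contributes itself plus \code{factor - 1} transformed
#' variants, cycling through random rotation, horizontal flip, vertical
#' flip, random scaling and slight colour transformation, with label
#' boxes transformed consistently. A rotation or scaling that would push
#' a box out of the frame is resampled with a shrunken magnitude.
#'
#' @param dataset a \code{"yolo_dataset"} from [render_frames()].
#' @param factor total multiplication factor (default 6).
#' @param seed RNG seed.
#' @return An augmented \code{"yolo_dataset"} with
#'   \code{factor * length(originals)} entries.
#' @export
augment <- function(dataset, factor = 6L, seed = 1L) {
  stopifnot(inherits(dataset, "yolo_dataset"), factor >= 1)
  n <- length(dataset$images)
  if (!n) stop("empty dataset", call. = FALSE)
  set.seed(seed)
  kinds <- c("rotate", "hflip", "vflip", "scale", "color")
  images <- vector("list", n * factor)
  labels <- vector("list", n * factor)
  out_i <- 0L
  for (f in seq_len(n)) {
    img <- dataset$images[[f]]; lab <- dataset$labels[[f]]
    out_i <- out_i + 1L
    images[[out_i]] <- img; labels[[out_i]] <- lab
    for (v in seq_len(factor - 1L)) {
      kind <- kinds[(v - 1L) %% length(kinds) + 1L]
      res <- switch(kind,
        rotate = {
          ang <- stats::runif(1, -15, 15) * pi / 180
          r <- rotate_sample(img, lab, ang)
          tries <- 0L
          while (!label_in_frame(r$label) && tries < 8L) {
            ang <- ang / 2
            r <- rotate_sample(img, lab, ang)
            tries <- tries + 1L
          }
          if (!label_in_frame(r$label)) list(image = img, label = lab) else r
        },
        hflip = {
          im <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
          nl <- lab; nl$cx <- 1 - lab$cx
          list(image = im, label = nl)
        },
        vflip = {
          im <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
          nl <- lab; nl$cy <- 1 - lab$cy
          list(image = im, label = nl)
        },
        scale = {
          sc <- stats::runif(1, 0.8, 1.2)
          r <- scale_sample(img, lab, sc)
          tries <- 0L
          while (!label_in_frame(r$label) && tries < 8L) {
            sc <- 1 + (sc - 1) / 2
            r <- scale_sample(img, lab, sc)
            tries <- tries + 1L
          }
          if (!label_in_frame(r$label)) list(image = img, label = lab) else r
        },
        color = {
          gains <- stats::runif(3, 0.8, 1.2)
          shift <- stats::runif(1, -0.05, 0.05)
          im <- img
          for (ch in 1:3) im[, , ch] <- im[, , ch] * gains[ch] + shift
          list(image = pmin(pmax(im, 0), 1), label = lab)
        })
      out_i <- out_i + 1L
      images[[out_i]] <- res$image
      labels[[out_i]] <- res$label
    }
  }
  structure(list(images = images, labels = labels, size = dataset$size),
            class = "yolo_dataset")
}

#' Split a dataset into train/test/validation manifests
#'
#' Items are shuffled (seeded) and partitioned into disjoint, exhaustive
#' sets whose sizes follow largest-remainder apportionment of the
#' ratios.
#'
#' @param n number of items, or anything with a length.
#' @param ratios three non-negative weights (default 8:1:1).
#' @param seed RNG seed.
#' @return A list of integer index vectors \code{train}, \code{test},
#'   \code{val}.
#' @export
split_dataset <- function(n, ratios = c(8, 1, 1), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L) n <- length(n)
  n <- as.integer(n)
  if (n < 1L) stop("empty dataset", call. = FALSE)
  if (length(ratios) != 3L || any(ratios < 0) || sum(ratios) <= 0)
    stop("need three non-negative ratios", call. = FALSE)
  q <- n * ratios / sum(ratios)
  sizes <- floor(q)
  rem <- q - sizes
  left <- n - sum(sizes)
  if (left > 0) {
    give <- order(-rem, seq_along(rem))[seq_len(left)]
    sizes[give] <- sizes[give] + 1L
  }
  set.seed(seed)
  perm <- sample.int(n)
  bounds <- cumsum(sizes)
  list(train = sort(perm[seq_len(sizes[1])]),
       test = sort(perm[(bounds[1] + 1L):bounds[2]]),
       val = if (sizes[3] > 0) sort(perm[(bounds[2] + 1L):bounds[3]])
             else integer(0))
}

#' Write a dataset in Yolo layout
#'
#' Images as PNG, labels as one text file per image with lines
#' \code{class cx cy w h} (normalised, six decimals).
#'
#' @param dataset a \code{"yolo_dataset"}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written image paths.
#' @export
write_yolo_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "yolo_dataset"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(dataset$images))
  for (f in seq_along(dataset$images)) {
    stem <- sprintf("frame_%05d", f)
    paths[f] <- file.path(dir, "images", paste0(stem, ".png"))
    png::writePNG(dataset$images[[f]], paths[f])
    lab <- dataset$labels[[f]]
    writeLines(sprintf("%d %.6f %.6f %.6f %.6f",
                       lab$class, lab$cx, lab$cy, lab$w, lab$h),
               file.path(dir, "labels", paste0(stem, ".txt")))
  }
  invisible(paths)
}
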