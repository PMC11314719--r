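#' Marker box track
#'
#' A per-frame record of the tracked marker-wristband detection box at the
#' processing-window resolution: frame index, timestamp, box centre,
#' box size and detection confidence. Frames may be missing (dropped
#' detections); timestamps must be strictly increasing.
#'
#' @param frame integer frame indices.
#' @param time_s timestamps in seconds, strictly increasing.
#' @param cx,cy box centre in window pixels.
#' @param w,h box width and height in window pixels.
#' @param conf detection confidence in \[0, 1\].
#' @param window_resolution integer \code{c(width, height)} of the window.
#' @return A data frame of class \code{"box_track"} with the window
#'   resolution attached as attribute \code{window_resolution}.
#' @export
box_track <- function(frame, time_s, cx, cy, w, h,
                      conf = rep(1, length(frame)),
                      window_resolution) {
  if (is.unsorted(time_s, strictly = TRUE))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(conf < 0 | conf > 1))
    stop("confidences must lie in [0, 1]", call. = FALSE)
  out <- data.frame(frame = as.integer(frame), time_s = time_s,
                    cx = cx, cy = cy, w = w, h = h, conf = conf)
  attr(out, "window_resolution") <- as.integer(window_resolution)
  class(out) <- c("box_track", "data.frame")
  out
}

#' Read / write a box track as CSV
#'
#' The CSV schema is \code{frame, time_s, cx, cy, w, h, conf}; the window
#' resolution is carried in a comment header line
#' \code{# window_resolution: <w> <h>}.
#'
#' @param path CSV file path.
#' @param track for [write_box_track()], a [box_track()].
#' @return [read_box_track()] returns a [box_track()].
#' @export
read_box_track <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 1L)
  wres <- c(352L, 352L)
  if (grepl("^#\\s*window_resolution:", hdr)) {
    wres <- as.integer(strsplit(sub("^#\\s*window_resolution:\\s*", "", hdr),
                                "\\s+")[[1]])
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("frame", "time_s", "cx", "cy", "w", "h")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed track CSV (", path, "): missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  num <- suppressWarnings(
    vapply(df[need], function(col) is.finite(as.numeric(col)),
           logical(nrow(df))))
  bad <- which(!apply(matrix(num, nrow = nrow(df)), 1, all))
  if (length(bad))
    stop("malformed track CSV (", path, "): non-numeric or missing value at data row ",
         bad[1], call. = FALSE)
  if (is.null(df$conf)) df$conf <- 1
  box_track(df$frame, df$time_s, df$cx, df$cy, df$w, df$h, df$conf,
            window_resolution = wres)
}

#' @rdname read_box_track
#' @export
write_box_track <- function(track, path) {
  stopifnot(inherits(track, "box_track"))
  wres <- attr(track, "window_resolution")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# window_resolution: %d %d", wres[1], wres[2]), con)
  utils::write.csv(as.data.frame(track), con, row.names = FALSE)
  invisible(path)
}

#' Extract the vertical displacement series from a box track
#'
#' Rescales the vertical box-centre positions to the camera's ideal
#' resolution, fills short detection gaps by linear interpolation on a
#' regular frame grid, and applies a centred moving average. The smoothed
#' signal is used to locate compression extrema; the raw (gap-filled but
#' unsmoothed) signal is retained so that cycle amplitudes are read
#' without the amplitude attenuation a moving average introduces.
#'
#' @param track a [box_track()].
#' @param rmap a [resolution_map()]; its window resolution must agree with
#'   the track's.
#' @param smoothing_window moving-average width in seconds (default 0.1).
#' @param max_gap longest tolerated detection gap in seconds (default
#'   0.25); a longer gap raises a track-broken error naming the interval.
#' @return An object of class \code{"displacement_series"}: a list with
#'   \code{time}, \code{v_pos} (smoothed ideal-resolution vertical
#'   position), \code{v_raw}, and the window/ideal scale factor.
#' @export
extract_displacement <- function(track, rmap, smoothing_window = 0.1,
                                 max_gap = 0.25) {
  stopifnot(inherits(track, "box_track"), inherits(rmap, "resolution_map"))
  if (nrow(track) < 2L)
    stop("need at least 2 frames to form a displacement series",
         call. = FALSE)
  gaps <- diff(track$time_s)
  too_long <- which(gaps > max_gap)
  if (length(too_long)) {
    i <- too_long[1]
    stop(sprintf(
      "track broken: detection gap of %.3f s between t = %.3f s and t = %.3f s exceeds max_gap = %.3f s",
      gaps[i], track$time_s[i], track$time_s[i + 1], max_gap), call. = FALSE)
  }
  scale_v <- rmap$ideal_resolution[2] / rmap$window_resolution[2]
  dt <- stats::median(gaps)
  grid <- seq(track$time_s[1], track$time_s[nrow(track)], by = dt)
  v_raw <- stats::approx(track$time_s, track$cy * scale_v, xout = grid)$y
  k <- max(1L, round(smoothing_window / dt))
  if (k %% 2L == 0L) k <- k + 1L
  v_sm <- moving_average(v_raw, k)
  structure(list(time = grid, v_pos = v_sm, v_raw = v_raw,
                 scale_v = scale_v, dt = dt),
            class = "displacement_series")
}

# centred moving average with shrinking windows at the edges
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
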