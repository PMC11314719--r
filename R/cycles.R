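#' Detect compression cycles in a displacement series
#'
#' Finds alternating peaks (hands at the top of the stroke) and troughs
#' (bottom of the stroke) in the vertical displacement signal with a
#' hysteresis rule: an extremum is confirmed only once the signal has
#' moved away from it by at least \code{min_amplitude_px}, which is
#' equivalent to requiring that prominence. One complete
#' peak-trough-peak excursion is one chest compression. Extremum
#' positions are located on the smoothed signal; extremum values are read
#' from the unsmoothed signal so that amplitudes are not attenuated by
#' the moving average.
#'
#' @param series a \code{"displacement_series"} from
#'   [extract_displacement()].
#' @param min_amplitude_px hysteresis threshold in ideal-resolution
#'   pixels. Default: 25\% of the trace's typical peak-to-trough
#'   excursion, estimated robustly as the 5\%-95\% quantile range of the
#'   post-warm-up smoothed signal.
#' @param min_period_s minimum cycle duration in seconds (default 0.3,
#'   capping the plausible compression rate at 200 per minute).
#' @param warmup_s compressions whose bottom-of-stroke extremum falls
#'   within this many seconds of the start of the series are discarded
#'   (default 2); the first moments of a recording are dominated by
#'   marker settling rather than compressions.
#' @return A data frame of class \code{"compression_cycles"}, one row per
#'   cycle: \code{peak_time}, \code{trough_time}, \code{peak2_time},
#'   \code{amplitude_px} (ideal resolution), \code{B0} (window
#'   resolution), and index columns into the series.
#' @export
detect_cycles <- function(series, min_amplitude_px = NULL,
                          min_period_s = 0.3, warmup_s = 2) {
  stopifnot(inherits(series, "displacement_series"))
  t <- series$time
  h <- -series$v_pos          # height: up is positive
  h_raw <- -series$v_raw
  keep <- t >= t[1] + warmup_s
  empty <- structure(
    data.frame(peak_time = numeric(0), trough_time = numeric(0),
               peak2_time = numeric(0), amplitude_px = numeric(0),
               B0 = numeric(0), peak_i = integer(0), trough_i = integer(0),
               peak2_i = integer(0)),
    class = c("compression_cycles", "data.frame"))
  if (sum(keep) < 3L) return(empty)
  if (is.null(min_amplitude_px)) {
    q <- stats::quantile(h[keep], c(0.05, 0.95), names = FALSE)
    min_amplitude_px <- 0.25 * (q[2] - q[1])
    if (min_amplitude_px <= 0) return(empty)
  }
  ext <- find_alternating_extrema(h, min_amplitude_px)
  if (nrow(ext) < 3L) return(empty)

  # assemble peak -> trough -> peak triplets; compressions whose bottom
  # falls inside the warm-up window are discarded (marker settling)
  rows <- list()
  for (j in seq_len(nrow(ext) - 2L)) {
    if (ext$type[j] == "peak" && ext$type[j + 1L] == "trough" &&
        ext$type[j + 2L] == "peak") {
      pi <- ext$i[j]; ti <- ext$i[j + 1L]; p2 <- ext$i[j + 2L]
      if (t[ti] < t[1] + warmup_s) next
      if (t[p2] - t[pi] < min_period_s) next
      amp <- mean(c(refine_extremum(h_raw, pi), refine_extremum(h_raw, p2))) -
        refine_extremum(h_raw, ti)
      if (amp <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        peak_time = t[pi], trough_time = t[ti], peak2_time = t[p2],
        amplitude_px = amp, B0 = amp / series$scale_v,
        peak_i = pi, trough_i = ti, peak2_i = p2)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("compression_cycles", "data.frame")
  out
}

# hysteresis extremum detector: confirms a local max (peak) once the
# signal has fallen >= thr below it, a local min (trough) once it has
# risen >= thr above it; returns alternating extrema in order.
find_alternating_extrema <- function(h, thr) {
  n <- length(h)
  idx <- integer(0); typ <- character(0)
  last_max <- h[1]; last_max_i <- 1L
  last_min <- h[1]; last_min_i <- 1L
  direction <- 0L   # +1 rising (last confirmed = trough), -1 falling
  for (i in 2:n) {
    if (h[i] > last_max) { last_max <- h[i]; last_max_i <- i }
    if (h[i] < last_min) { last_min <- h[i]; last_min_i <- i }
    if (direction >= 0L && h[i] <= last_max - thr) {
      idx <- c(idx, last_max_i); typ <- c(typ, "peak")
      direction <- -1L
      last_min <- h[i]; last_min_i <- i
    } else if (direction <= 0L && h[i] >= last_min + thr) {
      idx <- c(idx, last_min_i); typ <- c(typ, "trough")
      direction <- 1L
      last_max <- h[i]; last_max_i <- i
    }
  }
  # the trace may end on the way up from the final trough: close the
  # final compression with the pending maximum if its one-sided
  # prominence already qualifies
  if (direction == 1L && last_max >= last_min + thr) {
    idx <- c(idx, last_max_i); typ <- c(typ, "peak")
  }
  data.frame(i = idx, type = typ, stringsAsFactors = FALSE)
}

# sub-sample extremum value by a 3-point parabola on the raw signal;
# falls back to the sample value at boundaries or degenerate curvature
refine_extremum <- function(h, i) {
  n <- length(h)
  if (i <= 1L || i >= n) return(h[i])
  a <- h[i - 1L]; b <- h[i]; c <- h[i + 1L]
  den <- a - 2 * b + c
  if (abs(den) < 1e-12) return(b)
  shift <- (a - c)^2 / (8 * den)
  if (abs(shift) > abs(a - c)) return(b)   # noisy / non-parabolic: keep sample
  b - shift
}

#' Count compressions
#' @param cycles a \code{"compression_cycles"} data frame.
#' @return Integer number of detected compressions.
#' @export
count_compressions <- function(cycles) nrow(cycles)

#' Compression frequency in compressions per minute
#' @param cycles a \code{"compression_cycles"} data frame.
#' @param duration_s trace duration in seconds (> 0).
#' @return Frequency in compressions per minute.
#' @export
compression_frequency <- function(cycles, duration_s) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  count_compressions(cycles) / duration_s * 60
}

#' Per-cycle compression depths in centimetres
#'
#' For each detected cycle the marker's apparent pixel length is averaged
#' over the cycle's frames and converted to a camera-marker range; the
#' cycle's vertical pixel amplitude is then mapped to a real-world depth
#' through the pinhole geometry. Cycles without any usable marker-length
#' observation get \code{NA} depth and are flagged, never dropped.
#'
#' @param cycles a \code{"compression_cycles"} data frame.
#' @param track the originating [box_track()].
#' @param cam a [camera_model()].
#' @param rmap a [resolution_map()].
#' @param marker_length_cm marker physical length (default 33.40).
#' @return A data frame with \code{depth_cm}, \code{range_cm},
#'   \code{Ap_px} and logical \code{depth_available} per cycle.
#' @export
cycle_depths <- function(cycles, track, cam, rmap, marker_length_cm = 33.40) {
  stopifnot(inherits(cycles, "compression_cycles"),
            inherits(track, "box_track"),
            inherits(cam, "camera_model"), inherits(rmap, "resolution_map"))
  scale_u <- rmap$ideal_resolution[1] / rmap$window_resolution[1]
  n <- nrow(cycles)
  depth <- range_cm <- ap <- rep(NA_real_, n)
  avail <- rep(FALSE, n)
  for (j in seq_len(n)) {
    in_cycle <- track$time_s >= cycles$peak_time[j] &
      track$time_s <= cycles$peak2_time[j] & is.finite(track$w) &
      track$w > 0
    if (!any(in_cycle)) next
    Ap <- mean(track$w[in_cycle]) * scale_u
    L <- estimate_range(Ap, cam, marker_length_cm)
    H <- displacement_to_depth(cycles$amplitude_px[j], L, cam)
    ap[j] <- Ap; range_cm[j] <- L; depth[j] <- H; avail[j] <- TRUE
  }
  data.frame(depth_cm = depth, range_cm = range_cm, Ap_px = ap,
             depth_available = avail)
}

#' Aggregate CPR quality metrics
#'
#' @param cycles a \code{"compression_cycles"} data frame.
#' @param depths_cm numeric per-cycle depths (may contain \code{NA}).
#' @param duration_s trace duration in seconds.
#' @return An object of class \code{"cpr_metrics"}: count, frequency in
#'   compressions/minute, per-cycle depths, mean depth, duration.
#' @export
cpr_metrics <- function(cycles, depths_cm, duration_s) {
  count <- count_compressions(cycles)
  if (length(depths_cm) != count)
    stop("depths_cm must have one entry per cycle", call. = FALSE)
  structure(list(count = count,
                 frequency_cpm = if (duration_s > 0)
                   count / duration_s * 60 else NA_real_,
                 depths_cm = depths_cm,
                 mean_depth_cm = mean(depths_cm, na.rm = TRUE),
                 duration_s = duration_s),
            class = "cpr_metrics")
}

#' @export
print.cpr_metrics <- function(x, ...) {
  cat("CPR quality metrics\n")
  cat(sprintf("  compressions : %d over %.1f s\n", x$count, x$duration_s))
  cat(sprintf("  frequency    : %.1f per minute\n", x$frequency_cpm))
  cat(sprintf("  mean depth   : %.2f cm (%d cycles with depth)\n",
              x$mean_depth_cm, sum(is.finite(x$depths_cm))))
  invisible(x)
}

#' Compare estimated metrics against ground truth
#'
#' Per-cycle depth errors are computed after matching each estimated
#' cycle to the nearest ground-truth cycle by trough time. The depth
#' accuracy is the fraction of matched cycles with absolute depth error
#' strictly below \code{depth_tol_cm}; the count is correct when the
#' absolute count error is at most \code{count_tol}.
#'
#' @param estimated,truth \code{"cpr_metrics"} objects; \code{truth} may
#'   carry cycle times in \code{trough_times} for matching (otherwise
#'   cycles are matched by order).
#' @param depth_tol_cm depth tolerance in cm, strict \code{<} (default 1).
#' @param count_tol count tolerance, inclusive (default 2).
#' @return A list: \code{depth_accuracy}, \code{depth_errors_cm},
#'   \code{count_correct}, \code{count_error}, \code{frequency_error_cpm}.
#' @export
evaluate_accuracy <- function(estimated, truth, depth_tol_cm = 1.0,
                              count_tol = 2L) {
  stopifnot(inherits(estimated, "cpr_metrics"), inherits(truth, "cpr_metrics"))
  if (is.finite(estimated$duration_s) && is.finite(truth$duration_s) &&
      abs(estimated$duration_s - truth$duration_s) > 1)
    warning("estimated and truth durations differ by more than 1 s")
  n <- min(length(estimated$depths_cm), length(truth$depths_cm))
  e <- estimated$depths_cm; g <- truth$depths_cm
  if (!is.null(estimated$trough_times) && !is.null(truth$trough_times)) {
    m <- vapply(estimated$trough_times,
                function(tt) which.min(abs(truth$trough_times - tt)),
                integer(1))
    err <- abs(e - g[m])
  } else {
    err <- abs(e[seq_len(n)] - g[seq_len(n)])
  }
  err <- err[is.finite(err)]
  list(depth_accuracy = if (length(err)) mean(err < depth_tol_cm) else NA_real_,
       depth_errors_cm = err,
       count_correct = abs(estimated$count - truth$count) <= count_tol,
       count_error = estimated$count - truth$count,
       frequency_error_cpm = estimated$frequency_cpm - truth$frequency_cpm)
}
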