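#' Synthetic CPR scene specification
#'
#' A generative description of the measurement conditions the pipeline
#' is designed for: a fluorescent-green marker wristband of known
#' physical size viewed by a pinhole camera at 50-75 cm, undergoing
#' quasi-sinusoidal vertical motion as the rescuer compresses, with
#' detection-level noise. Defaults emulate the observed error regime at
#' desk scale: 1 px box-centre jitter, 1\% marker-length measurement
#' noise, 2\% detection dropout, 0.2 cm per-cycle depth variability.
#'
#' @param marker_length_cm,marker_width_cm marker physical size
#'   (defaults 33.40 x 3.80).
#' @param cam a [camera_model()] (default: 600 px focal, 704 x 704 frame).
#' @param rmap a [resolution_map()] (default window 352 x 352).
#' @param range_cm camera-marker horizontal distance (default 60, the
#'   middle of the 50-75 cm deployment band).
#' @param depth_cm mean compression stroke (default 5).
#' @param rate_cpm compression rate per minute (default 110).
#' @param depth_jitter_cm per-cycle stroke standard deviation (cm).
#' @param period_jitter_frac per-cycle period jitter (fraction).
#' @param center_noise_px box-centre noise, window pixels.
#' @param marker_len_noise_frac multiplicative noise on the measured
#'   marker pixel length.
#' @param dropout_prob per-frame detection dropout probability.
#' @param settle_amp_cm amplitude of the pre-compression marker
#'   settling wobble during the lead-in.
#' @param lead_in_s settling time before the first compression
#'   (default 2 s, matched by the cycle detector's warm-up discard).
#' @param fps frame rate (default 30).
#' @param clutter number of distractor rectangles in rendered frames.
#' @param clutter_marker_like number of those sharing the marker colour.
#' @param illum_jitter background illumination jitter range.
#' @return An object of class \code{"scene_spec"}.
#' @export
scene_spec <- function(marker_length_cm = 33.40, marker_width_cm = 3.80,
                       cam = camera_model(fx = 600,
                                          ideal_resolution = c(704, 704)),
                       rmap = resolution_map(c(352, 352), c(704, 704)),
                       range_cm = 60,
                       depth_cm = 5, rate_cpm = 110,
                       depth_jitter_cm = 0.2, period_jitter_frac = 0.02,
                       center_noise_px = 1.0, marker_len_noise_frac = 0.01,
                       dropout_prob = 0.02, settle_amp_cm = 0.2,
                       lead_in_s = 2, fps = 30,
                       clutter = 4L, clutter_marker_like = 1L,
                       illum_jitter = 0.15) {
  stopifnot(marker_length_cm > 0, marker_width_cm > 0, range_cm > 0,
            depth_cm > 0, rate_cpm > 0, fps > 0,
            dropout_prob >= 0, dropout_prob <= 1)
  structure(as.list(environment()), class = "scene_spec")
}

#' Simulate a tracked marker trajectory with ground truth
#'
#' Generates an analytic compression trace: after a lead-in settling
#' phase the marker follows per-cycle cosine strokes (one complete
#' top-bottom-top excursion per compression), is projected through the
#' scene's pinhole camera at the scene range, rescaled to the detection
#' window, and corrupted with centre noise, marker-length measurement
#' noise and detection dropout. The ground truth (per-cycle depths,
#' count, frequency, per-frame true box) is recorded before any noise.
#'
#' @param spec a [scene_spec()].
#' @param duration_s compression-phase duration; alternatively give
#'   \code{n_compressions}.
#' @param n_compressions number of compressions to generate.
#' @param seed RNG seed.
#' @return A list with \code{track} (a [box_track()]) and \code{truth}
#'   (class \code{"trial_truth"}): per-cycle \code{depths_cm},
#'   \code{count}, \code{frequency_cpm}, \code{trough_times},
#'   \code{true_boxes}, and a \code{"cpr_metrics"} view in
#'   \code{metrics}.
#' @export
simulate_track <- function(spec, duration_s = NULL, n_compressions = NULL,
                           seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(seed)
  period <- 60 / spec$rate_cpm
  if (is.null(n_compressions)) {
    if (is.null(duration_s) || duration_s <= 0)
      stop("need duration_s > 0 or n_compressions", call. = FALSE)
    n_compressions <- max(1L, floor(duration_s / period))
  }
  strokes <- spec$depth_cm +
    stats::rnorm(n_compressions, 0, spec$depth_jitter_cm)
  strokes <- pmax(strokes, 0.5)
  periods <- period *
    (1 + stats::rnorm(n_compressions, 0, spec$period_jitter_frac))
  periods <- pmax(periods, 0.2)
  starts <- spec$lead_in_s + c(0, cumsum(periods))[seq_len(n_compressions)]
  t_end <- spec$lead_in_s + sum(periods)
  tgrid <- seq(0, t_end, by = 1 / spec$fps)

  # downward displacement of the marker centre, cm
  disp <- numeric(length(tgrid))
  lead <- tgrid < spec$lead_in_s
  if (any(lead) && spec$settle_amp_cm > 0)
    disp[lead] <- spec$settle_amp_cm *
      0.5 * (1 - cos(2 * pi * tgrid[lead] / max(spec$lead_in_s, 0.5)))
  cyc_idx <- findInterval(tgrid, starts)
  active <- cyc_idx >= 1 & tgrid >= spec$lead_in_s
  ci <- cyc_idx[active]
  phase <- (tgrid[active] - starts[ci]) / periods[ci]
  disp[active] <- strokes[ci] / 2 * (1 - cos(2 * pi * pmin(phase, 1)))

  # pinhole projection at range L (camera axis horizontal, depth constant)
  cam <- spec$cam; rmap <- spec$rmap
  L <- spec$range_cm
  y_rest_cm <- 0                       # marker rest height on the optical axis
  v_ideal <- cam$v0 + cam$fy * (y_rest_cm + disp) / L
  u_ideal <- rep(cam$u0, length(tgrid))
  w_ideal <- cam$fx * spec$marker_length_cm / L
  h_ideal <- cam$fy * spec$marker_width_cm / L
  su <- rmap$window_resolution[1] / rmap$ideal_resolution[1]
  sv <- rmap$window_resolution[2] / rmap$ideal_resolution[2]

  true_boxes <- data.frame(time_s = tgrid,
                           cx = u_ideal * su, cy = v_ideal * sv,
                           w = w_ideal * su, h = h_ideal * sv)

  nfr <- length(tgrid)
  cx <- true_boxes$cx + stats::rnorm(nfr, 0, spec$center_noise_px)
  cy <- true_boxes$cy + stats::rnorm(nfr, 0, spec$center_noise_px)
  w <- true_boxes$w *
    (1 + stats::rnorm(nfr, 0, spec$marker_len_noise_frac))
  h <- true_boxes$h *
    (1 + stats::rnorm(nfr, 0, spec$marker_len_noise_frac))
  keep <- stats::runif(nfr) >= spec$dropout_prob
  keep[1] <- TRUE; keep[nfr] <- TRUE
  track <- box_track(frame = which(keep), time_s = tgrid[keep],
                     cx = cx[keep], cy = cy[keep], w = w[keep], h = h[keep],
                     conf = rep(0.99, sum(keep)),
                     window_resolution = rmap$window_resolution)

  comp_duration <- sum(periods)
  truth <- structure(list(
    depths_cm = strokes,
    count = n_compressions,
    frequency_cpm = n_compressions / comp_duration * 60,
    trough_times = starts + periods / 2,
    start_times = starts,
    duration_s = comp_duration,
    lead_in_s = spec$lead_in_s,
    true_boxes = true_boxes,
    spec = spec, seed = seed), class = "trial_truth")
  truth$metrics <- structure(list(count = truth$count,
                                  frequency_cpm = truth$frequency_cpm,
                                  depths_cm = truth$depths_cm,
                                  mean_depth_cm = mean(truth$depths_cm),
                                  duration_s = comp_duration,
                                  trough_times = truth$trough_times),
                             class = "cpr_metrics")
  list(track = track, truth = truth)
}
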