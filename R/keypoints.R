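# Keypoint-rule posture checks and synthetic keypoint fixtures.
# Pose estimation itself is external; only its serialised keypoints are
# consumed (image convention: y grows downward).

kp_joints <- c("nose", "l_shoulder", "r_shoulder", "l_elbow", "r_elbow",
               "l_wrist", "r_wrist", "l_hip", "r_hip", "l_knee", "r_knee",
               "l_ankle", "r_ankle")

#' Construct a keypoint frame
#'
#' @param joints named list; each element is \code{c(x, y, conf)} in
#'   pixels with confidence in \[0, 1\]. Expected names: nose,
#'   l/r_shoulder, l/r_elbow, l/r_wrist, l/r_hip, l/r_knee, l/r_ankle.
#' @param layout layout tag (default \code{"COCO-18"}).
#' @return An object of class \code{"keypoint_frame"}.
#' @export
keypoint_frame <- function(joints, layout = "COCO-18") {
  cf <- vapply(joints, function(j) j[3], numeric(1))
  if (any(cf < 0 | cf > 1))
    stop("confidences must lie in [0, 1]", call. = FALSE)
  structure(joints, layout = layout, class = "keypoint_frame")
}

kp_get <- function(kp, name) {
  j <- kp[[name]]
  if (is.null(j)) c(NA_real_, NA_real_, 0) else j
}

#' Angle of the compressing arm from the image vertical
#'
#' The angle between the shoulder-to-wrist vector and straight-down, in
#' degrees within \[0, 90\]. By default the compressing arm is the one
#' whose wrist sits lower in the image.
#'
#' @param kp a [keypoint_frame()].
#' @param side \code{"l"}, \code{"r"} or \code{NULL} (auto: lowest wrist).
#' @param min_conf minimum joint confidence; below it the angle is
#'   unavailable (\code{NA}) and callers should fall back to the
#'   visibility check.
#' @return Angle in degrees, or \code{NA} if the joints are unreliable.
#' @export
arm_vertical_angle <- function(kp, side = NULL, min_conf = 0.3) {
  stopifnot(inherits(kp, "keypoint_frame"))
  if (is.null(side)) {
    lw <- kp_get(kp, "l_wrist"); rw <- kp_get(kp, "r_wrist")
    side <- if (isTRUE(rw[2] > lw[2])) "r" else "l"
  }
  sh <- kp_get(kp, paste0(side, "_shoulder"))
  wr <- kp_get(kp, paste0(side, "_wrist"))
  if (sh[3] < min_conf || wr[3] < min_conf) return(NA_real_)
  dx <- wr[1] - sh[1]
  dy <- wr[2] - sh[2]            # positive when the wrist is below
  ang <- atan2(abs(dx), dy) * 180 / pi
  min(max(ang, 0), 90)
}

#' One-knee kneeling check
#'
#' Flags an unstable one-knee stance when the vertical gap between the
#' knees exceeds a fraction of the torso length (mean-shoulder to
#' mean-hip pixel distance).
#'
#' @param kp a [keypoint_frame()].
#' @param knee_gap_frac flag threshold as a fraction of torso length
#'   (default 0.15).
#' @param min_conf minimum knee confidence; below it the check is
#'   indeterminate.
#' @return A list: \code{flag}, \code{gap_frac} (evidence),
#'   \code{indeterminate}.
#' @export
check_kneeling <- function(kp, knee_gap_frac = 0.15, min_conf = 0.3) {
  stopifnot(inherits(kp, "keypoint_frame"))
  lk <- kp_get(kp, "l_knee"); rk <- kp_get(kp, "r_knee")
  if (lk[3] < min_conf || rk[3] < min_conf)
    return(list(flag = NA, gap_frac = NA_real_, indeterminate = TRUE))
  sh <- (kp_get(kp, "l_shoulder")[1:2] + kp_get(kp, "r_shoulder")[1:2]) / 2
  hp <- (kp_get(kp, "l_hip")[1:2] + kp_get(kp, "r_hip")[1:2]) / 2
  torso <- sqrt(sum((sh - hp)^2))
  if (!is.finite(torso) || torso <= 0)
    return(list(flag = NA, gap_frac = NA_real_, indeterminate = TRUE))
  gap_frac <- abs(lk[2] - rk[2]) / torso
  list(flag = gap_frac > knee_gap_frac, gap_frac = gap_frac,
       indeterminate = FALSE)
}

#' Arm visibility check
#'
#' Dark clothing or low contrast shows up as low pose-estimator
#' confidence on the arm joints; the flag is raised when the mean arm
#' confidence falls strictly below the floor.
#'
#' @param kp a [keypoint_frame()].
#' @param conf_floor confidence floor (default 0.3).
#' @return A list: \code{flag}, \code{mean_arm_conf} (evidence).
#' @export
check_visibility <- function(kp, conf_floor = 0.3) {
  stopifnot(inherits(kp, "keypoint_frame"))
  arm <- c("l_shoulder", "r_shoulder", "l_elbow", "r_elbow",
           "l_wrist", "r_wrist")
  cf <- vapply(arm, function(j) kp_get(kp, j)[3], numeric(1))
  m <- mean(cf)
  list(flag = m < conf_floor, mean_arm_conf = m)
}

#' Assess posture over a keypoint sequence
#'
#' Applies the three incorrect-posture rules per frame (non-vertical
#' compression arm, one-knee stance, low arm visibility) and smooths
#' each flag with a majority vote over a sliding window to suppress
#' single-frame jitter.
#'
#' @param frames list of [keypoint_frame()].
#' @param fps frame rate of the sequence (default 30).
#' @param angle_thr non-vertical threshold in degrees (default 15).
#' @param knee_gap_frac,min_conf,conf_floor rule thresholds.
#' @param vote_window_s majority-vote window in seconds (default 1).
#' @return An object of class \code{"posture_report"}: per-frame flags
#'   and evidence, smoothed flags, and per-rule flagged fractions.
#' @export
assess_posture <- function(frames, fps = 30, angle_thr = 15,
                           knee_gap_frac = 0.15, min_conf = 0.3,
                           conf_floor = 0.3, vote_window_s = 1) {
  n <- length(frames)
  per <- data.frame(frame = seq_len(n),
                    angle_deg = NA_real_, non_vertical = NA,
                    knee_gap_frac = NA_real_, one_knee = NA,
                    mean_arm_conf = NA_real_, low_visibility = NA)
  for (i in seq_len(n)) {
    kp <- frames[[i]]
    ang <- arm_vertical_angle(kp, min_conf = min_conf)
    per$angle_deg[i] <- ang
    per$non_vertical[i] <- if (is.na(ang)) NA else ang > angle_thr
    kn <- check_kneeling(kp, knee_gap_frac, min_conf)
    per$knee_gap_frac[i] <- kn$gap_frac
    per$one_knee[i] <- kn$flag
    vis <- check_visibility(kp, conf_floor)
    per$mean_arm_conf[i] <- vis$mean_arm_conf
    per$low_visibility[i] <- vis$flag
  }
  k <- max(1L, round(vote_window_s * fps))
  if (k %% 2L == 0L) k <- k + 1L
  vote <- function(f) {
    x <- ifelse(is.na(f), 0, as.numeric(f))
    moving_average(x, k) > 0.5
  }
  smoothed <- data.frame(non_vertical = vote(per$non_vertical),
                         one_knee = vote(per$one_knee),
                         low_visibility = vote(per$low_visibility))
  structure(list(per_frame = per, smoothed = smoothed,
                 fractions = colMeans(smoothed),
                 thresholds = list(angle_thr = angle_thr,
                                   knee_gap_frac = knee_gap_frac,
                                   min_conf = min_conf,
                                   conf_floor = conf_floor,
                                   vote_window_s = vote_window_s)),
            class = "posture_report")
}

#' @export
print.posture_report <- function(x, ...) {
  cat("Posture report over", nrow(x$per_frame), "frames\n")
  f <- x$fractions
  cat(sprintf("  non-vertical arm : %4.1f%% of frames\n", 100 * f[1]))
  cat(sprintf("  one-knee stance  : %4.1f%% of frames\n", 100 * f[2]))
  cat(sprintf("  low visibility   : %4.1f%% of frames\n", 100 * f[3]))
  invisible(x)
}

# COCO-18 serialisation order used by common pose estimators
kp18_order <- c("nose", "neck", "r_shoulder", "r_elbow", "r_wrist",
                "l_shoulder", "l_elbow", "l_wrist", "r_hip", "r_knee",
                "r_ankle", "l_hip", "l_knee", "l_ankle", "r_eye", "l_eye",
                "r_ear", "l_ear")

#' Read / write keypoint frames as pose-estimator JSON
#'
#' The on-disk layout is the common multi-person format:
#' \code{\{"people": [\{"pose_keypoints_2d": [x1, y1, c1, x2, ...]\}]\}}
#' in COCO-18 joint order, one file per frame; only the first person is
#' read.
#'
#' @param paths character vector of per-frame JSON files.
#' @param frames for [write_keypoints()], a list of [keypoint_frame()].
#' @param dir output directory.
#' @return [read_keypoints()] returns a list of [keypoint_frame()].
#' @export
read_keypoints <- function(paths) {
  lapply(paths, function(p) {
    js <- jsonlite::fromJSON(p, simplifyVector = TRUE)
    if (is.null(js$people) || !length(js$people$pose_keypoints_2d))
      stop("no people in keypoint file: ", p, call. = FALSE)
    flat <- if (is.list(js$people$pose_keypoints_2d))
      js$people$pose_keypoints_2d[[1]] else js$people$pose_keypoints_2d
    m <- matrix(as.numeric(flat), ncol = 3, byrow = TRUE)
    joints <- list()
    for (k in seq_len(min(nrow(m), length(kp18_order)))) {
      nm <- kp18_order[k]
      if (nm %in% kp_joints) joints[[nm]] <- m[k, ]
    }
    keypoint_frame(joints)
  })
}

#' @rdname read_keypoints
#' @export
write_keypoints <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    kp <- frames[[i]]
    flat <- unlist(lapply(kp18_order, function(nm) {
      j <- kp[[nm]]
      if (is.null(j)) c(0, 0, 0) else j
    }))
    paths[i] <- file.path(dir, sprintf("frame_%05d_keypoints.json", i))
    jsonlite::write_json(
      list(version = 1.3,
           people = list(list(pose_keypoints_2d = round(flat, 3)))),
      paths[i], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Generate synthetic posture keypoint sequences
#'
#' Kinematically plausible keypoints of a rescuer seen from the side,
#' oscillating with the compression rhythm, embodying one of the
#' assessed scenarios: \code{correct}, \code{non_vertical} (arm angle
#' drawn from 25-40 degrees), \code{one_knee} (knee height gap about
#' 40\% of torso length), or \code{dark_arms} (arm confidences below
#' 0.2).
#'
#' @param scenario one of \code{"correct"}, \code{"non_vertical"},
#'   \code{"one_knee"}, \code{"dark_arms"}.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param fps frame rate (default 30).
#' @param rate_cpm compression rate (default 110).
#' @return A list of [keypoint_frame()].
#' @export
synth_keypoints <- function(scenario = c("correct", "non_vertical",
                                         "one_knee", "dark_arms"),
                            n_frames = 60L, seed = 1L, fps = 30,
                            rate_cpm = 110) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  arm_len <- 170
  torso <- 140
  lean_angle <- if (scenario == "non_vertical")
    stats::runif(1, 25, 40) * pi / 180 else 0
  out <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    t <- (i - 1) / fps
    osc <- 14 * (1 - cos(2 * pi * rate_cpm / 60 * t)) / 2
    jit <- function(s = 1.5) stats::rnorm(1, 0, s)
    cf <- function() stats::runif(1, 0.75, 0.95)
    arm_cf <- function() if (scenario == "dark_arms")
      stats::runif(1, 0.05, 0.18) else cf()
    shx <- 330 + jit(); shy <- 200 + osc + jit()
    wrx <- shx + sin(lean_angle) * arm_len + jit()
    wry <- shy + cos(lean_angle) * arm_len + jit()
    elx <- (shx + wrx) / 2 + jit(); ely <- (shy + wry) / 2 + jit()
    hipx <- shx + 80 + jit(); hipy <- shy + torso + jit()
    kny_l <- hipy + 90 + jit(3)
    kny_r <- hipy + 90 + jit(3) -
      if (scenario == "one_knee") 0.4 * torso else 0
    joints <- list(
      nose = c(shx - 30 + jit(), shy - 45 + jit(), cf()),
      l_shoulder = c(shx - 12 + jit(), shy + jit(), arm_cf()),
      r_shoulder = c(shx + 12 + jit(), shy + jit(), arm_cf()),
      l_elbow = c(elx - 10 + jit(), ely + jit(), arm_cf()),
      r_elbow = c(elx + 10 + jit(), ely + jit(), arm_cf()),
      l_wrist = c(wrx - 6 + jit(), wry + jit(), arm_cf()),
      r_wrist = c(wrx + 6 + jit(), wry + jit(), arm_cf()),
      l_hip = c(hipx - 14 + jit(), hipy + jit(), cf()),
      r_hip = c(hipx + 14 + jit(), hipy + jit(), cf()),
      l_knee = c(hipx - 20 + jit(), kny_l, cf()),
      r_knee = c(hipx + 30 + jit(), kny_r, cf()),
      l_ankle = c(hipx - 25 + jit(), kny_l + 70 + jit(), cf()),
      r_ankle = c(hipx + 45 + jit(), kny_r + 60 + jit(), cf()))
    out[[i]] <- keypoint_frame(joints)
  }
  out
}
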