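#' Pinhole camera model
#'
#' Bundles the intrinsic description of the camera used for marker-based
#' depth measurement: physical focal length and pixel pitch (optional),
#' pixel focal lengths \code{fx = f/dx}, \code{fy = f/dy}, the principal
#' point, and the native ("ideal") frame resolution. The focal length in
#' pixels used by the depth mapping, \code{L'}, is the vertical pixel
#' focal length \code{fy}, because compressions displace the marker along
#' the image v-axis.
#'
#' @param fx,fy focal lengths in pixels along u and v. If only \code{fx}
#'   is given, square pixels are assumed (\code{fy = fx}).
#' @param u0,v0 principal point in pixels; defaults to the frame centre.
#' @param ideal_resolution integer vector \code{c(width, height)} of the
#'   native camera frame in pixels.
#' @param f,dx,dy optional physical focal length and pixel pitch (same
#'   length unit); when all three are given they must satisfy
#'   \code{fx = f/dx}, \code{fy = f/dy}.
#' @return An object of class \code{"camera_model"} with fields
#'   \code{fx}, \code{fy}, \code{u0}, \code{v0}, \code{focal_px_L} (the
#'   depth-mapping focal length \code{L'}), \code{ideal_resolution} and
#'   the 3x3 intrinsic matrix \code{K}.
#' @examples
#' cam <- camera_model(fx = 600, ideal_resolution = c(704, 704))
#' cam$K
#' @export
camera_model <- function(fx, fy = fx, u0 = NULL, v0 = NULL,
                         ideal_resolution = c(704, 704),
                         f = NULL, dx = NULL, dy = NULL) {
  if (!is.numeric(fx) || fx <= 0 || !is.numeric(fy) || fy <= 0)
    stop("focal lengths fx, fy must be positive", call. = FALSE)
  ideal_resolution <- as.integer(ideal_resolution)
  if (length(ideal_resolution) != 2L || any(ideal_resolution <= 0L))
    stop("ideal_resolution must be two positive integers (width, height)",
         call. = FALSE)
  if (is.null(u0)) u0 <- ideal_resolution[1] / 2
  if (is.null(v0)) v0 <- ideal_resolution[2] / 2
  if (!is.null(f) && !is.null(dx) && !is.null(dy)) {
    if (abs(f / dx - fx) > 1e-6 * fx || abs(f / dy - fy) > 1e-6 * fy)
      stop("inconsistent physical focal length / pixel pitch: need fx = f/dx, fy = f/dy",
           call. = FALSE)
  }
  K <- matrix(c(fx, 0, u0,
                0, fy, v0,
                0,  0,  1), nrow = 3, byrow = TRUE)
  structure(list(fx = fx, fy = fy, u0 = u0, v0 = v0,
                 focal_px_L = fy,   # L' of the depth mapping
                 f = f, dx = dx, dy = dy,
                 ideal_resolution = ideal_resolution, K = K),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("Pinhole camera model\n")
  cat(sprintf("  fx = %.2f px, fy = %.2f px (L' = %.2f px)\n",
              x$fx, x$fy, x$focal_px_L))
  cat(sprintf("  principal point (%.1f, %.1f) px, ideal resolution %d x %d\n",
              x$u0, x$v0, x$ideal_resolution[1], x$ideal_resolution[2]))
  invisible(x)
}

#' Rigid camera extrinsics
#'
#' A world-to-camera rigid transform: an orthogonal rotation \code{R}
#' with determinant +1 and a translation 3-vector \code{T}.
#'
#' @param R 3x3 rotation matrix.
#' @param T length-3 translation vector.
#' @return An object of class \code{"rigid_transform"}.
#' @export
rigid_transform <- function(R = diag(3), T = c(0, 0, 0)) {
  R <- as.matrix(R); T <- as.numeric(T)
  if (!all(dim(R) == c(3, 3)) || length(T) != 3)
    stop("R must be 3x3 and T length 3", call. = FALSE)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop("invalid transform: R is not orthogonal (RtR != I within 1e-9)",
         call. = FALSE)
  if (abs(det(R) - 1) > 1e-9)
    stop("invalid transform: det(R) must be +1 (proper rotation)",
         call. = FALSE)
  structure(list(R = R, T = T), class = "rigid_transform")
}

#' Window-to-ideal resolution mapping
#'
#' Detection runs at a processing-window resolution; the depth mapping is
#' defined at the camera's native resolution. This object carries both and
#' provides the linear conversion of vertical pixel displacements.
#'
#' @param window_resolution,ideal_resolution integer \code{c(width, height)}.
#' @return An object of class \code{"resolution_map"}.
#' @export
resolution_map <- function(window_resolution, ideal_resolution) {
  w <- as.integer(window_resolution); i <- as.integer(ideal_resolution)
  if (length(w) != 2L || length(i) != 2L || any(c(w, i) <= 0L))
    stop("resolutions must be positive integer pairs (width, height)",
         call. = FALSE)
  structure(list(window_resolution = w, ideal_resolution = i),
            class = "resolution_map")
}

#' Transform a world point into camera coordinates
#'
#' @param pw length-3 world point.
#' @param ext a [rigid_transform()].
#' @return Length-3 camera-frame point \code{R \%*\% pw + T}.
#' @export
world_to_camera <- function(pw, ext) {
  stopifnot(inherits(ext, "rigid_transform"), length(pw) == 3)
  as.numeric(ext$R %*% as.numeric(pw) + ext$T)
}

#' Project a world point to pixel coordinates
#'
#' Applies the rigid transform, perspective division by the camera-frame
#' depth, and the intrinsic matrix, i.e. the composed mapping
#' \code{zc (u, v, 1)' = K [R | T] (xw, yw, zw, 1)'}.
#'
#' @param pw length-3 world point.
#' @param ext a [rigid_transform()].
#' @param cam a [camera_model()].
#' @return Length-2 pixel point \code{c(u, v)}.
#' @export
project_point <- function(pw, ext, cam) {
  stopifnot(inherits(cam, "camera_model"))
  pc <- world_to_camera(pw, ext)
  if (pc[3] <= 0)
    stop("point is behind the camera (camera-frame z <= 0)", call. = FALSE)
  uvw <- cam$K %*% (pc / pc[3])
  as.numeric(uvw[1:2])
}

#' Convert a window-resolution displacement to ideal resolution
#'
#' Vertical box displacements are measured at the processing-window
#' resolution (\code{B0}) and rescaled to the native camera resolution
#' (\code{Bp}) by the ratio of vertical resolutions.
#'
#' @param B0 vertical displacement in window pixels (non-negative).
#' @param rmap a [resolution_map()].
#' @return Displacement \code{Bp} in ideal-resolution pixels.
#' @export
to_ideal_resolution <- function(B0, rmap) {
  stopifnot(inherits(rmap, "resolution_map"))
  if (any(B0 < 0)) stop("B0 must be non-negative", call. = FALSE)
  B0 * rmap$ideal_resolution[2] / rmap$window_resolution[2]
}

#' Estimate camera-to-marker range from the marker's apparent length
#'
#' The marker wristband has a known physical length; by similar triangles
#' its apparent pixel length \code{Ap} at the ideal resolution determines
#' the horizontal camera-marker distance
#' \code{L = physical_length * L' / Ap}.
#'
#' @param Ap apparent marker length in ideal-resolution pixels.
#' @param cam a [camera_model()].
#' @param physical_length marker true length in cm (default 33.40).
#' @return Range \code{L} in cm.
#' @export
estimate_range <- function(Ap, cam, physical_length = 33.40) {
  stopifnot(inherits(cam, "camera_model"))
  if (any(!is.finite(Ap)) || any(Ap <= 0))
    stop("degenerate observation: apparent marker length Ap must be > 0",
         call. = FALSE)
  if (physical_length <= 0)
    stop("marker physical length must be > 0", call. = FALSE)
  physical_length * cam$focal_px_L / Ap
}

#' Map a pixel displacement to real compression depth
#'
#' At range \code{L}, a vertical pixel displacement \code{Bp} (ideal
#' resolution) corresponds to a real-world depth
#' \code{H = Bp * L / L'} where \code{L'} is the focal length in pixels.
#'
#' @param Bp vertical displacement in ideal-resolution pixels.
#' @param L camera-to-marker range in cm.
#' @param cam a [camera_model()].
#' @return Depth \code{H} in cm.
#' @export
displacement_to_depth <- function(Bp, L, cam) {
  stopifnot(inherits(cam, "camera_model"))
  if (any(L <= 0)) stop("range L must be > 0", call. = FALSE)
  if (any(Bp < 0)) stop("Bp must be non-negative", call. = FALSE)
  Bp * L / cam$focal_px_L
}

#' Read camera calibration from a YAML or JSON file
#'
#' Expected keys: \code{focal_px} (scalar or \code{[fx, fy]}),
#' \code{principal_point} (\code{[u0, v0]}, optional),
#' \code{ideal_resolution}, \code{window_resolution},
#' \code{marker_length_cm}, \code{marker_width_cm}.
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return A list with elements \code{cam} ([camera_model()]),
#'   \code{rmap} ([resolution_map()]), \code{marker_length_cm},
#'   \code{marker_width_cm}.
#' @export
read_camera_config <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path,
                               call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path)
  req <- c("focal_px", "ideal_resolution", "window_resolution",
           "marker_length_cm")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("calibration file missing required keys: ",
         paste(miss, collapse = ", "), call. = FALSE)
  fpx <- as.numeric(cfg$focal_px)
  pp <- cfg$principal_point
  cam <- camera_model(fx = fpx[1], fy = if (length(fpx) > 1) fpx[2] else fpx[1],
                      u0 = if (!is.null(pp)) pp[1] else NULL,
                      v0 = if (!is.null(pp)) pp[2] else NULL,
                      ideal_resolution = cfg$ideal_resolution)
  rmap <- resolution_map(cfg$window_resolution, cfg$ideal_resolution)
  list(cam = cam, rmap = rmap,
       marker_length_cm = cfg$marker_length_cm,
       marker_width_cm = if (!is.null(cfg$marker_width_cm))
         cfg$marker_width_cm else 3.80)
}

# small rotation helpers used by tests and the scene generator
#' Rotation matrix about the z axis
#' @param theta angle in radians
#' @return 3x3 rotation matrix
#' @export
rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta),  cos(theta), 0,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

#' Rotation matrix about the x axis
#' @param theta angle in radians
#' @return 3x3 rotation matrix
#' @export
rot_x <- function(theta) {
  matrix(c(1, 0, 0,
           0, cos(theta), -sin(theta),
           0, sin(theta),  cos(theta)), nrow = 3, byrow = TRUE)
}
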