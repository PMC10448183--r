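#' Eye aspect ratio
#'
#' `EAR = (||p2 - p6|| + ||p3 - p5||) / (2 ||p1 - p4||)` on the six eye
#' landmarks ordered outer corner, upper lid (x2), inner corner, lower lid
#' (x2) -- i.e. points 36-41 (right eye) or 42-47 (left eye). Dimensionless,
#' invariant under similarity transforms; drops toward 0 during blinks.
#'
#' @param eye_points 6 x 2 numeric matrix, rows p1..p6, columns x, y.
#' @return the ratio, or `NA` when the horizontal axis `||p1 - p4||` is
#'   degenerate.
#' @export
eye_aspect_ratio <- function(eye_points) {
  stopifnot(is.matrix(eye_points), nrow(eye_points) == 6L)
  d <- function(i, j) sqrt(sum((eye_points[i, ] - eye_points[j, ])^2))
  h <- d(1, 4)
  if (h == 0) return(NA_real_)
  (d(2, 6) + d(3, 5)) / (2 * h)
}

#' Mouth aspect ratio
#'
#' Defined on the eight inner-lip landmarks 60-67 by direct analogy with the
#' eye aspect ratio: three vertical inner-lip distances over twice the
#' mouth-corner distance,
#' `MAR = (||p61 - p67|| + ||p62 - p66|| + ||p63 - p65||) / (2 ||p60 - p64||)`.
#' Rises with mouth opening; similarity invariant.
#'
#' @param inner_mouth_points 8 x 2 numeric matrix, rows in index order
#'   60..67.
#' @return the ratio, or `NA` when the corner distance is degenerate.
#' @export
mouth_aspect_ratio <- function(inner_mouth_points) {
  stopifnot(is.matrix(inner_mouth_points), nrow(inner_mouth_points) == 8L)
  p <- inner_mouth_points
  d <- function(i, j) sqrt(sum((p[i, ] - p[j, ])^2))
  # rows 1..8 are points 60..67
  h <- d(1, 5)
  if (h == 0) return(NA_real_)
  (d(2, 8) + d(3, 7) + d(4, 6)) / (2 * h)
}

# vectorised across frames: distance between landmark i and j per frame
.frame_dist <- function(coords, i, j) {
  sqrt((coords[, .col_x(i)] - coords[, .col_x(j)])^2 +
         (coords[, .col_y(i)] - coords[, .col_y(j)])^2)
}

.ear_series <- function(coords, pts) {
  h <- .frame_dist(coords, pts[1], pts[4])
  v <- .frame_dist(coords, pts[2], pts[6]) + .frame_dist(coords, pts[3], pts[5])
  out <- v / (2 * h)
  out[h == 0] <- NA_real_
  out
}

.mar_series <- function(coords) {
  h <- .frame_dist(coords, 60, 64)
  v <- .frame_dist(coords, 61, 67) + .frame_dist(coords, 62, 66) +
    .frame_dist(coords, 63, 65)
  out <- v / (2 * h)
  out[h == 0] <- NA_real_
  out
}

#' Head-pose Euler angles per frame
#'
#' Rigid head pose from six 2-D/3-D correspondences (points 33, 27, 36, 45,
#' 48, 54 against the canonical template, [face_template_3d()]) under a
#' pinhole camera with focal length = image width and principal point at the
#' image centre. The rotation is decomposed as
#' `R = Rz(roll) Ry(yaw) Rx(pitch)` and reported in degrees in
#' `(-180, 180]`. Solved per frame by damped Gauss-Newton, warm-started from
#' the previous frame; frames where the fit fails are `NA`.
#'
#' @param trajectory a [landmark_trajectory()] with `image_size` set.
#' @return data.frame with columns `pitch`, `yaw`, `roll` (degrees), one row
#'   per frame.
#' @export
head_euler_angles <- function(trajectory) {
  validate_trajectory(trajectory)
  if (is.null(trajectory$image_size))
    stop("head-pose estimation needs image_size on the trajectory")
  tmpl <- face_template_3d()
  model <- tmpl[as.character(.pose_points), , drop = FALSE]
  co <- trajectory$coords
  pts <- cbind(co[, .col_x(.pose_points), drop = FALSE],
               co[, .col_y(.pose_points), drop = FALSE])
  f <- trajectory$image_size[1]
  cx <- trajectory$image_size[1] / 2
  cy <- trajectory$image_size[2] / 2
  # scale init: observed spread vs template spread on the first frame
  span_obs <- max(pts[1, 1:6]) - min(pts[1, 1:6])
  span_mod <- max(model[, 1]) - min(model[, 1])
  tz0 <- if (span_obs > 0) f * span_mod / span_obs else f
  tx0 <- (mean(pts[1, 1:6]) - cx) * tz0 / f - mean(model[, 1])
  ty0 <- (mean(pts[1, 7:12]) - cy) * tz0 / f - mean(model[, 2])
  fit <- pose_fit_frames(pts, model, f, cx, cy,
                         c(0, 0, 0, tx0, ty0, tz0))
  out <- data.frame(pitch = fit[, 1], yaw = fit[, 2], roll = fit[, 3])
  out[!is.finite(fit[, 7]) | fit[, 7] > 0.05 * f, ] <- NA_real_
  out
}

#' Nose-anchored point-angle series
#'
#' Per frame, the angle of the vector from the anchor landmark (default 33,
#' the subnasale) to a target landmark:
#' `atan2(y_target - y_anchor, x_target - x_anchor)` in degrees, image
#' convention (y down, so a target below the anchor is at +90).
#'
#' @param trajectory a [landmark_trajectory()].
#' @param target target landmark index in 17..67, different from `anchor`.
#' @param anchor anchor landmark index (default 33).
#' @return numeric vector of per-frame angles in `(-180, 180]`; `NA` where
#'   anchor and target coincide.
#' @export
point_angle_series <- function(trajectory, target, anchor = 33L) {
  validate_trajectory(trajectory)
  stopifnot(anchor %in% .lm_points, target %in% .lm_points, anchor != target)
  .angle_series(trajectory$coords, target, anchor)
}

.angle_series <- function(coords, target, anchor) {
  dx <- coords[, .col_x(target)] - coords[, .col_x(anchor)]
  dy <- coords[, .col_y(target)] - coords[, .col_y(anchor)]
  out <- atan2(dy, dx) * 180 / pi
  out[dx == 0 & dy == 0] <- NA_real_
  out
}

#' Unwrap an angle series given in degrees
#'
#' Removes artificial +/-360 jumps where a series crosses the +/-180 branch
#' cut, so that dispersion summaries reflect true angular movement. Missing
#' values are passed through.
#'
#' @param x numeric vector of angles in degrees.
#' @return unwrapped series (no longer confined to `(-180, 180]`).
#' @export
unwrap_degrees <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) < 2L) return(x)
  v <- x[ok]
  d <- diff(v)
  adj <- cumsum(ifelse(d > 180, -360, ifelse(d < -180, 360, 0)))
  x[ok] <- c(v[1], v[-1] + adj)
  x
}

#' Per-frame scalar signals of a trajectory
#'
#' Computes every per-frame signal the feature set summarises: the eye
#' aspect ratio (mean of left eye 42-47 and right eye 36-41, per-eye series
#' retained), the mouth aspect ratio on the inner lips 60-67, head-pose
#' Euler angles (when `image_size` is available), and the 50 nose-anchored
#' point-angle series. Undefined values are recorded as `NA`, never dropped,
#' so every series has one value per frame.
#'
#' @param trajectory a [landmark_trajectory()].
#' @return object of class `frame_signals`: a list with elements `ear`,
#'   `ear_left`, `ear_right`, `mar` (numeric per-frame vectors), `euler`
#'   (data.frame pitch/yaw/roll or `NULL` without `image_size`), `angles`
#'   (matrix, one column per non-anchor landmark, named `angle_33_to_<j>`),
#'   plus the raw `coords`, `frames` and `fps` pass-through.
#' @export
per_frame_signals <- function(trajectory) {
  validate_trajectory(trajectory)
  co <- trajectory$coords
  ear_r <- .ear_series(co, 36:41)
  ear_l <- .ear_series(co, 42:47)
  targets <- setdiff(.lm_points, 33L)
  ang <- vapply(targets, function(j) .angle_series(co, j, 33L),
                numeric(nrow(co)))
  if (nrow(co) == 1L) ang <- matrix(ang, nrow = 1L)
  colnames(ang) <- paste0("angle_33_to_", targets)
  structure(
    list(ear = rowMeans(cbind(ear_l, ear_r)),
         ear_left = ear_l, ear_right = ear_r,
         mar = .mar_series(co),
         euler = if (!is.null(trajectory$image_size))
           head_euler_angles(trajectory),
         angles = ang,
         coords = co,
         frames = trajectory$frames,
         fps = trajectory$fps),
    class = "frame_signals")
}

#' @export
print.frame_signals <- function(x, ...) {
  cat(sprintf("frame_signals: %d frames; ear/mar/%s%d point-angle series\n",
              length(x$ear), if (is.null(x$euler)) "" else "euler/",
              ncol(x$angles)))
  invisible(x)
}
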