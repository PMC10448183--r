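#' Canonical 3-D face template
#'
#' A synthetic neutral-face template giving 3-D coordinates (template units,
#' roughly millimetres) for the 51 landmarks 17-67, in camera-aligned axes:
#' x right, y down (image convention), z away from the camera. It anchors
#' head-pose estimation (six correspondence points) and the synthetic cohort
#' generator (all 51 points). Shipped as
#' `inst/extdata/face_template_3d_synthetic.csv`.
#'
#' @return numeric 51 x 3 matrix with rownames `"17".."67"` and columns
#'   `x, y, z`.
#' @export
face_template_3d <- function() {
  path <- system.file("extdata", "face_template_3d_synthetic.csv",
                      package = "facekin", mustWork = TRUE)
  df <- utils::read.csv(path)
  m <- as.matrix(df[, c("x", "y", "z")])
  rownames(m) <- as.character(df$point)
  m
}

# the six pose correspondence points: subnasale, nose bridge, outer eye
# corners, mouth corners
.pose_points <- c(33L, 27L, 36L, 45L, 48L, 54L)

#' Pinhole camera projection of 3-D points
#'
#' Camera model used throughout: focal length equal to the image width,
#' principal point at the image centre, x right, y down.
#'
#' @param pts n x 3 matrix of camera-frame points (z > 0, away from camera).
#' @param image_size `c(width, height)` pixels.
#' @return n x 2 matrix of pixel coordinates.
#' @export
project_points <- function(pts, image_size) {
  f <- image_size[1]
  cx <- image_size[1] / 2
  cy <- image_size[2] / 2
  cbind(cx + f * pts[, 1] / pts[, 3],
        cy + f * pts[, 2] / pts[, 3])
}

#' Euler-angle rotation matrix
#'
#' `R = Rz(roll) %*% Ry(yaw) %*% Rx(pitch)`, angles in degrees.
#'
#' @param pitch,yaw,roll rotation angles in degrees about the x, y, z camera
#'   axes respectively.
#' @return 3 x 3 rotation matrix.
#' @export
euler_rotation <- function(pitch, yaw, roll) {
  p <- pitch * pi / 180; y <- yaw * pi / 180; r <- roll * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(p), -sin(p)), c(0, sin(p), cos(p)))
  Ry <- rbind(c(cos(y), 0, sin(y)), c(0, 1, 0), c(-sin(y), 0, cos(y)))
  Rz <- rbind(c(cos(r), -sin(r), 0), c(sin(r), cos(r), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}
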