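# Test fixtures, all generated in code.

coord_names <- c(paste0("x_", 17:67), paste0("y_", 17:67))

# arbitrary finite coordinates -- enough for I/O and bookkeeping tests
random_trajectory <- function(n_frames = 5, seed = 1, fps = 10,
                              image_size = c(1280, 720)) {
  set.seed(seed)
  co <- matrix(runif(n_frames * 102, 100, 900), n_frames,
               dimnames = list(NULL, coord_names))
  landmark_trajectory(paste0("rt", seed), fps, seq_len(n_frames) - 1L, co,
                      image_size = image_size)
}

# independent forward model for pose tests: rotate the template by known
# Euler angles (explicit ZYX matrices written out here, not the package's
# euler_rotation), translate, project through the pinhole camera
project_pose <- function(tmpl, pitch, yaw, roll, tvec = c(0, 0, 600),
                         image_size = c(1280, 720)) {
  d <- pi / 180
  p <- pitch * d; y <- yaw * d; r <- roll * d
  Rx <- matrix(c(1, 0, 0, 0, cos(p), sin(p), 0, -sin(p), cos(p)), 3)
  Ry <- matrix(c(cos(y), 0, -sin(y), 0, 1, 0, sin(y), 0, cos(y)), 3)
  Rz <- matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3)
  R <- Rz %*% Ry %*% Rx
  cen <- colMeans(tmpl)
  cam <- sweep(t(R %*% t(sweep(tmpl, 2, cen))), 2, tvec, "+")
  f <- image_size[1]
  cbind(image_size[1] / 2 + f * cam[, 1] / cam[, 3],
        image_size[2] / 2 + f * cam[, 2] / cam[, 3])
}

# trajectory whose frames are projections of the template under given poses
posed_trajectory <- function(poses, image_size = c(1280, 720), fps = 10) {
  tmpl <- face_template_3d()
  co <- t(vapply(seq_len(nrow(poses)), function(i) {
    uv <- project_pose(tmpl, poses[i, 1], poses[i, 2], poses[i, 3],
                       image_size = image_size)
    c(uv[, 1], uv[, 2])
  }, numeric(102)))
  colnames(co) <- coord_names
  landmark_trajectory("posed", fps, seq_len(nrow(poses)) - 1L, co,
                      image_size = image_size)
}

# a small feature_table built directly (no trajectories): p noise features,
# the first `n_informative` of which separate the groups by `delta`
fake_feature_table <- function(n_arms = 10, n_controls = 12, p = 20,
                               n_informative = 0, delta = 2, seed = 1) {
  set.seed(seed)
  n <- n_arms + n_controls
  group <- factor(rep(c("ARMS", "CONTROL"), c(n_arms, n_controls)),
                  levels = c("CONTROL", "ARMS"))
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("feat_", seq_len(p))
  if (n_informative > 0)
    X[group == "ARMS", seq_len(n_informative)] <-
      X[group == "ARMS", seq_len(n_informative)] + delta
  ids <- sprintf("F%03d", seq_len(n))
  rownames(X) <- ids
  manifest <- data.frame(name = colnames(X), signal = colnames(X),
                         statistic = "IQR")
  class(manifest) <- c("feature_manifest", "data.frame")
  ear <- lapply(seq_len(n), function(i) runif(50, 0.2, 0.4))
  structure(list(participants = ids, group = group, X = X,
                 manifest = manifest, ear_series = setNames(ear, ids),
                 labels = data.frame(participant_id = ids, group = group)),
            class = "feature_table")
}

# fast spec for pipeline-level tests
small_cohort_spec <- function(...) {
  cohort_spec(n_arms = 8, n_controls = 8, frames = 300, seed = 7, ...)
}
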