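test_that("eye and mouth aspect ratios match hand-computed values", {
  ep <- rbind(c(0, 0), c(1, 1), c(3, 1), c(4, 0), c(3, -1), c(1, -1))
  expect_equal(eye_aspect_ratio(ep), 0.5)
  closed <- ep
  closed[c(2, 3), ] <- closed[c(6, 5), ]   # lids meet
  expect_equal(eye_aspect_ratio(closed), 0)
  degen <- ep
  degen[4, ] <- degen[1, ]                 # corners coincide
  expect_true(is.na(eye_aspect_ratio(degen)))

  mp <- rbind(c(0, 0), c(1, 1), c(2, 1), c(3, 1),
              c(4, 0), c(3, -1), c(2, -1), c(1, -1))
  expect_equal(mouth_aspect_ratio(mp), (2 + 2 + 2) / (2 * 4))
  shut <- mp
  shut[c(2, 3, 4), ] <- shut[c(8, 7, 6), ]
  expect_equal(mouth_aspect_ratio(shut), 0)
})

test_that("aspect ratios are invariant under similarity transforms", {
  set.seed(42)
  ep <- rbind(c(0, 0), c(1, 1.2), c(3, 0.8), c(4.2, 0), c(3, -1), c(1, -0.9))
  mp <- rbind(c(0, 0), c(1, 1), c(2, 1.4), c(3, 1),
              c(4, 0.2), c(3, -1), c(2, -0.8), c(1, -1))
  for (i in 1:25) {
    th <- runif(1, -pi, pi); s <- runif(1, 0.2, 8); tr <- runif(2, -50, 50)
    Rm <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    f <- function(p) sweep(p %*% t(Rm), 2, tr, "+")
    expect_equal(eye_aspect_ratio(f(ep)), eye_aspect_ratio(ep))
    expect_equal(mouth_aspect_ratio(f(mp)), mouth_aspect_ratio(mp))
  }
})

test_that("point-angle series follow the image-axis convention", {
  co <- matrix(500, 2, 102, dimnames = list(NULL, coord_names))
  co[, "x_30"] <- co[, "x_33"] + 1      # one pixel to the right
  tr <- landmark_trajectory("a", 10, 0:1, co)
  expect_equal(point_angle_series(tr, 30), c(0, 0))
  co[, "x_30"] <- co[, "x_33"]
  co[, "y_30"] <- co[, "y_33"] + 5      # below: larger y
  expect_equal(point_angle_series(landmark_trajectory("a", 10, 0:1, co), 30),
               c(90, 90))
  co[, "y_30"] <- co[, "y_33"] - 5      # above
  expect_equal(point_angle_series(landmark_trajectory("a", 10, 0:1, co), 30),
               c(-90, -90))
  co[, "y_30"] <- co[, "y_33"]          # coincident -> undefined
  expect_true(all(is.na(
    point_angle_series(landmark_trajectory("a", 10, 0:1, co), 30))))
})

test_that("in-plane rotation shifts angle series by exactly theta", {
  tr <- random_trajectory(n_frames = 4, seed = 9)
  base <- point_angle_series(tr, 54)
  th <- 37
  d <- th * pi / 180
  Rm <- matrix(c(cos(d), sin(d), -sin(d), cos(d)), 2)
  xs <- tr$coords[, 1:51]; ys <- tr$coords[, 52:102]
  rot <- cbind(xs * Rm[1, 1] + ys * Rm[1, 2], xs * Rm[2, 1] + ys * Rm[2, 2])
  colnames(rot) <- coord_names
  rtr <- landmark_trajectory("r", 10, tr$frames, rot)
  shift <- (point_angle_series(rtr, 54) - base) %% 360
  expect_equal(shift, rep(th, 4), tolerance = 1e-10)
})

test_that("head pose recovers known synthetic orientations", {
  # identity pose
  tr0 <- posed_trajectory(rbind(c(0, 0, 0), c(0, 0, 0)))
  e0 <- head_euler_angles(tr0)
  expect_lt(max(abs(as.matrix(e0))), 1e-3)
  # known rotation, recovered within half a degree
  tr1 <- posed_trajectory(rbind(c(10, -15, 5), c(10, -15, 5)))
  e1 <- head_euler_angles(tr1)
  expect_lt(max(abs(e1[1, ] - c(10, -15, 5))), 0.5)
  # a short sweep of poses, each within tolerance
  poses <- cbind(seq(-12, 12, length.out = 7), seq(18, -18, length.out = 7),
                 seq(-8, 8, length.out = 7))
  es <- head_euler_angles(posed_trajectory(poses))
  expect_lt(max(abs(as.matrix(es) - poses)), 0.5)
})

test_that("in-plane image rotation adds to roll and leaves pitch/yaw", {
  pose <- c(4, -6, 2)
  tr <- posed_trajectory(rbind(pose, pose))
  th <- 9
  d <- th * pi / 180
  img <- tr$image_size
  cx <- img[1] / 2; cy <- img[2] / 2
  xs <- tr$coords[, 1:51] - cx; ys <- tr$coords[, 52:102] - cy
  # rotate the image by theta about the principal point (image axes, y down)
  rot <- cbind(cx + xs * cos(d) - ys * sin(d), cy + xs * sin(d) + ys * cos(d))
  colnames(rot) <- coord_names
  er <- head_euler_angles(landmark_trajectory("r", 10, tr$frames, rot,
                                              image_size = img))
  e0 <- head_euler_angles(tr)
  expect_equal(er$roll[1] - e0$roll[1], th, tolerance = 0.2)
  expect_lt(abs(er$pitch[1] - e0$pitch[1]), 0.5)
  expect_lt(abs(er$yaw[1] - e0$yaw[1]), 0.5)
})

test_that("unwrap_degrees removes branch-cut jumps only", {
  x <- c(170, 178, -179, -172, -166)
  u <- unwrap_degrees(x)
  expect_equal(u, c(170, 178, 181, 188, 194))
  expect_equal(diff(u), diff(x) %% 360 - ifelse(diff(x) %% 360 > 180, 360, 0))
  smooth <- c(-20, -10, 5, 20)
  expect_equal(unwrap_degrees(smooth), smooth)
  with_na <- c(179, NA, -179)
  expect_equal(unwrap_degrees(with_na), c(179, NA, 181))
})

test_that("per_frame_signals has one value per frame and keeps missingness", {
  tr <- generate_trajectory("CONTROL", small_cohort_spec(), 3, "s1")
  sig <- per_frame_signals(tr)
  n <- length(tr$frames)
  expect_length(sig$ear, n)
  expect_length(sig$mar, n)
  expect_equal(nrow(sig$euler), n)
  expect_equal(dim(sig$angles), c(n, 50))
  expect_false(anyNA(sig$ear))

  # degenerate eye on one frame -> that frame's ear missing, others intact
  co <- tr$coords
  eye <- c(36:41)
  co[4, paste0("x_", eye)] <- 300
  co[4, paste0("y_", eye)] <- 300
  sig2 <- per_frame_signals(landmark_trajectory("d", tr$fps, tr$frames, co,
                                                image_size = tr$image_size))
  expect_true(is.na(sig2$ear[4]))
  expect_false(anyNA(sig2$ear[-4]))

  # constant trajectory -> constant signals
  cs <- cohort_spec(n_arms = 2, n_controls = 2, frames = 10, jitter_sd = 0,
                    blink_rate = 0, smile_rate = 0, brow_rate = 0,
                    speech_amp = 0, motion_sd = c(0, 0, 0))
  tc <- generate_trajectory("CONTROL", cs, 1, "const")
  sc <- per_frame_signals(tc)
  expect_equal(sd(sc$ear), 0)
  expect_equal(sd(sc$mar), 0)
  expect_lt(max(apply(sc$angles, 2, sd)), 1e-12)
})
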