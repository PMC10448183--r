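test_that("robust dispersion matches hand-computed quartiles and MAD", {
  expect_equal(robust_dispersion(rep(3.2, 10)), c(iqr = 0, mad = 0))
  expect_equal(robust_dispersion(1:5), c(iqr = 2, mad = 1))
  expect_equal(robust_dispersion(c(NA, 1:5, NA)), c(iqr = 2, mad = 1))
  expect_true(all(is.na(robust_dispersion(c(NA, 7)))))
  # robustness: one extreme outlier moves the MAD far less than the SD
  set.seed(1)
  x <- rnorm(100)
  x2 <- c(x, 1000)
  mad_shift <- abs(robust_dispersion(x2)["mad"] - robust_dispersion(x)["mad"])
  sd_shift <- abs(sd(x2) - sd(x))
  expect_lt(mad_shift, sd_shift / 100)
})

test_that("outlier fraction applies Tukey fences", {
  expect_equal(outlier_fraction(rep(5, 20)), 0)
  expect_equal(outlier_fraction(c(rep(0, 99), 1000)), 0.01)
  expect_true(is.na(outlier_fraction(c(1, 2, 3))))
  # normal-theory Tukey rate: P(|Z| > 2.698) ~ 0.698%
  set.seed(7)
  fr <- outlier_fraction(rnorm(1e5))
  expect_equal(fr, 2 * pnorm(-2.697959), tolerance = 0.25)
})

test_that("PACF base case and AR(1) recovery", {
  set.seed(11)
  x <- cumsum(rnorm(300))
  # Durbin-Levinson base case: lag-1 PACF equals lag-1 sample ACF
  a1 <- stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(pacf_coefficient(x, 1), a1, tolerance = 1e-12)
  # AR(1): PACF(1) ~ phi, PACF(2) ~ 0
  phi <- 0.6
  e <- rnorm(5000)
  y <- as.numeric(stats::filter(e, phi, method = "recursive"))
  expect_equal(pacf_coefficient(y, 1), phi, tolerance = 0.05)
  expect_lt(abs(pacf_coefficient(y, 2)), 0.05)
  # white-noise null stays inside the 3/sqrt(n) band
  set.seed(12)
  w <- rnorm(5000)
  expect_lt(abs(pacf_coefficient(w, 1)), 3 / sqrt(5000))
  expect_true(is.na(pacf_coefficient(rep(2, 50), 1)))
})

test_that("Spearman rho agrees with a brute-force rank-then-Pearson oracle", {
  expect_equal(spearman_pair(1:10, 1:10), 1)
  expect_equal(spearman_pair(1:10, 10:1), -1)
  # ties, n = 6: explicit average ranks + Pearson product-moment formula
  a <- c(1, 2, 2, 4, 5, 5)
  b <- c(3, 3, 1, 6, 6, 2)
  ra <- rank(a); rb <- rank(b)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(spearman_pair(a, b), oracle)
  expect_true(is.na(spearman_pair(c(1, 2), c(3, 4))))
  expect_true(is.na(spearman_pair(rep(1, 10), 1:10)))
  # pairwise-complete filtering
  expect_equal(spearman_pair(c(1:5, NA), c(2:6, 100)), 1)
})

test_that("below-reference percentage counts strict exceedances", {
  expect_equal(below_reference_fraction(5:10, 2), 0)
  x <- c(1, 3, 5, 7, 9, 11, 13)          # odd length, all distinct
  expect_equal(below_reference_fraction(x, median(x)), 100 * 3 / 7)
  set.seed(3)
  u <- runif(20000)
  q1 <- quantile(u, 0.25, names = FALSE)
  expect_equal(below_reference_fraction(u, q1), 25, tolerance = 0.05)
})

test_that("default manifest holds exactly 649 uniquely named features", {
  man <- default_feature_manifest()
  expect_equal(nrow(man), 649L)
  expect_false(anyDuplicated(man$name) > 0)
  expect_true(all(c("spearman_48_54_x", "spearman_48_54_y", "face_57_x_pacf",
                    "ear_below_q1_pct", "face_33_angle_face30_mad",
                    "face_19_x_outliers", "spearman_40_47_y") %in% man$name))
  expect_equal(nrow(symmetric_pairs()), 21L)
  # manifest round-trips as plain CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_manifest(man, path)
  expect_equal(read_feature_manifest(path)$name, man$name)
})

test_that("feature vectors are complete, deterministic, and invariant", {
  tr <- generate_trajectory("ARMS", small_cohort_spec(), 21, "p1")
  fv <- build_feature_vector(tr)
  expect_length(fv, 649L)
  expect_identical(names(fv), default_feature_manifest()$name)
  expect_identical(fv, build_feature_vector(tr))
  man <- default_feature_manifest()
  disp <- man$statistic %in% c("IQR", "MAD", "OUTLIER_FRACTION", "SPEED_MAD")
  expect_true(all(fv[disp] >= 0, na.rm = TRUE))
  sp <- man$statistic == "SPEARMAN"
  expect_true(all(abs(fv[sp]) <= 1, na.rm = TRUE))
  expect_true(fv["ear_below_q1_pct"] >= 0 && fv["ear_below_q1_pct"] <= 100)

  # global translation: similarity-invariant features unchanged, coordinate
  # dispersion unchanged
  co <- tr$coords + 37.5
  fv2 <- build_feature_vector(
    landmark_trajectory("p2", tr$fps, tr$frames, co, tr$image_size))
  keep <- man$statistic %in% c("IQR", "MAD", "SPEARMAN") |
    grepl("^(ear|mar)_", man$name) | grepl("angle", man$name)
  expect_equal(fv2[keep & !grepl("^euler", man$name)],
               fv[keep & !grepl("^euler", man$name)], tolerance = 1e-8)
})

test_that("a static trajectory yields zero dispersion and undefined rank stats", {
  cs <- cohort_spec(n_arms = 2, n_controls = 2, frames = 20, jitter_sd = 0,
                    blink_rate = 0, smile_rate = 0, brow_rate = 0,
                    speech_amp = 0, motion_sd = c(0, 0, 0))
  fv <- build_feature_vector(generate_trajectory("CONTROL", cs, 2, "st"))
  man <- default_feature_manifest()
  disp <- man$statistic %in% c("IQR", "MAD", "OUTLIER_FRACTION", "SPEED_MAD")
  expect_true(all(abs(fv[disp]) < 1e-9, na.rm = TRUE))
  expect_true(all(is.na(fv[man$statistic == "SPEARMAN"])))
  expect_true(all(is.na(fv[man$statistic == "PACF1"])))
})

test_that("feature tables align to the manifest and guard against leakage", {
  spec <- cohort_spec(n_arms = 2, n_controls = 2, frames = 120, seed = 5)
  cohort <- generate_cohort(spec)
  ft <- build_feature_table(cohort$trajectories, cohort$labels)
  expect_equal(dim(ft$X), c(4L, 649L))
  expect_identical(colnames(ft$X), default_feature_manifest()$name)
  expect_identical(ft$participants, cohort$labels$participant_id)

  dup <- cohort$trajectories
  names(dup)[2] <- names(dup)[1]
  dup[[2]]$participant_id <- dup[[1]]$participant_id
  expect_error(build_feature_table(dup, cohort$labels), "duplicated")

  # training-only references: mutating rows outside the training set never
  # changes the training rows' imputed matrix or the medians
  ft2 <- ft
  ft2$X[4, ] <- ft2$X[4, ] + 1e6
  ft2$ear_series[[4]] <- ft2$ear_series[[4]] * 10
  train_idx <- 1:3
  a <- facekin:::.apply_split_references(ft, train_idx)
  b <- facekin:::.apply_split_references(ft2, train_idx)
  expect_identical(a$X[train_idx, ], b$X[train_idx, ])
  expect_identical(a$medians, b$medians)
  expect_identical(a$ear_q1, b$ear_q1)
})
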