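#' Synthetic cohort specification
#'
#' Parameters of the two-group synthetic landmark cohort. The generator
#' emulates the published study conditions: 58 at-risk (ARMS) and 70
#' control participants, 5-minute recordings (3000 frames at 10 fps), with
#' the ARMS group showing blunted expressivity -- expression-event
#' amplitudes scaled by `expressivity_attenuation` and head-motion
#' variability scaled by `motion_sd_ratio`. Controls always have both
#' factors at 1; setting both parameters to 1 yields an exchangeable null
#' cohort.
#'
#' @param n_arms,n_controls group sizes (defaults 58 / 70).
#' @param frames frames per recording (default 3000).
#' @param fps frames per second (default 10).
#' @param expressivity_attenuation multiplier in (0, 1] on ARMS expression
#'   amplitudes (default 0.6).
#' @param motion_sd_ratio multiplier on ARMS head-motion standard
#'   deviations (default 0.7).
#' @param blink_rate blinks per minute, both groups (default 15).
#' @param smile_rate,brow_rate expression events per minute (defaults 4 and
#'   6).
#' @param speech_amp amplitude (template mm) of the continuous
#'   mouth-opening process (default 2.5).
#' @param motion_sd control-group stationary SDs in degrees of the AR(1)
#'   pitch/yaw/roll processes (default `c(3, 4, 2)`).
#' @param motion_phi AR(1) coefficient of the head-motion processes
#'   (default 0.95), keeping lag-1 partial autocorrelations informative.
#' @param jitter_sd landmark localisation noise, pixels (default 0.5).
#' @param subject_sd lognormal SDs of per-participant heterogeneity in
#'   expressivity and motion scale (default `c(0.25, 0.15)`).
#' @param image_size synthetic camera frame, pixels (default 1280 x 720).
#' @param seed master seed; all participant seeds derive from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_arms = 58L, n_controls = 70L, frames = 3000L,
                        fps = 10, expressivity_attenuation = 0.6,
                        motion_sd_ratio = 0.7, blink_rate = 15,
                        smile_rate = 4, brow_rate = 6, speech_amp = 2.5,
                        motion_sd = c(3, 4, 2), motion_phi = 0.95,
                        jitter_sd = 0.5, subject_sd = c(0.25, 0.15),
                        image_size = c(1280, 720), seed = 1L) {
  stopifnot(n_arms >= 2L, n_controls >= 2L, frames >= 2L, fps > 0,
            expressivity_attenuation > 0, expressivity_attenuation <= 1,
            motion_sd_ratio > 0, all(motion_sd >= 0), jitter_sd >= 0,
            motion_phi >= 0, motion_phi < 1)
  structure(as.list(environment()), class = "cohort_spec")
}

# stationary AR(1) path of length n with coefficient phi and stationary sd
.ar1 <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  eps <- rnorm(n - 1, 0, innov_sd)
  for (t in 2:n) x[t] <- phi * x[t - 1] + eps[t - 1]
  x
}

# raised-cosine activation windows for n_events transient events; returns an
# n_frames vector of summed activations (each event peaks at its amplitude)
.event_activation <- function(n_frames, fps, rate_per_min, dur_range, amps) {
  act <- numeric(n_frames)
  n_events <- length(amps)
  if (!n_events) return(act)
  starts <- runif(n_events, 0, max(n_frames / fps - dur_range[2], 0.1))
  durs <- runif(n_events, dur_range[1], dur_range[2])
  for (e in seq_len(n_events)) {
    i0 <- floor(starts[e] * fps) + 1L
    len <- max(3L, round(durs[e] * fps))
    i1 <- min(n_frames, i0 + len - 1L)
    idx <- i0:i1
    w <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = length(idx))))
    act[idx] <- act[idx] + amps[e] * w
  }
  act
}

#' Generate one synthetic landmark trajectory
#'
#' One participant's recording: the canonical 3-D face template animated by
#' (a) AR(1) head-pose Euler-angle processes, (b) transient smile and
#' brow-raise events plus a continuous mouth-opening process, with
#' amplitudes scaled by the participant's realized expressivity, (c) blinks
#' closing the eyelid landmarks, all projected through the pinhole camera
#' used by [head_euler_angles()], plus (d) i.i.d. Gaussian pixel jitter.
#' ARMS participants draw their expressivity around
#' `spec$expressivity_attenuation` and their head-motion scale around
#' `spec$motion_sd_ratio`; controls around 1.
#'
#' @param group `"ARMS"` or `"CONTROL"`.
#' @param spec a [cohort_spec()].
#' @param participant_seed integer seed; the trajectory is a deterministic
#'   function of (group, spec, participant_seed).
#' @param participant_id identifier for the trajectory.
#' @return a [landmark_trajectory()] with attribute `"attenuation"` (the
#'   realized expressivity factor) and `"motion_scale"`.
#' @export
generate_trajectory <- function(group = c("CONTROL", "ARMS"), spec = cohort_spec(),
                                participant_seed = 1L,
                                participant_id = "synthetic") {
  group <- match.arg(group)
  .with_seed(participant_seed, {
    n <- spec$frames
    fps <- spec$fps
    minutes <- n / fps / 60
    tmpl <- face_template_3d()
    centroid <- colMeans(tmpl)
    base_att <- if (group == "ARMS") spec$expressivity_attenuation else 1
    base_mot <- if (group == "ARMS") spec$motion_sd_ratio else 1
    att <- base_att * exp(rnorm(1, 0, spec$subject_sd[1]))
    att <- min(max(att, 0.05), 1.5)
    mot <- base_mot * exp(rnorm(1, 0, spec$subject_sd[2]))

    pitch <- .ar1(n, spec$motion_phi, spec$motion_sd[1] * mot)
    yaw <- .ar1(n, spec$motion_phi, spec$motion_sd[2] * mot)
    roll <- .ar1(n, spec$motion_phi, spec$motion_sd[3] * mot)

    pts <- as.character(.lm_points)
    DX <- matrix(0, n, 51, dimnames = list(NULL, pts))
    DY <- matrix(0, n, 51, dimnames = list(NULL, pts))

    # smiles: mouth corners out and up, neighbours scaled
    n_sm <- rpois(1, spec$smile_rate * minutes)
    if (n_sm > 0 && att > 0) {
      amps <- pmax(rnorm(n_sm, 6, 1.5), 0) * att
      a <- .event_activation(n, fps, spec$smile_rate, c(1, 3), amps)
      for (p in c("48", "54")) {
        sgn <- if (p == "48") -1 else 1
        DX[, p] <- DX[, p] + sgn * 0.8 * a
        DY[, p] <- DY[, p] - a
      }
      for (p in c("49", "53", "59", "55")) DY[, p] <- DY[, p] - 0.5 * a
      for (p in c("50", "52", "58", "56")) DY[, p] <- DY[, p] - 0.25 * a
    }

    # brow raises
    n_br <- rpois(1, spec$brow_rate * minutes)
    if (n_br > 0 && att > 0) {
      amps <- pmax(rnorm(n_br, 4, 1), 0) * att
      a <- .event_activation(n, fps, spec$brow_rate, c(0.5, 1.5), amps)
      wts <- c(0.4, 0.7, 1, 1, 0.8, 0.8, 1, 1, 0.7, 0.4)
      for (k in seq_along(17:26))
        DY[, as.character(16 + k)] <- DY[, as.character(16 + k)] - wts[k] * a
    }

    # continuous mouth opening (speech-like): smoothed non-negative process
    if (spec$speech_amp > 0 && att > 0) {
      o <- abs(.ar1(n, 0.9, spec$speech_amp * att))
      for (p in c("65", "66", "67")) DY[, p] <- DY[, p] + 0.8 * o
      for (p in c("61", "62", "63")) DY[, p] <- DY[, p] - 0.2 * o
      for (p in c("55", "56", "57", "58", "59")) DY[, p] <- DY[, p] + o
      for (p in c("49", "50", "51", "52", "53")) DY[, p] <- DY[, p] - 0.2 * o
      for (p in c("48", "54")) DY[, p] <- DY[, p] + 0.4 * o
    }

    # blinks: upper lids meet lower lids; closure in [0, 1]
    n_bl <- rpois(1, spec$blink_rate * minutes)
    if (n_bl > 0) {
      cl <- pmin(.event_activation(n, fps, spec$blink_rate, c(0.25, 0.4),
                                   runif(n_bl, 0.85, 1)), 1)
      for (eye in list(c(up = 37, lo = 41), c(up = 38, lo = 40),
                       c(up = 43, lo = 47), c(up = 44, lo = 46))) {
        gap <- tmpl[as.character(eye["lo"]), "y"] - tmpl[as.character(eye["up"]), "y"]
        DY[, as.character(eye["up"])] <- DY[, as.character(eye["up"])] + 0.65 * gap * cl
        DY[, as.character(eye["lo"])] <- DY[, as.character(eye["lo"])] - 0.35 * gap * cl
      }
    }

    # assemble camera-frame points: rotate deformed template about its
    # centroid, translate to a per-participant position in front of the camera
    tvec <- c(rnorm(1, 0, 5), rnorm(1, 0, 5), 600 + rnorm(1, 0, 20))
    one <- rep(1, n)
    Xt <- one %*% t(tmpl[, 1] - centroid[1]) + DX
    Yt <- one %*% t(tmpl[, 2] - centroid[2]) + DY
    Zt <- one %*% t(tmpl[, 3] - centroid[3])
    p <- pitch * pi / 180; yw <- yaw * pi / 180; r <- roll * pi / 180
    cp <- cos(p); sp <- sin(p); cy <- cos(yw); sy <- sin(yw)
    cr <- cos(r); sr <- sin(r)
    # R = Rz(roll) Ry(yaw) Rx(pitch), applied per frame
    Xc <- (cr * cy) * Xt + (cr * sy * sp - sr * cp) * Yt +
      (cr * sy * cp + sr * sp) * Zt + tvec[1]
    Yc <- (sr * cy) * Xt + (sr * sy * sp + cr * cp) * Yt +
      (sr * sy * cp - cr * sp) * Zt + tvec[2]
    Zc <- (-sy) * Xt + (cy * sp) * Yt + (cy * cp) * Zt + tvec[3]
    f <- spec$image_size[1]
    u <- spec$image_size[1] / 2 + f * Xc / Zc
    v <- spec$image_size[2] / 2 + f * Yc / Zc
    if (spec$jitter_sd > 0) {
      u <- u + matrix(rnorm(n * 51, 0, spec$jitter_sd), n)
      v <- v + matrix(rnorm(n * 51, 0, spec$jitter_sd), n)
    }
    coords <- cbind(u, v)
    colnames(coords) <- .coord_cols()
    out <- landmark_trajectory(participant_id, fps, seq_len(n) - 1L, coords,
                               image_size = spec$image_size)
    attr(out, "attenuation") <- att
    attr(out, "motion_scale") <- mot
    out
  })
}

#' Generate a synthetic two-group cohort
#'
#' `n_arms + n_controls` trajectories ([generate_trajectory()]) with a
#' labels table carrying group, synthetic SIPS negative items N1-N6 and
#' demographic covariates. Items N2 (avolition) and N3 (expression of
#' emotion) increase stochastically as a participant's realized
#' expressivity decreases, enabling convergent-validity testing; N1 and
#' N4-N6 carry only weak group-level signal. The labels table also records
#' each participant's generator ground truth (`attenuation`,
#' `motion_scale`) for construction checks; these columns exist only for
#' synthetic data.
#'
#' @param spec a [cohort_spec()].
#' @return list with `trajectories` (named list) and `labels` (data.frame:
#'   `participant_id`, `group`, `N1..N6`, `age`, `gender`, `education`,
#'   `attenuation`, `motion_scale`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  n_total <- spec$n_arms + spec$n_controls
  groups <- rep(c("ARMS", "CONTROL"), c(spec$n_arms, spec$n_controls))
  ids <- sprintf("P%03d", seq_len(n_total))
  trajectories <- vector("list", n_total)
  att <- mot <- numeric(n_total)
  for (i in seq_len(n_total)) {
    trajectories[[i]] <- generate_trajectory(
      groups[i], spec, participant_seed = .derive_seed(spec$seed, i, 7L),
      participant_id = ids[i])
    att[i] <- attr(trajectories[[i]], "attenuation")
    mot[i] <- attr(trajectories[[i]], "motion_scale")
  }
  names(trajectories) <- ids
  labels <- .with_seed(.derive_seed(spec$seed, 0L, 8L), {
    sym <- function(slope, noise_sd)
      pmin(6L, pmax(0L, as.integer(round(slope * (1 - att) +
                                           rnorm(n_total, 0, noise_sd)))))
    arms <- groups == "ARMS"
    data.frame(
      participant_id = ids,
      group = factor(groups, levels = c("CONTROL", "ARMS")),
      N1 = pmin(6L, rpois(n_total, 0.6 + 0.6 * arms)),
      N2 = sym(4.5, 0.9),
      N3 = sym(5.5, 0.7),
      N4 = pmin(6L, rpois(n_total, 0.7 + 0.5 * arms)),
      N5 = pmin(6L, rpois(n_total, 0.5 + 0.4 * arms)),
      N6 = pmin(6L, rpois(n_total, 0.5 + 0.5 * arms)),
      age = round(rnorm(n_total, 28.5, 4.5)),
      gender = sample(c("male", "female"), n_total, TRUE, prob = c(0.34, 0.66)),
      education = sample(c("0-9", "10-12", "13+"), n_total, TRUE,
                         prob = c(0.02, 0.32, 0.66)),
      attenuation = att,
      motion_scale = mot)
  })
  list(trajectories = trajectories, labels = labels)
}

#' Write a synthetic cohort to disk
#'
#' Per-participant landmark CSVs ([write_landmark_csv()]) plus a
#' `labels.csv` in a directory.
#'
#' @param cohort a list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$trajectories))
    write_landmark_csv(cohort$trajectories[[id]],
                       file.path(dir, paste0(id, ".csv")))
  write_cohort_labels(cohort$labels, file.path(dir, "labels.csv"))
  invisible(dir)
}
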