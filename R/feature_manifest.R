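#' Bilaterally symmetric landmark pairs
#'
#' The 21 left/right mirror-image landmark pairs whose x and y coordinate
#' series are correlated as features: eyebrows (17,26) (18,25) (19,24)
#' (20,23) (21,22); eyes (36,45) (37,44) (38,43) (39,42) (40,47) (41,46);
#' nostrils (31,35) (32,34); outer mouth (48,54) (49,53) (50,52) (59,55)
#' (58,56); inner mouth (60,64) (61,63) (67,65).
#'
#' @return 21 x 2 integer matrix, columns `left` (lower-index side) and
#'   `right`.
#' @export
symmetric_pairs <- function() {
  m <- rbind(c(17, 26), c(18, 25), c(19, 24), c(20, 23), c(21, 22),
             c(36, 45), c(37, 44), c(38, 43), c(39, 42), c(40, 47), c(41, 46),
             c(31, 35), c(32, 34),
             c(48, 54), c(49, 53), c(50, 52), c(59, 55), c(58, 56),
             c(60, 64), c(61, 63), c(67, 65))
  colnames(m) <- c("left", "right")
  m
}

# landmarks whose inter-frame displacement MAD is a feature: the expressive
# subset (eyes, outer mouth, mid-eyebrows)
.speed_points <- c(36:47, 48:59, 19:24)

#' Default 649-feature manifest
#'
#' The feature inventory summarising a landmark trajectory, grouped as:
#' \describe{
#'   \item{coordinates}{51 points x 2 axes x \{IQR, MAD, outlier fraction,
#'     lag-1 PACF\} = 408, named `face_<i>_<x|y>_<stat>`.}
#'   \item{nose-anchored angles}{50 angle series from point 33 x \{IQR, MAD,
#'     outlier fraction\} = 150, named `face_33_angle_face<j>_<stat>`.}
#'   \item{symmetric-pair correlations}{21 mirror pairs x 2 axes Spearman
#'     rho = 42, named `spearman_<i>_<j>_<x|y>`.}
#'   \item{Euler angles}{pitch/yaw/roll x \{IQR, MAD, outlier fraction\}
#'     = 9, named `euler_<angle>_<stat>`.}
#'   \item{EAR}{IQR, MAD, outlier fraction, lag-1 PACF, percentage of frames
#'     below the first-quartile reference = 5.}
#'   \item{MAR}{same five statistics = 5.}
#'   \item{movement speed}{inter-frame displacement-magnitude MAD for the
#'     30-point expressive subset (eyes 36-47, outer mouth 48-59,
#'     mid-eyebrows 19-24), named `face_<i>_speed_mad`.}
#' }
#' Total 649. The manifest is plain data, so an alternative inventory can be
#' swapped in without code change ([read_feature_manifest()]).
#'
#' @return data.frame of class `feature_manifest` with columns `name`,
#'   `signal` (series identifier) and `statistic` (one of `IQR`, `MAD`,
#'   `OUTLIER_FRACTION`, `PACF1`, `SPEARMAN`, `BELOW_Q1_PCT`, `SPEED_MAD`).
#' @export
default_feature_manifest <- function() {
  rows <- list()
  add <- function(name, signal, statistic)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, signal = signal,
                                             statistic = statistic)
  stat3 <- c(IQR = "iqr", MAD = "mad", OUTLIER_FRACTION = "outliers")
  stat4 <- c(stat3, PACF1 = "pacf")
  for (i in .lm_points)
    for (ax in c("x", "y"))
      for (s in names(stat4))
        add(sprintf("face_%d_%s_%s", i, ax, stat4[[s]]),
            sprintf("coord_%d_%s", i, ax), s)
  for (j in setdiff(.lm_points, 33L))
    for (s in names(stat3))
      add(sprintf("face_33_angle_face%d_%s", j, stat3[[s]]),
          sprintf("angle_33_%d", j), s)
  sp <- symmetric_pairs()
  for (k in seq_len(nrow(sp)))
    for (ax in c("x", "y"))
      add(sprintf("spearman_%d_%d_%s", sp[k, 1], sp[k, 2], ax),
          sprintf("pair_%d_%d_%s", sp[k, 1], sp[k, 2], ax), "SPEARMAN")
  for (a in c("pitch", "yaw", "roll"))
    for (s in names(stat3))
      add(sprintf("euler_%s_%s", a, stat3[[s]]), sprintf("euler_%s", a), s)
  stat5 <- c(stat4, BELOW_Q1_PCT = "below_q1_pct")
  for (sig in c("ear", "mar"))
    for (s in names(stat5))
      add(sprintf("%s_%s", sig, stat5[[s]]), sig, s)
  for (i in .speed_points)
    add(sprintf("face_%d_speed_mad", i), sprintf("speed_%d", i), "SPEED_MAD")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_manifest", "data.frame")
  validate_manifest(out)
}

#' Validate a feature manifest
#'
#' @param manifest a `feature_manifest` data.frame (`name`, `signal`,
#'   `statistic`).
#' @return the manifest, invisibly validated (names unique, statistics from
#'   the known set).
#' @export
validate_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest),
            all(c("name", "signal", "statistic") %in% names(manifest)))
  if (anyDuplicated(manifest$name))
    stop("manifest feature names must be unique")
  known <- c("IQR", "MAD", "OUTLIER_FRACTION", "PACF1", "SPEARMAN",
             "BELOW_Q1_PCT", "SPEED_MAD")
  bad <- setdiff(unique(manifest$statistic), known)
  if (length(bad))
    stop("unknown statistic(s): ", paste(bad, collapse = ", "))
  if (!inherits(manifest, "feature_manifest"))
    class(manifest) <- c("feature_manifest", class(manifest))
  manifest
}

#' Read / write a feature manifest CSV
#'
#' @param path CSV path with columns `name`, `signal`, `statistic`.
#' @return `read_feature_manifest()`: a validated manifest;
#'   `write_feature_manifest()`: `path`, invisibly.
#' @export
read_feature_manifest <- function(path) {
  validate_manifest(data.table::fread(path, data.table = FALSE))
}

#' @rdname read_feature_manifest
#' @param manifest a manifest to write.
#' @export
write_feature_manifest <- function(manifest, path) {
  data.table::fwrite(validate_manifest(manifest), path)
  invisible(path)
}
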