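#' Construct a landmark trajectory
#'
#' A `landmark_trajectory` holds one participant's per-frame coordinates for
#' the 51 facial landmarks 17-67 (iBUG/300-W numbering, jawline excluded),
#' in image convention: origin top-left, y increasing downward, units pixels.
#'
#' @param participant_id single string identifier.
#' @param fps frames per second (> 0).
#' @param frames integer vector of strictly increasing frame indices.
#' @param coords numeric matrix, `length(frames)` rows and 102 columns named
#'   `x_17..x_67, y_17..y_67`.
#' @param image_size optional `c(width, height)` in pixels; required for
#'   head-pose estimation.
#' @param breaks optional two-column matrix of recorded gap endpoints
#'   (`from`, `to` frame indices) left unfilled by [interpolate_gaps()].
#' @return object of class `landmark_trajectory`.
#' @export
landmark_trajectory <- function(participant_id, fps, frames, coords,
                                image_size = NULL, breaks = NULL) {
  obj <- structure(
    list(participant_id = as.character(participant_id),
         fps = as.numeric(fps),
         frames = as.integer(frames),
         coords = as.matrix(coords),
         image_size = if (!is.null(image_size)) as.numeric(image_size),
         breaks = breaks),
    class = "landmark_trajectory")
  validate_trajectory(obj)
}

#' Validate a landmark trajectory's invariants
#'
#' Checks frame count, strictly increasing frame indices, the full 102-column
#' coordinate layout, and finiteness of every coordinate.
#'
#' @param x a `landmark_trajectory`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_trajectory <- function(x) {
  stopifnot(inherits(x, "landmark_trajectory"))
  if (length(x$participant_id) != 1L || is.na(x$participant_id))
    stop("participant_id must be a single non-missing string")
  if (!is.finite(x$fps) || x$fps <= 0)
    stop("fps must be a positive number")
  n <- length(x$frames)
  if (n < 2L)
    stop("a trajectory needs at least 2 frames")
  if (any(diff(x$frames) <= 0L))
    stop("frame indices must be strictly increasing")
  if (nrow(x$coords) != n)
    stop("coords must have one row per frame")
  want <- .coord_cols()
  if (!identical(colnames(x$coords), want)) {
    missing <- setdiff(want, colnames(x$coords))
    if (length(missing))
      stop("missing landmark column(s): ", paste(missing, collapse = ", "))
    x$coords <- x$coords[, want, drop = FALSE]
  }
  if (!all(is.finite(x$coords)))
    stop("all landmark coordinates must be finite")
  if (!is.null(x$image_size) &&
      (length(x$image_size) != 2L || any(!is.finite(x$image_size)) ||
       any(x$image_size <= 0)))
    stop("image_size must be c(width, height), both positive")
  invisible(x)
}

#' @export
print.landmark_trajectory <- function(x, ...) {
  cat(sprintf("landmark_trajectory '%s': %d frames @ %g fps (%.1f s), 51 points\n",
              x$participant_id, length(x$frames), x$fps,
              length(x$frames) / x$fps))
  if (!is.null(x$image_size))
    cat(sprintf("  image %d x %d px\n", x$image_size[1], x$image_size[2]))
  if (!is.null(x$breaks) && nrow(x$breaks))
    cat(sprintf("  %d recorded gap(s) left uninterpolated\n", nrow(x$breaks)))
  invisible(x)
}

#' Read a landmark-trajectory CSV
#'
#' Expects the wide dialect: one row per frame, a `frame` column and the 102
#' coordinate columns `x_17..x_67, y_17..y_67`. Optional `image_width` /
#' `image_height` columns (constant) populate `image_size`.
#'
#' @param path path to a CSV file.
#' @param participant_id identifier; defaults to the file name without
#'   extension.
#' @return a [landmark_trajectory()].
#' @param fps frames per second to attach (the file format does not carry it
#'   unless an `fps` column is present).
#' @export
read_landmark_csv <- function(path, participant_id = NULL, fps = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  want <- c("frame", .coord_cols())
  missing <- setdiff(want, names(dt))
  if (length(missing))
    stop("landmark CSV is missing column(s): ", paste(missing, collapse = ", "))
  for (cl in want) {
    v <- dt[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s' at data row %d", cl,
                   if (is.na(bad)) 1L else bad))
    }
  }
  if (anyDuplicated(dt$frame))
    stop("duplicate frame index in ", path)
  dt <- dt[order(dt$frame), , drop = FALSE]
  img <- NULL
  if (all(c("image_width", "image_height") %in% names(dt)))
    img <- c(dt$image_width[1], dt$image_height[1])
  if (is.null(fps)) fps <- if ("fps" %in% names(dt)) dt$fps[1] else 30
  if (is.null(participant_id))
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  co <- as.matrix(dt[, .coord_cols(), drop = FALSE])
  rownames(co) <- NULL
  landmark_trajectory(participant_id, fps, dt$frame, co, image_size = img)
}

#' Write a landmark trajectory as CSV
#'
#' Inverse of [read_landmark_csv()]; full-precision coordinates so the
#' round trip is exact.
#'
#' @param trajectory a valid [landmark_trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(trajectory, path) {
  validate_trajectory(trajectory)
  # 17 significant digits so doubles survive the round trip bit-exactly
  txt <- apply(trajectory$coords, 2L, function(v) sprintf("%.17g", v))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = 1L,
                                       dimnames = list(NULL,
                                                       colnames(trajectory$coords)))
  df <- data.frame(frame = trajectory$frames, txt, check.names = FALSE)
  df$fps <- trajectory$fps
  if (!is.null(trajectory$image_size)) {
    df$image_width <- trajectory$image_size[1]
    df$image_height <- trajectory$image_size[2]
  }
  data.table::fwrite(df, path, sep = ",", quote = FALSE)
  invisible(path)
}

#' Fill short frame gaps by linear interpolation
#'
#' Gaps of at most `max_gap` missing frame indices are filled per coordinate
#' by linear interpolation between the flanking observed frames. Longer gaps
#' are left untouched and recorded in the returned trajectory's `breaks`
#' field, so downstream summaries know the series is segmented rather than
#' silently fabricated.
#'
#' @param trajectory a [landmark_trajectory()].
#' @param max_gap largest number of consecutive missing frames to fill
#'   (default 5).
#' @return a [landmark_trajectory()]; observed frames are never altered.
#' @export
interpolate_gaps <- function(trajectory, max_gap = 5L) {
  validate_trajectory(trajectory)
  stopifnot(max_gap >= 0)
  fr <- trajectory$frames
  gaps <- diff(fr) - 1L
  if (!any(gaps > 0L)) return(trajectory)
  fill <- integer(0)
  brk <- list()
  for (i in which(gaps > 0L)) {
    if (gaps[i] <= max_gap) {
      fill <- c(fill, seq.int(fr[i] + 1L, fr[i + 1L] - 1L))
    } else {
      brk[[length(brk) + 1L]] <- c(from = fr[i], to = fr[i + 1L])
    }
  }
  new_frames <- sort(c(fr, fill))
  if (length(fill)) {
    co <- apply(trajectory$coords, 2L,
                function(v) approx(fr, v, xout = new_frames)$y)
    colnames(co) <- colnames(trajectory$coords)
    # observed frames keep their original values bit-exactly
    co[match(fr, new_frames), ] <- trajectory$coords
  } else {
    co <- trajectory$coords
  }
  landmark_trajectory(trajectory$participant_id, trajectory$fps, new_frames,
                      co, image_size = trajectory$image_size,
                      breaks = if (length(brk)) do.call(rbind, brk))
}

#' Read a cohort label file
#'
#' Labels CSV: `participant_id`, `group` (ARMS / CONTROL), optional SIPS
#' negative items `N1..N6` (integer 0-6), optional `age`, `gender`,
#' `education` covariates.
#'
#' @param path CSV path.
#' @return a `data.frame` with `group` as a factor with levels
#'   `CONTROL`, `ARMS`.
#' @export
read_cohort_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  if (!all(c("participant_id", "group") %in% names(df)))
    stop("labels file needs participant_id and group columns")
  df$participant_id <- as.character(df$participant_id)
  if (anyDuplicated(df$participant_id))
    stop("duplicate participant_id in labels")
  if (!all(df$group %in% c("ARMS", "CONTROL")))
    stop("group must be ARMS or CONTROL")
  df$group <- factor(df$group, levels = c("CONTROL", "ARMS"))
  for (it in grep("^N[1-6]$", names(df), value = TRUE)) {
    ok <- is.na(df[[it]]) | (df[[it]] >= 0 & df[[it]] <= 6)
    if (!all(ok)) stop("SIPS item ", it, " outside [0, 6]")
  }
  df
}

#' Write a cohort label file
#'
#' @param labels data.frame as returned by [read_cohort_labels()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_labels <- function(labels, path) {
  data.table::fwrite(labels, path, sep = ",", quote = FALSE)
  invisible(path)
}
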