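#' Robust dispersion of a per-frame signal
#'
#' IQR (type-7 linearly interpolated quantiles) and unscaled MAD
#' (`median(|x - median(x)|)`, no 1.4826 consistency factor -- the MAD is
#' used as a robust summary, not as a sigma estimator).
#'
#' @param series numeric vector; `NA`s ignored.
#' @return named vector `c(iqr =, mad =)`; both `NA` with fewer than 2
#'   non-missing values.
#' @export
robust_dispersion <- function(series) {
  x <- series[!is.na(series)]
  if (length(x) < 2L) return(c(iqr = NA_real_, mad = NA_real_))
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  c(iqr = q[2] - q[1], mad = mad(x, constant = 1))
}

#' Fraction of values outside the Tukey fences
#'
#' Fraction of non-missing values outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (quartiles type-7).
#'
#' @param series numeric vector.
#' @return fraction in `[0, 1]`; `NA` with fewer than 4 non-missing values.
#' @export
outlier_fraction <- function(series) {
  x <- series[!is.na(series)]
  if (length(x) < 4L) return(NA_real_)
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  mean(x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr)
}

#' Partial autocorrelation coefficient
#'
#' Sample PACF at a given lag (Durbin-Levinson recursion on the sample
#' autocorrelations, as computed by [stats::acf()] with `type = "partial"`).
#' At lag 1 this equals the lag-1 sample autocorrelation.
#'
#' @param series numeric vector; missing values removed (segments are
#'   concatenated).
#' @param lag positive integer lag (default 1).
#' @return value in `[-1, 1]`, or `NA` for a zero-variance or too-short
#'   series.
#' @export
pacf_coefficient <- function(series, lag = 1L) {
  stopifnot(lag >= 1L)
  x <- series[!is.na(series)]
  if (length(x) <= lag + 1L || var(x) == 0) return(NA_real_)
  p <- stats::pacf(x, lag.max = lag, plot = FALSE)$acf[lag]
  if (!is.finite(p)) NA_real_ else p
}

#' Spearman rank correlation of two paired series
#'
#' Spearman rho with average ranks for ties, on pairwise-complete
#' observations.
#'
#' @param series_a,series_b numeric vectors of equal length.
#' @return rho in `[-1, 1]`; `NA` with fewer than 3 complete pairs or zero
#'   rank variance in either series.
#' @export
spearman_pair <- function(series_a, series_b) {
  stopifnot(length(series_a) == length(series_b))
  ok <- !is.na(series_a) & !is.na(series_b)
  if (sum(ok) < 3L) return(NA_real_)
  a <- series_a[ok]; b <- series_b[ok]
  if (var(rank(a)) == 0 || var(rank(b)) == 0) return(NA_real_)
  cor(a, b, method = "spearman")
}

#' Percentage of values below a reference
#'
#' `100 * (# values strictly below reference) / (# non-missing values)`;
#' used for the EAR below-first-quartile feature (a blink-pressure proxy).
#'
#' @param series numeric vector.
#' @param reference finite reference value.
#' @return percentage in `[0, 100]`; `NA` if all values are missing.
#' @export
below_reference_fraction <- function(series, reference) {
  stopifnot(is.finite(reference))
  x <- series[!is.na(series)]
  if (!length(x)) return(NA_real_)
  100 * mean(x < reference)
}

# inter-frame displacement magnitude of one landmark; NA where the frame
# step is not 1 (recorded breaks must not fabricate speed)
.speed_series <- function(coords, frames, i) {
  dx <- diff(coords[, .col_x(i)])
  dy <- diff(coords[, .col_y(i)])
  sp <- sqrt(dx^2 + dy^2)
  sp[diff(frames) != 1L] <- NA_real_
  sp
}

# resolve one manifest signal identifier to its numeric series
.signal_series <- function(signals, signal) {
  if (signal == "ear") return(signals$ear)
  if (signal == "mar") return(signals$mar)
  if (startsWith(signal, "euler_")) {
    if (is.null(signals$euler)) return(rep(NA_real_, length(signals$ear)))
    return(signals$euler[[sub("euler_", "", signal)]])
  }
  if (startsWith(signal, "coord_")) {
    p <- strsplit(signal, "_")[[1]]
    return(signals$coords[, paste0(p[3], "_", p[2])])
  }
  if (startsWith(signal, "angle_33_")) {
    j <- sub("angle_33_", "", signal)
    return(unwrap_degrees(signals$angles[, paste0("angle_33_to_", j)]))
  }
  if (startsWith(signal, "speed_")) {
    i <- as.integer(sub("speed_", "", signal))
    return(.speed_series(signals$coords, signals$frames, i))
  }
  stop("unknown signal identifier: ", signal)
}

#' Summarise per-frame signals into a named feature vector
#'
#' Applies every manifest entry to precomputed [per_frame_signals()].
#' Statistics that are undefined on the input (zero variance, too few
#' frames, missing pose) come back as `NA`; imputation happens at table
#' level, inside each training split.
#'
#' @param signals a `frame_signals` object.
#' @param manifest a feature manifest (default [default_feature_manifest()]).
#' @param ear_q1_reference reference value for the EAR below-quartile
#'   feature. `NULL` (default) uses this recording's own first quartile;
#'   cross-validated analyses pass the pooled training-cohort Q1 instead.
#' @return named numeric vector, `length(manifest$name)` entries in manifest
#'   order.
#' @export
featurize_signals <- function(signals, manifest = default_feature_manifest(),
                              ear_q1_reference = NULL) {
  manifest <- validate_manifest(manifest)
  if (is.null(ear_q1_reference))
    ear_q1_reference <- quantile(signals$ear, 0.25, na.rm = TRUE,
                                 names = FALSE, type = 7)
  cache <- new.env(parent = emptyenv())
  get_series <- function(sig) {
    if (is.null(cache[[sig]])) cache[[sig]] <- .signal_series(signals, sig)
    cache[[sig]]
  }
  out <- vapply(seq_len(nrow(manifest)), function(r) {
    stat <- manifest$statistic[r]
    sig <- manifest$signal[r]
    if (stat == "SPEARMAN") {
      p <- strsplit(sig, "_")[[1]]  # pair_i_j_axis
      a <- get_series(sprintf("coord_%s_%s", p[2], p[4]))
      b <- get_series(sprintf("coord_%s_%s", p[3], p[4]))
      return(spearman_pair(a, b))
    }
    x <- get_series(sig)
    switch(stat,
           IQR = robust_dispersion(x)[["iqr"]],
           MAD = robust_dispersion(x)[["mad"]],
           OUTLIER_FRACTION = outlier_fraction(x),
           PACF1 = pacf_coefficient(x, 1L),
           BELOW_Q1_PCT = if (is.na(ear_q1_reference)) NA_real_ else
             below_reference_fraction(x, ear_q1_reference),
           SPEED_MAD = robust_dispersion(x)[["mad"]])
  }, numeric(1))
  names(out) <- manifest$name
  out
}

#' Build the full feature vector of one trajectory
#'
#' Convenience wrapper: [per_frame_signals()] then [featurize_signals()].
#' With the default manifest the result has exactly 649 named entries.
#'
#' @inheritParams featurize_signals
#' @param trajectory a [landmark_trajectory()].
#' @return named numeric vector in manifest order.
#' @export
build_feature_vector <- function(trajectory,
                                 manifest = default_feature_manifest(),
                                 ear_q1_reference = NULL) {
  featurize_signals(per_frame_signals(trajectory), manifest,
                    ear_q1_reference)
}

#' Assemble the participants x features table of a cohort
#'
#' Rows are participants, columns the manifest features. The EAR
#' below-quartile feature is stored here against the pooled all-cohort EAR
#' first quartile, and each participant's raw EAR series is retained so that
#' split-wise analyses ([monte_carlo_cv()]) can recompute the reference from
#' training participants only and impute missing cells with training-set
#' medians -- no test-row information ever enters a fitted model.
#'
#' @param trajectories list of [landmark_trajectory()] objects (or of
#'   precomputed `frame_signals`).
#' @param labels cohort labels data.frame (see [read_cohort_labels()]) with
#'   at least 2 participants per group.
#' @param manifest feature manifest (default the 649-entry
#'   [default_feature_manifest()]).
#' @return object of class `feature_table`: list with `participants`,
#'   `group` (factor aligned to rows), `X` (numeric matrix, `NA` where a
#'   statistic was undefined), `manifest`, `ear_series` (list of per-frame
#'   EAR vectors), `labels`.
#' @export
build_feature_table <- function(trajectories, labels,
                                manifest = default_feature_manifest()) {
  manifest <- validate_manifest(manifest)
  sigs <- lapply(trajectories, function(tr)
    if (inherits(tr, "frame_signals")) tr else per_frame_signals(tr))
  ids <- vapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    if (inherits(tr, "landmark_trajectory")) tr$participant_id
    else if (!is.null(names(trajectories))) names(trajectories)[i]
    else as.character(i)
  }, character(1))
  if (anyDuplicated(ids))
    stop("duplicated participant id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!all(ids %in% labels$participant_id))
    stop("participant(s) missing from labels")
  labels <- labels[match(ids, labels$participant_id), , drop = FALSE]
  if (any(table(labels$group) < 2L))
    stop("need at least 2 participants per group")
  ear_series <- lapply(sigs, `[[`, "ear")
  pooled_q1 <- quantile(unlist(ear_series), 0.25, na.rm = TRUE,
                        names = FALSE, type = 7)
  X <- t(vapply(sigs, featurize_signals, numeric(nrow(manifest)),
                manifest = manifest, ear_q1_reference = pooled_q1))
  rownames(X) <- ids
  structure(list(participants = ids,
                 group = factor(as.character(labels$group),
                                levels = c("CONTROL", "ARMS")),
                 X = X, manifest = manifest,
                 ear_series = setNames(ear_series, ids),
                 labels = labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d participants x %d features (%d ARMS, %d CONTROL); %d missing cell(s)\n",
              nrow(x$X), ncol(x$X), sum(x$group == "ARMS"),
              sum(x$group == "CONTROL"), sum(is.na(x$X))))
  invisible(x)
}

#' Write / read a feature table as CSV
#'
#' Plain participants x features CSV keyed by `participant_id` (group and
#' EAR series are carried by the labels file / recomputation, not here).
#'
#' @param table a `feature_table`.
#' @param path CSV path.
#' @return the path / a data.frame with `participant_id` first column.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(participant_id = table$participants, table$X,
                   check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table_csv <- function(path) {
  data.table::fread(path, data.table = FALSE)
}

# Split-wise references: EAR-Q1 column recomputed from training rows' pooled
# EAR values; residual NAs imputed with training-column medians.
# Returns list(X = imputed matrix, ear_q1, medians).
.apply_split_references <- function(table, train_idx) {
  X <- table$X
  q1 <- quantile(unlist(table$ear_series[train_idx]), 0.25, na.rm = TRUE,
                 names = FALSE, type = 7)
  bq <- which(table$manifest$statistic == "BELOW_Q1_PCT" &
                table$manifest$signal == "ear")
  if (length(bq) && is.finite(q1)) {
    X[, bq] <- vapply(table$ear_series, below_reference_fraction, numeric(1),
                      reference = q1)
  }
  med <- apply(X[train_idx, , drop = FALSE], 2L, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in which(colSums(is.na(X)) > 0L)) X[is.na(X[, j]), j] <- med[j]
  list(X = X, ear_q1 = q1, medians = med)
}
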