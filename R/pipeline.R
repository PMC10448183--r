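#' Run the full analysis pipeline
#'
#' Orchestrates every stage with one configuration and one master seed:
#' landmark input (a directory of landmark CSVs plus labels, an in-memory
#' cohort, or a synthetic [cohort_spec()]) -> per-frame signals and the
#' 649-feature table -> Monte Carlo cross-validation with split-wise
#' references, selection and AdaBoost fitting -> metric summary, averaged
#' ROC, optional summed permutation importance -> convergent-validity
#' rank-sum tests of the most frequently selected features against the SIPS
#' negative items. All stochastic stages key their seeds off `seed`, so a
#' rerun with the same inputs reproduces the report bit for bit.
#'
#' @param cohort_dir directory of per-participant landmark CSVs with a
#'   `labels.csv` (as written by [write_cohort()]); or
#' @param trajectories,labels an in-memory cohort; or
#' @param spec a [cohort_spec()] to simulate one.
#' @param manifest feature manifest (default the 649-entry one).
#' @param selection,ensemble stage configurations.
#' @param n_splits,train_frac,threshold cross-validation settings.
#' @param importance_repeats per-split permutation-importance repeats
#'   (0 = skip).
#' @param validity_top how many of the most frequently selected features to
#'   carry into the convergent-validity tests (default 5; 0 = skip).
#' @param seed master seed.
#' @param out_dir if non-`NULL`, report files are written there:
#'   `metrics_summary.csv`, `per_split_metrics.csv`, `roc_mean.csv`,
#'   `importance.csv`, `validity.csv`, `provenance.json`.
#' @param fps frame rate to assume when reading landmark CSVs without one.
#' @return list of class `pipeline_report`: `metrics` (the
#'   [monte_carlo_cv()] result), `validity`, `selected_counts`, `table`,
#'   `provenance`.
#' @export
run_pipeline <- function(cohort_dir = NULL, trajectories = NULL,
                         labels = NULL, spec = NULL,
                         manifest = default_feature_manifest(),
                         selection = selection_config(),
                         ensemble = ensemble_config(),
                         n_splits = 100L, train_frac = 0.7, threshold = 0.5,
                         importance_repeats = 0L, validity_top = 5L,
                         seed = 1L, out_dir = NULL, fps = NULL) {
  stage <- function(what, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", what, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] %.1fs", what,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  if (!is.null(spec)) {
    cohort <- stage("simulate", generate_cohort(spec))
    trajectories <- cohort$trajectories
    labels <- cohort$labels
  } else if (!is.null(cohort_dir)) {
    trajectories <- stage("read", {
      files <- setdiff(list.files(cohort_dir, "\\.csv$", full.names = TRUE),
                       file.path(cohort_dir, "labels.csv"))
      lapply(files, read_landmark_csv, fps = fps)
    })
    labels <- read_cohort_labels(file.path(cohort_dir, "labels.csv"))
  }
  if (is.null(trajectories) || is.null(labels))
    stop("provide cohort_dir, trajectories + labels, or spec")
  ftab <- stage("extract-features",
                 build_feature_table(trajectories, labels, manifest))
  cv <- stage("train-eval",
              monte_carlo_cv(ftab, n_splits = n_splits,
                             train_frac = train_frac, selection = selection,
                             ensemble = ensemble, seed = seed,
                             importance_repeats = importance_repeats,
                             threshold = threshold))
  counts <- sort(table(unlist(cv$selected)), decreasing = TRUE)
  selected_counts <- data.frame(feature = names(counts),
                                n_splits_selected = as.integer(counts))
  validity <- NULL
  items <- grep("^N[1-6]$", names(labels), value = TRUE)
  if (validity_top > 0L && length(items)) {
    validity <- stage("validity",
                      validity_table(ftab,
                                     head(selected_counts$feature, validity_top),
                                     items = items))
  }
  provenance <- list(package_version = as.character(utils::packageVersion("facekin")),
                     r_version = R.version.string,
                     seed = seed, n_splits = n_splits,
                     train_frac = train_frac, threshold = threshold,
                     selection = unclass(selection),
                     ensemble = unclass(ensemble),
                     split_seeds = cv$seeds,
                     n_participants = nrow(ftab$X),
                     n_features = ncol(ftab$X),
                     timestamp = format(Sys.time(), tz = "UTC"))
  report <- structure(list(metrics = cv, validity = validity,
                           selected_counts = selected_counts, table = ftab,
                           provenance = provenance),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(cv$summary, file.path(out_dir, "metrics_summary.csv"))
    data.table::fwrite(cv$per_split, file.path(out_dir, "per_split_metrics.csv"))
    data.table::fwrite(cv$roc, file.path(out_dir, "roc_mean.csv"))
    data.table::fwrite(selected_counts, file.path(out_dir, "selected_features.csv"))
    if (!is.null(cv$importance))
      data.table::fwrite(cv$importance, file.path(out_dir, "importance.csv"))
    if (!is.null(validity))
      data.table::fwrite(validity, file.path(out_dir, "validity.csv"))
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  print(x$metrics)
  cat(sprintf("features selected in >= half the splits: %d\n",
              sum(x$selected_counts$n_splits_selected >=
                    x$metrics$n_splits / 2)))
  if (!is.null(x$validity)) {
    top <- x$validity[order(x$validity$p_value), ][1, ]
    cat(sprintf("strongest convergent-validity signal: %s vs %s (p = %.2g)\n",
                top$feature, top$item, top$p_value))
  }
  invisible(x)
}
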