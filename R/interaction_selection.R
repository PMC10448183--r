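#' Feature-selection configuration
#'
#' Settings for the two-stage gradient-boosting feature selection: stage 1
#' ranks the base features and keeps the top `stage1_top_m`; stage 2 appends
#' all pairwise products of the survivors; stage 3 re-ranks the combined set
#' and keeps the top `final_top_k`. Importance is the booster's `"gain"`
#' (average information gain of a feature's splits) or `"split"` (number of
#' times a feature splits a tree).
#'
#' @param stage1_top_m base features kept before interaction generation
#'   (default 40).
#' @param final_top_k features returned (default 30).
#' @param importance_type `"gain"` (default) or `"split"`.
#' @param nrounds,eta,max_depth selection-booster settings (defaults 80 /
#'   0.1 / 3; the booster is run without row or column subsampling, so
#'   ranking is deterministic).
#' @param seed retained for provenance.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(stage1_top_m = 40L, final_top_k = 30L,
                             importance_type = c("gain", "split"),
                             nrounds = 80L, eta = 0.1, max_depth = 3L,
                             seed = 1L) {
  importance_type <- match.arg(importance_type)
  stopifnot(stage1_top_m >= 1L,
            final_top_k >= 1L,
            final_top_k <= stage1_top_m + choose(stage1_top_m, 2))
  structure(list(stage1_top_m = as.integer(stage1_top_m),
                 final_top_k = as.integer(final_top_k),
                 importance_type = importance_type,
                 nrounds = as.integer(nrounds), eta = eta,
                 max_depth = as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "selection_config")
}

.as_feature_matrix <- function(table) {
  if (inherits(table, "feature_table")) table$X else as.matrix(table)
}

#' Append pairwise product interactions
#'
#' For every unordered pair of distinct candidate features, appends a column
#' holding their elementwise product, named `"<a> * <b>"`. Original columns
#' are retained.
#'
#' @param table numeric matrix (participants x features) or
#'   `feature_table`.
#' @param candidate_names names of the features to combine; must exist in
#'   the table.
#' @return the same kind of object with `choose(m, 2)` extra columns.
#' @export
generate_interactions <- function(table, candidate_names) {
  X <- .as_feature_matrix(table)
  missing <- setdiff(candidate_names, colnames(X))
  if (length(missing))
    stop("candidate feature(s) not in table: ", paste(missing, collapse = ", "))
  m <- length(candidate_names)
  if (m >= 2L) {
    pairs <- utils::combn(candidate_names, 2L)
    prod_cols <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
    colnames(prod_cols) <- paste(pairs[1, ], "*", pairs[2, ])
    X <- cbind(X, prod_cols)
  }
  if (inherits(table, "feature_table")) {
    table$X <- X
    table
  } else X
}

# fit the selection booster and return per-column importance (0 for columns
# the booster never used); columns are renamed internally because product
# names contain spaces
.gbm_importance <- function(X, y01, config) {
  safe <- paste0("f", seq_len(ncol(X)))
  Xs <- X
  colnames(Xs) <- safe
  dtrain <- xgboost::xgb.DMatrix(Xs, label = y01, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = config$max_depth, eta = config$eta,
                  subsample = 1, colsample_bytree = 1, nthread = 1),
    data = dtrain, nrounds = config$nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = booster)
  score <- setNames(numeric(ncol(X)), safe)
  col <- if (config$importance_type == "gain") "Gain" else "Frequency"
  score[imp$Feature] <- imp[[col]]
  setNames(as.numeric(score), colnames(X))
}

#' Rank features by gradient-boosting importance
#'
#' Trains a gradient-boosted tree classifier (xgboost, no subsampling, one
#' thread -- deterministic) on the table and returns the features ordered by
#' decreasing importance; ties (including never-used features at importance
#' 0) keep their column order.
#'
#' @param table numeric matrix or `feature_table`.
#' @param labels binary factor/vector; the second level (or `"ARMS"`) is the
#'   positive class.
#' @param config a [selection_config()].
#' @return data.frame `feature`, `importance`, sorted descending.
#' @export
gbm_rank_features <- function(table, labels, config = selection_config()) {
  X <- .as_feature_matrix(table)
  y01 <- .labels01(labels, nrow(X))
  if (length(unique(y01)) < 2L)
    stop("both classes must be present to rank features")
  score <- .gbm_importance(X, y01, config)
  ord <- order(-score, seq_along(score))
  data.frame(feature = colnames(X)[ord], importance = as.numeric(score[ord]))
}

.labels01 <- function(labels, n) {
  if (inherits(labels, "factor")) {
    y01 <- as.integer(labels == levels(labels)[nlevels(labels)])
    if ("ARMS" %in% levels(labels)) y01 <- as.integer(labels == "ARMS")
  } else if (is.character(labels)) {
    y01 <- as.integer(labels == "ARMS")
  } else {
    y01 <- as.integer(labels != 0)
  }
  stopifnot(length(y01) == n)
  y01
}

#' Two-stage interaction-aware feature selection
#'
#' Stage 1 ranks all base features and keeps the top
#' `config$stage1_top_m`; stage 2 appends every pairwise product of the
#' survivors ([generate_interactions()]); stage 3 re-ranks the combined set
#' and returns the names of the top `config$final_top_k`. Base features may
#' survive alongside products. A pure function of the training rows.
#'
#' @inheritParams gbm_rank_features
#' @param train_table training rows only (matrix or `feature_table`).
#' @return character vector of `final_top_k` selected names (base names or
#'   `"<a> * <b>"` products), resolvable on new data by
#'   [apply_feature_recipe()].
#' @export
select_features <- function(train_table, labels, config = selection_config()) {
  X <- .as_feature_matrix(train_table)
  stage1 <- gbm_rank_features(X, labels, config)
  keep <- head(stage1$feature, config$stage1_top_m)
  X2 <- generate_interactions(X[, keep, drop = FALSE], keep)
  stage3 <- gbm_rank_features(X2, labels, config)
  head(stage3$feature, config$final_top_k)
}

#' Materialise selected features on any table
#'
#' Resolves a selected-feature list (base names and `"<a> * <b>"` products)
#' against a base-feature table, so test rows are transformed exactly like
#' training rows.
#'
#' @param table numeric matrix or `feature_table` holding the base features.
#' @param selected character vector from [select_features()].
#' @return numeric matrix with `length(selected)` columns in that order.
#' @export
apply_feature_recipe <- function(table, selected) {
  X <- .as_feature_matrix(table)
  out <- vapply(selected, function(nm) {
    if (nm %in% colnames(X)) return(X[, nm])
    parts <- strsplit(nm, " \\* ")[[1]]
    if (length(parts) == 2L && all(parts %in% colnames(X)))
      return(X[, parts[1]] * X[, parts[2]])
    stop("cannot resolve selected feature: ", nm)
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, selected))
  out
}
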