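#' AdaBoost ensemble configuration
#'
#' Settings of the boosted classifier: `n_estimators` random-forest weak
#' learners combined by discrete AdaBoost, each forest having `rf_trees`
#' trees of depth `rf_max_depth` with `log2(p)` candidate features per
#' split. The defaults (900 estimators, learning rate 2, 5 trees, depth 1,
#' log2 features) are the published operating point; the learning rate is
#' unusually large but retained as published and configurable.
#'
#' @param n_estimators boosting rounds (default 900).
#' @param learning_rate multiplier on each round's weight `alpha_m`
#'   (default 2).
#' @param rf_trees trees per random forest (default 5).
#' @param rf_max_depth tree depth (default 1, stumps).
#' @param rf_max_features `"log2"` (default) or `"sqrt"` candidate features
#'   per split.
#' @param seed integer; every forest's RNG derives from it.
#' @return list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_estimators = 900L, learning_rate = 2,
                            rf_trees = 5L, rf_max_depth = 1L,
                            rf_max_features = c("log2", "sqrt"),
                            seed = 1L) {
  rf_max_features <- match.arg(rf_max_features)
  stopifnot(n_estimators >= 1L, learning_rate > 0, rf_trees >= 1L,
            rf_max_depth >= 1L)
  structure(list(n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate,
                 rf_trees = as.integer(rf_trees),
                 rf_max_depth = as.integer(rf_max_depth),
                 rf_max_features = rf_max_features,
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Fit an AdaBoost ensemble of shallow random forests
#'
#' Discrete AdaBoost with random-forest weak learners `G_m`: at round `m`
#' a forest is fitted under the current case weights, its weighted training
#' error `err_m` gives the learner weight
#' `alpha_m = learning_rate * 0.5 * log((1 - err_m) / err_m)`, and case
#' weights are multiplied by `exp(-alpha_m)` when correctly classified and
#' `exp(alpha_m)` when misclassified, then renormalised. The committee
#' decision is the alpha-weighted vote
#' `G(x) = sign(sum_m alpha_m G_m(x))`; [predict_scores()] reports the
#' normalised weighted vote as a score in `[0, 1]`. Boosting stops early at
#' a perfect round or when a round is no better than chance.
#'
#' @param train_table numeric matrix of predictor columns (typically the
#'   output of [apply_feature_recipe()]).
#' @param labels binary labels (`ARMS` positive).
#' @param config an [ensemble_config()].
#' @return object of class `adaboost_rf`: weak learners, weights `alphas`,
#'   feature names, factor levels, config.
#' @export
fit_adaboost_rf <- function(train_table, labels, config = ensemble_config()) {
  X <- .as_feature_matrix(train_table)
  y <- .labels01(labels, nrow(X))
  if (length(unique(y)) < 2L)
    stop("both classes must be present to fit the ensemble")
  if (nrow(unique(X)) == 1L)
    stop("degenerate training data: all rows identical")
  feature_names <- colnames(X)
  safe <- paste0("f", seq_len(ncol(X)))
  df <- as.data.frame(X)
  colnames(df) <- safe
  mtry <- max(1L, floor(if (config$rf_max_features == "log2")
    log2(ncol(X)) else sqrt(ncol(X))))
  yf <- factor(y, levels = c(0L, 1L))
  n <- nrow(X)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  for (m in seq_len(config$n_estimators)) {
    rf <- ranger::ranger(x = df, y = yf, num.trees = config$rf_trees,
                         mtry = min(mtry, ncol(X)),
                         max.depth = config$rf_max_depth,
                         case.weights = w, num.threads = 1L,
                         seed = .derive_seed(config$seed, m),
                         verbose = FALSE)
    pred <- as.integer(as.character(
      stats::predict(rf, df, num.threads = 1L, verbose = FALSE)$predictions))
    miss <- pred != y
    err <- sum(w[miss])
    if (err <= 1e-12) {                      # perfect weak learner
      learners[[length(learners) + 1L]] <- rf
      alphas <- c(alphas, config$learning_rate * 0.5 * log((1 - 1e-12) / 1e-12))
      break
    }
    if (err >= 0.5) {
      if (!length(learners)) {               # keep one chance-level voter
        learners[[1L]] <- rf
        alphas <- 1e-8
      }
      break
    }
    alpha <- config$learning_rate * 0.5 * log((1 - err) / err)
    learners[[length(learners) + 1L]] <- rf
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(miss, 1, -1))
    w <- w / sum(w)
  }
  structure(list(learners = learners, alphas = alphas,
                 feature_names = feature_names, safe_names = safe,
                 config = config),
            class = "adaboost_rf")
}

#' @export
print.adaboost_rf <- function(x, ...) {
  cat(sprintf("adaboost_rf: %d weak learner(s) on %d feature(s); alpha in [%.3g, %.3g]\n",
              length(x$learners), length(x$feature_names),
              min(x$alphas), max(x$alphas)))
  invisible(x)
}

# resolve newdata to the model's feature columns, via the stored selection
# recipe and split references when the input is a base-feature table
.prepare_newdata <- function(model, newdata) {
  X <- .as_feature_matrix(newdata)
  if (!is.null(colnames(X)) && all(model$feature_names %in% colnames(X)))
    return(X[, model$feature_names, drop = FALSE])
  if (!is.null(model$recipe)) {
    if (inherits(newdata, "feature_table") && !is.null(model$references)) {
      q1 <- model$references$ear_q1
      bq <- which(newdata$manifest$statistic == "BELOW_Q1_PCT" &
                    newdata$manifest$signal == "ear")
      if (length(bq) && is.finite(q1))
        X[, bq] <- vapply(newdata$ear_series, below_reference_fraction,
                          numeric(1), reference = q1)
      med <- model$references$medians
      for (j in which(colSums(is.na(X)) > 0L)) X[is.na(X[, j]), j] <- med[j]
    }
    return(apply_feature_recipe(X, model$recipe))
  }
  stop("newdata does not provide the model's features and no recipe is stored")
}

#' Predict ensemble scores
#'
#' The normalised alpha-weighted vote for class ARMS,
#' `sum_m alpha_m [G_m(x) = ARMS] / sum_m alpha_m`, in `[0, 1]`; class ARMS
#' is called when the score exceeds 0.5.
#'
#' @param model an `adaboost_rf` fit.
#' @param newdata matrix with the model's feature columns, or a
#'   `feature_table` of base features when the model carries a selection
#'   recipe.
#' @return numeric score per row.
#' @export
predict_scores <- function(model, newdata) {
  stopifnot(inherits(model, "adaboost_rf"))
  X <- .prepare_newdata(model, newdata)
  df <- as.data.frame(X)
  colnames(df) <- model$safe_names
  votes <- vapply(model$learners, function(rf)
    as.numeric(as.character(
      stats::predict(rf, df, num.threads = 1L, verbose = FALSE)$predictions)),
    numeric(nrow(df)))
  if (nrow(df) == 1L) votes <- matrix(votes, nrow = 1L)
  as.numeric(votes %*% model$alphas) / sum(model$alphas)
}
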