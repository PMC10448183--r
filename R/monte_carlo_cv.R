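# evaluate expr under a local RNG state; global .Random.seed is restored
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Monte Carlo cross-validation of the full model
#'
#' Repeated stratified 70/30 evaluation (leave-group-out): each split draws
#' `floor(train_frac * n)` participants per class into training, recomputes
#' every data-dependent reference on the training rows only (pooled-EAR
#' first quartile, imputation medians), runs two-stage feature selection
#' ([select_features()]), fits the AdaBoost-over-random-forest ensemble and
#' scores the held-out rows. Metrics are summarised as mean, SD, max and min
#' over splits, with a vertically averaged ROC curve. No information flows
#' from any test row into references, selection or fitting.
#'
#' @param table a `feature_table` from [build_feature_table()].
#' @param n_splits number of random splits (default 100).
#' @param train_frac training fraction per class (default 0.7).
#' @param selection a [selection_config()].
#' @param ensemble an [ensemble_config()].
#' @param seed master seed; per-split seeds are derived from it.
#' @param importance_repeats if > 0, per-split permutation feature
#'   importance ([permutation_importance()]) with this many repeats is
#'   computed on the held-out rows and the F1 drops are summed per feature
#'   across splits (default 0, off).
#' @param threshold decision threshold (default 0.5).
#' @return object of class `mc_cv_result`: `summary` (data.frame metric x
#'   mean/sd/max/min), `per_split` (data.frame), `roc` (averaged curve),
#'   `importance` (summed F1 drops, or `NULL`), `selected` (list of
#'   per-split selected features), `seeds`, configs.
#' @export
monte_carlo_cv <- function(table, n_splits = 100L, train_frac = 0.7,
                           selection = selection_config(),
                           ensemble = ensemble_config(),
                           seed = 1L, importance_repeats = 0L,
                           threshold = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  y <- table$group
  n <- length(y)
  idx_by_class <- split(seq_len(n), y)
  n_train <- vapply(idx_by_class, function(ix) floor(train_frac * length(ix)),
                    numeric(1))
  if (any(n_train < 1L) || any(lengths(idx_by_class) - n_train < 1L))
    stop("a class is too small to stratify at this train_frac")
  per_split <- vector("list", n_splits)
  curves <- vector("list", n_splits)
  selected_all <- vector("list", n_splits)
  imp_sum <- NULL
  split_seeds <- vapply(seq_len(n_splits), function(s)
    .derive_seed(seed, s, 1L), integer(1))
  for (s in seq_len(n_splits)) {
    train_idx <- sort(unlist(.with_seed(split_seeds[s], lapply(
      names(idx_by_class), function(cl)
        sample(idx_by_class[[cl]], n_train[[cl]])))))
    test_idx <- setdiff(seq_len(n), train_idx)
    refs <- .apply_split_references(table, train_idx)
    ytr <- y[train_idx]; yte <- y[test_idx]
    sel_cfg <- selection
    sel_cfg$seed <- .derive_seed(seed, s, 2L)
    selected <- select_features(refs$X[train_idx, , drop = FALSE], ytr, sel_cfg)
    selected_all[[s]] <- selected
    Mtr <- apply_feature_recipe(refs$X[train_idx, , drop = FALSE], selected)
    Mte <- apply_feature_recipe(refs$X[test_idx, , drop = FALSE], selected)
    ens_cfg <- ensemble
    ens_cfg$seed <- .derive_seed(seed, s, 3L)
    model <- fit_adaboost_rf(Mtr, ytr, ens_cfg)
    scores <- predict_scores(model, Mte)
    met <- compute_metrics(yte, scores, threshold)
    per_split[[s]] <- data.frame(split = s, as.data.frame(met))
    curves[[s]] <- roc_curve(yte, scores)
    if (importance_repeats > 0L) {
      imp <- permutation_importance(model, Mte, yte,
                                    n_repeats = importance_repeats,
                                    seed = .derive_seed(seed, s, 4L),
                                    threshold = threshold)
      if (is.null(imp_sum)) imp_sum <- numeric(0)
      add <- setNames(imp$importance, imp$feature)
      new <- setdiff(names(add), names(imp_sum))
      imp_sum[new] <- 0
      imp_sum[names(add)] <- imp_sum[names(add)] + add
    }
  }
  per_split <- do.call(rbind, per_split)
  metrics <- c("f1", "specificity", "sensitivity", "balanced_accuracy",
               "roc_auc")
  summary <- do.call(rbind, lapply(metrics, function(mname) {
    v <- per_split[[mname]]
    data.frame(metric = mname, mean = mean(v, na.rm = TRUE),
               sd = sd(v, na.rm = TRUE), max = max(v, na.rm = TRUE),
               min = min(v, na.rm = TRUE))
  }))
  importance <- if (!is.null(imp_sum))
    data.frame(feature = names(sort(imp_sum, decreasing = TRUE)),
               summed_f1_drop = as.numeric(sort(imp_sum, decreasing = TRUE)))
  structure(list(summary = summary, per_split = per_split,
                 roc = mean_roc_curve(curves), importance = importance,
                 selected = selected_all, seeds = split_seeds,
                 selection = selection, ensemble = ensemble,
                 n_splits = n_splits, train_frac = train_frac, seed = seed),
            class = "mc_cv_result")
}

#' @export
print.mc_cv_result <- function(x, ...) {
  cat(sprintf("Monte Carlo cross-validation: %d splits, train fraction %.2f\n",
              x$n_splits, x$train_frac))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s mean %.3f  sd %.3f  max %.3f  min %.3f\n",
                s$metric[i], s$mean[i], s$sd[i], s$max[i], s$min[i]))
  invisible(x)
}

#' Permutation feature importance
#'
#' Mean drop in a held-out score (F1 by default) after randomly permuting
#' one feature's values across the test rows, repeated `n_repeats` times
#' per feature. Across cross-validation splits ([monte_carlo_cv()]) the
#' drops are summed per feature.
#'
#' @param model an `adaboost_rf` fit.
#' @param test_table matrix of the model's feature columns for held-out
#'   rows.
#' @param labels held-out labels.
#' @param n_repeats permutations per feature (default 100).
#' @param seed RNG seed for the permutations.
#' @param threshold decision threshold for F1 (default 0.5).
#' @return data.frame `feature`, `importance` (mean F1 drop), sorted
#'   descending.
#' @export
permutation_importance <- function(model, test_table, labels,
                                   n_repeats = 100L, seed = 1L,
                                   threshold = 0.5) {
  X <- .prepare_newdata(model, test_table)
  y <- .labels01(labels, nrow(X))
  if (nrow(X) < 2L) stop("need at least 2 test rows")
  base_f1 <- compute_metrics(y, predict_scores(model, X), threshold)$f1
  drops <- .with_seed(seed, vapply(seq_len(ncol(X)), function(j) {
    mean(vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, j] <- X[sample(nrow(X)), j]
      base_f1 - compute_metrics(y, predict_scores(model, Xp), threshold)$f1
    }, numeric(1)))
  }, numeric(1)))
  out <- data.frame(feature = colnames(X), importance = drops)
  out[order(-out$importance), , drop = FALSE]
}
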