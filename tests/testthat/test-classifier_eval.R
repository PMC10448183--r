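test_that("metric arithmetic: balanced accuracy, F1, perfect case", {
  expect_equal(balanced_accuracy(0.81, 0.89), 0.85)
  y <- factor(rep(c("ARMS", "CONTROL"), each = 4), levels = c("CONTROL", "ARMS"))
  s <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1)
  m <- compute_metrics(y, s)
  expect_equal(unlist(m), c(f1 = 1, specificity = 1, sensitivity = 1,
                            balanced_accuracy = 1, roc_auc = 1))
  # a mixed case, confusion counted by hand: threshold 0.5
  y2 <- factor(c("ARMS", "ARMS", "ARMS", "CONTROL", "CONTROL", "CONTROL"),
               levels = c("CONTROL", "ARMS"))
  s2 <- c(0.9, 0.4, 0.8, 0.6, 0.2, 0.3)   # TP=2 FN=1 FP=1 TN=2
  m2 <- compute_metrics(y2, s2)
  expect_equal(m2$sensitivity, 2 / 3)
  expect_equal(m2$specificity, 2 / 3)
  expect_equal(m2$f1, 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(m2$balanced_accuracy, (m2$sensitivity + m2$specificity) / 2)
})

test_that("rank AUC equals the concordant-pair count and is monotone-invariant", {
  y <- c(1, 1, 0, 0, 1, 0)
  s <- c(0.7, 0.4, 0.4, 0.1, 0.95, 0.5)
  pos <- s[y == 1]; neg <- s[y == 0]
  pairs <- expand.grid(p = pos, n = neg)
  oracle <- (sum(pairs$p > pairs$n) + 0.5 * sum(pairs$p == pairs$n)) /
    nrow(pairs)
  expect_equal(roc_auc(y, s), oracle)
  expect_equal(roc_auc(y, qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6))),
               roc_auc(y, s))
  expect_true(is.na(roc_auc(rep(1, 4), runif(4))))
  # cross-check against an independent implementation
  skip_if_not_installed("pROC")
  set.seed(31)
  y3 <- rbinom(40, 1, 0.5); s3 <- runif(40)
  expect_equal(roc_auc(y3, s3),
               as.numeric(suppressMessages(
                 pROC::auc(pROC::roc(y3, s3, levels = c(0, 1),
                                     direction = "<", quiet = TRUE)))))
})

test_that("ROC curves pass the endpoints and average consistently", {
  y <- rep(c(1, 0), 10)
  set.seed(2)
  curves <- lapply(1:5, function(i) roc_curve(y, runif(20)))
  for (cv in curves) {
    expect_equal(cv[1, ], data.frame(fpr = 0, tpr = 0))
    expect_equal(unlist(cv[nrow(cv), ]), c(fpr = 1, tpr = 1))
  }
  avg <- mean_roc_curve(curves)
  expect_equal(avg$tpr_mean[1], 0)
  expect_equal(avg$tpr_mean[101], 1)
  same <- mean_roc_curve(list(curves[[1]], curves[[1]], curves[[1]]))
  expect_true(all(same$tpr_sd == 0))
  # trapezoid on the mean curve stays within one sd of the mean of AUCs
  set.seed(4)
  ys <- lapply(1:8, function(i) rbinom(30, 1, 0.5))
  ss <- lapply(1:8, function(i) runif(30))
  aucs <- mapply(roc_auc, ys, ss)
  m <- mean_roc_curve(mapply(roc_curve, ys, ss, SIMPLIFY = FALSE))
  trap <- sum(diff(m$fpr) * (head(m$tpr_mean, -1) + tail(m$tpr_mean, -1)) / 2)
  expect_lt(abs(trap - mean(aucs)), max(sd(aucs), 0.05))
})

test_that("AdaBoost-RF separates separable data and is seed-deterministic", {
  ft <- fake_feature_table(n_arms = 15, n_controls = 15, p = 6,
                           n_informative = 2, delta = 4, seed = 3)
  cfg <- ensemble_config(n_estimators = 30, seed = 42)
  model <- fit_adaboost_rf(ft$X, ft$group, cfg)
  s <- predict_scores(model, ft$X)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(as.integer(s > 0.5), as.integer(ft$group == "ARMS"))
  # identical seed/data -> identical predictions; different seed differs
  model2 <- fit_adaboost_rf(ft$X, ft$group, cfg)
  expect_identical(predict_scores(model2, ft$X), s)
  expect_identical(s, predict_scores(model, ft$X))
  expect_error(fit_adaboost_rf(ft$X, factor(rep("ARMS", 30),
                                            levels = c("CONTROL", "ARMS"))),
               "both classes")
  Xd <- ft$X
  Xd[] <- 1
  expect_error(fit_adaboost_rf(Xd, ft$group), "degenerate")
})

test_that("label permutation drives held-out performance to chance", {
  set.seed(17)
  ft <- fake_feature_table(n_arms = 30, n_controls = 30, p = 8,
                           n_informative = 2, delta = 3, seed = 8)
  yperm <- sample(ft$group)
  tr <- c(1:20, 31:50)
  te <- setdiff(1:60, tr)
  model <- fit_adaboost_rf(ft$X[tr, ], yperm[tr],
                           ensemble_config(n_estimators = 40, seed = 5))
  auc <- compute_metrics(yperm[te], predict_scores(model, ft$X[te, ]))$roc_auc
  expect_gt(auc, 0.2)
  expect_lt(auc, 0.8)
})

test_that("Monte Carlo CV stratifies, summarises, and reproduces", {
  ft <- fake_feature_table(n_arms = 12, n_controls = 14, p = 10,
                           n_informative = 2, delta = 2.5, seed = 2)
  sel <- selection_config(stage1_top_m = 6, final_top_k = 4, nrounds = 25)
  ens <- ensemble_config(n_estimators = 15)
  cv <- monte_carlo_cv(ft, n_splits = 6, selection = sel, ensemble = ens,
                       seed = 99)
  expect_equal(nrow(cv$per_split), 6L)
  # balanced accuracy identity holds per split to machine precision
  expect_equal(cv$per_split$balanced_accuracy,
               (cv$per_split$sensitivity + cv$per_split$specificity) / 2)
  # summary ordering
  expect_true(all(cv$summary$max >= cv$summary$mean - 1e-12))
  expect_true(all(cv$summary$mean >= cv$summary$min - 1e-12))
  # reproducibility from the master seed
  cv2 <- monte_carlo_cv(ft, n_splits = 6, selection = sel, ensemble = ens,
                        seed = 99)
  expect_identical(cv$summary, cv2$summary)
  expect_identical(cv$selected, cv2$selected)
  expect_error(monte_carlo_cv(ft, train_frac = 0.05), "stratify")
})

test_that("no test-row information reaches selection or the fitted model", {
  ft <- fake_feature_table(n_arms = 12, n_controls = 14, p = 10,
                           n_informative = 2, delta = 2.5, seed = 6)
  n <- length(ft$group)
  seed <- 123
  # reconstruct split 1's training rows the way the CV loop draws them
  idx_by_class <- split(seq_len(n), ft$group)
  train_idx <- sort(unlist(facekin:::.with_seed(
    facekin:::.derive_seed(seed, 1L, 1L),
    lapply(names(idx_by_class), function(cl)
      sample(idx_by_class[[cl]], floor(0.7 * length(idx_by_class[[cl]])))))))
  test_idx <- setdiff(seq_len(n), train_idx)
  ft_mut <- ft
  ft_mut$X[test_idx, ] <- ft_mut$X[test_idx, ] * 50 + 1000
  ft_mut$ear_series[test_idx] <- lapply(ft_mut$ear_series[test_idx], `*`, 5)
  sel <- selection_config(stage1_top_m = 6, final_top_k = 4, nrounds = 25)
  ens <- ensemble_config(n_estimators = 10)
  cv_a <- monte_carlo_cv(ft, n_splits = 1, selection = sel, ensemble = ens,
                         seed = seed)
  cv_b <- monte_carlo_cv(ft_mut, n_splits = 1, selection = sel,
                         ensemble = ens, seed = seed)
  expect_identical(cv_a$selected, cv_b$selected)
  refs_a <- facekin:::.apply_split_references(ft, train_idx)
  refs_b <- facekin:::.apply_split_references(ft_mut, train_idx)
  expect_identical(refs_a$X[train_idx, ], refs_b$X[train_idx, ])
})

test_that("permutation importance isolates the informative feature", {
  ft <- fake_feature_table(n_arms = 14, n_controls = 14, p = 4,
                           n_informative = 1, delta = 4, seed = 10)
  X <- cbind(ft$X, dead = 0)   # a constant column the stumps can never use
  model <- fit_adaboost_rf(X, ft$group,
                           ensemble_config(n_estimators = 20, seed = 2))
  imp <- permutation_importance(model, X, ft$group, n_repeats = 10, seed = 4)
  expect_equal(imp$importance[imp$feature == "dead"], 0)
  expect_equal(imp$feature[1], "feat_1")
  expect_gt(imp$importance[1], max(imp$importance[-1]))
  imp2 <- permutation_importance(model, X, ft$group, n_repeats = 10, seed = 4)
  expect_identical(imp, imp2)
})
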