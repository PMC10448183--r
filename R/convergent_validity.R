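#' Dichotomize a SIPS symptom item
#'
#' Scores 0-1 become `absent`, 2-6 `present`; missing stays missing.
#'
#' @param scores integer scores in `[0, 6]` (NAs allowed).
#' @return factor with levels `absent`, `present`.
#' @export
dichotomize_symptom <- function(scores) {
  ok <- is.na(scores) | (scores >= 0 & scores <= 6)
  if (!all(ok)) stop("SIPS scores must lie in [0, 6]")
  factor(ifelse(is.na(scores), NA, ifelse(scores >= 2, "present", "absent")),
         levels = c("absent", "present"))
}

#' Wilcoxon rank-sum test of a feature between two groups
#'
#' Two-sided rank-sum test that the feature values of the two groups are
#' drawn from the same distribution. The p-value uses the tie-corrected
#' normal approximation of the Mann-Whitney U statistic; when both groups
#' have at most `exact_max` observations and there are no ties, the exact
#' null distribution is used instead. Per-group means with normal-theory
#' (t) 95% confidence intervals accompany the test for trend displays.
#'
#' @param feature_values numeric vector.
#' @param groups binary factor/vector aligned with `feature_values`;
#'   pairs with missing values are dropped.
#' @param exact_max largest per-group size for the exact null (default 12).
#' @return object of class `validity_result`: a one-row data.frame with
#'   `n_a`, `n_b`, `statistic` (U of the first group), `p_value`,
#'   `mean_a`, `ci_lo_a`, `ci_hi_a`, `mean_b`, `ci_lo_b`, `ci_hi_b`.
#' @export
ranksum_test <- function(feature_values, groups, exact_max = 12L) {
  ok <- !is.na(feature_values) & !is.na(groups)
  x <- feature_values[ok]
  g <- factor(groups[ok])
  if (nlevels(g) != 2L || any(table(g) < 2L))
    stop("need two groups with at least 2 non-missing values each")
  lev <- levels(g)
  xa <- x[g == lev[1]]; xb <- x[g == lev[2]]
  n1 <- length(xa); n2 <- length(xb); N <- n1 + n2
  r <- rank(x)
  U <- sum(r[g == lev[1]]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(x) > 0L
  if (!has_ties && n1 <= exact_max && n2 <= exact_max) {
    p <- 2 * min(pwilcox(U, n1, n2), 1 - pwilcox(U - 1, n1, n2))
  } else {
    mu <- n1 * n2 / 2
    ties <- table(x)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
    p <- 2 * pnorm(-abs(z))
  }
  p <- min(p, 1)
  ci <- function(v) {
    m <- mean(v)
    half <- qt(0.975, length(v) - 1L) * sd(v) / sqrt(length(v))
    c(m, m - half, m + half)
  }
  ca <- ci(xa); cb <- ci(xb)
  structure(data.frame(n_a = n1, n_b = n2, statistic = U, p_value = p,
                       mean_a = ca[1], ci_lo_a = ca[2], ci_hi_a = ca[3],
                       mean_b = cb[1], ci_lo_b = cb[2], ci_hi_b = cb[3]),
            class = c("validity_result", "data.frame"))
}

#' Convergent validity of features against symptom items
#'
#' For each requested feature and SIPS negative item, dichotomizes the item
#' (absence 0-1 vs presence >= 2) and rank-sum tests the feature between the
#' two symptom groups. P-values are reported per feature-item pair without
#' multiple-testing correction, matching per-feature reporting; set
#' `adjust = "BH"` for Benjamini-Hochberg adjusted values in an extra
#' column.
#'
#' @param table a `feature_table` (with `labels` carrying the items) or a
#'   participants x features matrix.
#' @param labels labels data.frame with `participant_id` and the item
#'   columns; defaults to the table's own labels.
#' @param features character vector of feature names (base names or
#'   `"<a> * <b>"` products resolved via [apply_feature_recipe()]).
#' @param items item column names (default the `N1..N6` columns present).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame, one row per feature x item, with the
#'   [ranksum_test()] columns; pairs whose dichotomy leaves a group with
#'   fewer than 2 observations come back as `NA` rows with a warning.
#' @export
validity_table <- function(table, features, labels = NULL, items = NULL,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(labels)) {
    stopifnot(inherits(table, "feature_table"))
    labels <- table$labels
  }
  if (is.null(items))
    items <- grep("^N[1-6]$", names(labels), value = TRUE)
  if (!length(items)) stop("no symptom item columns found")
  M <- apply_feature_recipe(table, features)
  rows <- list()
  na_row <- function() {
    out <- data.frame(n_a = NA_integer_, n_b = NA_integer_,
                      statistic = NA_real_, p_value = NA_real_,
                      mean_a = NA_real_, ci_lo_a = NA_real_,
                      ci_hi_a = NA_real_, mean_b = NA_real_,
                      ci_lo_b = NA_real_, ci_hi_b = NA_real_)
    out
  }
  for (it in items) {
    grp <- dichotomize_symptom(labels[[it]])
    for (k in seq_along(features)) {
      res <- tryCatch(ranksum_test(M[, k], grp), error = function(e) {
        warning(sprintf("%s vs %s not testable: %s", features[k], it,
                        conditionMessage(e)), call. = FALSE)
        na_row()
      })
      rows[[length(rows) + 1L]] <-
        data.frame(feature = features[k], item = it, res)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}
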