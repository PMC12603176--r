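#' Relative concentration difference between two groups
#'
#' Signed percent difference of group means against their average:
#' `100 * (mean(g2) - mean(g1)) / ((mean(g1) + mean(g2)) / 2)`. The
#' symmetric-mean denominator allows magnitudes above 100 (a metabolite
#' all-but-absent in one group approaches +/-200). Negative values mean
#' the second-listed group has the lower level. Computed on
#' pre-adjustment concentrations, as a descriptive contrast.
#'
#' @param values_g1 concentrations of the first-listed group.
#' @param values_g2 concentrations of the second-listed group.
#' @return Delta percent; NA with a warning when the symmetric mean is
#'   not positive.
#' @export
delta_percent <- function(values_g1, values_g2) {
  m1 <- mean(values_g1, na.rm = TRUE)
  m2 <- mean(values_g2, na.rm = TRUE)
  denom <- (m1 + m2) / 2
  if (!is.finite(denom) || denom <= 0) {
    warning("delta_percent undefined: non-positive mean denominator")
    return(NA_real_)
  }
  100 * (m2 - m1) / denom
}

#' Mann-Whitney U test between two groups
#'
#' The U statistic counts, over all cross-group pairs, the pairs where the
#' first group's value is larger (ties count 0.5). The two-sided p-value
#' comes from the exact distribution when both samples are small and
#' untied, otherwise from the normal approximation with tie and continuity
#' correction; the method used is recorded.
#'
#' @param values_g1,values_g2 numeric vectors, each with >= 1 value.
#' @return list with `U` (orientation: g1 greater), `p` (two-sided) and
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
mwu_test <- function(values_g1, values_g2) {
  x <- values_g1[!is.na(values_g1)]
  y <- values_g2[!is.na(values_g2)]
  stopifnot(length(x) >= 1, length(y) >= 1)
  U <- sum(vapply(x, function(xi) {
    sum((xi > y) + 0.5 * (xi == y))
  }, numeric(1)))
  ties <- any(duplicated(c(x, y)))
  exact_ok <- !ties && length(x) < 50 && length(y) < 50
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact_ok,
                       correct = TRUE)
  )
  list(U = U, p = unname(wt$p.value),
       method = if (exact_ok) "exact" else "normal_approx")
}

#' ROC-AUC between two groups
#'
#' Direction-free discrimination: `AUC = max(U, n1*n2 - U) / (n1*n2)`,
#' the probability that a randomly drawn pair is correctly ordered by the
#' better-ordered direction, so the value is always in [0.5, 1]. Ties
#' contribute 0.5. The raw direction is recoverable from the sign of
#' [delta_percent()].
#'
#' @param values_g1,values_g2 numeric vectors, each with >= 1 value.
#' @return AUC in [0.5, 1].
#' @export
roc_auc <- function(values_g1, values_g2) {
  x <- values_g1[!is.na(values_g1)]
  y <- values_g2[!is.na(values_g2)]
  U <- mwu_test(x, y)$U
  n12 <- length(x) * length(y)
  max(U, n12 - U) / n12
}

#' Bonferroni significance flag
#'
#' @param p p-value in (0, 1].
#' @param n_tests number of tests in the family — the number of
#'   metabolites tested after QC (e.g. 181), not the number selected.
#' @param alpha family-wise level.
#' @return `TRUE` iff `p < alpha / n_tests`.
#' @export
bonferroni_flag <- function(p, n_tests, alpha = 0.05) {
  stopifnot(all(p > 0), all(p <= 1), n_tests >= 1)
  p < alpha / n_tests
}

#' Random-forest evaluation of a selected metabolite set
#'
#' Grows a 1,000-tree classification forest on the selected features only
#' and reports the Mean Decrease Gini importance per metabolite, the
#' out-of-bag error (fraction of samples misclassified by out-of-bag
#' votes), and the misclassified sample ids.
#'
#' @param X_selected numeric matrix, samples x selected metabolites
#'   (residuals), no NA.
#' @param y group labels.
#' @param n_trees number of trees (default 1000).
#' @param seed integer seed.
#' @return list with `mdg` (named numeric), `oob_error`, `misclassified`
#'   (sample ids from rownames of `X_selected`), and `confusion`.
#' @export
rf_evaluate <- function(X_selected, y, n_trees = 1000, seed = 0L) {
  X_selected <- as.matrix(X_selected)
  stopifnot(ncol(X_selected) >= 1)
  if (any(!is.finite(X_selected))) {
    stop("X_selected contains NA or non-finite values", call. = FALSE)
  }
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need >= 2 classes", call. = FALSE)
  if (any(apply(X_selected, 2, stats::sd) == 0)) {
    warning("constant feature(s) in the selected set; their MDG will be 0")
  }
  fit <- withr::with_seed(seed, randomForest::randomForest(
    x = as.data.frame(X_selected), y = y, ntree = n_trees
  ))
  pred <- fit$predicted   # OOB predictions
  wrong <- which(pred != y)
  ids <- rownames(X_selected)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X_selected)))
  list(
    mdg = fit$importance[, "MeanDecreaseGini"],
    oob_error = length(wrong) / length(y),
    misclassified = ids[wrong],
    confusion = fit$confusion
  )
}

#' Within-group Pearson correlation screen
#'
#' Pearson correlations between all pairs of the selected metabolites,
#' computed within one group's samples; pairs with `|r| >=` the threshold
#' are flagged regardless of their p-value.
#'
#' @param residuals a `ResidualMatrix`.
#' @param metabolites character vector of metabolite names (>= 2).
#' @param group single group label with >= 3 samples.
#' @param flag_threshold absolute correlation at or above which a pair is
#'   flagged.
#' @return list with `r` (symmetric correlation matrix, unit diagonal; NA
#'   rows/columns for constant metabolites), `flagged` (logical matrix),
#'   and `pairs` (data.frame of flagged off-diagonal pairs).
#' @export
within_group_correlations <- function(residuals, metabolites, group,
                                      flag_threshold = 0.5) {
  stopifnot(inherits(residuals, "ResidualMatrix"), length(metabolites) >= 2)
  keep <- residuals$sample_meta$group == group
  if (sum(keep) < 3) {
    stop("group '", group, "' has fewer than 3 samples", call. = FALSE)
  }
  miss <- setdiff(metabolites, colnames(residuals$residuals))
  if (length(miss) > 0) {
    stop("unknown metabolite(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- residuals$residuals[keep, metabolites, drop = FALSE]
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  diag(r) <- ifelse(apply(X, 2, function(v) {
    stats::sd(v, na.rm = TRUE) > 0
  }), 1, NA_real_)
  flagged <- !is.na(r) & abs(r) >= flag_threshold
  diag(flagged) <- FALSE
  idx <- which(flagged & upper.tri(flagged), arr.ind = TRUE)
  pairs <- data.frame(
    metabolite_1 = rownames(r)[idx[, 1]],
    metabolite_2 = colnames(r)[idx[, 2]],
    r = r[idx],
    stringsAsFactors = FALSE
  )
  list(r = r, flagged = flagged, pairs = pairs)
}

#' Evaluate the selected metabolites of a pairwise comparison
#'
#' Builds the per-metabolite results table — Delta% on raw concentrations,
#' Mean Decrease Gini from the 1,000-tree forest, ROC-AUC, Mann-Whitney U
#' and p, Bonferroni flag at `alpha / n_tests`, and the stability
#' category — together with the forest-level out-of-bag error and
#' misclassified samples. Rank-based statistics and the forest run on
#' residuals; Delta% is a descriptive contrast of concentrations.
#'
#' @param panel the cleaned `MetabolitePanel` (concentration scale, for
#'   Delta%).
#' @param residuals the `ResidualMatrix` of the cleaned panel.
#' @param stability a `StabilityReport` for the comparison.
#' @param comparison a pairwise [comparison_spec()].
#' @param selection which reliability level counts as selected
#'   (reliable-or-better by default).
#' @param n_tests Bonferroni family size; defaults to the number of
#'   metabolites in the cleaned panel.
#' @param alpha family-wise significance level.
#' @param n_trees evaluation forest size.
#' @param seed seed for the evaluation forest.
#' @return object of class `EvaluationTable`: `metabolites` data.frame
#'   sorted by decreasing MDG, `oob_error`, `misclassified`, `n_tests`,
#'   `alpha`, and the comparison label.
#' @export
evaluate_comparison <- function(panel, residuals, stability, comparison,
                                selection = c("moderately_reliable",
                                              "highly_reliable"),
                                n_tests = NULL, alpha = 0.05,
                                n_trees = 1000, seed = 0L) {
  stopifnot(comparison$mode == "pairwise")
  selection <- match.arg(selection)
  selected <- reliable_set(stability, selection)
  if (length(selected) == 0) {
    return(structure(list(
      metabolites = data.frame(), oob_error = NA_real_,
      misclassified = character(0),
      n_tests = n_tests %||% ncol(panel$concentrations), alpha = alpha,
      comparison = comparison_label(comparison)
    ), class = "EvaluationTable"))
  }
  if (is.null(n_tests)) n_tests <- ncol(panel$concentrations)
  cm <- comparison_matrix(residuals, comparison)
  sm <- panel$sample_meta
  g1 <- comparison$groups[1]
  g2 <- comparison$groups[2]
  rows1 <- which(!sm$is_qc & sm$group == g1)
  rows2 <- which(!sm$is_qc & sm$group == g2)
  res1 <- cm$X[cm$y == g1, , drop = FALSE]
  res2 <- cm$X[cm$y == g2, , drop = FALSE]

  per_met <- lapply(selected, function(m) {
    mw <- mwu_test(res1[, m], res2[, m])
    data.frame(
      metabolite = m,
      analyte_class = panel$metabolite_meta$analyte_class[
        match(m, panel$metabolite_meta$name)],
      delta_percent = delta_percent(panel$concentrations[rows1, m],
                                    panel$concentrations[rows2, m]),
      auc = roc_auc(res1[, m], res2[, m]),
      mwu_U = mw$U,
      mwu_p = mw$p,
      mwu_method = mw$method,
      bonferroni_significant = bonferroni_flag(mw$p, n_tests, alpha),
      reliability_category = stability$metabolites$category[
        match(m, stability$metabolites$name)],
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, per_met)
  rf <- rf_evaluate(cm$X[, selected, drop = FALSE], cm$y,
                    n_trees = n_trees, seed = seed)
  tab$mdg <- unname(rf$mdg[tab$metabolite])
  tab <- tab[order(-tab$mdg, tab$metabolite), ]
  rownames(tab) <- NULL
  tab <- tab[, c("metabolite", "analyte_class", "delta_percent", "mdg",
                 "auc", "mwu_U", "mwu_p", "mwu_method",
                 "bonferroni_significant", "reliability_category")]
  structure(list(
    metabolites = tab,
    oob_error = rf$oob_error,
    misclassified = rf$misclassified,
    n_tests = n_tests,
    alpha = alpha,
    comparison = comparison_label(comparison)
  ), class = "EvaluationTable")
}

#' @export
print.EvaluationTable <- function(x, ...) {
  cat("EvaluationTable [", x$comparison, "]: ", nrow(x$metabolites),
      " selected metabolites\n", sep = "")
  if (!is.na(x$oob_error)) {
    cat(sprintf("OOB error: %.1f%% (%d misclassified)\n",
                100 * x$oob_error, length(x$misclassified)))
  }
  if (nrow(x$metabolites) > 0) {
    print(utils::head(x$metabolites[, c("metabolite", "delta_percent",
                                        "mdg", "auc", "mwu_p")], 10))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
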