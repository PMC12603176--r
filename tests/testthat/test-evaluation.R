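test_that("delta percent matches the symmetric-mean formula", {
  expect_equal(delta_percent(c(2, 2), c(2, 2)), 0)
  expect_equal(delta_percent(c(2, 2, 2), c(1, 1, 1)), -66.66667,
               tolerance = 1e-6)
  expect_equal(delta_percent(c(1, 1), c(3, 3)), 100)
  # magnitudes can exceed 100 when one group is near zero
  expect_gt(abs(delta_percent(c(10, 10), c(0.1, 0.1))), 100)
  expect_warning(out <- delta_percent(c(0, 0), c(0, 0)), "undefined")
  expect_true(is.na(out))
})

test_that("delta percent is exactly antisymmetric in group order", {
  withr::with_seed(8, {
    for (i in 1:20) {
      a <- rexp(sample(3:10, 1), 1 / 10)
      b <- rexp(sample(3:10, 1), 1 / 10)
      expect_equal(delta_percent(a, b), -delta_percent(b, a))
    }
  })
})

test_that("U statistic matches brute-force pair counting", {
  expect_equal(mwu_test(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mwu_test(c(4, 5, 6), c(1, 2, 3))$U, 9)
  expect_equal(mwu_test(c(1, 3), c(2, 4))$U, 1)
  # identical multisets: all information is in ties
  expect_equal(mwu_test(c(1, 2, 3), c(1, 2, 3))$U, 4.5)
})

test_that("exact p-values agree with exhaustive enumeration", {
  g1 <- c(1, 2, 3); g2 <- c(4, 5, 6)
  out <- mwu_test(g1, g2)
  expect_equal(out$method, "exact")
  expect_equal(out$p, 0.1)
  expect_equal(out$p, enumerate_mwu_p(g1, g2))
  withr::with_seed(15, {
    for (i in 1:10) {
      a <- rnorm(4); b <- rnorm(5)  # continuous: no ties
      out <- mwu_test(a, b)
      expect_equal(out$method, "exact")
      expect_equal(out$p, enumerate_mwu_p(a, b), tolerance = 1e-12)
    }
  })
})

test_that("p-values are invariant under strictly monotone transforms", {
  withr::with_seed(23, {
    a <- rexp(8); b <- rexp(6) + 0.3
    p0 <- mwu_test(a, b)$p
    expect_equal(mwu_test(exp(a), exp(b))$p, p0)
    expect_equal(mwu_test(log(a), log(b))$p, p0)
    r <- rank(c(a, b))
    expect_equal(mwu_test(r[1:8], r[9:14])$p, p0)
  })
})

test_that("AUC is the normalized direction-free U", {
  expect_equal(roc_auc(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(roc_auc(c(1, 3), c(2, 4)), 0.75)
  expect_equal(roc_auc(c(5, 5), c(5, 5)), 0.5)
  withr::with_seed(31, {
    for (i in 1:25) {
      a <- rnorm(sample(2:8, 1))
      b <- rnorm(sample(2:8, 1), sample(0:2, 1))
      U <- mwu_test(a, b)$U
      n12 <- length(a) * length(b)
      expect_equal(roc_auc(a, b) * n12, max(U, n12 - U))
      expect_gte(roc_auc(a, b), 0.5)
      expect_lte(roc_auc(a, b), 1)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(37, {
    for (i in 1:10) {
      a <- rnorm(10); b <- rnorm(12, 1)
      ref <- as.numeric(suppressMessages(
        pROC::auc(rep(c(0, 1), c(10, 12)), c(a, b))))
      expect_equal(roc_auc(a, b), max(ref, 1 - ref), tolerance = 1e-12)
    }
  })
})

test_that("Bonferroni flag applies the family-size threshold", {
  expect_false(bonferroni_flag(1, 10))
  expect_true(bonferroni_flag(1.5e-6, 181))    # threshold 0.05/181
  expect_false(bonferroni_flag(2.8e-4, 181))   # 2.8e-4 > 2.7624e-4
  expect_true(bonferroni_flag(2.7e-4, 181))
  expect_true(bonferroni_flag(0.04, 1))
  # invariant to anything but (p, n_tests, alpha)
  expect_identical(bonferroni_flag(c(1e-5, 0.2, 1), 181),
                   c(TRUE, FALSE, FALSE))
})

test_that("the evaluation forest separates strong signal and not noise", {
  # near-separable construction: 3 features with 5-sd class separation
  withr::with_seed(61, {
    n <- 24
    X <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(paste0("s", 1:n), paste0("m", 1:8)))
    y <- factor(rep(c("A", "B"), each = 12))
    X[y == "B", 1:3] <- X[y == "B", 1:3] + 5
  })
  oob <- vapply(1:10, function(s) {
    rf_evaluate(X, y, n_trees = 500, seed = s)$oob_error
  }, numeric(1))
  expect_lte(max(oob), 0.05)
  # permuted labels: chance-level error around 0.5
  oob_null <- vapply(1:10, function(s) {
    y_perm <- withr::with_seed(1000 + s, sample(y))
    rf_evaluate(X, y_perm, n_trees = 300, seed = s)$oob_error
  }, numeric(1))
  expect_gte(mean(oob_null), 0.35)
  expect_lte(mean(oob_null), 0.65)
})

test_that("misclassified ids and OOB error are consistent", {
  pm <- planted_matrix(n_per_group = 10, n_noise = 2, shift = 3, seed = 5)
  rownames(pm$X) <- paste0("s", 1:20)
  out <- rf_evaluate(pm$X, pm$y, n_trees = 300, seed = 1)
  expect_equal(out$oob_error, length(out$misclassified) / 20)
  expect_true(all(out$misclassified %in% rownames(pm$X)))
  expect_equal(sort(names(out$mdg)), sort(colnames(pm$X)))
  expect_true(all(out$mdg >= 0))
})

test_that("within-group correlations flag real linear structure", {
  withr::with_seed(41, {
    n <- 200
    x <- rnorm(n)
    anti <- -0.8 * x + sqrt(1 - 0.64) * rnorm(n)
    mat <- cbind(m_x = x, m_double = 2 * x, m_anti = anti,
                 m_indep = rnorm(n))
    rownames(mat) <- paste0("s", 1:n)
    res <- fake_residuals(mat, group = rep("A", n))
    out <- within_group_correlations(res, colnames(mat), "A")
    expect_equal(diag(out$r), rep(1, 4), ignore_attr = TRUE)
    expect_equal(out$r, t(out$r))
    expect_equal(out$r["m_x", "m_double"], 1, tolerance = 1e-12)
    expect_true(out$flagged["m_x", "m_double"])
    expect_lt(out$r["m_x", "m_anti"], -0.5)
    expect_true(out$flagged["m_x", "m_anti"])
    expect_false(out$flagged["m_x", "m_indep"])
    # constant metabolite gives NA correlations, never a flag
    mat2 <- cbind(mat, m_const = rep(1, n))
    res2 <- fake_residuals(mat2, group = rep("A", n))
    out2 <- suppressWarnings(
      within_group_correlations(res2, colnames(mat2), "A"))
    expect_true(all(is.na(out2$r["m_const", ])))
    expect_false(any(out2$flagged["m_const", ]))
  })
})

test_that("pairwise evaluation assembles the results table", {
  sf <- strong_fixture()
  st <- strong_small_validation()
  ev <- evaluate_comparison(sf$clean, sf$residuals, st, sf$comparison,
                            n_trees = 500, seed = 1)
  tab <- ev$metabolites
  expect_gt(nrow(tab), 0)
  expect_setequal(tab$metabolite, reliable_set(st))
  # MDG-sorted, all AUC in [0.5, 1], Bonferroni consistent with p
  expect_true(all(diff(tab$mdg) <= 0))
  expect_true(all(tab$auc >= 0.5 & tab$auc <= 1))
  expect_identical(tab$bonferroni_significant,
                   tab$mwu_p < ev$alpha / ev$n_tests)
  expect_equal(ev$n_tests, ncol(sf$clean$concentrations))
  expect_equal(ev$oob_error,
               length(ev$misclassified) /
                 sum(!sf$clean$sample_meta$is_qc))
})
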