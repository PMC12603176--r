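# Panel builder with controllable QC rows and LODs.
qc_panel <- function(values, qc_values, lod = 0, extra_noise = 3,
                     seed = 11) {
  withr::with_seed(seed, {
    n <- length(values)
    conc <- cbind(target = values,
                  matrix(abs(rnorm(n * extra_noise, 10, 1)), n,
                         dimnames = list(NULL,
                                         paste0("stable", 1:extra_noise))))
    qc <- cbind(target = qc_values,
                matrix(10, length(qc_values), extra_noise,
                       dimnames = list(NULL,
                                       paste0("stable", 1:extra_noise))))
    all <- rbind(conc, qc)
    rownames(all) <- c(paste0("s", 1:n), paste0("QC_", seq_along(qc_values)))
    sm <- data.frame(
      sample_id = rownames(all),
      group = c(rep(c("A", "B"), length.out = n), rep("QC",
                                                      length(qc_values))),
      sex = "gilt",
      carcass_weight = 100,
      is_qc = c(rep(FALSE, n), rep(TRUE, length(qc_values))),
      stringsAsFactors = FALSE)
    mm <- data.frame(name = colnames(all), analyte_class = "AA",
                     lod = c(lod, rep(0, extra_noise)),
                     stringsAsFactors = FALSE)
    metabolite_panel(all, sm, mm)
  })
}

test_that("replicate CV follows the direct formula", {
  expect_equal(compute_cv(c(5, 5)), 0)
  expect_equal(compute_cv(c(10, 12)), 100 * sd(c(10, 12)) / 11)
  expect_equal(compute_cv(c(10, 12)), 12.85649, tolerance = 1e-6)
  expect_error(compute_cv(c(5)), "fewer than 2")
  expect_error(compute_cv(c(NA, 5)), "fewer than 2")
  expect_error(compute_cv(c(0, 0)), "mean is zero")
})

test_that("high-CV metabolites are excluded with reason CV", {
  # replicates 10 vs 16 give CV ~31% > 20%
  p <- qc_panel(values = rep(10, 10), qc_values = c(10, 16))
  out <- apply_filters(p)
  rep_row <- out$report$metabolites[out$report$metabolites$name == "target", ]
  expect_true(rep_row$excluded)
  expect_equal(rep_row$reason, "CV")
  expect_gt(rep_row$cv_percent, 20)
  expect_false("target" %in% out$panel$metabolite_meta$name)
})

test_that("below-LOD sample fraction rule uses a strict 30% threshold", {
  # 4 of 10 samples below LOD = 40% > 30% -> excluded
  v <- c(rep(0.5, 4), rep(5, 6))
  p <- qc_panel(values = v, qc_values = c(5, 5.2), lod = 1)
  out <- apply_filters(p)
  rep_row <- out$report$metabolites[out$report$metabolites$name == "target", ]
  expect_equal(rep_row$frac_below_lod_samples, 0.4)
  expect_equal(rep_row$reason, "LOD_SAMPLES")
  # exactly 30% is not an exclusion
  v2 <- c(rep(0.5, 3), rep(5, 7))
  out2 <- apply_filters(qc_panel(values = v2, qc_values = c(5, 5.2),
                                 lod = 1))
  expect_equal(
    out2$report$metabolites$reason[out2$report$metabolites$name == "target"],
    "none")
})

test_that("below-LOD across QC replicates is its own exclusion reason", {
  p <- qc_panel(values = rep(5, 10), qc_values = c(0.5, 0.6), lod = 1)
  out <- apply_filters(p)
  expect_equal(
    out$report$metabolites$reason[out$report$metabolites$name == "target"],
    "LOD_QC")
  # with rule "all", one replicate above LOD rescues the metabolite
  p2 <- qc_panel(values = rep(5, 10), qc_values = c(0.5, 1.4), lod = 1)
  out_all <- apply_filters(p2, qc_thresholds(cv_max = Inf,
                                             lod_qc_rule = "all"))
  expect_equal(
    out_all$report$metabolites$reason[
      out_all$report$metabolites$name == "target"], "none")
  out_any <- apply_filters(p2, qc_thresholds(cv_max = Inf,
                                             lod_qc_rule = "any"))
  expect_equal(
    out_any$report$metabolites$reason[
      out_any$report$metabolites$name == "target"], "LOD_QC")
})

test_that("NA/zero rate rule and rule precedence behave as documented", {
  v <- c(rep(NA, 2), rep(0, 2), rep(5, 6))  # 40% NA-or-zero
  p <- qc_panel(values = v, qc_values = c(5, 5.1))
  out <- apply_filters(p)
  rep_row <- out$report$metabolites[out$report$metabolites$name == "target", ]
  expect_equal(rep_row$frac_na_zero, 0.4)
  expect_equal(rep_row$reason, "NA_ZERO")
  # CV failure takes precedence over a simultaneous LOD_QC failure
  p2 <- qc_panel(values = rep(5, 10), qc_values = c(0.2, 0.9), lod = 1)
  out2 <- apply_filters(p2)  # CV of (0.2, 0.9) is ~90%
  expect_equal(
    out2$report$metabolites$reason[out2$report$metabolites$name == "target"],
    "CV")
})

test_that("non-binding thresholds return the panel unchanged", {
  p <- qc_panel(values = rep(5, 10), qc_values = c(5, 5.2), lod = 1)
  out <- apply_filters(p, qc_thresholds(cv_max = Inf,
                                        lod_sample_frac = 1,
                                        na_zero_frac = 1))
  expect_identical(out$panel$concentrations, p$concentrations)
  expect_false(any(out$report$metabolites$excluded))
})

test_that("report covers every metabolite and filtering is order-invariant", {
  gen <- generate_panel(metabostab:::fixture_configs()$censored)
  out <- apply_filters(gen$panel)
  expect_equal(nrow(out$report$metabolites),
               ncol(gen$panel$concentrations))
  expect_equal(sum(!out$report$metabolites$excluded),
               ncol(out$panel$concentrations))
  # permuting metabolite columns leaves per-metabolite decisions unchanged
  perm <- withr::with_seed(1, sample.int(ncol(gen$panel$concentrations)))
  out_perm <- apply_filters(subset_panel(gen$panel, metabolites = perm))
  m1 <- out$report$metabolites
  m2 <- out_perm$report$metabolites
  m2 <- m2[match(m1$name, m2$name), ]
  expect_equal(m1$reason, m2$reason)
})

test_that("relaxing a threshold never removes more metabolites", {
  gen <- generate_panel(metabostab:::fixture_configs()$censored)
  retained <- vapply(c(0.1, 0.3, 0.5, 1), function(fr) {
    out <- apply_filters(gen$panel,
                         qc_thresholds(lod_sample_frac = fr,
                                       na_zero_frac = fr))
    ncol(out$panel$concentrations)
  }, numeric(1))
  expect_true(all(diff(retained) >= 0))
})

test_that("outlier flagging finds gross outliers and nothing else", {
  withr::with_seed(4, {
    conc <- matrix(abs(rnorm(12 * 8, 10, 1)), 12, 8,
                   dimnames = list(paste0("s", 1:12), paste0("m", 1:8)))
    sm <- data.frame(sample_id = rownames(conc), group = "A", sex = "gilt",
                     carcass_weight = 100, is_qc = FALSE,
                     stringsAsFactors = FALSE)
    p_clean <- metabolite_panel(conc, sm)
    expect_equal(nrow(flag_outlier_samples(p_clean)), 0)
    # shift one sample by 10 sd on every metabolite
    conc2 <- conc
    conc2["s12", ] <- conc2["s12", ] + 10
    flags <- flag_outlier_samples(metabolite_panel(conc2, sm))
    expect_equal(flags$sample_id, "s12")
    # identical samples cannot be outliers
    conc3 <- matrix(5, 6, 4, dimnames = list(paste0("s", 1:6),
                                             paste0("m", 1:4)))
    sm3 <- sm[1:6, ]; sm3$sample_id <- rownames(conc3)
    expect_equal(nrow(flag_outlier_samples(metabolite_panel(conc3, sm3))), 0)
    # an all-NA sample is flagged unconditionally
    conc4 <- conc
    conc4["s3", ] <- NA
    flags4 <- flag_outlier_samples(metabolite_panel(conc4, sm))
    expect_true("s3" %in% flags4$sample_id)
    expect_equal(flags4$reason[flags4$sample_id == "s3"],
                 "all_values_missing")
  })
})

test_that("CV filtering without QC rows is a configuration error", {
  p <- tiny_panel(with_qc = FALSE)
  expect_error(apply_filters(p), "QC replicate rows")
  # disabling the CV rule makes QC-free panels legal
  out <- apply_filters(p, qc_thresholds(cv_max = Inf))
  expect_false(any(out$report$metabolites$excluded))
})
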