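# Shared fixtures, built in code. Expensive objects are cached for the
# duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Hand-built 4-sample x 3-metabolite panel (plus optional QC rows).
tiny_panel <- function(with_qc = FALSE) {
  conc <- matrix(c(10, 12, 9, 11,
                   0.5, 0.7, 0.6, 0.4,
                   100, 110, 95, 105),
                 nrow = 4,
                 dimnames = list(paste0("s", 1:4), c("m1", "m2", "m3")))
  sm <- data.frame(sample_id = rownames(conc),
                   group = c("A", "A", "B", "B"),
                   sex = c("gilt", "castrated_male", "gilt",
                           "castrated_male"),
                   carcass_weight = c(120, 132, 125, 128),
                   is_qc = FALSE, stringsAsFactors = FALSE)
  mm <- data.frame(name = colnames(conc),
                   analyte_class = c("AA", "AC", "PC"),
                   lod = c(0, 0.1, 1), stringsAsFactors = FALSE)
  if (with_qc) {
    qc <- matrix(c(10.5, 10.4, 0.55, 0.56, 101, 99), nrow = 2,
                 dimnames = list(c("QC_1", "QC_2"), colnames(conc)))
    conc <- rbind(conc, qc)
    sm <- rbind(sm, data.frame(sample_id = c("QC_1", "QC_2"), group = "QC",
                               sex = "gilt", carcass_weight = 126,
                               is_qc = TRUE))
  }
  metabolite_panel(conc, sm, mm)
}

# Two balanced groups, one planted feature `shift` within-group sds apart,
# plus pure-noise features. Returns X (matrix) and y (factor).
planted_matrix <- function(n_per_group = 12, n_noise = 20, shift = 5,
                           seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    X <- matrix(rnorm(n * (n_noise + 1)), n, n_noise + 1)
    colnames(X) <- c("planted", paste0("noise", seq_len(n_noise)))
    y <- factor(rep(c("A", "B"), each = n_per_group))
    X[y == "B", "planted"] <- X[y == "B", "planted"] + shift
    list(X = X, y = y)
  })
}

# Minimal ResidualMatrix wrapper around an arbitrary matrix, for testing
# downstream operations in isolation.
fake_residuals <- function(mat, group) {
  structure(list(
    residuals = mat,
    coefficients = data.frame(),
    sample_meta = data.frame(sample_id = rownames(mat), group = group,
                             sex = "gilt", carcass_weight = 100,
                             is_qc = FALSE, stringsAsFactors = FALSE),
    sex_mapping = NULL, dropped_terms = character(0),
    log_transform = FALSE
  ), class = "ResidualMatrix")
}

# Strong-signal fixture pipeline inputs, shared across test files.
strong_fixture <- function() {
  cached("strong", {
    gen <- generate_panel(metabostab:::fixture_configs()$strong)
    qc <- apply_filters(gen$panel)
    res <- fit_and_residualize(qc$panel)
    list(gen = gen, clean = qc$panel, residuals = res,
         comparison = comparison_spec(c("ILA", "ILW"), "pairwise"))
  })
}

# Shared small stability validation on the strong fixture (2 seeds x 24
# held-out samples = 48 runs), for structural tests of report shape.
strong_small_validation <- function() {
  cached("strong_smallval", {
    sf <- strong_fixture()
    run_validation(sf$residuals, sf$comparison,
                   params = boruta_params(n_trees = 150, max_iter = 60,
                                          seed = 2),
                   n_seeds = 2)
  })
}

# Exhaustive Mann-Whitney oracle: distribution of U over all
# assignments of the pooled values into two groups of the given sizes.
enumerate_mwu_p <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  idx <- utils::combn(length(pooled), n1)
  u_stat <- function(a, b) {
    sum(vapply(a, function(x) sum((x > b) + 0.5 * (x == b)), numeric(1)))
  }
  u_obs <- u_stat(g1, g2)
  u_all <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  # two-sided: distance of U from its center n1*n2/2
  center <- n1 * (length(pooled) - n1) / 2
  mean(abs(u_all - center) >= abs(u_obs - center))
}

# Fast selector settings for structural (non-power) tests.
fast_params <- function(seed = 0L) {
  boruta_params(n_trees = 50, max_iter = 15, seed = seed)
}
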