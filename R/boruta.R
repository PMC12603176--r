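#' Parameters for the all-relevant selection core
#'
#' The selector is a shadow-feature random-forest wrapper: at each
#' iteration every real feature competes against permuted copies of the
#' feature set inside a random forest, and binomial tests on the
#' accumulated "hit" counts promote features to Confirmed or demote them
#' to Rejected.
#'
#' @param max_iter maximum number of iterations.
#' @param alpha significance level for the binomial hit tests.
#' @param perc percentile of the shadow importances a real feature must
#'   exceed to score a hit; 100 = the shadow maximum (the strictest,
#'   canonical choice).
#' @param n_trees trees per internal forest. Independent of the 1,000-tree
#'   evaluation forest; 500 by default.
#' @param two_step_correction `TRUE` (default) applies
#'   Benjamini-Hochberg FDR across undecided features plus an
#'   alpha/iteration guard; `FALSE` applies a plain Bonferroni correction
#'   over all features.
#' @param seed integer seed; fixes the permutation and forest streams so
#'   identical inputs give identical decisions.
#' @return list of class `boruta_params`.
#' @export
boruta_params <- function(max_iter = 100, alpha = 0.05, perc = 100,
                          n_trees = 500, two_step_correction = TRUE,
                          seed = 0L) {
  stopifnot(max_iter >= 1, alpha > 0, alpha < 1, perc > 0, perc <= 100,
            n_trees >= 1)
  structure(list(max_iter = as.integer(max_iter), alpha = alpha,
                 perc = perc, n_trees = as.integer(n_trees),
                 two_step_correction = isTRUE(two_step_correction),
                 seed = as.integer(seed)),
            class = "boruta_params")
}

#' Run the shadow-feature selection on one data set
#'
#' At each iteration a shuffled shadow copy of every feature is appended
#' to the predictor matrix, a random-forest classifier is fitted, and a
#' real feature scores a hit when its impurity (Gini) importance exceeds
#' the `perc` percentile of the shadow importances. Shadows are rebuilt
#' from the full feature set even after features are rejected, so the
#' shadow maximum keeps estimating the largest chance association among
#' all p features; the real-side competition shrinks as features are
#' rejected.
#' From iteration 5 onward, one-sided binomial tail tests (success
#' probability 0.5) on the hit counts — corrected per
#' `two_step_correction` — confirm clearly-winning features and reject
#' clearly-losing ones; rejected features leave the competition. Features
#' still undecided at `max_iter` are Tentative.
#'
#' @param X numeric matrix, samples x features, no NA/non-finite values.
#' @param y group labels (coerced to factor); >= 2 classes with >= 2
#'   samples each.
#' @param params a [boruta_params()].
#' @return object of class `BorutaDecision`: `decisions` data.frame
#'   (`feature`, `status` in Confirmed/Tentative/Rejected, `hits`,
#'   `n_iterations_tested`), `converged_at` (iteration at which every
#'   feature was decided, or NA), and the `params` used.
#' @export
run_boruta <- function(X, y, params = boruta_params()) {
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("at least one feature is required", call. = FALSE)
  if (any(!is.finite(X))) {
    stop("X contains NA or non-finite values", call. = FALSE)
  }
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need >= 2 classes", call. = FALSE)
  if (any(table(y) < 2)) {
    stop("every class needs >= 2 samples", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  withr::with_seed(params$seed, run_boruta_impl(X, y, params))
}

# Shadow copies: every column independently permuted, which breaks any
# association with the response while preserving each column's multiset
# of values (and hence its marginal distribution). As in the canonical
# algorithm, at least 5 shadow columns are kept — when few features are
# still competing, columns are recycled (and re-permuted) so the shadow
# maximum remains a meaningful null reference.
make_shadow <- function(X, min_shadows = 5L) {
  idx <- rep_len(seq_len(ncol(X)), max(ncol(X), min_shadows))
  base <- X[, idx, drop = FALSE]
  shadow <- apply(base, 2, sample)
  if (!is.matrix(shadow)) shadow <- matrix(shadow, nrow = nrow(X))
  colnames(shadow) <- paste0(".shadow_", make.unique(colnames(base)))
  rownames(shadow) <- rownames(X)
  shadow
}

run_boruta_impl <- function(X, y, params) {
  p <- ncol(X)
  status <- rep("Tentative", p)
  hits <- integer(p)
  tested <- integer(p)
  names(status) <- names(hits) <- names(tested) <- colnames(X)
  converged_at <- NA_integer_

  for (iter in seq_len(params$max_iter)) {
    active <- which(status != "Rejected")   # shadows come from these
    undecided <- which(status == "Tentative")
    if (length(undecided) == 0) {
      converged_at <- iter - 1L
      break
    }
    Xa <- X[, active, drop = FALSE]
    # shadows are rebuilt from the FULL feature set every iteration, so
    # the shadow maximum stays an estimate of the largest chance
    # association among p features even after most reals drop out
    shadow <- make_shadow(X)
    dat <- cbind(Xa, shadow)
    fit <- ranger::ranger(
      x = as.data.frame(dat), y = y,
      num.trees = params$n_trees,
      importance = "impurity",
      seed = sample.int(.Machine$integer.max, 1),
      num.threads = 1
    )
    imp <- fit$variable.importance
    thr <- stats::quantile(imp[colnames(shadow)], params$perc / 100,
                           names = FALSE, type = 7)
    hit_now <- imp[colnames(Xa)] > thr
    idx <- active
    hits[idx] <- hits[idx] + as.integer(hit_now)
    tested[idx] <- tested[idx] + 1L

    if (iter >= 5) {
      u <- which(status == "Tentative")
      n <- tested[u]
      h <- hits[u]
      p_conf <- stats::pbinom(h - 1, n, 0.5, lower.tail = FALSE)
      p_rej <- stats::pbinom(h, n, 0.5)
      if (params$two_step_correction) {
        conf <- stats::p.adjust(p_conf, "BH") <= params$alpha &
          p_conf <= params$alpha / iter
        rej <- stats::p.adjust(p_rej, "BH") <= params$alpha &
          p_rej <= params$alpha / iter
      } else {
        conf <- p_conf <= params$alpha / p
        rej <- p_rej <= params$alpha / p
      }
      status[u[conf]] <- "Confirmed"
      status[u[rej & !conf]] <- "Rejected"
      if (all(status != "Tentative")) converged_at <- iter
    }
  }

  structure(list(
    decisions = data.frame(feature = colnames(X), status = status,
                           hits = hits, n_iterations_tested = tested,
                           row.names = NULL, stringsAsFactors = FALSE),
    converged_at = converged_at,
    params = params
  ), class = "BorutaDecision")
}

#' @export
print.BorutaDecision <- function(x, ...) {
  tab <- table(factor(x$decisions$status,
                      c("Confirmed", "Tentative", "Rejected")))
  cat("BorutaDecision:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  if (!is.na(x$converged_at)) {
    cat("converged at iteration", x$converged_at, "\n")
  }
  invisible(x)
}

#' Confirmed features of a decision
#' @param decision a `BorutaDecision`.
#' @return character vector of Confirmed feature names.
#' @export
confirmed_features <- function(decision) {
  stopifnot(inherits(decision, "BorutaDecision"))
  decision$decisions$feature[decision$decisions$status == "Confirmed"]
}

#' Reliability thresholds for stability classification
#'
#' @param high retention fraction for "highly reliable" (1.00 = selected
#'   in every run).
#' @param moderate retention fraction for "moderately reliable" (0.90 =
#'   e.g. at least 108 of 120 runs).
#' @return list of thresholds.
#' @export
reliability_thresholds <- function(high = 1.00, moderate = 0.90) {
  stopifnot(high >= moderate, moderate > 0)
  list(high = high, moderate = moderate)
}

#' Classify a metabolite's stability over validation runs
#'
#' @param retained number of runs in which the metabolite was Confirmed.
#' @param total_runs total number of validation runs executed.
#' @param thresholds a [reliability_thresholds()] list.
#' @return `"highly_reliable"`, `"moderately_reliable"`, or `"unstable"`.
#' @export
classify_reliability <- function(retained, total_runs,
                                 thresholds = reliability_thresholds()) {
  stopifnot(total_runs > 0, retained >= 0, retained <= total_runs)
  frac <- retained / total_runs
  if (frac >= thresholds$high) "highly_reliable"
  else if (frac >= thresholds$moderate) "moderately_reliable"
  else "unstable"
}

# Deterministic per-run seed from (base seed, seed index, held-out id):
# polynomial rolling hash of the concatenated key, in the positive
# 32-bit integer range.
derive_run_seed <- function(base_seed, seed_index, held_out_id) {
  key <- paste(base_seed, seed_index, held_out_id, sep = "|")
  h <- 17
  for (b in utf8ToInt(key)) {
    h <- (h * 1296 + b) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

#' Multi-seed leave-one-out stability validation
#'
#' The selection is rerun once per (held-out sample, seed) combination:
#' for each of the N comparison samples, that sample is removed and the
#' selector runs `n_seeds` times with different seeds on the remaining
#' N-1 samples — 5 seeds x 24 samples = 120 runs for a pairwise
#' comparison of two groups of 12, 5 x 36 = 180 for the three-group
#' multi-class setup. A metabolite's retention count is the number of runs
#' in which it was Confirmed; retention fractions are classified with
#' [classify_reliability()] (100% highly reliable, >= 90% moderately
#' reliable, otherwise unstable).
#'
#' @param residuals a `ResidualMatrix` from [fit_and_residualize()].
#' @param comparison a [comparison_spec()].
#' @param params a [boruta_params()]; the per-run seed is derived from
#'   `params$seed`, the seed index and the held-out sample id, so each run
#'   is individually reproducible.
#' @param n_seeds number of seeds per held-out sample (default 5).
#' @param thresholds a [reliability_thresholds()] list.
#' @return object of class `StabilityReport`: `metabolites` data.frame
#'   (`name`, `retained`, `total_runs`, `retention_frac`, `category`),
#'   `run_log` (one row per run with held-out sample, seed index, derived
#'   seed and the Confirmed set), `total_runs`, and the comparison label.
#' @export
run_validation <- function(residuals, comparison,
                           params = boruta_params(), n_seeds = 5,
                           thresholds = reliability_thresholds()) {
  stopifnot(n_seeds >= 1)
  cm <- comparison_matrix(residuals, comparison)
  n <- nrow(cm$X)
  feats <- colnames(cm$X)
  retained <- stats::setNames(integer(length(feats)), feats)
  log_rows <- vector("list", n * n_seeds)
  total <- 0L
  k <- 0L
  for (i in seq_len(n)) {
    y_tr <- cm$y[-i]
    if (any(table(droplevels(y_tr)) < 2) ||
        nlevels(droplevels(y_tr)) < length(comparison$groups)) {
      warning("run skipped: holding out sample ", cm$sample_ids[i],
              " leaves a class with < 2 samples")
      next
    }
    for (s in seq_len(n_seeds) - 1L) {
      run_seed <- derive_run_seed(params$seed, s, cm$sample_ids[i])
      run_params <- params
      run_params$seed <- run_seed
      dec <- run_boruta(cm$X[-i, , drop = FALSE], y_tr, run_params)
      conf <- confirmed_features(dec)
      retained[conf] <- retained[conf] + 1L
      total <- total + 1L
      k <- k + 1L
      log_rows[[k]] <- data.frame(
        held_out_sample = cm$sample_ids[i], seed_index = s,
        run_seed = run_seed, n_confirmed = length(conf),
        confirmed = paste(conf, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (total == 0L) stop("no validation runs could be executed", call. = FALSE)
  frac <- retained / total
  category <- vapply(feats, function(f) {
    classify_reliability(retained[[f]], total, thresholds)
  }, character(1))
  structure(list(
    metabolites = data.frame(name = feats, retained = as.integer(retained),
                             total_runs = total, retention_frac = frac,
                             category = category, row.names = NULL,
                             stringsAsFactors = FALSE),
    run_log = do.call(rbind, log_rows[seq_len(k)]),
    total_runs = total,
    comparison = comparison_label(comparison),
    thresholds = thresholds,
    params = params
  ), class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  tab <- table(factor(x$metabolites$category,
                      c("highly_reliable", "moderately_reliable",
                        "unstable")))
  cat("StabilityReport [", x$comparison, "]: ", x$total_runs,
      " runs\n", sep = "")
  cat(paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Metabolites retained at a reliability level
#'
#' @param report a `StabilityReport`.
#' @param level `"highly_reliable"` or `"moderately_reliable"`; the latter
#'   includes the highly reliable set (reliable-or-better).
#' @return character vector of metabolite names.
#' @export
reliable_set <- function(report,
                         level = c("moderately_reliable",
                                   "highly_reliable")) {
  stopifnot(inherits(report, "StabilityReport"))
  level <- match.arg(level)
  keep <- if (level == "highly_reliable") {
    report$metabolites$category == "highly_reliable"
  } else {
    report$metabolites$category %in% c("highly_reliable",
                                       "moderately_reliable")
  }
  report$metabolites$name[keep]
}
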