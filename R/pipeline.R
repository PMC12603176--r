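#' Pipeline configuration
#'
#' One object drives the full workflow: ingest or simulate a panel, QC
#' filter, residualize, run stability-validated selection for every
#' configured comparison, evaluate, and run PCA before/after selection.
#'
#' @param input either a file path to a wide panel table or a
#'   [sim_config()].
#' @param comparisons list of [comparison_spec()] objects; defaults (when
#'   the panel has >= 2 groups) to every pairwise comparison plus, with
#'   >= 3 groups, one multi-class comparison over all groups.
#' @param qc a [qc_thresholds()] list.
#' @param boruta a [boruta_params()] list; its seed is re-derived from
#'   `base_seed` per comparison.
#' @param n_seeds seeds per held-out sample in the validation scheme.
#' @param reliability a [reliability_thresholds()] list.
#' @param selection reliability level treated as "selected" downstream.
#' @param alpha evaluation significance level (Bonferroni at
#'   `alpha / n post-QC metabolites`).
#' @param eval_trees evaluation forest size (1,000 as standard).
#' @param n_pca_components components exported from each PCA (default 2,
#'   the plotted pair).
#' @param out_dir output directory; `NULL` disables artifact writing.
#' @param base_seed integer master seed.
#' @param metabolite_meta_path optional sidecar when `input` is a path.
#' @param dialect a [panel_dialect()] for file I/O.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input,
                            comparisons = NULL,
                            qc = qc_thresholds(),
                            boruta = boruta_params(),
                            n_seeds = 5,
                            reliability = reliability_thresholds(),
                            selection = "moderately_reliable",
                            alpha = 0.05,
                            eval_trees = 1000,
                            n_pca_components = 2,
                            out_dir = NULL,
                            base_seed = 0L,
                            metabolite_meta_path = NULL,
                            dialect = panel_dialect()) {
  structure(list(input = input, comparisons = comparisons, qc = qc,
                 boruta = boruta, n_seeds = n_seeds,
                 reliability = reliability, selection = selection,
                 alpha = alpha, eval_trees = eval_trees,
                 n_pca_components = n_pca_components, out_dir = out_dir,
                 base_seed = as.integer(base_seed),
                 metabolite_meta_path = metabolite_meta_path,
                 dialect = dialect),
            class = "pipeline_config")
}

default_comparisons <- function(groups) {
  out <- list()
  if (length(groups) >= 2) {
    for (a in seq_len(length(groups) - 1)) {
      for (b in (a + 1):length(groups)) {
        out[[length(out) + 1]] <- comparison_spec(groups[c(a, b)],
                                                  "pairwise")
      }
    }
  }
  if (length(groups) >= 3) {
    out[[length(out) + 1]] <- comparison_spec(groups, "multiclass")
  }
  out
}

# Small stable config digest (rolling hash over the serialized config)
# for the manifest; not cryptographic, just change detection.
config_hash <- function(config) {
  s <- jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 17
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 1296 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: ingest/simulate, QC filtering, covariate
#' residualization, stability-validated selection for every comparison,
#' evaluation (pairwise comparisons) or forest-only evaluation
#' (multi-class), and PCA before and after selection. When `out_dir` is
#' set, every stage's tables are written as TSV under one subdirectory
#' per comparison, plus a JSON manifest recording the config, its hash,
#' all seeds and package versions. Any stage failure aborts with an error
#' naming the stage; artifacts from completed stages remain on disk.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (invisibly contains all in-memory results under
#'   `$results`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out_dir <- config$out_dir
  writing <- !is.null(out_dir)
  if (writing) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## ingest ------------------------------------------------------------
  ingest <- stage("ingest", {
    if (inherits(config$input, "sim_config")) {
      generate_panel(config$input)
    } else {
      list(panel = read_panel(config$input, dialect = config$dialect,
                              metabolite_meta_path =
                                config$metabolite_meta_path),
           truth = NULL)
    }
  })
  panel <- ingest$panel

  ## qc ----------------------------------------------------------------
  qc <- stage("qc", apply_filters(panel, config$qc))
  clean <- qc$panel
  if (writing) {
    write_table(qc$report$metabolites, file.path(out_dir, "qc_report.tsv"))
    write_panel(clean, file.path(out_dir, "clean_panel.tsv"),
                metabolite_meta_path = file.path(out_dir,
                                                 "clean_metabolites.tsv"))
  }

  ## adjust ------------------------------------------------------------
  residuals <- stage("adjust", fit_and_residualize(clean))
  if (writing) {
    res_df <- data.frame(sample_id = rownames(residuals$residuals),
                         as.data.frame(residuals$residuals,
                                       check.names = FALSE),
                         check.names = FALSE)
    write_table(res_df, file.path(out_dir, "residuals.tsv"))
    coef_df <- data.frame(metabolite = rownames(residuals$coefficients),
                          residuals$coefficients)
    write_table(coef_df, file.path(out_dir, "coefficients.tsv"))
  }

  groups <- unique(residuals$sample_meta$group)
  comparisons <- config$comparisons %||% default_comparisons(groups)
  if (length(comparisons) == 0) stop("no comparisons configured")

  ## select + evaluate + pca per comparison -----------------------------
  results <- list()
  seeds_used <- list()
  for (ci in seq_along(comparisons)) {
    comp <- comparisons[[ci]]
    label <- comparison_label(comp)
    check_comparison(clean, comp)
    sub_dir <- if (writing) file.path(out_dir, label) else NULL
    if (writing) dir.create(sub_dir, showWarnings = FALSE)

    bp <- config$boruta
    bp$seed <- derive_run_seed(config$base_seed, ci, label)
    seeds_used[[label]] <- bp$seed

    stab <- stage(paste0("select[", label, "]"),
                  run_validation(residuals, comp, params = bp,
                                 n_seeds = config$n_seeds,
                                 thresholds = config$reliability))
    selected <- reliable_set(stab, config$selection)

    evaluation <- NULL
    if (comp$mode == "pairwise") {
      evaluation <- stage(paste0("evaluate[", label, "]"),
                          evaluate_comparison(clean, residuals, stab, comp,
                                              selection = config$selection,
                                              alpha = config$alpha,
                                              n_trees = config$eval_trees,
                                              seed = bp$seed))
    } else if (length(selected) > 0) {
      cm <- comparison_matrix(residuals, comp)
      rf <- stage(paste0("evaluate[", label, "]"),
                  rf_evaluate(cm$X[, selected, drop = FALSE], cm$y,
                              n_trees = config$eval_trees, seed = bp$seed))
      evaluation <- structure(list(metabolites = data.frame(),
                                   oob_error = rf$oob_error,
                                   misclassified = rf$misclassified,
                                   mdg = rf$mdg,
                                   n_tests = ncol(clean$concentrations),
                                   alpha = config$alpha,
                                   comparison = label),
                              class = "EvaluationTable")
    }

    cm <- comparison_matrix(residuals, comp)
    pca_before <- stage(paste0("pca[", label, "]"),
                        run_pca(cm$X,
                                n_components = config$n_pca_components))
    pca_after <- if (length(selected) >= 2) {
      run_pca(cm$X, metabolite_subset = selected,
              n_components = config$n_pca_components)
    } else NULL

    if (writing) {
      write_table(stab$metabolites, file.path(sub_dir, "stability.tsv"))
      write_table(stab$run_log, file.path(sub_dir, "run_log.tsv"),
                  sort_by = NULL)
      if (!is.null(evaluation) && nrow(evaluation$metabolites) > 0) {
        write_table(evaluation$metabolites,
                    file.path(sub_dir, "evaluation.tsv"),
                    sort_by = "metabolite")
      }
      pca_df <- data.frame(sample_id = rownames(pca_before$scores),
                           pca_before$scores, check.names = FALSE)
      write_table(pca_df, file.path(sub_dir, "pca_scores_before.tsv"))
      if (!is.null(pca_after)) {
        write_table(data.frame(sample_id = rownames(pca_after$scores),
                               pca_after$scores, check.names = FALSE),
                    file.path(sub_dir, "pca_scores_after.tsv"))
      }
    }
    results[[label]] <- list(comparison = comp, stability = stab,
                             selected = selected, evaluation = evaluation,
                             pca_before = pca_before,
                             pca_after = pca_after)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("metabostab")),
    r_version = R.version.string,
    config_hash = config_hash(config),
    base_seed = config$base_seed,
    comparison_seeds = seeds_used,
    n_seeds = config$n_seeds,
    comparisons = names(results),
    n_metabolites_input = ncol(panel$concentrations),
    n_metabolites_retained = ncol(clean$concentrations),
    selected = lapply(results, `[[`, "selected")
  )
  if (writing) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest$results <- results
  manifest$panel <- panel
  manifest$clean_panel <- clean
  manifest$residuals <- residuals
  manifest$qc_report <- qc$report
  manifest$truth <- ingest$truth
  class(manifest) <- "pipeline_manifest"
  invisible(manifest)
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("pipeline_manifest (config", x$config_hash, ")\n")
  cat("metabolites:", x$n_metabolites_retained, "retained of",
      x$n_metabolites_input, "\n")
  for (nm in x$comparisons) {
    cat(sprintf("  %s: %d selected\n", nm, length(x$selected[[nm]])))
  }
  invisible(x)
}

#' Compare the selections of two pipeline runs
#'
#' Venn-style replication analysis: for every comparison label present in
#' both manifests, the named intersection and the run-specific remainders
#' of the selected metabolite sets.
#'
#' @param manifest_a,manifest_b `pipeline_manifest` objects (or any lists
#'   with a `selected` element of named character vectors).
#' @return data.frame with one row per common comparison
#'   (`n_a`, `n_b`, `n_shared`, `shared`, `only_a`, `only_b`), with the
#'   named sets attached as the `sets` attribute.
#' @export
compare_runs <- function(manifest_a, manifest_b) {
  common <- intersect(names(manifest_a$selected),
                      names(manifest_b$selected))
  if (length(common) == 0) {
    stop("no common comparison label between the two runs", call. = FALSE)
  }
  sets <- list()
  rows <- lapply(common, function(nm) {
    a <- manifest_a$selected[[nm]]
    b <- manifest_b$selected[[nm]]
    sh <- intersect(a, b)
    sets[[nm]] <<- list(shared = sh, only_a = setdiff(a, b),
                        only_b = setdiff(b, a))
    data.frame(comparison = nm, n_a = length(a), n_b = length(b),
               n_shared = length(sh),
               shared = paste(sort(sh), collapse = ";"),
               only_a = paste(sort(setdiff(a, b)), collapse = ";"),
               only_b = paste(sort(setdiff(b, a)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "sets") <- sets
  out
}
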