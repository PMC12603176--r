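#' Residualize metabolite levels on sex and carcass weight
#'
#' Fits, per metabolite, the ordinary least squares model
#' `y_i = beta0 + beta_w * w_i + beta_s * s_i + error` across all non-QC
#' samples jointly (all groups pooled — group labels never enter the
#' design), and returns the residuals for downstream analysis. Sex is
#' coded as a single 0/1 contrast (first level alphabetically = 0); the
#' mapping is recorded in the result. NA concentrations are excluded from
#' that metabolite's fit and propagate as NA residuals.
#'
#' @param panel a cleaned `MetabolitePanel` (post-QC); carcass weight must
#'   be non-NA for every non-QC sample.
#' @param log_transform fit on `log(y)` instead of `y` (off by default:
#'   levels are modelled on the concentration scale).
#' @return object of class `ResidualMatrix`: `residuals` (samples x
#'   metabolites, QC rows excluded), `coefficients` (per metabolite
#'   `beta0`, `beta_w`, `beta_s`), `sample_meta` (non-QC rows),
#'   `sex_mapping`, and `dropped_terms` notes.
#' @export
fit_and_residualize <- function(panel, log_transform = FALSE) {
  validate_panel(panel)
  smp <- which(!panel$sample_meta$is_qc)
  sm <- panel$sample_meta[smp, , drop = FALSE]
  if (any(is.na(sm$carcass_weight))) {
    stop("carcass_weight must be non-NA for all non-QC samples",
         call. = FALSE)
  }
  y_all <- panel$concentrations[smp, , drop = FALSE]
  if (log_transform) {
    if (any(y_all <= 0, na.rm = TRUE)) {
      stop("log transform requires strictly positive concentrations",
           call. = FALSE)
    }
    y_all <- log(y_all)
  }

  sex_levels <- sort(unique(sm$sex))
  dropped <- character(0)
  if (length(sex_levels) > 2) {
    stop("sex must have at most 2 levels; found: ",
         paste(sex_levels, collapse = ", "), call. = FALSE)
  }
  use_sex <- length(sex_levels) == 2
  if (!use_sex) {
    warning("sex has a single level; sex term dropped from the model")
    dropped <- c(dropped, "sex")
  }
  use_w <- stats::sd(sm$carcass_weight) > 0
  if (!use_w) {
    warning("carcass_weight is constant; weight term dropped from the model")
    dropped <- c(dropped, "carcass_weight")
  }
  s01 <- if (use_sex) as.numeric(sm$sex == sex_levels[2]) else NULL
  X <- cbind(`(Intercept)` = rep(1, nrow(sm)),
             if (use_w) cbind(beta_w = sm$carcass_weight),
             if (use_sex) cbind(beta_s = s01))

  p <- ncol(y_all)
  res <- matrix(NA_real_, nrow(sm), p,
                dimnames = dimnames(y_all))
  coefs <- matrix(NA_real_, p, 3,
                  dimnames = list(colnames(y_all),
                                  c("beta0", "beta_w", "beta_s")))
  for (j in seq_len(p)) {
    y <- y_all[, j]
    ok <- !is.na(y)
    if (sum(ok) <= ncol(X)) {
      warning("metabolite ", colnames(y_all)[j],
              ": too few non-NA values to fit; residuals set NA")
      next
    }
    fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
    b <- fit$coefficients
    coefs[j, "beta0"] <- b["(Intercept)"]
    coefs[j, "beta_w"] <- if (use_w) b["beta_w"] else 0
    coefs[j, "beta_s"] <- if (use_sex) b["beta_s"] else 0
    res[ok, j] <- fit$residuals
  }

  structure(list(
    residuals = res,
    coefficients = as.data.frame(coefs),
    sample_meta = sm,
    sex_mapping = if (use_sex) {
      stats::setNames(c(0, 1), sex_levels)
    } else NULL,
    dropped_terms = dropped,
    log_transform = log_transform
  ), class = "ResidualMatrix")
}

#' @export
print.ResidualMatrix <- function(x, ...) {
  cat("ResidualMatrix:", nrow(x$residuals), "samples x",
      ncol(x$residuals), "metabolites\n")
  if (!is.null(x$sex_mapping)) {
    cat("sex contrast:",
        paste(names(x$sex_mapping), x$sex_mapping, sep = "=",
              collapse = ", "), "\n")
  }
  if (length(x$dropped_terms)) {
    cat("dropped terms:", paste(x$dropped_terms, collapse = ", "), "\n")
  }
  invisible(x)
}

# Residuals restricted to the samples of a comparison, NA-bearing
# metabolites dropped (with a warning from the caller when relevant).
comparison_matrix <- function(residuals, comparison) {
  stopifnot(inherits(residuals, "ResidualMatrix"))
  sm <- residuals$sample_meta
  keep <- sm$group %in% comparison$groups
  if (!all(comparison$groups %in% sm$group)) {
    stop("comparison group(s) absent from residual matrix: ",
         paste(setdiff(comparison$groups, sm$group), collapse = ", "),
         call. = FALSE)
  }
  X <- residuals$residuals[keep, , drop = FALSE]
  y <- factor(sm$group[keep], levels = comparison$groups)
  has_na <- colSums(is.na(X)) > 0
  if (any(has_na)) {
    warning(sum(has_na), " metabolite(s) with NA residuals dropped from ",
            "the comparison matrix")
    X <- X[, !has_na, drop = FALSE]
  }
  list(X = X, y = y, sample_ids = sm$sample_id[keep])
}
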