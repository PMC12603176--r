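#' Coefficient of variation across QC replicates
#'
#' Intraplate CV in percent: `100 * sd(x) / mean(x)` over the replicate
#' concentrations of one metabolite. Undefined when fewer than two non-NA
#' replicates remain or the replicate mean is zero; callers treat an
#' undefined CV as a failed CV check.
#'
#' @param qc_values numeric vector of replicate concentrations.
#' @return CV in percent.
#' @export
compute_cv <- function(qc_values) {
  x <- qc_values[!is.na(qc_values)]
  if (length(x) < 2) {
    stop("CV undefined: fewer than 2 non-NA replicate values",
         call. = FALSE)
  }
  m <- mean(x)
  if (m == 0) stop("CV undefined: replicate mean is zero", call. = FALSE)
  100 * stats::sd(x) / m
}

#' Default QC filter thresholds
#'
#' @param cv_max maximum intraplate CV in percent (exclusive bound:
#'   metabolites with CV strictly greater are excluded).
#' @param lod_qc_rule `"all"` (exclude when every QC replicate is below
#'   the LOD) or `"any"`.
#' @param lod_sample_frac exclude when more than this fraction of non-QC
#'   samples is below the LOD.
#' @param na_zero_frac exclude when more than this fraction of non-QC
#'   values is missing (NA) or zero. NA and zero are distinct states but
#'   count toward the same rate; zeros are otherwise legal concentrations.
#' @return list of thresholds.
#' @export
qc_thresholds <- function(cv_max = 20, lod_qc_rule = c("all", "any"),
                          lod_sample_frac = 0.30, na_zero_frac = 0.30) {
  lod_qc_rule <- match.arg(lod_qc_rule)
  list(cv_max = cv_max, lod_qc_rule = lod_qc_rule,
       lod_sample_frac = lod_sample_frac, na_zero_frac = na_zero_frac)
}

#' Three-step metabolite filtering
#'
#' Applies, per metabolite and in order of precedence, (1) the replicate
#' CV rule, (2) the below-LOD-across-QC rule, (3) the below-LOD sample
#' fraction rule, and (4) the NA/zero fraction rule; the first failing
#' rule is the recorded exclusion reason. Samples are never removed here —
#' outlier samples are only flagged (see [flag_outlier_samples()]).
#'
#' @param panel a `MetabolitePanel` containing at least two QC replicate
#'   rows when the CV rule is enabled (`cv_max` finite).
#' @param thresholds a [qc_thresholds()] list.
#' @param outlier_cutoff robust-z cutoff passed to
#'   [flag_outlier_samples()].
#' @return a list with `panel` (the filtered panel, QC rows retained) and
#'   `report` (a `QCReport`: per-metabolite statistics, exclusion flag and
#'   reason, plus flagged `outlier_samples`).
#' @export
apply_filters <- function(panel, thresholds = qc_thresholds(),
                          outlier_cutoff = 3.5) {
  validate_panel(panel)
  qc_rows <- which(panel$sample_meta$is_qc)
  smp_rows <- which(!panel$sample_meta$is_qc)
  cv_enabled <- is.finite(thresholds$cv_max)
  if (cv_enabled && length(qc_rows) < 2) {
    stop("CV filtering requires >= 2 QC replicate rows; found ",
         length(qc_rows), call. = FALSE)
  }
  conc <- panel$concentrations
  mm <- panel$metabolite_meta
  p <- ncol(conc)

  cv <- frac_lod_qc <- frac_lod_smp <- frac_na_zero <- numeric(p)
  reason <- rep("none", p)
  for (j in seq_len(p)) {
    qv <- conc[qc_rows, j]
    sv <- conc[smp_rows, j]
    lod <- mm$lod[j]
    cv[j] <- tryCatch(compute_cv(qv), error = function(e) NA_real_)
    frac_lod_qc[j] <- if (length(qc_rows) > 0) {
      mean(!is.na(qv) & qv < lod)
    } else 0
    frac_lod_smp[j] <- mean(!is.na(sv) & sv < lod)
    frac_na_zero[j] <- mean(is.na(sv) | sv == 0)

    if (cv_enabled && (is.na(cv[j]) || cv[j] > thresholds$cv_max)) {
      reason[j] <- "CV"
    } else if (length(qc_rows) > 0 &&
               ((thresholds$lod_qc_rule == "all" &&
                 all(!is.na(qv) & qv < lod) && length(qv) > 0) ||
                (thresholds$lod_qc_rule == "any" &&
                 any(!is.na(qv) & qv < lod)))) {
      reason[j] <- "LOD_QC"
    } else if (frac_lod_smp[j] > thresholds$lod_sample_frac) {
      reason[j] <- "LOD_SAMPLES"
    } else if (frac_na_zero[j] > thresholds$na_zero_frac) {
      reason[j] <- "NA_ZERO"
    }
  }

  report <- structure(list(
    metabolites = data.frame(
      name = mm$name,
      analyte_class = mm$analyte_class,
      cv_percent = cv,
      frac_below_lod_qc = frac_lod_qc,
      frac_below_lod_samples = frac_lod_smp,
      frac_na_zero = frac_na_zero,
      excluded = reason != "none",
      reason = reason,
      stringsAsFactors = FALSE
    ),
    outlier_samples = flag_outlier_samples(panel, cutoff = outlier_cutoff),
    thresholds = thresholds
  ), class = "QCReport")

  keep <- which(reason == "none")
  list(panel = subset_panel(panel, metabolites = keep), report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  tab <- table(x$metabolites$reason)
  cat("QCReport:", nrow(x$metabolites), "metabolites,",
      sum(x$metabolites$excluded), "excluded\n")
  cat("reasons:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("flagged outlier samples:", nrow(x$outlier_samples), "\n")
  invisible(x)
}

#' Flag outlier samples
#'
#' Advisory outlier screen over the non-QC samples: each metabolite is
#' centred and scaled to unit variance, missing values are median-imputed
#' for scoring only, and a sample's outlyingness is the robust z-score
#' (median/MAD) of its Euclidean distance from the centroid in that scaled
#' space. Samples scoring above the cutoff are flagged, never removed; an
#' all-NA sample is flagged unconditionally.
#'
#' @param panel a `MetabolitePanel` with >= 3 non-QC samples.
#' @param cutoff robust z-score above which a sample is flagged.
#' @return data.frame with columns `sample_id`, `score`, `flagged`,
#'   `reason`, restricted to flagged samples.
#' @export
flag_outlier_samples <- function(panel, cutoff = 3.5) {
  validate_panel(panel)
  smp <- which(!panel$sample_meta$is_qc)
  if (length(smp) < 3) {
    stop("outlier flagging requires >= 3 non-QC samples", call. = FALSE)
  }
  x <- panel$concentrations[smp, , drop = FALSE]
  all_na <- rowSums(!is.na(x)) == 0
  xs <- apply(x, 2, function(col) {
    col[is.na(col)] <- stats::median(col, na.rm = TRUE)
    s <- stats::sd(col)
    if (is.na(s) || s == 0) return(rep(0, length(col)))
    (col - mean(col)) / s
  })
  d <- sqrt(rowSums(xs^2))
  med <- stats::median(d)
  mad <- stats::mad(d)
  score <- if (mad > 0) (d - med) / mad else rep(0, length(d))
  flagged <- score > cutoff | all_na
  data.frame(
    sample_id = panel$sample_meta$sample_id[smp][flagged],
    score = score[flagged],
    reason = ifelse(all_na[flagged], "all_values_missing",
                    "distance_from_centroid"),
    stringsAsFactors = FALSE
  )
}
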