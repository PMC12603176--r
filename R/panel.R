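#' Construct a metabolite panel
#'
#' A `MetabolitePanel` is the single input currency of the pipeline: a
#' samples x metabolites concentration matrix (micromolar, `NA` allowed)
#' together with per-sample metadata (group label, sex, carcass weight,
#' QC-replicate flag) and per-metabolite metadata (analyte class, limit of
#' detection).
#'
#' @param concentrations numeric matrix, samples in rows, metabolites in
#'   columns; rownames are sample ids, colnames metabolite names. Non-NA
#'   entries must be >= 0.
#' @param sample_meta data.frame with columns `sample_id`, `group`, `sex`,
#'   `carcass_weight`, `is_qc`, one row per matrix row, in matrix order.
#' @param metabolite_meta data.frame with columns `name`, `analyte_class`,
#'   `lod`, one row per matrix column, in matrix order. If `NULL`, a
#'   default with class `"unknown"` and `lod = 0` is built.
#' @return object of class `MetabolitePanel`.
#' @examples
#' conc <- matrix(abs(rnorm(12, 10)), 4, 3,
#'                dimnames = list(paste0("s", 1:4), paste0("m", 1:3)))
#' meta <- data.frame(sample_id = rownames(conc),
#'                    group = c("A", "A", "B", "B"),
#'                    sex = c("F", "M", "F", "M"),
#'                    carcass_weight = c(120, 130, 125, 128),
#'                    is_qc = FALSE)
#' p <- metabolite_panel(conc, meta)
#' dim(p)
#' @export
metabolite_panel <- function(concentrations, sample_meta,
                             metabolite_meta = NULL) {
  concentrations <- as.matrix(concentrations)
  storage.mode(concentrations) <- "double"
  if (is.null(metabolite_meta)) {
    metabolite_meta <- data.frame(
      name = colnames(concentrations),
      analyte_class = "unknown",
      lod = 0,
      stringsAsFactors = FALSE
    )
  }
  panel <- structure(
    list(concentrations = concentrations,
         sample_meta = as.data.frame(sample_meta),
         metabolite_meta = as.data.frame(metabolite_meta)),
    class = "MetabolitePanel"
  )
  validate_panel(panel)
  panel
}

#' Validate a metabolite panel
#'
#' Checks the structural invariants: matrix dimensions match the metadata,
#' sample ids and metabolite names are unique, non-NA concentrations are
#' non-negative, weights positive, and required metadata columns present.
#'
#' @param panel a `MetabolitePanel`.
#' @return the panel, invisibly; stops with an informative error otherwise.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "MetabolitePanel"))
  conc <- panel$concentrations
  sm <- panel$sample_meta
  mm <- panel$metabolite_meta
  req_s <- c("sample_id", "group", "sex", "carcass_weight", "is_qc")
  miss <- setdiff(req_s, names(sm))
  if (length(miss) > 0) {
    stop("sample_meta is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  req_m <- c("name", "analyte_class", "lod")
  miss <- setdiff(req_m, names(mm))
  if (length(miss) > 0) {
    stop("metabolite_meta is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(conc) != nrow(sm)) {
    stop("concentration matrix has ", nrow(conc), " rows but sample_meta has ",
         nrow(sm), call. = FALSE)
  }
  if (ncol(conc) != nrow(mm)) {
    stop("concentration matrix has ", ncol(conc),
         " columns but metabolite_meta has ", nrow(mm), " rows",
         call. = FALSE)
  }
  if (anyDuplicated(sm$sample_id)) {
    dup <- unique(sm$sample_id[duplicated(sm$sample_id)])
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(mm$name)) {
    dup <- unique(mm$name[duplicated(mm$name)])
    stop("duplicate metabolite name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(conc < 0, na.rm = TRUE)) {
    stop("negative concentrations are not allowed", call. = FALSE)
  }
  if (any(!is.na(mm$lod) & mm$lod < 0)) {
    stop("negative LOD values are not allowed", call. = FALSE)
  }
  if (!is.logical(sm$is_qc)) {
    stop("is_qc must be logical", call. = FALSE)
  }
  invisible(panel)
}

#' @export
dim.MetabolitePanel <- function(x) dim(x$concentrations)

#' @export
print.MetabolitePanel <- function(x, ...) {
  sm <- x$sample_meta
  grp <- table(sm$group[!sm$is_qc])
  cat("MetabolitePanel: ", nrow(x$concentrations), " samples (",
      sum(sm$is_qc), " QC) x ", ncol(x$concentrations), " metabolites\n",
      sep = "")
  cat("groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  cat("analyte classes:",
      paste(sort(unique(x$metabolite_meta$analyte_class)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Subset a panel by samples and/or metabolites
#'
#' @param panel a `MetabolitePanel`.
#' @param samples logical/integer/character index into samples (default all).
#' @param metabolites logical/integer/character index into metabolites.
#' @return a `MetabolitePanel` restricted to the selection.
#' @export
subset_panel <- function(panel, samples = NULL, metabolites = NULL) {
  validate_panel(panel)
  if (is.null(samples)) samples <- seq_len(nrow(panel$concentrations))
  if (is.null(metabolites)) metabolites <- seq_len(ncol(panel$concentrations))
  if (is.character(samples)) {
    samples <- match(samples, panel$sample_meta$sample_id)
  }
  if (is.character(metabolites)) {
    metabolites <- match(metabolites, panel$metabolite_meta$name)
  }
  metabolite_panel(
    panel$concentrations[samples, metabolites, drop = FALSE],
    panel$sample_meta[samples, , drop = FALSE],
    panel$metabolite_meta[metabolites, , drop = FALSE]
  )
}

#' Specify a group comparison
#'
#' A comparison is either `pairwise` (exactly two group labels; the order
#' fixes the sign of the relative concentration difference) or `multiclass`
#' (two or more labels analysed jointly against a multi-level response).
#'
#' @param groups character vector of distinct group labels; length 2 for
#'   pairwise mode.
#' @param mode `"pairwise"` or `"multiclass"`.
#' @return object of class `ComparisonSpec`.
#' @export
comparison_spec <- function(groups, mode = c("pairwise", "multiclass")) {
  mode <- match.arg(mode)
  groups <- as.character(groups)
  if (anyDuplicated(groups)) stop("comparison groups must be distinct")
  if (mode == "pairwise" && length(groups) != 2) {
    stop("pairwise comparison requires exactly 2 groups")
  }
  if (length(groups) < 2) stop("a comparison requires at least 2 groups")
  structure(list(mode = mode, groups = groups), class = "ComparisonSpec")
}

#' @export
print.ComparisonSpec <- function(x, ...) {
  cat("ComparisonSpec [", x$mode, "]: ",
      paste(x$groups, collapse = " vs "), "\n", sep = "")
  invisible(x)
}

# Label used to namespace a comparison's artifacts, e.g. "ILA-IDU" or
# "multiclass-ILA-ILW-IDU".
comparison_label <- function(comparison) {
  if (comparison$mode == "pairwise") {
    paste(comparison$groups, collapse = "-")
  } else {
    paste(c("multiclass", comparison$groups), collapse = "-")
  }
}

# Check the comparison's groups exist in the panel with >= 2 non-QC samples.
check_comparison <- function(panel, comparison) {
  labs <- panel$sample_meta$group[!panel$sample_meta$is_qc]
  missing <- setdiff(comparison$groups, unique(labs))
  if (length(missing) > 0) {
    stop("comparison group(s) not present in panel: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
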