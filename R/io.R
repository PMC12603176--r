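#' File dialect for panel tables
#'
#' Wide-format tables are the interchange currency: one row per sample,
#' metadata columns first, then one column per metabolite. This helper
#' bundles the configurable parsing knobs so the reader is not hard-coded
#' to one export habit.
#'
#' @param sep field separator; `"\t"` (default) or `","`.
#' @param na_tokens character vector of tokens parsed as `NA`. `"<LOD"` is
#'   included by default because some vendor exports censor below-LOD
#'   values that way; a zero is never treated as missing.
#' @param meta_cols names of the required sample-metadata columns, in order.
#' @param precision number of significant digits written for floats.
#' @return a list of class `panel_dialect`.
#' @export
panel_dialect <- function(sep = "\t",
                          na_tokens = c("", "NA", "<LOD"),
                          meta_cols = c("sample_id", "group", "sex",
                                        "carcass_weight", "is_qc"),
                          precision = 10) {
  structure(list(sep = sep, na_tokens = na_tokens, meta_cols = meta_cols,
                 precision = precision),
            class = "panel_dialect")
}

#' Read a metabolite panel from a wide TSV/CSV file
#'
#' Expects the sample-metadata columns named by the dialect followed by one
#' numeric column per metabolite. An optional sidecar table supplies
#' per-metabolite analyte class and limit of detection; without it the
#' class is `"unknown"` and LOD is 0.
#'
#' @param path path to the wide table.
#' @param dialect a [panel_dialect()].
#' @param metabolite_meta_path optional path to a sidecar TSV with columns
#'   `name`, `analyte_class`, `lod`.
#' @return a validated [metabolite_panel()].
#' @export
read_panel <- function(path, dialect = panel_dialect(),
                       metabolite_meta_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  miss <- setdiff(dialect$meta_cols, names(raw))
  if (length(miss) > 0) {
    stop("input is missing required metadata column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  met_cols <- setdiff(names(raw), dialect$meta_cols)
  if (length(met_cols) == 0) stop("no metabolite columns found", call. = FALSE)

  parse_num <- function(x, col) {
    x[x %in% dialect$na_tokens] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      stop(sprintf("cannot parse value '%s' in column '%s', data row %d",
                   x[bad[1]], col, bad[1]), call. = FALSE)
    }
    out
  }
  parse_bool <- function(x, col) {
    x[x %in% dialect$na_tokens] <- NA_character_
    low <- tolower(x)
    out <- rep(NA, length(x))
    out[low %in% c("true", "t", "1", "yes")] <- TRUE
    out[low %in% c("false", "f", "0", "no")] <- FALSE
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      stop(sprintf("cannot parse value '%s' in column '%s', data row %d",
                   x[bad[1]], col, bad[1]), call. = FALSE)
    }
    out[is.na(out)] <- FALSE
    out
  }

  sm <- data.frame(
    sample_id = raw$sample_id,
    group = raw$group,
    sex = raw$sex,
    carcass_weight = parse_num(raw$carcass_weight, "carcass_weight"),
    is_qc = parse_bool(raw$is_qc, "is_qc"),
    stringsAsFactors = FALSE
  )
  conc <- vapply(met_cols, function(cn) parse_num(raw[[cn]], cn),
                 numeric(nrow(raw)))
  conc <- matrix(conc, nrow = nrow(raw),
                 dimnames = list(sm$sample_id, met_cols))

  mm <- NULL
  if (!is.null(metabolite_meta_path)) {
    mm <- utils::read.table(metabolite_meta_path, header = TRUE,
                            sep = dialect$sep, stringsAsFactors = FALSE,
                            check.names = FALSE, quote = "\"",
                            comment.char = "")
    need <- setdiff(c("name", "analyte_class", "lod"), names(mm))
    if (length(need) > 0) {
      stop("metabolite metadata is missing column(s): ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    mm <- mm[match(met_cols, mm$name), c("name", "analyte_class", "lod")]
    if (any(is.na(mm$name))) {
      stop("metabolite metadata does not cover all panel metabolites",
           call. = FALSE)
    }
  }
  metabolite_panel(conc, sm, mm)
}

#' Write a metabolite panel to a wide table
#'
#' Inverse of [read_panel()]: metadata columns then metabolite columns, at
#' the dialect's float precision. A sidecar metabolite-metadata table is
#' written alongside when `metabolite_meta_path` is given.
#'
#' @param panel a `MetabolitePanel`.
#' @param path output path.
#' @param dialect a [panel_dialect()].
#' @param metabolite_meta_path optional sidecar output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, dialect = panel_dialect(),
                        metabolite_meta_path = NULL) {
  validate_panel(panel)
  sm <- panel$sample_meta
  conc <- panel$concentrations
  df <- cbind(
    sm[, dialect$meta_cols, drop = FALSE],
    as.data.frame(conc, check.names = FALSE)
  )
  write_table(df, path, dialect = dialect, sort_by = NULL)
  if (!is.null(metabolite_meta_path)) {
    write_table(panel$metabolite_meta, metabolite_meta_path,
                dialect = dialect, sort_by = NULL)
  }
  invisible(path)
}

#' Write a result table as TSV
#'
#' All result tables leave the pipeline through this writer: header row,
#' floats at fixed precision, `NA` written as the literal token `"NA"`
#' (never an empty string), and a deterministic row order so repeated runs
#' are byte-identical.
#'
#' @param rows a data.frame with at least one column.
#' @param path output path.
#' @param dialect a [panel_dialect()]; controls separator and precision.
#' @param sort_by column name used as the sort key (default: first column);
#'   `NULL` keeps the input order.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, dialect = panel_dialect(),
                        sort_by = names(rows)[1]) {
  rows <- as.data.frame(rows)
  if (ncol(rows) == 0) stop("refusing to write a table with no columns")
  if (!is.null(sort_by) && nrow(rows) > 1) {
    if (!sort_by %in% names(rows)) {
      stop("sort key '", sort_by, "' is not a column")
    }
    rows <- rows[order(rows[[sort_by]], method = "radix"), , drop = FALSE]
  }
  fmt <- function(x) {
    if (is.double(x)) {
      out <- sprintf("%.*g", dialect$precision, x)
      out[is.na(x)] <- "NA"
      out
    } else if (is.logical(x)) {
      ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE"))
    } else {
      out <- as.character(x)
      out[is.na(x)] <- "NA"
      out
    }
  }
  mat <- vapply(rows, fmt, character(nrow(rows)))
  if (nrow(rows) == 1) mat <- matrix(mat, nrow = 1)
  con <- file(path, open = "wb")  # binary mode: LF endings on all platforms
  on.exit(close(con))
  writeLines(paste(names(rows), collapse = dialect$sep), con)
  if (nrow(rows) > 0) {
    writeLines(apply(mat, 1, paste, collapse = dialect$sep), con)
  }
  invisible(path)
}
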