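# Tabular omics data series: identifier-keyed rows, grouped sample columns,
# numeric matrix with missing values.

#' Construct an omics data series
#'
#' @param values Numeric matrix, rows = measured features, columns = samples
#'   (missing values as `NA`).
#' @param row_ids List of character vectors — each row may carry one
#'   identifier or a set of identifiers (typically database accessions).
#' @param samples Sample names; default taken from `colnames(values)`.
#' @param groups Optional named list partitioning the samples into groups
#'   (replicate structure, time points). Defaults to one group per sample.
#' @param name Series name.
#' @param annotations Character vector of free-text metadata lines.
#' @return A `bnv_series` object.
#' @export
data_series <- function(values, row_ids, samples = colnames(values),
                        groups = NULL, name = "series",
                        annotations = character()) {
  values <- as.matrix(values)
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(values)))
  if (length(row_ids) != nrow(values))
    rlang::abort("row_ids length must match the number of rows")
  if (length(samples) != ncol(values))
    rlang::abort("samples length must match the number of columns")
  if (is.null(groups)) groups <- stats::setNames(as.list(samples), samples)
  flat <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(flat) || !setequal(flat, samples))
    rlang::abort("groups must partition the samples (cover all, no overlap)")
  colnames(values) <- samples
  structure(list(name = name, row_ids = lapply(row_ids, as.character),
                 samples = samples, groups = groups, values = values,
                 annotations = annotations),
            class = "bnv_series")
}

#' @export
print.bnv_series <- function(x, ...) {
  cat(sprintf("<bnv_series> '%s': %d rows x %d samples in %d group(s)\n",
              x$name, nrow(x$values), length(x$samples), length(x$groups)))
  invisible(x)
}

#' Tidy a data series into long form
#'
#' @param x A `bnv_series`.
#' @param ... Unused.
#' @return A tibble with columns row, id (first identifier), sample, group,
#'   value.
#' @export
tidy.bnv_series <- function(x, ...) {
  gmap <- stats::setNames(
    rep(names(x$groups), lengths(x$groups)), unlist(x$groups))
  tibble::tibble(
    row = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    id = rep(vapply(x$row_ids, function(r)
      if (length(r)) r[1] else NA_character_, ""), times = ncol(x$values)),
    sample = rep(x$samples, each = nrow(x$values)),
    group = unname(gmap[rep(x$samples, each = nrow(x$values))]),
    value = as.vector(x$values))
}

#' Read tabular omics data (CSV, TSV or minimal SOFT)
#'
#' The leading `id_cols` column(s) key the rows (an identifier cell may hold
#' several accessions separated by `id_sep`); the header row names the
#' samples; remaining cells are parsed numerically with blanks and
#' non-numeric tokens becoming missing values. The SOFT dialect parses the
#' lines between `!sample_table_begin` and `!sample_table_end` as TSV and
#' keeps `!`-prefixed metadata lines as annotations.
#'
#' @param text File content (string or lines) or a file path.
#' @param dialect "csv", "tsv" or "soft".
#' @param id_cols Number of leading identifier columns (default 1).
#' @param id_sep Separator splitting multiple accessions inside one
#'   identifier cell (default ";").
#' @param name Series name; defaults to the dialect.
#' @return A `bnv_series`. Duplicate row identifiers are kept and flagged in
#'   the `"duplicate_rows"` attribute.
#' @export
read_table <- function(text, dialect = c("tsv", "csv", "soft"), id_cols = 1,
                       id_sep = ";", name = NULL) {
  dialect <- match.arg(dialect)
  lines <- as_lines(text)
  annotations <- character()
  if (dialect == "soft") {
    beg <- grep("^!sample_table_begin", lines)
    end <- grep("^!sample_table_end", lines)
    if (length(beg) == 0 || length(end) == 0)
      rlang::abort("SOFT input lacks !sample_table_begin/!sample_table_end")
    annotations <- grep("^!", lines, value = TRUE)
    annotations <- annotations[!grepl("^!sample_table_(begin|end)",
                                      annotations)]
    lines <- lines[(beg[1] + 1):(end[1] - 1)]
  }
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                          header = TRUE, colClasses = "character",
                          check.names = FALSE, quote = "\"",
                          comment.char = "", blank.lines.skip = TRUE)
  if (ncol(df) <= id_cols)
    rlang::abort("table has no numeric (sample) columns")
  idpart <- df[, seq_len(id_cols), drop = FALSE]
  row_ids <- lapply(seq_len(nrow(df)), function(i) {
    raw <- unlist(idpart[i, ], use.names = FALSE)
    unique(trimws(unlist(strsplit(raw, id_sep, fixed = TRUE))))
  })
  num <- df[, -seq_len(id_cols), drop = FALSE]
  values <- suppressWarnings(
    matrix(as.numeric(as.matrix(num)), nrow = nrow(df),
           dimnames = list(NULL, colnames(num))))
  if (all(is.na(values)) && nrow(values) > 0)
    rlang::abort("table has no numeric column")
  keys <- vapply(row_ids, paste, "", collapse = ";")
  dup <- unique(keys[duplicated(keys)])
  ser <- data_series(values, row_ids,
                     name = name %||% paste0(dialect, "_series"),
                     annotations = annotations)
  attr(ser, "duplicate_rows") <- dup
  ser
}

`%||%` <- function(a, b) if (is.null(a)) b else a
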