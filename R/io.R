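split_fields <- function(line, delim) strsplit(line, delim, fixed = TRUE)[[1L]]

detect_delim <- function(line) {
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t"
  else if (grepl(",", line, fixed = TRUE)) ","
  else abort("cannot detect delimiter (no tab or comma in the header line)")
}

parse_numeric_cells <- function(fields, line_no) {
  vals <- suppressWarnings(as.numeric(fields))
  bad <- which(is.na(vals) & !(fields %in% c("NA", "nan", "NaN")))
  if (length(bad))
    abort("non-numeric cell(s) on line ", line_no, ": '",
          paste(fields[bad], collapse = "', '"), "'")
  if (anyNA(vals))
    abort("missing value(s) on line ", line_no)
  vals
}

#' Read a delimited expression table
#'
#' Parses a TSV/CSV table with a header row and a leading identifier
#' column into an [expression_matrix()].  The default orientation is genes
#' in rows and samples in columns; `orientation = "samples_by_genes"`
#' transposes after parsing.  The delimiter is auto-detected from the
#' header (tab, then comma) unless forced.  Duplicate identifiers, ragged
#' rows and non-numeric cells are reported with their line number.
#'
#' @param path file path.
#' @param orientation `"genes_by_samples"` (default) or
#'   `"samples_by_genes"`.
#' @param delim `"\t"`, `","` or NULL to auto-detect.
#' @param scale scale tag for the resulting matrix.
#' @return an `otcc_expression`.
#' @export
read_expression_table <- function(path,
                                  orientation = c("genes_by_samples",
                                                  "samples_by_genes"),
                                  delim = NULL,
                                  scale = c("raw_intensity", "log10")) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort("table needs a header and at least one row")
  delim <- delim %||% detect_delim(lines[[1L]])
  header <- split_fields(lines[[1L]], delim)
  col_ids <- header[-1L]
  ncols <- length(col_ids)
  if (ncols < 1L) abort("header has no sample columns")
  row_ids <- character(length(lines) - 1L)
  values <- matrix(NA_real_, nrow = length(lines) - 1L, ncol = ncols)
  for (i in seq_along(lines)[-1L]) {
    fields <- split_fields(lines[[i]], delim)
    if (length(fields) != ncols + 1L)
      abort("ragged row on line ", i, ": expected ", ncols + 1L,
            " fields, found ", length(fields))
    row_ids[i - 1L] <- fields[1L]
    values[i - 1L, ] <- parse_numeric_cells(fields[-1L], i)
  }
  if (anyDuplicated(row_ids))
    abort("duplicate row id(s): ",
          paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  if (anyDuplicated(col_ids))
    abort("duplicate column id(s): ",
          paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  if (orientation == "samples_by_genes") {
    values <- t(values)
    tmp <- row_ids; row_ids <- col_ids; col_ids <- tmp
  }
  expression_matrix(values, gene_ids = row_ids, sample_ids = col_ids,
                    scale = scale)
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()] in the genes-by-samples
#' orientation; full double precision is kept so a write/read round trip
#' is bit-identical.
#'
#' @param expr an `otcc_expression`.
#' @param path output path.
#' @param delim field delimiter.
#' @export
write_expression_table <- function(expr, path, delim = "\t") {
  stopifnot(inherits(expr, "otcc_expression"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", expr$sample_ids), collapse = delim), con)
  body <- vapply(seq_len(nrow(expr$values)), function(i)
    paste(c(expr$gene_ids[i],
            format(expr$values[i, ], digits = 17, trim = TRUE,
                   scientific = FALSE)), collapse = delim), character(1))
  writeLines(body, con)
}

#' Write a similarity matrix as annotated TSV
#'
#' The first line is a `#scale=` comment carrying the scale tag, so that a
#' reader can refuse to unit-map an already unit-scale matrix (or feed a
#' signed matrix to a strict solver) instead of failing silently.
#'
#' @param sim an `otcc_similarity`.
#' @param path output path.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "otcc_similarity"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#scale=", sim$scale), con)
  writeLines(paste(c("sample_id", sim$sample_ids), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(sim$values)), function(i)
    paste(c(sim$sample_ids[i],
            format(sim$values[i, ], digits = 17, trim = TRUE,
                   scientific = FALSE)), collapse = "\t"), character(1))
  writeLines(body, con)
}

#' Read a similarity TSV written by [write_similarity()]
#'
#' @param path file path.
#' @return an `otcc_similarity`.
#' @export
read_similarity <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!startsWith(lines[[1L]], "#scale="))
    abort("similarity file must start with a #scale= line")
  scale <- sub("^#scale=", "", lines[[1L]])
  if (!scale %in% c("pearson_raw", "unit"))
    abort("unknown similarity scale '", scale, "'")
  header <- split_fields(lines[[2L]], "\t")
  ids <- header[-1L]
  n <- length(ids)
  if (length(lines) != n + 2L)
    abort("expected ", n, " matrix rows, found ", length(lines) - 2L)
  values <- matrix(NA_real_, n, n)
  row_ids <- character(n)
  for (i in seq_len(n)) {
    fields <- split_fields(lines[[i + 2L]], "\t")
    if (length(fields) != n + 1L)
      abort("ragged row on line ", i + 2L)
    row_ids[i] <- fields[1L]
    values[i, ] <- parse_numeric_cells(fields[-1L], i + 2L)
  }
  if (!identical(row_ids, ids))
    abort("row ids do not match column ids")
  similarity_matrix(values, sample_ids = ids, scale = scale)
}

#' Read / write two-column label tables
#'
#' Plain TSV with header `sample_id<TAB>class_id`; the format used both
#' for known labels (prediction input) and for hard calls (output).
#'
#' @param path file path.
#' @return data.frame with `sample_id` and `class_id`.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#")
  if (!all(c("sample_id", "class_id") %in% names(df)))
    abort("label file needs columns sample_id and class_id")
  df
}

#' @rdname read_labels
#' @param labels named character vector (names = sample ids) or a
#'   data.frame with `sample_id` / `class_id`.
#' @param confidence optional numeric vector aligned with `labels`.
#' @export
write_labels <- function(labels, path, confidence = NULL) {
  df <- if (is.data.frame(labels)) labels
  else data.frame(sample_id = names(labels), class_id = as.character(labels),
                  stringsAsFactors = FALSE)
  if (!is.null(confidence)) df$confidence <- round(confidence, 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

newick_quote <- function(x) {
  needs <- grepl("[][(),:;'[:space:]]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Newick serialization of a discovery tree
#'
#' Every sample becomes a Newick tip; a multi-member leaf cluster becomes
#' a polytomy so that cluster membership is recoverable as a clade.
#' Internal nodes are labeled with their minimum inner similarity to four
#' decimals.  Identifiers containing Newick-reserved characters are
#' single-quoted.
#'
#' @param tree an `otcc_tree`.
#' @return a Newick string terminated by `;`.
#' @export
as_newick <- function(tree) {
  stopifnot(inherits(tree, "otcc_tree"))
  lab <- function(x) if (is.finite(x)) sprintf("%.4f", x) else ""
  build <- function(node) {
    tips <- newick_quote(tree$sample_ids[node$members])
    if (is.null(node$children)) {
      if (length(tips) == 1L) return(tips)
      return(paste0("(", paste(tips, collapse = ","), ")",
                    lab(node$inner_min_similarity)))
    }
    paste0("(", build(node$children[[1L]]), ",",
           build(node$children[[2L]]), ")", lab(node$inner_min_similarity))
  }
  body <- build(tree$root)
  if (!startsWith(body, "(")) body <- paste0("(", body, ")")
  paste0(body, ";")
}

#' @rdname as_newick
#' @param path output path.
#' @export
write_tree_newick <- function(tree, path) {
  writeLines(as_newick(tree), path)
  invisible(path)
}

#' Parse a class tree from a Newick string or file
#'
#' Converts a Newick description of the relationship between class ids
#' (tips = class ids) into the nested-list form consumed by
#' [predict_multiclass_tree()].  Non-binary nodes are refused.
#'
#' @param x a Newick string (containing `;`) or a file path.
#' @return nested 2-element lists with character leaves.
#' @export
read_class_tree <- function(x) {
  txt <- if (grepl(";", x, fixed = TRUE)) x else paste0(readLines(x), collapse = "")
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) abort("could not parse Newick class tree")
  build <- function(node) {
    kids <- phy$edge[phy$edge[, 1L] == node, 2L]
    if (length(kids) == 0L) return(phy$tip.label[node])
    if (length(kids) != 2L)
      abort("class tree must be strictly binary; node has ", length(kids),
            " children")
    list(build(kids[1L]), build(kids[2L]))
  }
  build(length(phy$tip.label) + 1L)
}
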