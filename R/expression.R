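#' Expression matrix container
#'
#' Lightweight container for a genes x samples expression table, the raw
#' input of similarity construction.  Values must be finite; identifier
#' lists must match the matrix dimensions.  The `scale` tag records whether
#' the values are raw hybridization intensities or already
#' log10-transformed, so that downstream steps can refuse to re-apply the
#' preprocessing recipe.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of row identifiers (default: rownames).
#' @param sample_ids character vector of column identifiers (default:
#'   colnames).
#' @param scale `"raw_intensity"` for untransformed chip intensities,
#'   `"log10"` after the clip/filter/log10 recipe.
#' @return an object of class `otcc_expression` with fields `values`,
#'   `gene_ids`, `sample_ids`, `scale`.
#' @seealso [preprocess_expression()], [pearson_similarity()]
#' @export
expression_matrix <- function(values,
                              gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              scale = c("raw_intensity", "log10")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    abort("expression values must be a numeric matrix (genes x samples)")
  if (any(!is.finite(values)))
    abort("expression values contain missing or non-finite entries")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    abort("gene_ids length (", length(gene_ids), ") != number of rows (",
          nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    abort("sample_ids length (", length(sample_ids), ") != number of columns (",
          ncol(values), ")")
  if (anyDuplicated(gene_ids)) abort("duplicate gene ids")
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, scale = scale),
            class = "otcc_expression")
}

#' @export
print.otcc_expression <- function(x, ...) {
  cat(sprintf("<otcc_expression> %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Clip, filter and log-transform raw microarray intensities
#'
#' Standard informative-gene preprocessing for two-color / oligonucleotide
#' intensity data: intensities are clipped into `[floor, ceiling]`, genes
#' whose across-sample variation after clipping is weak -- fold change
#' `max/min <= fold_min` OR absolute range `max - min <= diff_min` -- are
#' discarded, and the surviving values are log10-transformed.  The defaults
#' (16000 / 100 / 5 / 500) are the conventional thresholds for the classic
#' 6817-gene acute leukemia chips.
#'
#' The step order is fixed: clip, then filter (on the clipped values), then
#' log.  Clipping is idempotent, so re-clipping preprocessed intensities is
#' a no-op; the `scale` tag nevertheless guards against running the recipe
#' twice.
#'
#' @param expr an [expression_matrix()] with `scale = "raw_intensity"`.
#' @param ceiling,floor intensity clip bounds; `ceiling > floor > 0`.
#' @param fold_min genes with clipped `max/min <= fold_min` are removed.
#' @param diff_min genes with clipped `max - min <= diff_min` are removed.
#' @return an `otcc_expression` with the surviving genes, log10 values and
#'   `scale = "log10"`.
#' @export
preprocess_expression <- function(expr, ceiling = 16000, floor = 100,
                                  fold_min = 5, diff_min = 500) {
  stopifnot(inherits(expr, "otcc_expression"))
  if (expr$scale != "raw_intensity")
    abort("preprocess_expression expects raw intensities; input is already '",
          expr$scale, "'")
  if (!is_number(floor) || floor <= 0) abort("floor must be > 0")
  if (!is_number(ceiling) || ceiling <= floor) abort("ceiling must exceed floor")
  v <- pmin(pmax(expr$values, floor), ceiling)
  gmax <- apply(v, 1L, max)
  gmin <- apply(v, 1L, min)
  keep <- !(gmax / gmin <= fold_min | gmax - gmin <= diff_min)
  if (!any(keep))
    abort("no genes survive filtering: every gene has max/min <= ", fold_min,
          " or max - min <= ", diff_min)
  expression_matrix(log10(v[keep, , drop = FALSE]),
                    gene_ids = expr$gene_ids[keep],
                    sample_ids = expr$sample_ids,
                    scale = "log10")
}

#' Select phenotype-correlated biomarker genes
#'
#' Ranks genes by the absolute Pearson correlation of their expression with
#' a binary phenotype and keeps those exceeding `r_threshold` (strictly, in
#' absolute value), optionally truncated to the strongest `top_k`.  This is
#' the biomarker rule used for contrasts such as normal-vs-cancer or
#' stromal-vs-epithelial; run it once per contrast and union the results if
#' several contrasts are of interest.
#'
#' Genes with zero variance across samples have no defined correlation and
#' are silently excluded (with a diagnostic message), unlike in similarity
#' construction where a degenerate sample is a hard error.
#'
#' @param expr an [expression_matrix()].
#' @param phenotype 0/1 (or two-level) vector of length `m` samples.
#' @param r_threshold absolute-correlation cutoff in (0, 1); default 0.6.
#' @param top_k optional cap on the number of genes returned.
#' @return integer vector of gene indices, ordered by decreasing `|r|`
#'   (ties by gene index), with the correlations as a `"r"` attribute.
#' @export
select_biomarkers <- function(expr, phenotype, r_threshold = 0.6,
                              top_k = NULL) {
  stopifnot(inherits(expr, "otcc_expression"))
  ph <- phenotype
  if (is.factor(ph) || is.character(ph)) ph <- as.integer(factor(ph)) - 1L
  ph <- as.numeric(ph)
  if (length(ph) != ncol(expr$values))
    abort("phenotype length must equal the number of samples")
  if (length(unique(ph)) != 2L)
    abort("phenotype must contain exactly two classes, both present")
  if (!is_number(r_threshold) || r_threshold <= 0 || r_threshold >= 1)
    abort("r_threshold must lie in (0, 1)")
  sds <- apply(expr$values, 1L, stats::sd)
  degenerate <- sds == 0
  if (any(degenerate))
    message(sum(degenerate), " zero-variance gene(s) excluded from ",
            "biomarker selection (undefined correlation)")
  r <- rep(NA_real_, nrow(expr$values))
  ok <- which(!degenerate)
  if (length(ok))
    r[ok] <- as.vector(stats::cor(t(expr$values[ok, , drop = FALSE]), ph))
  hits <- which(!is.na(r) & abs(r) > r_threshold)
  hits <- hits[order(-abs(r[hits]), hits)]
  if (!is.null(top_k)) {
    if (!is_count(top_k)) abort("top_k must be a positive integer")
    hits <- utils::head(hits, top_k)
  }
  structure(hits, r = r[hits])
}
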