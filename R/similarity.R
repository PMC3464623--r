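#' Sample-similarity matrix container
#'
#' Symmetric N x N matrix of pairwise sample-similarity scores, the sole
#' input of the labeling model.  The `scale` tag distinguishes raw Pearson
#' correlations on `[-1, 1]` from unit-mapped scores on `[0, 1]`; carrying
#' the tag explicitly lets downstream code refuse a double unit-mapping or
#' a criterion evaluated on the wrong scale.
#'
#' Validation enforces symmetry to 1e-10 and a unit diagonal (the scale
#' maximum, which both scales share).  Entries of `unit`-scale matrices
#' must lie in `[0, 1]`; `pearson_raw` entries are nominally in `[-1, 1]`
#' but the range is not enforced so that noise-perturbed simulated
#' matrices, which can leave the interval, remain representable on the
#' signed scale.
#'
#' @param values numeric N x N symmetric matrix.
#' @param sample_ids character vector of length N (default: rownames).
#' @param scale `"pearson_raw"` or `"unit"`.
#' @return object of class `otcc_similarity`.
#' @export
similarity_matrix <- function(values, sample_ids = rownames(values),
                              scale = c("pearson_raw", "unit")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    abort("similarity values must be a numeric matrix")
  check_symmetric(values, tol = 1e-10, what = "similarity matrix")
  if (any(!is.finite(values))) abort("similarity values must be finite")
  n <- nrow(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n)
    abort("sample_ids length (", length(sample_ids), ") != matrix order (",
          n, ")")
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids")
  if (max(abs(diag(values) - 1)) > 1e-6)
    abort("similarity diagonal must equal the scale maximum (1)")
  if (scale == "unit" &&
      (min(values) < -1e-10 || max(values) > 1 + 1e-10))
    abort("unit-scale similarities must lie in [0, 1]")
  values <- (values + t(values)) / 2   # remove sub-tolerance asymmetry
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(values = values, sample_ids = sample_ids, scale = scale),
            class = "otcc_similarity")
}

#' @export
print.otcc_similarity <- function(x, ...) {
  cat(sprintf("<otcc_similarity> %d samples, scale = %s, range [%.3f, %.3f]\n",
              length(x$sample_ids), x$scale, min(x$values), max(x$values)))
  invisible(x)
}

#' First-order Pearson sample similarity
#'
#' Pairwise Pearson correlation between sample expression profiles (columns
#' of the expression matrix), the basic similarity measure on the signed
#' `[-1, 1]` scale.  The correlation is normalization-invariant, so the
#' population-vs-sample variance convention cancels and the result does not
#' depend on it.
#'
#' @param expr an [expression_matrix()] with at least 2 genes.
#' @return an `otcc_similarity` with `scale = "pearson_raw"` and unit
#'   diagonal.
#' @export
pearson_similarity <- function(expr) {
  stopifnot(inherits(expr, "otcc_expression"))
  if (nrow(expr$values) < 2L)
    abort("at least 2 genes are required to correlate samples")
  sds <- apply(expr$values, 2L, stats::sd)
  if (any(sds == 0))
    abort("zero-variance sample column(s): ",
          paste(expr$sample_ids[sds == 0], collapse = ", "),
          "; Pearson similarity is undefined for them")
  s <- stats::cor(expr$values)
  diag(s) <- 1
  similarity_matrix(s, sample_ids = expr$sample_ids, scale = "pearson_raw")
}

#' Second-order (correlation-of-correlations) similarity
#'
#' Treats row i of a first-order similarity matrix -- sample i's vector of
#' similarities to every sample -- as that sample's feature vector, and
#' correlates those rows pairwise.  Two samples are second-order similar
#' when they relate to the whole cohort in the same way, which injects
#' global structure that pairwise first-order correlation cannot see.  This
#' is the similarity used to expose subtle subtype structure.
#'
#' Pearson correlation is invariant under a common positive affine
#' transform of the inputs, so the result is identical whether the
#' first-order matrix is on the raw or the unit scale.
#'
#' @param first_order an `otcc_similarity`, N >= 3.
#' @return an `otcc_similarity` with `scale = "pearson_raw"`.
#' @export
second_order_similarity <- function(first_order) {
  stopifnot(inherits(first_order, "otcc_similarity"))
  v <- first_order$values
  if (nrow(v) < 3L) abort("second-order similarity needs at least 3 samples")
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0))
    abort("constant similarity row(s): ",
          paste(first_order$sample_ids[sds == 0], collapse = ", "),
          "; second-order correlation is undefined for them")
  s <- stats::cor(t(v))
  diag(s) <- 1
  similarity_matrix(s, sample_ids = first_order$sample_ids,
                    scale = "pearson_raw")
}

#' Map raw correlations onto the unit interval
#'
#' The affine map `s -> (s + 1) / 2` takes `[-1, 1]` to `[0, 1]`,
#' producing the non-negative similarities required for the convexity
#' guarantee of the labeling model.  The map is strictly increasing, so
#' the ranking of sample pairs is preserved.  Applying it twice would
#' silently compress the scale; a matrix already on the unit scale is
#' therefore rejected.
#'
#' @param sim an `otcc_similarity` with `scale = "pearson_raw"`.
#' @return the unit-scale `otcc_similarity`.
#' @export
rescale_unit <- function(sim) {
  stopifnot(inherits(sim, "otcc_similarity"))
  if (sim$scale != "pearson_raw")
    abort("similarity is already on the unit scale; refusing to map twice")
  similarity_matrix((sim$values + 1) / 2, sample_ids = sim$sample_ids,
                    scale = "unit")
}

# Matrix on the scale actually handed to the solver.  Raw-scale input is
# clipped at zero ("permissive" route); unit-scale input is used as is.
solver_values <- function(sim, clip = c("permissive", "strict", "unit")) {
  clip <- match.arg(clip)
  v <- sim$values
  if (sim$scale == "unit") return(v)
  if (clip == "unit") return((v + 1) / 2)
  neg <- sum(v < 0)
  if (neg > 0) {
    if (clip == "strict")
      abort(neg, " negative similarity entries; strict mode requires ",
            "non-negative similarities (rescale_unit() or clip them)")
    message("clipped ", neg, " negative similarity entries to 0 for solving")
    v[v < 0] <- 0
  }
  v
}
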