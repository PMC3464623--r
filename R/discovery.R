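#' Most-dissimilar seed pair
#'
#' Class discovery has no labeled samples, so seeds come from the
#' most-dissimilar assumption: the pair of samples with the minimal
#' similarity must belong to different classes (otherwise there is only
#' one class).  When several pairs tie at the minimum, the tie is broken
#' by re-ranking the tied pairs on entries of the matrix powers S^2, S^3,
#' ... up to `max_power` -- a pair that is also dissimilar through
#' longer paths is the better seed choice.  A tie surviving every power is
#' resolved lexicographically (smallest `(i, j)`) with a degeneracy
#' warning of class `otcc_degenerate_tie`.
#'
#' Only originally tied pairs enter the power re-ranking; powers are
#' computed on the member-restricted matrix on the scale of `sim` as
#' given.  Floating-point ties are detected with a small relative
#' tolerance, since algebraically identical entries of a correlation
#' matrix can differ in the last bit depending on summation order.
#'
#' @param sim an `otcc_similarity`.
#' @param members indices of the samples to consider (default: all).
#' @param max_power largest matrix power tried for tie-breaking.
#' @return integer vector `c(a, b)` of global sample indices, `a < b`;
#'   `a` receives Class Zero.
#' @export
find_seed_pair <- function(sim, members = NULL, max_power = 5L) {
  stopifnot(inherits(sim, "otcc_similarity"))
  v <- sim$values
  if (is.null(members)) members <- seq_len(nrow(v))
  members <- as.integer(members)
  if (length(members) < 2L) abort("need at least 2 members to pick a seed pair")
  sub <- v[members, members, drop = FALSE]
  m <- length(members)
  pairs <- which(upper.tri(sub), arr.ind = TRUE)   # local i < j
  vals <- sub[pairs]
  tie_tol <- function(x) 1e-9 * max(1, abs(x))
  lo <- min(vals)
  cand <- which(vals - lo <= tie_tol(lo))
  if (length(cand) > 1L && max_power >= 2L) {
    P <- sub
    for (p in 2:max_power) {
      P <- P %*% sub
      pv <- P[pairs[cand, , drop = FALSE]]
      lo <- min(pv)
      cand <- cand[pv - lo <= tie_tol(lo)]
      if (length(cand) == 1L) break
    }
  }
  if (length(cand) > 1L) {
    warning(warningCondition(paste0(
      length(cand), " seed-pair candidates still tied after S^", max_power,
      "; using the lexicographically smallest pair"),
      class = "otcc_degenerate_tie"))
    ord <- order(pairs[cand, 1L], pairs[cand, 2L])
    cand <- cand[ord[1L]]
  }
  local <- pairs[cand[1L], ]
  sort(members[local])
}

#' Minimum within-cluster similarity
#'
#' The quantity behind the stopping rule of recursive discovery: a cluster
#' whose least similar member pair is still above the tolerance threshold
#' is considered homogeneous and is not split further.  Singletons return
#' `+Inf` and therefore never split.
#'
#' @param sim an `otcc_similarity` (or plain matrix).
#' @param members indices of the cluster members.
#' @return the minimum off-diagonal similarity among `members`.
#' @export
min_inner_similarity <- function(sim, members) {
  v <- if (inherits(sim, "otcc_similarity")) sim$values else sim
  members <- as.integer(members)
  if (length(members) < 1L) abort("members must be nonempty")
  if (length(members) == 1L) return(Inf)
  sub <- v[members, members, drop = FALSE]
  min(sub[upper.tri(sub)])
}

#' One divisive split of a cluster
#'
#' Seeds the member set with its most-dissimilar pair, solves the labeling
#' model on the member-restricted similarity and thresholds at 0.5.  The
#' Class-Zero side can act as a "pseudo-cluster": members with no positive
#' coupling to either seed keep the initialization value 0 and land there,
#' to be separated by a later split.
#'
#' @param sim an `otcc_similarity`.
#' @param members indices to split (at least 2).
#' @param clip negative-similarity policy passed to [label_problem()];
#'   default clips raw-scale similarities at zero.
#' @param tol,max_iter fixed-point solver controls.
#' @param max_power tie-break depth for [find_seed_pair()].
#' @return list with integer vectors `left` (Class Zero, contains seed a)
#'   and `right` (Class One, contains seed b), the `seed_pair`, and the
#'   continuous `solution`.
#' @export
split_cluster <- function(sim, members = NULL, clip = "permissive",
                          tol = 1e-6, max_iter = 10000L, max_power = 5L) {
  stopifnot(inherits(sim, "otcc_similarity"))
  if (is.null(members)) members <- seq_len(nrow(sim$values))
  members <- as.integer(members)
  if (length(members) < 2L) abort("cannot split fewer than 2 members")
  seeds <- find_seed_pair(sim, members, max_power = max_power)
  sub <- similarity_matrix(sim$values[members, members, drop = FALSE],
                           sample_ids = sim$sample_ids[members],
                           scale = sim$scale)
  prob <- label_problem(sub, match(seeds[1L], members), match(seeds[2L], members),
                        clip = clip)
  sol <- solve_iterative(prob, tol = tol, max_iter = max_iter,
                         record_objective = FALSE)
  bin <- binarize(sol, 0.5)
  list(left = members[bin == 0L], right = members[bin == 1L],
       seed_pair = seeds, solution = sol)
}

new_cluster_node <- function(members, inner, seed_pair = NULL,
                             children = NULL) {
  list(members = members, inner_min_similarity = inner,
       seed_pair = seed_pair, children = children)
}

#' Recursive divisive class discovery
#'
#' Repeatedly applies [split_cluster()] to every cluster whose minimum
#' within-cluster similarity lies below `threshold`, producing a binary
#' cluster tree whose leaves partition the samples.  The procedure needs
#' no preset number of clusters -- the threshold is a minimum tolerated
#' within-class similarity, a quantity a domain expert can set directly.
#' With `threshold = -Inf` nothing splits; with a threshold above the
#' largest similarity the recursion continues to single-sample leaves,
#' exposing the full fine structure.
#'
#' The stopping criterion is evaluated on `criterion_scale`: by default
#' the similarity values as given (`"input"`), which for raw Pearson input
#' makes `threshold = 0` the natural choice (negative correlation within a
#' cluster means it must split).  The solver itself consumes non-negative
#' values via the `clip` policy, so criterion scale and optimization scale
#' are decoupled.  Discovery is fully deterministic.
#'
#' @param sim an `otcc_similarity`, N >= 2.
#' @param threshold stopping threshold on the minimum inner similarity.
#' @param criterion_scale `"input"` (as given), `"raw"` or `"unit"` to
#'   evaluate the criterion after converting to that scale.
#' @param clip,tol,max_iter,max_power passed to [split_cluster()].
#' @return an `otcc_tree`; see [tree_leaves()], [tree_assignments()],
#'   [as_newick()], [cluster_summary()].
#' @export
discover <- function(sim, threshold = 0,
                     criterion_scale = c("input", "raw", "unit"),
                     clip = "permissive", tol = 1e-6, max_iter = 10000L,
                     max_power = 5L) {
  stopifnot(inherits(sim, "otcc_similarity"))
  criterion_scale <- match.arg(criterion_scale)
  n <- nrow(sim$values)
  if (n < 2L) abort("discovery needs at least 2 samples")
  crit <- switch(criterion_scale,
                 input = sim$values,
                 raw   = if (sim$scale == "unit") 2 * sim$values - 1 else sim$values,
                 unit  = if (sim$scale == "pearson_raw") (sim$values + 1) / 2 else sim$values)
  recurse <- function(members, depth) {
    if (depth > n) abort("recursion depth exceeded the number of samples")
    inner <- min_inner_similarity(crit, members)
    if (length(members) == 1L || inner >= threshold)
      return(new_cluster_node(members, inner))
    sp <- split_cluster(sim, members, clip = clip, tol = tol,
                        max_iter = max_iter, max_power = max_power)
    new_cluster_node(members, inner, seed_pair = sp$seed_pair,
                     children = list(recurse(sp$left, depth + 1L),
                                     recurse(sp$right, depth + 1L)))
  }
  root <- recurse(seq_len(n), 1L)
  structure(list(root = root, sample_ids = sim$sample_ids,
                 threshold = threshold, criterion_scale = criterion_scale),
            class = "otcc_tree")
}

#' Leaf clusters of a discovery tree
#'
#' @param tree an `otcc_tree`.
#' @return list of integer index vectors, left-to-right; together they
#'   partition the samples.
#' @export
tree_leaves <- function(tree) {
  stopifnot(inherits(tree, "otcc_tree"))
  out <- list()
  walk <- function(node) {
    if (is.null(node$children)) out[[length(out) + 1L]] <<- node$members
    else for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  out
}

#' Flat cluster assignment table
#'
#' @param tree an `otcc_tree`.
#' @return data.frame with `sample_id`, `leaf_id` (1-based, left-to-right)
#'   and `path`, the root-to-leaf bitstring ("0" = Class-Zero branch).
#' @export
tree_assignments <- function(tree) {
  stopifnot(inherits(tree, "otcc_tree"))
  rows <- list()
  walk <- function(node, path) {
    if (is.null(node$children)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = tree$sample_ids[node$members],
        leaf_id = NA_integer_, path = path, stringsAsFactors = FALSE)
    } else {
      walk(node$children[[1L]], paste0(path, "0"))
      walk(node$children[[2L]], paste0(path, "1"))
    }
  }
  walk(tree$root, "")
  for (i in seq_along(rows)) rows[[i]]$leaf_id <- i
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.otcc_tree <- function(x, ...) {
  lv <- tree_leaves(x)
  cat(sprintf("<otcc_tree> %d samples, %d leaf cluster(s), threshold = %g\n",
              length(x$sample_ids), length(lv), x$threshold))
  for (i in seq_along(lv))
    cat(sprintf("  leaf %d: %s\n", i,
                paste(x$sample_ids[lv[[i]]], collapse = " ")))
  invisible(x)
}

#' Within- and between-cluster mean similarities
#'
#' Averages the pairwise similarities within each leaf (off-diagonal
#' pairs) and between each leaf pair, on the scale of the matrix passed
#' in.  Equal between-cluster means are the signature of clusters that are
#' mutually equivalent rather than hierarchically nested.
#'
#' @param sim an `otcc_similarity`.
#' @param tree an `otcc_tree` with at least 2 leaves.
#' @return data.frame with `leaf_i`, `leaf_j`, `mean_similarity`,
#'   `n_pairs`; rows with `leaf_i == leaf_j` are within-cluster means
#'   (`NA` for singleton leaves).
#' @export
cluster_summary <- function(sim, tree) {
  stopifnot(inherits(sim, "otcc_similarity"), inherits(tree, "otcc_tree"))
  lv <- tree_leaves(tree)
  if (length(lv) < 2L) abort("cluster_summary needs a tree with >= 2 leaves")
  v <- sim$values
  rows <- list()
  for (i in seq_along(lv)) for (j in i:length(lv)) {
    if (i == j) {
      sub <- v[lv[[i]], lv[[i]], drop = FALSE]
      np <- length(lv[[i]]) * (length(lv[[i]]) - 1L) / 2L
      m <- if (np > 0) mean(sub[upper.tri(sub)]) else NA_real_
    } else {
      sub <- v[lv[[i]], lv[[j]], drop = FALSE]
      np <- length(sub)
      m <- mean(sub)
    }
    rows[[length(rows) + 1L]] <- data.frame(leaf_i = i, leaf_j = j,
                                            mean_similarity = m, n_pairs = np)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
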