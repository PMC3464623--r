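#' Known-label set for class prediction
#'
#' Normalizes user-supplied gold-standard labels into a canonical form:
#' a named character vector of class ids keyed by sample id, plus the
#' ordered class list.  Class order defaults to order of first appearance
#' and matters for seed orientation (first class = Class Zero in binary
#' prediction) and for deterministic tie-breaking in the multi-class
#' strategies.
#'
#' @param x a data.frame with columns `sample_id` and `class_id`, or a
#'   named vector (names = sample ids, values = class ids).
#' @param classes optional explicit class order.
#' @return object of class `otcc_known`.
#' @export
known_labels <- function(x, classes = NULL) {
  if (is.data.frame(x)) {
    if (!all(c("sample_id", "class_id") %in% names(x)))
      abort("label data.frame needs columns sample_id and class_id")
    ids <- as.character(x$sample_id)
    cls <- as.character(x$class_id)
  } else {
    if (is.null(names(x))) abort("label vector must be named by sample id")
    ids <- names(x)
    cls <- as.character(x)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    conf <- vapply(dup, function(d) length(unique(cls[ids == d])) > 1L, logical(1))
    if (any(conf))
      abort("sample(s) labeled with more than one class: ",
            paste(dup[conf], collapse = ", "))
    keep <- !duplicated(ids)
    ids <- ids[keep]; cls <- cls[keep]
  }
  if (is.null(classes)) classes <- default_classes(cls)
  classes <- as.character(classes)
  if (!all(cls %in% classes))
    abort("labels contain classes outside the declared class list")
  structure(list(assignments = stats::setNames(cls, ids), classes = classes),
            class = "otcc_known")
}

#' @export
print.otcc_known <- function(x, ...) {
  cat(sprintf("<otcc_known> %d labeled samples, classes: %s\n",
              length(x$assignments), paste(x$classes, collapse = ", ")))
  invisible(x)
}

check_known <- function(sim, known) {
  if (!inherits(known, "otcc_known")) known <- known_labels(known)
  miss <- setdiff(names(known$assignments), sim$sample_ids)
  if (length(miss))
    abort("labeled sample id(s) absent from the similarity matrix: ",
          paste(miss, collapse = ", "))
  present <- known$classes[known$classes %in% known$assignments]
  if (length(present) < length(known$classes))
    abort("class(es) without any labeled sample: ",
          paste(setdiff(known$classes, present), collapse = ", "))
  known
}

#' Binary class prediction from partial labels
#'
#' The prediction setting of the labeling model: the labeled samples of
#' the first class form seed set A (Class Zero), those of the second class
#' seed set B (Class One); solving the model propagates the labels to the
#' unlabeled samples, which are then thresholded at `cutoff`.  Known
#' labels are fixed by the constraints and are never altered.
#'
#' @param sim an `otcc_similarity`.
#' @param known an [known_labels()] object (or coercible) with exactly 2
#'   classes.
#' @param cutoff decision threshold; 0.5 unless learned from the training
#'   labels, see [learn_cutoff()].
#' @param clip negative-similarity policy for [label_problem()].
#' @param tol,max_iter solver controls.
#' @return list with `labels` (named character vector of class ids for all
#'   samples), `confidence` (`2 |f - 0.5|`, 1 at the seeds) and the
#'   continuous `solution`.
#' @export
predict_binary <- function(sim, known, cutoff = 0.5, clip = "permissive",
                           tol = 1e-6, max_iter = 10000L) {
  stopifnot(inherits(sim, "otcc_similarity"))
  known <- check_known(sim, known)
  if (length(known$classes) != 2L)
    abort("predict_binary needs exactly 2 classes; got ",
          length(known$classes))
  ass <- known$assignments
  a_ids <- names(ass)[ass == known$classes[1L]]
  b_ids <- names(ass)[ass == known$classes[2L]]
  prob <- label_problem(sim, a_ids, b_ids, clip = clip)
  sol <- solve_iterative(prob, tol = tol, max_iter = max_iter,
                         record_objective = FALSE)
  bin <- binarize(sol, cutoff)
  labels <- known$classes[bin + 1L]
  names(labels) <- sim$sample_ids
  labels[names(ass)] <- ass                # seeds keep their labels exactly
  conf <- 2 * abs(sol$f - 0.5)
  conf[match(names(ass), sim$sample_ids)] <- 1
  list(labels = labels, confidence = stats::setNames(conf, sim$sample_ids),
       solution = sol)
}

class_tree_leaves <- function(node) {
  if (is.character(node)) return(node)
  c(class_tree_leaves(node[[1L]]), class_tree_leaves(node[[2L]]))
}

left_deep_class_tree <- function(classes) {
  node <- classes[[1L]]
  for (k in classes[-1L]) node <- list(node, k)
  node
}

#' Multi-class prediction along a class tree
#'
#' When the known classes have a meaningful hierarchical relationship, the
#' binary model is applied recursively along a binary tree over class ids:
#' at each internal node the labeled samples under the left subtree seed
#' Class Zero, those under the right subtree seed Class One, unlabeled
#' samples are thresholded and passed down the matching branch until a
#' leaf assigns their class.  A tree that contradicts the real class
#' structure injects wrong prior information and degrades accuracy, so an
#' arbitrary tree is a fallback, not a free choice; if none is supplied, a
#' left-deep tree in class order is used with a warning.
#'
#' @param sim an `otcc_similarity`.
#' @param known an [known_labels()] object; every class needs a labeled
#'   sample.
#' @param class_tree nested 2-element lists with class-id character
#'   leaves, e.g. `list(list("c1", "c2"), "c3")`, or NULL.
#' @param cutoff,clip,tol,max_iter as in [predict_binary()].
#' @return named character vector of class ids for all samples.
#' @export
predict_multiclass_tree <- function(sim, known, class_tree = NULL,
                                    cutoff = 0.5, clip = "permissive",
                                    tol = 1e-6, max_iter = 10000L) {
  stopifnot(inherits(sim, "otcc_similarity"))
  known <- check_known(sim, known)
  if (is.null(class_tree)) {
    if (length(known$classes) > 2L)
      warning("no class tree supplied; using a left-deep tree in class order",
              call. = FALSE)
    class_tree <- left_deep_class_tree(known$classes)
  }
  tl <- class_tree_leaves(class_tree)
  if (!setequal(tl, known$classes) || anyDuplicated(tl))
    abort("class tree leaves must be exactly the known classes, once each")
  ass <- known$assignments
  out <- stats::setNames(rep(NA_character_, length(sim$sample_ids)),
                         sim$sample_ids)
  walk <- function(node, ids, path) {
    if (is.character(node)) { out[ids] <<- node; return(invisible()) }
    lcl <- class_tree_leaves(node[[1L]])
    rcl <- class_tree_leaves(node[[2L]])
    a_ids <- intersect(ids, names(ass)[ass %in% lcl])
    b_ids <- intersect(ids, names(ass)[ass %in% rcl])
    if (!length(a_ids) || !length(b_ids))
      abort("class-tree node '", path, "' has no labeled sample on the ",
            if (length(a_ids)) "right" else "left", " side")
    sub <- similarity_matrix(
      sim$values[ids, ids, drop = FALSE],
      sample_ids = ids, scale = sim$scale)
    prob <- label_problem(sub, a_ids, b_ids, clip = clip)
    sol <- solve_iterative(prob, tol = tol, max_iter = max_iter,
                           record_objective = FALSE)
    bin <- binarize(sol, cutoff)
    walk(node[[1L]], ids[bin == 0L], paste0(path, "0"))
    walk(node[[2L]], ids[bin == 1L], paste0(path, "1"))
  }
  walk(class_tree, sim$sample_ids, "")
  out[names(ass)] <- ass
  out
}

# Membership scores: one model per class with that class's labeled samples
# as Class One and every other labeled sample as Class Zero.
one_vs_all_scores <- function(sim, known, clip, tol, max_iter) {
  ass <- known$assignments
  scores <- sapply(known$classes, function(cl) {
    b_ids <- names(ass)[ass == cl]
    a_ids <- names(ass)[ass != cl]
    prob <- label_problem(sim, a_ids, b_ids, clip = clip)
    solve_iterative(prob, tol = tol, max_iter = max_iter,
                    record_objective = FALSE)$f
  })
  rownames(scores) <- sim$sample_ids
  scores
}

#' One-vs-all multi-class prediction
#'
#' For each class c a binary model is solved with the labeled samples of c
#' as Class One and all other labeled samples as Class Zero; sample i's
#' score for c is its continuous label f_c(i), and each unlabeled sample
#' is assigned to the class with the largest score, ties broken by class
#' order.  No cutoff is involved: the argmax over per-class membership
#' scores replaces thresholding.
#'
#' @param sim an `otcc_similarity`.
#' @param known an [known_labels()] object with >= 2 classes.
#' @param clip,tol,max_iter as in [predict_binary()].
#' @return list with `labels` (named character vector) and the N x K
#'   `scores` matrix.
#' @export
predict_one_vs_all <- function(sim, known, clip = "permissive",
                               tol = 1e-6, max_iter = 10000L) {
  stopifnot(inherits(sim, "otcc_similarity"))
  known <- check_known(sim, known)
  if (length(known$classes) < 2L) abort("need at least 2 known classes")
  scores <- one_vs_all_scores(sim, known, clip, tol, max_iter)
  pick <- apply(scores, 1L, function(r) which(r == max(r))[1L])
  degen <- apply(scores, 1L, function(r) all(abs(r - r[1L]) < 1e-12))
  if (any(degen[!sim$sample_ids %in% names(known$assignments)]))
    message("tied one-vs-all scores for ",
            sum(degen & !sim$sample_ids %in% names(known$assignments)),
            " sample(s); first class by order assigned")
  labels <- stats::setNames(known$classes[pick], sim$sample_ids)
  labels[names(known$assignments)] <- known$assignments
  list(labels = labels, scores = scores)
}

#' One-vs-one multi-class prediction by pairwise voting
#'
#' Runs [predict_binary()] on every unordered class pair, restricted to
#' the samples labeled with either class plus all unlabeled samples, and
#' assigns each unlabeled sample the class winning most pairwise votes
#' (ties broken by class order).
#'
#' @inheritParams predict_one_vs_all
#' @param cutoff threshold for each pairwise model.
#' @return list with `labels` and the N x K `votes` matrix.
#' @export
predict_one_vs_one <- function(sim, known, cutoff = 0.5, clip = "permissive",
                               tol = 1e-6, max_iter = 10000L) {
  stopifnot(inherits(sim, "otcc_similarity"))
  known <- check_known(sim, known)
  K <- length(known$classes)
  if (K < 2L) abort("need at least 2 known classes")
  ass <- known$assignments
  votes <- matrix(0L, nrow = length(sim$sample_ids), ncol = K,
                  dimnames = list(sim$sample_ids, known$classes))
  unl <- setdiff(sim$sample_ids, names(ass))
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    ci <- known$classes[i]; cj <- known$classes[j]
    ids <- c(names(ass)[ass %in% c(ci, cj)], unl)
    ids <- sim$sample_ids[sim$sample_ids %in% ids]   # keep matrix order
    sub <- similarity_matrix(sim$values[ids, ids, drop = FALSE],
                             sample_ids = ids, scale = sim$scale)
    kn <- known_labels(ass[ass %in% c(ci, cj)], classes = c(ci, cj))
    pred <- predict_binary(sub, kn, cutoff = cutoff, clip = clip,
                           tol = tol, max_iter = max_iter)
    for (id in ids) votes[id, pred$labels[[id]]] <- votes[id, pred$labels[[id]]] + 1L
  }
  pick <- apply(votes, 1L, function(r) which(r == max(r))[1L])
  labels <- stats::setNames(known$classes[pick], sim$sample_ids)
  labels[names(ass)] <- ass
  list(labels = labels, votes = votes)
}

#' Learn a decision cutoff by cross-validation
#'
#' Grid-searches the binarization cutoff by k-fold cross-validation on the
#' labeled samples: each fold is held out, the model is solved with the
#' remaining labels as seeds, and every candidate cutoff is scored by its
#' held-out accuracy.  Ties between cutoffs go to the one closest to the
#' default 0.5 (then the smaller).  Folds are stratified by class; a fold
#' that would empty one class's seed set is skipped.
#'
#' @param sim an `otcc_similarity`.
#' @param known an [known_labels()] object with exactly 2 classes.
#' @param folds number of CV folds.
#' @param grid candidate cutoffs.
#' @param seed optional RNG seed for the fold assignment.
#' @param clip,tol,max_iter solver controls.
#' @return list with the selected `cutoff` and the per-cutoff mean
#'   held-out `accuracy` table.
#' @export
learn_cutoff <- function(sim, known, folds = 5L,
                         grid = seq(0.05, 0.95, by = 0.05), seed = NULL,
                         clip = "permissive", tol = 1e-6, max_iter = 10000L) {
  stopifnot(inherits(sim, "otcc_similarity"))
  known <- check_known(sim, known)
  if (length(known$classes) != 2L)
    abort("cutoff learning is defined for the binary setting")
  ass <- known$assignments
  ids <- names(ass)
  fold_of <- with_seed(seed, {
    f <- integer(length(ids))
    for (cl in known$classes) {
      sel <- which(ass == cl)
      f[sel] <- sample(rep_len(seq_len(folds), length(sel)))
    }
    f
  })
  acc <- matrix(NA_real_, nrow = folds, ncol = length(grid))
  for (k in seq_len(folds)) {
    hold <- ids[fold_of == k]
    train <- ass[setdiff(ids, hold)]
    if (length(hold) == 0L || length(unique(train)) < 2L) next
    prob <- label_problem(sim, names(train)[train == known$classes[1L]],
                          names(train)[train == known$classes[2L]],
                          clip = clip)
    f <- solve_iterative(prob, tol = tol, max_iter = max_iter,
                         record_objective = FALSE)$f
    fh <- f[match(hold, sim$sample_ids)]
    truth <- ass[hold]
    for (g in seq_along(grid))
      acc[k, g] <- mean(known$classes[(fh >= grid[g]) + 1L] == truth)
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  best <- which(mean_acc == max(mean_acc))
  best <- best[order(abs(grid[best] - 0.5), grid[best])][1L]
  list(cutoff = grid[best],
       accuracy = data.frame(cutoff = grid, accuracy = mean_acc))
}
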