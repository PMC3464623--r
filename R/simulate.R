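#' Noisy two-class block similarity matrix
#'
#' Simulates the benchmark similarity structure directly: one class of
#' `size_small` samples (default 5) and one of `size_small * ratio`
#' samples, with within-class similarity 1, between-class similarity 0 and
#' a unit diagonal.  I.i.d. Gaussian noise with mean 0 and standard
#' deviation `sigma` is drawn for the strict upper triangle and mirrored,
#' keeping the matrix symmetric; the diagonal is left noise-free.  Noise
#' can leave `[0, 1]`, so the result is tagged on the signed
#' `pearson_raw` scale and is normally solved in permissive (clip at 0)
#' mode.
#'
#' @param size_small size of the first (small) class.
#' @param ratio the second class has `ratio`-fold the samples of the
#'   first.
#' @param sigma noise standard deviation, >= 0.
#' @param seed optional RNG seed; the caller's RNG stream is preserved.
#' @return list with `sim` (an `otcc_similarity`) and `labels` (integer
#'   vector, 0 for the small class, 1 for the large one).
#' @export
make_two_class_similarity <- function(size_small = 5L, ratio = 1L,
                                      sigma = 0, seed = NULL) {
  if (!is_count(size_small)) abort("size_small must be a positive integer")
  if (!is_count(ratio)) abort("ratio must be a positive integer")
  if (!is_number(sigma) || sigma < 0) abort("sigma must be >= 0")
  n1 <- as.integer(size_small)
  n2 <- n1 * as.integer(ratio)
  n <- n1 + n2
  labels <- c(rep(0L, n1), rep(1L, n2))
  s <- outer(labels, labels, `==`) * 1
  diag(s) <- 1
  if (sigma > 0) {
    noise <- with_seed(seed, stats::rnorm(n * (n - 1) / 2, 0, sigma))
    up <- upper.tri(s)
    s[up] <- s[up] + noise
    s[lower.tri(s)] <- t(s)[lower.tri(s)]   # mirror the noisy triangle
  }
  sim <- similarity_matrix(s, sample_ids = paste0("s", seq_len(n)),
                           scale = "pearson_raw")
  list(sim = sim, labels = labels)
}

#' Graph of fully connected components
#'
#' Builds the 0/1 adjacency matrix of a disjoint union of complete graphs
#' (one per entry of `component_sizes`), optionally perturbed by
#' `inter_links` distinct random between-component edges added
#' symmetrically.  The balanced three-component case
#' (`component_sizes = c(5, 5, 5)`, no links) is the canonical example of
#' a multi-cluster structure that is not inherently a binary tree.
#'
#' @param component_sizes integer vector, each >= 2.
#' @param inter_links number of between-component edges to add.
#' @param seed optional RNG seed for the link placement.
#' @return list with the `adjacency` matrix and `labels`, the component
#'   index of each node.
#' @export
make_component_graph <- function(component_sizes = c(5L, 5L, 5L),
                                 inter_links = 0L, seed = NULL) {
  sizes <- as.integer(component_sizes)
  if (length(sizes) < 1L || any(sizes < 2L))
    abort("every component needs at least 2 nodes")
  if (!is_count(inter_links, min = 0L)) abort("inter_links must be >= 0")
  labels <- rep(seq_along(sizes), sizes)
  n <- length(labels)
  adj <- (outer(labels, labels, `==`)) * 1
  diag(adj) <- 0
  if (inter_links > 0L) {
    cross <- which(upper.tri(adj) & outer(labels, labels, `!=`),
                   arr.ind = TRUE)
    if (inter_links > nrow(cross))
      abort("inter_links = ", inter_links, " exceeds the ", nrow(cross),
            " available between-component pairs")
    pick <- with_seed(seed, sample.int(nrow(cross), inter_links))
    for (k in pick) {
      adj[cross[k, 1L], cross[k, 2L]] <- 1
      adj[cross[k, 2L], cross[k, 1L]] <- 1
    }
  }
  dimnames(adj) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  list(adjacency = adj, labels = labels)
}

#' Similarity from graph connectivity
#'
#' Pairwise Pearson correlation of the rows of an adjacency matrix: two
#' nodes are similar when they connect to the same neighbours.  For a
#' disjoint union of complete graphs this yields positive within-component
#' and negative between-component scores (e.g. 29/44 and -4/11 for three
#' 5-cliques), so a discovery threshold of 0 separates the components.
#'
#' @param adjacency square symmetric 0/1 matrix with zero diagonal.
#' @return an `otcc_similarity` with `scale = "pearson_raw"`.
#' @export
graph_similarity <- function(adjacency) {
  a <- adjacency
  if (!is.matrix(a) || nrow(a) != ncol(a)) abort("adjacency must be square")
  if (!all(a %in% c(0, 1))) abort("adjacency must be 0/1")
  check_symmetric(a, tol = 0, what = "adjacency matrix")
  if (any(diag(a) != 0)) abort("adjacency diagonal must be zero")
  deg <- rowSums(a)
  if (any(deg == 0)) {
    ids <- rownames(a) %||% as.character(seq_len(nrow(a)))
    abort("isolated node(s) with no connections: ",
          paste(ids[deg == 0], collapse = ", "))
  }
  # constant rows (complete graph) would also break cor(); degree>0 plus a
  # zero diagonal guarantees each row has both 0s and 1s for n >= 2
  s <- stats::cor(t(a))
  diag(s) <- 1
  ids <- rownames(a) %||% paste0("n", seq_len(nrow(a)))
  similarity_matrix(s, sample_ids = ids, scale = "pearson_raw")
}

permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], p)
  out
}

#' Clustering accuracy under optimal label matching
#'
#' Cluster labels are arbitrary, so accuracy is the maximal fraction of
#' agreements over all bijections between predicted and true class ids
#' (exhaustive search over permutations of the union of label sets; fine
#' for the handfuls of classes used here).
#'
#' @param predicted,truth equal-length label vectors (any atomic type).
#' @return accuracy in `[0, 1]`.
#' @export
clustering_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    abort("label vectors must have equal length")
  lab <- unique(c(as.character(predicted), as.character(truth)))
  if (length(lab) > 8L)
    abort("more than 8 distinct labels; exhaustive matching refused")
  p <- match(as.character(predicted), lab)
  t <- match(as.character(truth), lab)
  best <- 0
  for (perm in permutations(seq_along(lab)))
    best <- max(best, mean(perm[p] == t))
  best
}

# One unsupervised two-class run: most-dissimilar seeding + a single split.
single_split_labels <- function(sim, tol = 1e-6, max_iter = 10000L) {
  sp <- split_cluster(sim, clip = "permissive", tol = tol,
                      max_iter = max_iter)
  out <- integer(length(sim$sample_ids))
  out[sp$right] <- 1L
  out
}

#' Discovery accuracy benchmark over a noise / class-ratio grid
#'
#' For every `(ratio, sigma)` cell, generates `reps` noisy two-class
#' block similarity matrices, runs one unsupervised split (most-dissimilar
#' seeding, fixed-point solve, 0.5 cutoff) and records the mean
#' permutation-matched clustering accuracy with its standard error.  The
#' published protocol uses 1000 replicates per cell; the test-suite runs
#' 100 to stay within desk runtime, which widens the Monte-Carlo error to
#' about half a percentage point.
#'
#' @param ratios integer vector of class-size ratios.
#' @param sigmas numeric vector of noise standard deviations.
#' @param size_small small-class size (default 5).
#' @param reps replicates per cell.
#' @param seed master seed; every cell/replicate derives deterministically
#'   from it.
#' @param tol,max_iter solver controls.
#' @return data.frame with `ratio`, `sigma`, `reps`, `mean_accuracy`,
#'   `se`.
#' @export
run_discovery_benchmark <- function(ratios = c(1L, 2L, 5L, 10L),
                                    sigmas = seq(0, 0.5, by = 0.1),
                                    size_small = 5L, reps = 1000L,
                                    seed = 1L, tol = 1e-6,
                                    max_iter = 10000L) {
  if (!is_count(reps)) abort("reps must be a positive integer")
  grid <- expand.grid(ratio = ratios, sigma = sigmas,
                      KEEP.OUT.ATTRS = FALSE)
  res <- with_seed(seed, {
    acc <- matrix(NA_real_, nrow = nrow(grid), ncol = reps)
    for (g in seq_len(nrow(grid))) {
      for (r in seq_len(reps)) {
        dat <- make_two_class_similarity(size_small, grid$ratio[g],
                                         grid$sigma[g], seed = NULL)
        pred <- suppressWarnings(suppressMessages(
          single_split_labels(dat$sim, tol = tol, max_iter = max_iter)))
        acc[g, r] <- clustering_accuracy(pred, dat$labels)
      }
    }
    acc
  })
  data.frame(ratio = grid$ratio, sigma = grid$sigma, reps = reps,
             mean_accuracy = rowMeans(res),
             se = apply(res, 1L, stats::sd) / sqrt(reps))
}

#' Prediction accuracy sweep over known-label counts
#'
#' Estimates how prior knowledge helps: for each grid cell `(k0, k1)` and
#' each replicate, a similarity matrix with true two-class labels is
#' obtained from `sim_source`, `k0` / `k1` known labels are sampled
#' uniformly within each class, the remaining samples are predicted with
#' [predict_binary()] and scored against the truth.  Cells requesting more
#' known labels than a class holds are skipped with a warning.
#'
#' @param sim_source either a function `(rep_index) -> list(sim, labels)`
#'   generating a fresh instance per replicate, or a fixed
#'   `list(sim, labels)` reused across replicates (then only the label
#'   sampling varies).
#' @param k0_grid,k1_grid known-label counts for class 0 / class 1.
#' @param reps replicates per cell.
#' @param seed master seed.
#' @param cutoff,tol,max_iter prediction controls.
#' @return data.frame with `k0`, `k1`, `reps`, `mean_accuracy`, `se`
#'   (accuracy over the unlabeled samples only).
#' @export
run_prediction_sweep <- function(sim_source, k0_grid = 1:4, k1_grid = 1:4,
                                 reps = 1000L, seed = 1L, cutoff = 0.5,
                                 tol = 1e-6, max_iter = 10000L) {
  if (!is_count(reps)) abort("reps must be a positive integer")
  fixed <- !is.function(sim_source)
  grid <- expand.grid(k0 = k0_grid, k1 = k1_grid, KEEP.OUT.ATTRS = FALSE)
  res <- with_seed(seed, {
    acc <- matrix(NA_real_, nrow = nrow(grid), ncol = reps)
    for (r in seq_len(reps)) {
      dat <- if (fixed) sim_source else sim_source(r)
      idx0 <- which(dat$labels == 0L)
      idx1 <- which(dat$labels == 1L)
      for (g in seq_len(nrow(grid))) {
        k0 <- grid$k0[g]; k1 <- grid$k1[g]
        if (k0 > length(idx0) || k1 > length(idx1)) next
        kn0 <- idx0[sample.int(length(idx0), k0)]
        kn1 <- idx1[sample.int(length(idx1), k1)]
        known <- known_labels(stats::setNames(
          as.character(dat$labels[c(kn0, kn1)]),
          dat$sim$sample_ids[c(kn0, kn1)]), classes = c("0", "1"))
        pred <- suppressMessages(
          predict_binary(dat$sim, known, cutoff = cutoff, tol = tol,
                         max_iter = max_iter))
        unl <- setdiff(seq_along(dat$labels), c(kn0, kn1))
        acc[g, r] <- mean(pred$labels[unl] == as.character(dat$labels[unl]))
      }
    }
    acc
  })
  skipped <- apply(res, 1L, function(x) all(is.na(x)))
  if (any(skipped))
    warning(sum(skipped), " cell(s) skipped: more known labels requested ",
            "than class members available", call. = FALSE)
  data.frame(k0 = grid$k0, k1 = grid$k1, reps = reps,
             mean_accuracy = rowMeans(res),
             se = apply(res, 1L, stats::sd) / sqrt(reps))
}
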