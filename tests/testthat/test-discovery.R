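test_that("unique-minimum seed pair needs no power tie-break", {
  s <- diag(8)
  s[upper.tri(s)] <- seq(0.2, 0.2 + 27 * 0.01, by = 0.01)
  s[3, 7] <- s[7, 3] <- 0.05   # unique minimum
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  diag(s) <- 1
  sim <- similarity_matrix(s, scale = "unit")
  expect_identical(find_seed_pair(sim), c(3L, 7L))
})

test_that("tied minima are separated by S^2, verified by an explicit power oracle", {
  s <- matrix(0.5, 6, 6)
  s[1, 2] <- s[2, 1] <- 0
  s[3, 4] <- s[4, 3] <- 0
  s[3, 5] <- s[5, 3] <- 0.2
  s[4, 5] <- s[5, 4] <- 0.2
  diag(s) <- 1
  sim <- similarity_matrix(s, scale = "unit")
  # oracle: brute-force S^2 entries for the two tied pairs
  s2 <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) for (k in 1:6) s2[i, j] <- s2[i, j] + s[i, k] * s[k, j]
  expect_lt(s2[3, 4], s2[1, 2])
  expect_identical(find_seed_pair(sim), c(3L, 4L))
})

test_that("fully degenerate ties fall back lexicographically with a warning", {
  s <- matrix(0.4, 5, 5); diag(s) <- 1
  sim <- similarity_matrix(s, scale = "unit")
  expect_warning(pair <- find_seed_pair(sim), class = "otcc_degenerate_tie")
  expect_identical(pair, c(1L, 2L))
})

test_that("min_inner_similarity covers singleton, pair and restriction", {
  sim <- random_unit_sim(6)
  expect_identical(min_inner_similarity(sim, 3), Inf)
  two <- similarity_matrix(matrix(c(1, 0.3, 0.3, 1), 2, 2), scale = "unit")
  expect_equal(min_inner_similarity(two, 1:2), 0.3)
  sub <- sim$values[2:5, 2:5]
  expect_equal(min_inner_similarity(sim, 2:5), min(sub[upper.tri(sub)]))
})

test_that("perfect two-block similarity splits exactly", {
  s <- matrix(0, 8, 8)
  s[1:3, 1:3] <- 1; s[4:8, 4:8] <- 1; diag(s) <- 1
  sim <- similarity_matrix(s, scale = "unit")
  sp <- suppressWarnings(split_cluster(sim))
  groups <- list(sort(sp$left), sort(sp$right))
  expect_true(identical(groups[[1]], 1:3) || identical(groups[[2]], 1:3))
  expect_true(identical(groups[[1]], 4:8) || identical(groups[[2]], 4:8))
})

test_that("split agrees with exhaustive minimum-cut labeling on a small noisy instance", {
  dat <- make_two_class_similarity(4L, 1L, sigma = 0.1, seed = 42L)
  sim <- dat$sim
  S <- suppressMessages(otcc:::solver_values(sim, "permissive"))
  seeds <- find_seed_pair(sim)
  n <- 8L
  # oracle: enumerate all 2^8 binary labelings honoring the seeds, pick the
  # minimum of the model objective
  best <- NULL; best_obj <- Inf
  for (code in 0:(2^n - 1)) {
    f <- as.integer(intToBits(code)[1:n])
    if (f[seeds[1]] != 0L || f[seeds[2]] != 1L) next
    obj <- 0.5 * sum(S * outer(f, f, `-`)^2)
    if (obj < best_obj) { best_obj <- obj; best <- f }
  }
  sp <- suppressMessages(split_cluster(sim))
  pred <- integer(n); pred[sp$right] <- 1L
  expect_equal(clustering_accuracy(pred, best), 1.0)
})

test_that("three-component graph is resolved through the pseudo-cluster route", {
  fx <- fig2a_sim()
  sp <- suppressMessages(suppressWarnings(split_cluster(fx$sim)))
  expect_identical(sp$seed_pair, c(1L, 6L))
  expect_identical(sort(sp$left), c(1:5, 11:15))
  expect_identical(sort(sp$right), 6:10)
  tree <- suppressMessages(suppressWarnings(discover(fx$sim, threshold = 0)))
  leaves <- lapply(tree_leaves(tree), sort)
  expect_length(leaves, 3L)
  expect_true(all(vapply(list(1:5, 6:10, 11:15), function(comp)
    any(vapply(leaves, identical, logical(1), comp)), logical(1))))
})

test_that("threshold extremes give one leaf and all-singleton leaves", {
  set.seed(13)
  sim <- random_unit_sim(7)
  one <- discover(sim, threshold = -1)
  expect_length(tree_leaves(one), 1L)
  all_single <- suppressWarnings(discover(sim, threshold = 1 + 1e-9,
                                          criterion_scale = "input"))
  expect_length(tree_leaves(all_single), 7L)
  expect_partition(tree_leaves(all_single), 7L)
})

test_that("leaves partition the samples and threshold is monotone in leaf count", {
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(6:14, 1)
    sim <- random_unit_sim(n)
    thresholds <- c(0.2, 0.5, 0.8)
    counts <- integer(0)
    for (th in thresholds) {
      tr <- suppressWarnings(discover(sim, threshold = th))
      expect_partition(tree_leaves(tr), n)
      counts <- c(counts, length(tree_leaves(tr)))
    }
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("discovery is deterministic", {
  set.seed(37)
  sim <- random_unit_sim(10)
  t1 <- suppressWarnings(discover(sim, threshold = 0.6))
  t2 <- suppressWarnings(discover(sim, threshold = 0.6))
  expect_identical(tree_leaves(t1), tree_leaves(t2))
  expect_identical(as_newick(t1), as_newick(t2))
})

test_that("cluster_summary equals a brute-force double loop", {
  set.seed(29)
  sim <- random_unit_sim(9)
  tree <- suppressWarnings(discover(sim, threshold = 0.7))
  lv <- tree_leaves(tree)
  if (length(lv) < 2L) skip("random instance produced a single leaf")
  tab <- cluster_summary(sim, tree)
  for (row in seq_len(nrow(tab))) {
    i <- tab$leaf_i[row]; j <- tab$leaf_j[row]
    vals <- c()
    for (a in lv[[i]]) for (b in lv[[j]])
      if (i != j || a < b) vals <- c(vals, sim$values[a, b])
    if (is.null(vals)) {
      expect_true(is.na(tab$mean_similarity[row]))   # singleton within-leaf
    } else {
      expect_equal(tab$mean_similarity[row], mean(vals), tolerance = 1e-12)
    }
  }
})

test_that("perfect-block tree summary: between mean 0, within mean 1", {
  s <- matrix(0, 6, 6); s[1:3, 1:3] <- 1; s[4:6, 4:6] <- 1; diag(s) <- 1
  sim <- similarity_matrix(s, scale = "unit")
  tree <- suppressWarnings(discover(sim, threshold = 0.5))
  tab <- cluster_summary(sim, tree)
  expect_equal(tab$mean_similarity[tab$leaf_i != tab$leaf_j], 0)
  expect_equal(tab$mean_similarity[tab$leaf_i == tab$leaf_j], c(1, 1))
})
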