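test_that("known_labels normalizes input and rejects contradictions", {
  df <- data.frame(sample_id = c("a", "b", "c"), class_id = c("x", "y", "x"))
  kn <- known_labels(df)
  expect_identical(kn$classes, c("x", "y"))
  expect_identical(unname(kn$assignments["c"]), "x")
  expect_error(known_labels(data.frame(sample_id = c("a", "a"),
                                       class_id = c("x", "y"))),
               "more than one class")
  expect_error(known_labels(c(a = "x", b = "y"), classes = "x"), "outside")
})

test_that("binary prediction: fully labeled input is returned unchanged", {
  set.seed(4)
  sim <- random_unit_sim(6)
  truth <- c("u", "u", "u", "v", "v", "v")
  kn <- known_labels(stats::setNames(truth, sim$sample_ids))
  p <- predict_binary(sim, kn)
  expect_identical(unname(p$labels), truth)
  expect_true(all(p$confidence == 1))
})

test_that("one labeled sample per perfect block labels everything correctly", {
  s <- matrix(0, 7, 7); s[1:3, 1:3] <- 1; s[4:7, 4:7] <- 1; diag(s) <- 1
  sim <- similarity_matrix(s, scale = "unit")
  kn <- known_labels(stats::setNames(c("low", "high"),
                                     sim$sample_ids[c(1, 4)]))
  p <- predict_binary(sim, kn)
  expect_identical(unname(p$labels), rep(c("low", "high"), c(3, 4)))
})

test_that("prediction agrees with the exact-solver oracle on noisy data", {
  dat <- make_two_class_similarity(5L, 5L, sigma = 0.2, seed = 7L)
  idx0 <- which(dat$labels == 0L); idx1 <- which(dat$labels == 1L)
  known_idx <- c(idx0[1], idx1[1:5])   # about 20% of the 30 samples
  kn <- known_labels(stats::setNames(as.character(dat$labels[known_idx]),
                                     dat$sim$sample_ids[known_idx]),
                     classes = c("0", "1"))
  p <- suppressMessages(predict_binary(dat$sim, kn))
  prob <- suppressMessages(label_problem(dat$sim,
                                         dat$sim$sample_ids[idx0[1]],
                                         dat$sim$sample_ids[idx1[1:5]],
                                         clip = "permissive"))
  oracle <- binarize(solve_exact(prob))
  expect_identical(unname(p$labels), as.character(oracle))
  # known labels never altered
  expect_identical(unname(p$labels[known_idx]),
                   as.character(dat$labels[known_idx]))
})

test_that("a 2-class tree degenerates to binary prediction", {
  set.seed(8)
  dat <- make_two_class_similarity(4L, 2L, sigma = 0.15, seed = 88L)
  idx0 <- which(dat$labels == 0L); idx1 <- which(dat$labels == 1L)
  kn <- known_labels(stats::setNames(
    c("a", "a", "b", "b"),
    dat$sim$sample_ids[c(idx0[1:2], idx1[1:2])]), classes = c("a", "b"))
  pb <- suppressMessages(predict_binary(dat$sim, kn))
  pt <- suppressMessages(predict_multiclass_tree(dat$sim, kn,
                                                 class_tree = list("a", "b")))
  expect_identical(pt, pb$labels)
})

test_that("three planted blocks are recovered by every multi-class strategy", {
  g <- make_component_graph(c(4L, 5L, 6L))
  sim <- graph_similarity(g$adjacency)
  truth <- c("c1", "c2", "c3")[g$labels]
  kn <- known_labels(stats::setNames(c("c1", "c2", "c3"),
                                     sim$sample_ids[c(1, 5, 10)]))
  pt <- suppressMessages(
    predict_multiclass_tree(sim, kn, list(list("c1", "c2"), "c3")))
  ova <- suppressMessages(predict_one_vs_all(sim, kn))
  ovo <- suppressMessages(predict_one_vs_one(sim, kn))
  expect_identical(unname(pt), truth)
  expect_identical(unname(ova$labels), truth)
  expect_identical(unname(ovo$labels), truth)
})

test_that("a wrong class tree degrades accuracy on noisy three-block data", {
  # classes c1 and c2 are similar (between-similarity 0.5), c3 is far;
  # the right tree separates c3 first, the wrong tree splits c1 | (c2, c3)
  set.seed(55)
  n_per <- 8L
  right_acc <- wrong_acc <- numeric(20)
  for (r in 1:20) {
    s <- matrix(0, 3 * n_per, 3 * n_per)
    blocks <- split(seq_len(3 * n_per), rep(1:3, each = n_per))
    for (b in blocks) s[b, b] <- 1
    s[blocks[[1]], blocks[[2]]] <- 0.5
    s[blocks[[2]], blocks[[1]]] <- 0.5
    noise <- matrix(stats::rnorm(length(s), 0, 0.25), nrow(s))
    noise <- (noise + t(noise)) / 2
    s <- s + noise
    diag(s) <- 1
    s <- pmin(pmax(s, -1), 1.5)
    sim <- similarity_matrix(s, scale = "pearson_raw")
    truth <- rep(c("c1", "c2", "c3"), each = n_per)
    kn <- known_labels(stats::setNames(
      c("c1", "c2", "c3"),
      sim$sample_ids[c(blocks[[1]][1], blocks[[2]][1], blocks[[3]][1])]))
    right <- suppressMessages(
      predict_multiclass_tree(sim, kn, list(list("c1", "c2"), "c3")))
    wrong <- suppressMessages(
      predict_multiclass_tree(sim, kn, list("c1", list("c2", "c3"))))
    right_acc[r] <- mean(right == truth)
    wrong_acc[r] <- mean(wrong == truth)
  }
  expect_gt(mean(right_acc), mean(wrong_acc))
})

test_that("one-vs-all is consistent with binary prediction for 2 classes", {
  set.seed(67)
  for (r in 1:5) {
    dat <- make_two_class_similarity(4L, 2L, sigma = 0.2, seed = NULL)
    idx0 <- which(dat$labels == 0L); idx1 <- which(dat$labels == 1L)
    kn <- known_labels(stats::setNames(
      c("0", "0", "1", "1"),
      dat$sim$sample_ids[c(idx0[1:2], idx1[1:2])]), classes = c("0", "1"))
    pb <- suppressMessages(predict_binary(dat$sim, kn))
    ova <- suppressMessages(predict_one_vs_all(dat$sim, kn))
    expect_identical(ova$labels, pb$labels)
  }
})

test_that("missing class tree for >2 classes warns and uses left-deep order", {
  g <- make_component_graph(c(3L, 3L, 3L))
  sim <- graph_similarity(g$adjacency)
  kn <- known_labels(stats::setNames(c("c1", "c2", "c3"),
                                     sim$sample_ids[c(1, 4, 7)]))
  expect_warning(p <- suppressMessages(predict_multiclass_tree(sim, kn)),
                 "left-deep")
  expect_identical(unname(p), c("c1", "c2", "c3")[g$labels])
})

test_that("prediction reduces to the discovery split at the dissimilar pair", {
  set.seed(73)
  sim <- random_unit_sim(12, density = 0.7)
  seeds <- suppressWarnings(find_seed_pair(sim))
  sp <- suppressWarnings(split_cluster(sim))
  kn <- known_labels(stats::setNames(c("zero", "one"),
                                     sim$sample_ids[seeds]),
                     classes = c("zero", "one"))
  p <- predict_binary(sim, kn)
  expect_identical(which(unname(p$labels) == "zero"), sp$left)
  expect_identical(which(unname(p$labels) == "one"), sp$right)
})

test_that("cross-validated cutoff recovers a sensible threshold", {
  dat <- make_two_class_similarity(10L, 1L, sigma = 0.15, seed = 3L)
  kn <- known_labels(stats::setNames(as.character(dat$labels),
                                     dat$sim$sample_ids),
                     classes = c("0", "1"))
  res <- suppressMessages(learn_cutoff(dat$sim, kn, folds = 5, seed = 9L))
  expect_true(res$cutoff > 0 && res$cutoff < 1)
  expect_equal(max(res$accuracy$accuracy), 1, tolerance = 0.05)
  # the selected cutoff maximizes CV accuracy
  expect_equal(res$accuracy$accuracy[res$accuracy$cutoff == res$cutoff],
               max(res$accuracy$accuracy))
})
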