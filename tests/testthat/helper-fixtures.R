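# Fixtures are built in code; nothing binary ships with the tests.

# Three fully connected 5-node components and their connectivity similarity.
fig2a_sim <- function() {
  g <- make_component_graph(c(5L, 5L, 5L), inter_links = 0L)
  list(graph = g, sim = graph_similarity(g$adjacency))
}

# Random symmetric similarity with unit diagonal on the unit scale;
# density < 1 zeroes out a fraction of off-diagonal pairs.
random_unit_sim <- function(n, density = 1) {
  s <- matrix(stats::runif(n * n), n, n)
  s <- (s + t(s)) / 2
  if (density < 1) {
    drop <- upper.tri(s) & matrix(stats::runif(n * n) > density, n, n)
    s[drop] <- 0
    s[lower.tri(s)] <- t(s)[lower.tri(s)]
  }
  diag(s) <- 1
  similarity_matrix(s, sample_ids = paste0("s", seq_len(n)), scale = "unit")
}

# Random labeling problem guaranteed connected (diag=1 keeps self loops out
# of connectivity; regenerate until every node reaches a seed).
random_connected_problem <- function(n, density = 0.5) {
  repeat {
    sim <- random_unit_sim(n, density)
    seeds <- sample.int(n, 2L)
    prob <- label_problem(sim, seeds[1L], seeds[2L], clip = "strict")
    adj <- prob$values > 0
    diag(adj) <- FALSE
    seen <- logical(n)
    seen[seeds] <- TRUE
    frontier <- seeds
    while (length(frontier)) {
      nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    if (all(seen)) return(prob)
  }
}

rand_expression <- function(n_genes, m, scale = "log10") {
  expression_matrix(matrix(stats::rnorm(n_genes * m), n_genes, m),
                    gene_ids = paste0("g", seq_len(n_genes)),
                    sample_ids = paste0("s", seq_len(m)), scale = scale)
}

expect_partition <- function(leaves, n) {
  all_members <- sort(unlist(leaves))
  expect_identical(all_members, seq_len(n))
}
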