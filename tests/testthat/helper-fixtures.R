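# shared fixtures, all generated in code

# random weighted graph, connected via a spanning path
random_connected_graph <- function(n, seed, edge_prob = 3 / n) {
  set.seed(seed)
  a <- matrix(0, n, n)
  idx <- which(upper.tri(a))
  on <- idx[stats::runif(length(idx)) < edge_prob]
  a[on] <- stats::runif(length(on), 0.5, 2)
  for (j in seq_len(n - 1)) a[j, j + 1] <- max(a[j, j + 1], stats::runif(1, 0.5, 2))
  a + t(a)
}

# small three-view SBM instance used across solver tests
small_sbm_instance <- function(seed = 5, p = NULL) {
  if (is.null(p)) p <- sbm_prob_matrices(60)$P2
  cfg <- sbm_config(list(c(20, 20, 20), c(15, 30, 15), c(18, 22, 20)),
                    p, seed = seed)
  generate_multiview_sbm(cfg)
}

random_embedding <- function(n, k, m, seed) {
  set.seed(seed)
  embedding_blocks(lapply(seq_len(m), function(i) matrix(stats::rnorm(n * k), n, k)))
}

# dense assembly of the coupled operator, for small-instance oracles
dense_coupled_matrix <- function(op) {
  n <- op$n_nodes
  m <- op$n_views
  big <- matrix(0, n * m, n * m)
  for (i in seq_len(m)) {
    rows <- (i - 1) * n + seq_len(n)
    big[rows, rows] <- as.matrix(op$laplacians[[i]])
    for (j in seq_len(m)) if (j != i) {
      cols <- (j - 1) * n + seq_len(n)
      big[rows, cols] <- -op$beta_couple * diag(n)
    }
  }
  big
}
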