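test_that("graph Laplacian has degree diagonal and zero row sums", {
  tri <- matrix(1, 3, 3) - diag(3)
  l <- graph_laplacian(tri)
  expect_equal(as.matrix(l$laplacian),
               matrix(c(2, -1, -1, -1, 2, -1, -1, -1, 2), 3),
               ignore_attr = TRUE)
  expect_equal(l$degrees, c(2, 2, 2))

  expect_equal(as.matrix(graph_laplacian(matrix(0, 4, 4))$laplacian),
               matrix(0, 4, 4), ignore_attr = TRUE)

  a <- random_connected_graph(6, seed = 1)
  lw <- graph_laplacian(a)
  expect_lt(max(abs(Matrix::rowSums(lw$laplacian))), 1e-12)

  bad <- matrix(c(0, 1, 0, 0), 2)
  expect_error(graph_laplacian(bad), "symmetric")
})

test_that("block operator application matches dense assembly on small instances", {
  set.seed(11)
  for (case in 1:5) {
    m <- sample(1:3, 1)
    n <- sample(4:15, 1)
    k <- sample(1:3, 1)
    beta <- runif(1, 0, 2)
    adj <- lapply(seq_len(m), function(i) random_connected_graph(n, seed = case * 10 + i))
    op <- block_operator(adj, beta_couple = beta)
    x <- random_embedding(n, k, m, seed = case)
    lx <- apply_block_operator(op, x)
    dense <- dense_coupled_matrix(op) %*% stack_blocks(x)
    expect_equal(stack_blocks(lx), dense, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("decoupled and zero cases of the block operator", {
  adj <- list(random_connected_graph(6, 1), random_connected_graph(6, 2))
  op0 <- block_operator(adj, beta_couple = 0)
  x <- random_embedding(6, 2, 2, seed = 3)
  lx <- apply_block_operator(op0, x)
  for (m in 1:2)
    expect_equal(lx$blocks[[m]],
                 as.matrix(op0$laplacians[[m]] %*% x$blocks[[m]]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  zero <- embedding_blocks(list(matrix(0, 6, 2), matrix(0, 6, 2)))
  expect_equal(stack_blocks(apply_block_operator(op0, zero)),
               matrix(0, 12, 2), ignore_attr = TRUE)
  expect_error(apply_block_operator(op0, random_embedding(5, 2, 2, 1)),
               "do not agree")
})

test_that("objective equals bottom-eigenvalue sums in the decoupled limit", {
  adj <- list(random_connected_graph(8, 4), random_connected_graph(8, 5))
  op <- block_operator(adj, beta_couple = 0)
  k <- 3
  blocks <- lapply(op$laplacians, function(l) {
    e <- eigen(as.matrix(l), symmetric = TRUE)
    e$vectors[, 8:6]
  })
  x <- embedding_blocks(blocks)
  expected <- sum(vapply(op$laplacians, function(l)
    sum(sort(eigen(as.matrix(l), symmetric = TRUE, only.values = TRUE)$values)[1:k]),
    numeric(1)))
  expect_equal(mv_objective(op, x), expected, tolerance = 1e-10)

  # duplicating a view doubles its contribution when decoupled
  op2 <- block_operator(list(adj[[1]], adj[[1]]), beta_couple = 0)
  x2 <- embedding_blocks(list(blocks[[1]], blocks[[1]]))
  x1 <- embedding_blocks(blocks[1])
  op1 <- block_operator(adj[1], beta_couple = 0)
  expect_equal(mv_objective(op2, x2), 2 * mv_objective(op1, x1))
})

test_that("objective is invariant under a joint right-rotation of all blocks", {
  g <- small_sbm_instance()
  op <- block_operator(g, 1)
  x <- random_embedding(60, 3, 3, seed = 6)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  xr <- embedding_blocks(lapply(x$blocks, function(b) b %*% q))
  expect_equal(mv_objective(op, xr), mv_objective(op, x), tolerance = 1e-10)
})

test_that("directional derivative of the objective matches <2LX, V>", {
  g <- small_sbm_instance()
  op <- block_operator(g, 1)
  set.seed(8)
  x <- random_embedding(60, 3, 3, seed = 8)
  v <- random_embedding(60, 3, 3, seed = 9)
  lx <- mv_gradient(op, x)
  analytic <- 2 * sum(stack_blocks(lx) * stack_blocks(v))
  eps <- 1e-6
  xp <- embedding_blocks(mapply(function(b, d) b + eps * d, x$blocks, v$blocks,
                                SIMPLIFY = FALSE))
  xm <- embedding_blocks(mapply(function(b, d) b - eps * d, x$blocks, v$blocks,
                                SIMPLIFY = FALSE))
  fd <- (mv_objective(op, xp) - mv_objective(op, xm)) / (2 * eps)
  expect_equal(fd, analytic, tolerance = 1e-6)
})

test_that("multiplier is the symmetrised cross-product", {
  set.seed(10)
  g <- matrix(rnorm(18), 6, 3)
  x <- matrix(rnorm(18), 6, 3)
  d <- mv_multiplier(g, x)
  expect_equal(d, (t(g) %*% x + t(x) %*% g) / 2)
  expect_identical(d, t(d))

  # eigen-aligned case: X orthonormal, G = X Lambda with Lambda symmetric
  xo <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  lam <- crossprod(matrix(rnorm(9), 3)); lam <- (lam + t(lam)) / 2
  expect_equal(mv_multiplier(xo %*% lam, xo), lam, tolerance = 1e-12)
})

test_that("merit equals the objective at feasible points and brute force otherwise", {
  g <- small_sbm_instance()
  op <- block_operator(g, 1)
  set.seed(12)
  feas <- embedding_blocks(lapply(1:3, function(m)
    qr.Q(qr(matrix(rnorm(180), 60, 3)))))
  f <- mv_objective(op, feas)
  expect_equal(mv_merit(op, feas, 0.5), f, tolerance = 1e-10)
  expect_equal(mv_merit(op, feas, 0), f, tolerance = 1e-10)

  x <- random_embedding(60, 3, 3, seed = 13)
  beta <- 0.7
  gx <- mv_gradient(op, x)
  brute <- mv_objective(op, x)
  for (m in 1:3) {
    viol <- crossprod(x$blocks[[m]]) - diag(3)
    gtx <- crossprod(gx$blocks[[m]], x$blocks[[m]])
    brute <- brute - sum(((gtx + t(gtx)) / 2) * viol) / 2 +
      beta * sum(viol^2) / 4
  }
  expect_equal(mv_merit(op, x, beta), brute, tolerance = 1e-10)
})
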