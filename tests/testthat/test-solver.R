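test_that("augmented-Lagrangian gradient matches the block formula", {
  g <- small_sbm_instance()
  op <- block_operator(g, 1)
  x <- random_embedding(60, 3, 3, seed = 21)
  beta <- 0.4
  d <- aug_lagrangian_gradient(op, x, beta)
  gx <- mv_gradient(op, x)
  for (m in 1:3) {
    xm <- x$blocks[[m]]; gm <- gx$blocks[[m]]
    expected <- gm - xm %*% mv_multiplier(gm, xm) +
      beta * xm %*% (crossprod(xm) - diag(3))
    expect_equal(d[[m]], expected, tolerance = 1e-12)
  }
  # literal printed sign for auditing
  d_lit <- aug_lagrangian_gradient(op, x, beta, literal_sign = TRUE)
  m1 <- x$blocks[[1]] %*% mv_multiplier(gx$blocks[[1]], x$blocks[[1]])
  expect_equal(d_lit[[1]] - d[[1]], 2 * m1, tolerance = 1e-12)
})

test_that("gradient vanishes on per-view invariant subspaces when decoupled", {
  adj <- list(random_connected_graph(10, 31), random_connected_graph(10, 32))
  op <- block_operator(adj, beta_couple = 0)
  blocks <- lapply(op$laplacians, function(l) {
    eigen(as.matrix(l), symmetric = TRUE)$vectors[, 10:8]
  })
  x <- embedding_blocks(blocks)
  d <- aug_lagrangian_gradient(op, x, 0.5)
  expect_lt(max(vapply(d, function(b) max(abs(b)), numeric(1))), 1e-10)

  zero <- embedding_blocks(list(matrix(0, 10, 3), matrix(0, 10, 3)))
  dz <- aug_lagrangian_gradient(op, zero, 0.5)
  expect_true(all(vapply(dz, function(b) all(b == 0), logical(1))))
})

test_that("gradient step projects onto the safeguard sphere when needed", {
  x <- random_embedding(8, 2, 2, seed = 22)
  d <- lapply(x$blocks, function(b) b * 0)
  expect_equal(step_and_safeguard(x, d, 1, r = 100)$blocks, x$blocks)

  d2 <- lapply(x$blocks, function(b) matrix(1, nrow(b), ncol(b)))
  out <- step_and_safeguard(x, d2, 0, r = 100)       # mu = 0: identity
  expect_equal(out$blocks, x$blocks)

  r <- 0.5
  out2 <- step_and_safeguard(x, d2, 2, r = r)
  for (b in out2$blocks) expect_equal(norm(b, "F"), r, tolerance = 1e-12)
})

test_that("BB stepsizes follow the alternating rule and safeguards", {
  expect_equal(bb_stepsize(NULL, NULL, 1, mu_init = 0.01), 0.01)
  s <- list(matrix(c(1, 1), 1)); y <- list(matrix(c(2, 0), 1))
  # BB1 = <S,S>/<S,Y> = 2/2 = 1 ; BB2 = <S,Y>/<Y,Y> = 2/4 = 0.5
  expect_equal(bb_stepsize(s, y, iter = 3, rule = "ABB"), 1)
  expect_equal(bb_stepsize(s, y, iter = 4, rule = "ABB"), 0.5)
  expect_equal(bb_stepsize(s, y, iter = 4, rule = "BB1"), 1)
  expect_equal(bb_stepsize(s, y, iter = 3, rule = "BB2"), 0.5)
  # Y = S gives 1 under both rules
  expect_equal(bb_stepsize(s, s, 2, "BB1"), bb_stepsize(s, s, 2, "BB2"))
  # scalar case from first principles: S = 1, Y = 2
  s1 <- list(matrix(1)); y1 <- list(matrix(2))
  expect_equal(bb_stepsize(s1, y1, 3, "BB1"), 0.5)
  expect_equal(bb_stepsize(s1, y1, 3, "BB2"), 0.5)
  # negative curvature falls back to the upper bound
  yneg <- list(matrix(c(-2, 0), 1))
  expect_equal(bb_stepsize(s, yneg, 3, "ABB", mu_max = 10), 10)
  # clamping
  ybig <- list(matrix(c(1e9, 0), 1))
  expect_equal(bb_stepsize(s, ybig, 3, "ABB", mu_min = 1e-4), 1e-4)
})

test_that("single-view solutions match the eigensolver oracle", {
  for (i in 1:4) {
    n <- c(20, 35, 50, 80)[i]
    k <- c(2, 3, 4, 5)[i]
    a <- random_connected_graph(n, seed = 40 + i)
    op <- block_operator(list(a), beta_couple = 0)
    fit <- solve_mvcpm(op, k, solver_config(seed = i,
                                            beta_pen = 2 * max(rowSums(a))))
    f <- mv_objective(op, fit$x)
    ev <- eigen(as.matrix(op$laplacians[[1]]), symmetric = TRUE)
    target <- sum(sort(ev$values)[1:k])
    expect_lt(abs(f - target) / max(abs(target), 1e-10), 1e-4)
    # converged subspace aligns with the bottom-K eigenvectors
    bottom <- ev$vectors[, n:(n - k + 1)]
    angles <- acos(pmin(1, svd(crossprod(bottom, fit$x$blocks[[1]]))$d))
    expect_lt(max(angles), 1e-3)
  }
})

test_that("solver reaches tight feasibility before and after the polar polish", {
  g <- small_sbm_instance()
  op <- block_operator(g, 1)
  fit <- solve_mvcpm(op, 3, solver_config(seed = 1))
  expect_true(fit$state$converged)
  expect_lt(fit$state$pre_polar_feasibility, 1e-3)
  expect_lt(fit$state$post_polar_feasibility, 1e-12)
})

test_that("solver histories are deterministic under a fixed seed", {
  g <- small_sbm_instance()
  op <- block_operator(g, 1)
  f1 <- solve_mvcpm(op, 3, solver_config(seed = 7))
  f2 <- solve_mvcpm(op, 3, solver_config(seed = 7))
  expect_identical(f1$state$history, f2$state$history)
  expect_identical(f1$x$blocks, f2$x$blocks)
})

test_that("merit is non-increasing under a small fixed stepsize", {
  g <- small_sbm_instance()
  op <- block_operator(g, 1)
  fit <- solve_mvcpm(op, 3, solver_config(seed = 3, stepsize_rule = "fixed",
                                          mu_init = 1e-3, max_iter = 50))
  h <- fit$state$history$h
  expect_true(all(diff(h) <= 1e-10))
})

test_that("iteration cap returns an unconverged state rather than an error", {
  g <- small_sbm_instance()
  op <- block_operator(g, 1)
  fit <- solve_mvcpm(op, 3, solver_config(seed = 1, max_iter = 3))
  expect_false(fit$state$converged)
  expect_equal(fit$state$iterations, 3L)
})

test_that("spectral initialisation also reaches the decoupled optimum", {
  a <- random_connected_graph(30, seed = 50)
  op <- block_operator(list(a), beta_couple = 0)
  fit <- solve_mvcpm(op, 3, solver_config(init = "spectral",
                                          beta_pen = 2 * max(rowSums(a))))
  target <- sum(sort(eigen(as.matrix(op$laplacians[[1]]), symmetric = TRUE,
                           only.values = TRUE)$values)[1:3])
  expect_lt(abs(mv_objective(op, fit$x) - target) / abs(target), 1e-4)
})
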