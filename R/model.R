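#' Graph Laplacian of a similarity network
#'
#' L = D - A with D the diagonal degree matrix (row sums of the adjacency).
#' Row sums of L are exactly zero.
#'
#' @param adjacency Square symmetric nonnegative matrix.
#' @return List with sparse \code{laplacian} and \code{degrees} (vector).
#' @export
graph_laplacian <- function(adjacency) {
  a <- if (inherits(adjacency, "Matrix")) adjacency
       else Matrix::Matrix(as.matrix(adjacency), sparse = TRUE)
  n <- nrow(a)
  if (ncol(a) != n) stop("adjacency must be square")
  if (max(abs(a - Matrix::t(a))) > 1e-10) stop("adjacency must be symmetric")
  if (min(a) < 0) stop("adjacency weights must be nonnegative")
  deg <- Matrix::rowSums(a)
  list(laplacian = Matrix::Diagonal(n, deg) - a, degrees = deg)
}

#' Coupled block operator over the per-view Laplacians
#'
#' Holds the M per-view Laplacians L_m on the diagonal and couples distinct
#' views with -beta_couple times the identity on every off-diagonal block.
#' The full (N M) x (N M) matrix is never materialised; see
#' \code{\link{apply_block_operator}}.
#'
#' @param graphs A \code{multiview_graphs} object or list of adjacency
#'   matrices.
#' @param beta_couple Nonnegative coupling strength between views
#'   (default 1).
#' @return Object of class \code{block_operator}.
#' @export
block_operator <- function(graphs, beta_couple = 1) {
  adj <- if (inherits(graphs, "multiview_graphs")) graphs$adjacency else graphs
  stopifnot(is.list(adj), length(adj) >= 1L, beta_couple >= 0)
  lap <- lapply(adj, graph_laplacian)
  n <- nrow(lap[[1L]]$laplacian)
  if (!all(vapply(lap, function(l) nrow(l$laplacian) == n, logical(1))))
    stop("all views must have the same number of nodes")
  structure(list(laplacians = lapply(lap, `[[`, "laplacian"),
                 degrees = lapply(lap, `[[`, "degrees"),
                 n_nodes = n,
                 n_views = length(adj),
                 beta_couple = beta_couple),
            class = "block_operator")
}

#' @export
print.block_operator <- function(x, ...) {
  cat("block_operator:", x$n_views, "view(s),", x$n_nodes,
      "nodes, beta_couple =", x$beta_couple, "\n")
  invisible(x)
}

#' Stacked per-view embedding blocks
#'
#' The solver's variable: M blocks X_m, each N x K, viewed as the stacked
#' matrix X = (X_1; ...; X_M).
#'
#' @param blocks List of M numeric matrices with common dimensions N x K.
#' @return Object of class \code{embedding_blocks}.
#' @export
embedding_blocks <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  dims <- vapply(blocks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all blocks must share the same N x K dimensions")
  structure(list(blocks = lapply(blocks, as.matrix),
                 n_nodes = dims[1, 1], n_dim = dims[2, 1],
                 n_views = length(blocks)),
            class = "embedding_blocks")
}

#' @export
print.embedding_blocks <- function(x, ...) {
  cat("embedding_blocks:", x$n_views, "block(s) of", x$n_nodes, "x",
      x$n_dim, "\n")
  invisible(x)
}

#' Stack embedding blocks into one (N M) x K matrix
#' @param x An \code{embedding_blocks} object.
#' @return Numeric matrix with the blocks stacked row-wise.
#' @export
stack_blocks <- function(x) {
  stopifnot(inherits(x, "embedding_blocks"))
  do.call(rbind, x$blocks)
}

#' Apply the coupled block operator: the product L X
#'
#' Block m of the result is L_m X_m - beta_couple * sum_{h != m} X_h,
#' computed without assembling the full block matrix.
#'
#' @param op A \code{\link{block_operator}}.
#' @param x An \code{\link{embedding_blocks}} object.
#' @return \code{embedding_blocks} holding L X.
#' @export
apply_block_operator <- function(op, x) {
  stopifnot(inherits(op, "block_operator"), inherits(x, "embedding_blocks"))
  if (op$n_views != x$n_views || op$n_nodes != x$n_nodes)
    stop("operator and embedding dimensions do not agree")
  total <- Reduce(`+`, x$blocks)
  out <- lapply(seq_len(op$n_views), function(m) {
    as.matrix(op$laplacians[[m]] %*% x$blocks[[m]]) -
      op$beta_couple * (total - x$blocks[[m]])
  })
  embedding_blocks(out)
}

#' Multiview spectral objective Tr(X' L X)
#'
#' @param op A \code{\link{block_operator}}.
#' @param x An \code{\link{embedding_blocks}} object.
#' @return Scalar objective value.
#' @export
mv_objective <- function(op, x) {
  lx <- apply_block_operator(op, x)
  sum(vapply(seq_len(x$n_views),
             function(m) sum(x$blocks[[m]] * lx$blocks[[m]]),
             numeric(1)))
}

#' Gradient of the objective in the solver's convention
#'
#' Returns G = L X (the true Euclidean gradient of Tr(X' L X) is 2 L X; the
#' constant factor is absorbed by the scale-adaptive Barzilai-Borwein
#' stepsizes and the solver consumes L X directly).
#'
#' @inheritParams mv_objective
#' @return \code{embedding_blocks} holding L X.
#' @export
mv_gradient <- function(op, x) apply_block_operator(op, x)

#' Closed-form Lagrangian multiplier for one block
#'
#' delta = psi(G' X) with psi the symmetrisation operator
#' psi(A) = (A + A') / 2; the multiplier is symmetric by construction.
#'
#' @param g_block,x_block N x K matrices (gradient block and iterate block).
#' @return K x K symmetric matrix.
#' @export
mv_multiplier <- function(g_block, x_block) {
  gtx <- crossprod(g_block, x_block)
  (gtx + t(gtx)) / 2
}

#' Penalty-model merit function
#'
#' h(X) = f(X) - 1/2 sum_m <psi(G_m' X_m), X_m' X_m - I>
#'             + beta_pen / 4 sum_m || X_m' X_m - I ||_F^2,
#' the monitoring merit of the penalty model; on feasible X (orthonormal
#' blocks) it coincides with the objective f.
#'
#' @inheritParams mv_objective
#' @param beta_pen Nonnegative penalty parameter.
#' @return Scalar merit value.
#' @export
mv_merit <- function(op, x, beta_pen) {
  g <- mv_gradient(op, x)
  f <- sum(vapply(seq_len(x$n_views),
                  function(m) sum(x$blocks[[m]] * g$blocks[[m]]),
                  numeric(1)))
  pen <- 0
  mult <- 0
  for (m in seq_len(x$n_views)) {
    viol <- crossprod(x$blocks[[m]]) - diag(x$n_dim)
    mult <- mult + sum(mv_multiplier(g$blocks[[m]], x$blocks[[m]]) * viol)
    pen <- pen + sum(viol^2)
  }
  f - mult / 2 + beta_pen * pen / 4
}

#' Orthogonality residual of the embedding blocks
#'
#' @param x An \code{\link{embedding_blocks}} object.
#' @return max over blocks of || X_m' X_m - I ||_F.
#' @export
feasibility_residual <- function(x) {
  max(vapply(x$blocks, function(b) {
    norm(crossprod(b) - diag(ncol(b)), "F")
  }, numeric(1)))
}
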