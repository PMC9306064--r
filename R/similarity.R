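#' Standardise each feature across samples
#'
#' Centres every feature (row) to mean zero and scales it to unit variance,
#' using the population variance (divisor N). Features with zero variance
#' carry no information for a distance-based similarity and are dropped with
#' a warning.
#'
#' @param x Numeric matrix, features in rows and samples in columns.
#' @return Matrix of the same orientation with standardised rows.
#' @examples
#' normalize_features(matrix(c(0, 2, 5, 5), 2, byrow = TRUE))
#' @export
normalize_features <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("feature matrix contains missing values")
  n <- ncol(x)
  mu <- rowMeans(x)
  v <- rowMeans(x^2) - mu^2   # population variance
  v[v < 0] <- 0
  keep <- v > 1e-24
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance feature(s) dropped")
    x <- x[keep, , drop = FALSE]
    mu <- mu[keep]
    v <- v[keep]
  }
  if (nrow(x) == 0L) stop("no features left after dropping zero-variance rows")
  (x - mu) / sqrt(v)
}

#' Gaussian similarity between samples
#'
#' Computes S(i, j) = exp(-d(i, j)^2 / (2 alpha^2)) where d is the Euclidean
#' distance between sample columns and the bandwidth alpha is the standard
#' deviation of the set of all pairwise distances. The diagonal is exactly 1.
#'
#' @param x Numeric matrix, features in rows and samples in columns (at
#'   least 2 samples).
#' @param alpha Optional bandwidth override; defaults to the pairwise
#'   distance standard deviation.
#' @return N x N symmetric similarity matrix with unit diagonal, plus the
#'   bandwidth as attribute \code{"alpha"}.
#' @export
gaussian_similarity <- function(x, alpha = NULL) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 2L) stop("need at least two samples")
  d <- stats::dist(t(x))
  if (is.null(alpha)) alpha <- stats::sd(d)
  if (!is.finite(alpha) || alpha <= 0)
    stop("degenerate geometry: pairwise distances have zero spread, ",
         "cannot set the similarity bandwidth")
  s <- exp(-as.matrix(d)^2 / (2 * alpha^2))
  diag(s) <- 1
  dimnames(s) <- list(colnames(x), colnames(x))
  attr(s, "alpha") <- alpha
  s
}

#' k-nearest-neighbour similarity graph
#'
#' Keeps the edge (i, j) with weight S(i, j) whenever j is among the k most
#' similar neighbours of i or i is among the k most similar neighbours of j
#' (union symmetrisation, so the result is symmetric by construction). Ties
#' in similarity are broken towards the lower node index. The diagonal is
#' zero.
#'
#' @param s Symmetric similarity matrix.
#' @param k Number of neighbours, between 1 and N - 1.
#' @return Symmetric weighted adjacency matrix with zero diagonal.
#' @export
knn_graph <- function(s, k) {
  s <- as.matrix(s)
  n <- nrow(s)
  if (ncol(s) != n) stop("similarity matrix must be square")
  if (k < 1L || k > n - 1L) stop("k must lie in [1, N-1]; got ", k)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    sim <- s[i, ]
    sim[i] <- -Inf
    nbr <- order(sim, decreasing = TRUE)[seq_len(k)]  # order() is stable:
    keep[i, nbr] <- TRUE                              # ties -> lower index
  }
  a <- s * (keep | t(keep))
  diag(a) <- 0
  a
}

#' Feature matrices to k-NN similarity networks
#'
#' The real-data front end: standardise features, compute the Gaussian
#' similarity between samples, sparsify to a k-NN graph — one network per
#' view, all over the same samples.
#'
#' @param features List of feature x sample matrices with identical,
#'   identically ordered sample columns.
#' @param knn Number of nearest neighbours (default 5).
#' @return \code{multiview_graphs} object (no ground-truth labels).
#' @export
build_similarity_networks <- function(features, knn = 5L) {
  stopifnot(is.list(features), length(features) >= 1L)
  ids <- lapply(features, colnames)
  if (!is.null(ids[[1L]])) {
    same <- vapply(ids, identical, logical(1), y = ids[[1L]])
    if (!all(same))
      stop("sample IDs differ across views: check view(s) ",
           paste(which(!same), collapse = ", "))
  }
  ns <- vapply(features, ncol, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all views must share the same number of samples")
  adjacency <- lapply(features, function(x) {
    knn_graph(gaussian_similarity(normalize_features(x)), knn)
  })
  structure(list(adjacency = adjacency, labels = NULL,
                 n_nodes = ns[1L], n_views = length(features),
                 n_clusters = NA_integer_),
            class = "multiview_graphs")
}
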