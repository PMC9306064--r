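#' Canonical connection-probability matrices for the benchmark simulations
#'
#' Returns the four 3x3 connection-probability matrices used throughout the
#' simulation study, scaled by \code{1/n}. Diagonal entries give the
#' within-cluster connection probabilities, off-diagonal entries the
#' between-cluster ones; the between-cluster connectivity increases from P1
#' (zero) to P4. With \code{n} equal to the number of nodes the expected
#' within-cluster degree stays near 5 at both benchmark scales (n = 150 and
#' n = 600).
#'
#' @param n Positive scalar divisor (typically the number of nodes N).
#' @return Named list of symmetric 3x3 probability matrices \code{P1}..\code{P4}.
#' @examples
#' sbm_prob_matrices(150)$P1
#' @export
sbm_prob_matrices <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n > 0)
  base <- list(
    P1 = matrix(c(16, 0, 0,
                  0, 18, 0,
                  0, 0, 17), 3, 3, byrow = TRUE),
    P2 = matrix(c(16, 0.4, 0.6,
                  0.4, 18, 0.55,
                  0.6, 0.55, 17), 3, 3, byrow = TRUE),
    P3 = matrix(c(16, 0.8, 1.2,
                  0.8, 18, 1.1,
                  1.2, 1.1, 17), 3, 3, byrow = TRUE),
    P4 = matrix(c(16, 1.2, 1.8,
                  1.2, 18, 1.65,
                  1.8, 1.65, 17), 3, 3, byrow = TRUE)
  )
  lapply(base, function(p) p / n)
}

#' Draw one stochastic block model graph
#'
#' Nodes are partitioned into \code{length(sizes)} blocks; an undirected,
#' unweighted edge between nodes in blocks l and s is drawn independently
#' with probability \code{prob_matrix[l, s]}. No self loops.
#'
#' @param sizes Integer vector of block sizes (sums to the node count N).
#' @param prob_matrix Symmetric K x K matrix of connection probabilities in
#'   \code{[0, 1]}.
#' @param seed Optional integer seed; when given the draw is reproducible.
#' @return List with \code{adjacency} (N x N symmetric 0/1 matrix, zero
#'   diagonal) and \code{labels} (integer block memberships 1..K).
#' @examples
#' g <- generate_sbm_view(c(5, 5), matrix(c(.9, .1, .1, .9), 2), seed = 1)
#' table(g$labels)
#' @export
generate_sbm_view <- function(sizes, prob_matrix, seed = NULL) {
  sizes <- as.integer(sizes)
  if (any(sizes <= 0L)) stop("block sizes must be positive integers")
  k <- length(sizes)
  if (!is.matrix(prob_matrix) || nrow(prob_matrix) != k || ncol(prob_matrix) != k)
    stop("prob_matrix must be a ", k, "x", k, " matrix matching length(sizes)")
  if (any(prob_matrix < 0 | prob_matrix > 1))
    stop("connection probabilities must lie in [0, 1]")
  if (max(abs(prob_matrix - t(prob_matrix))) > 1e-12)
    stop("prob_matrix must be symmetric")
  if (!is.null(seed)) set.seed(seed)

  n <- sum(sizes)
  labels <- rep.int(seq_len(k), sizes)
  # pairwise edge probabilities, drawn on the upper triangle only
  p_full <- prob_matrix[labels, labels]
  upper <- upper.tri(p_full)
  a <- matrix(0, n, n)
  a[upper] <- as.numeric(stats::runif(sum(upper)) < p_full[upper])
  a <- a + t(a)
  list(adjacency = a, labels = labels)
}

#' Configuration for a multiview stochastic block model draw
#'
#' @param cluster_sizes List of M integer vectors, one per view; each must
#'   sum to the same node count N and have the same number of blocks K.
#' @param prob_matrix K x K symmetric probability matrix (already scaled,
#'   i.e. entries in \code{[0,1]}).
#' @param seed Integer master seed; per-view draws use sub-seeds derived
#'   from it, so adding a view does not perturb earlier views.
#' @return Object of class \code{sbm_config}.
#' @export
sbm_config <- function(cluster_sizes, prob_matrix, seed = 1L) {
  if (!is.list(cluster_sizes) || length(cluster_sizes) < 1L)
    stop("cluster_sizes must be a non-empty list of integer vectors")
  totals <- vapply(cluster_sizes, sum, numeric(1))
  if (length(unique(totals)) != 1L)
    stop("cluster size vectors must sum to the same N across views; got ",
         paste(totals, collapse = ", "))
  ks <- vapply(cluster_sizes, length, integer(1))
  if (length(unique(ks)) != 1L)
    stop("all views must have the same number of clusters K")
  if (nrow(prob_matrix) != ks[1L])
    stop("prob_matrix dimension must equal the number of clusters")
  if (any(prob_matrix < 0 | prob_matrix > 1))
    stop("connection probabilities must lie in [0, 1]")
  structure(list(cluster_sizes = lapply(cluster_sizes, as.integer),
                 prob_matrix = prob_matrix,
                 n_views = length(cluster_sizes),
                 n_nodes = as.integer(totals[1L]),
                 n_clusters = ks[1L],
                 seed = as.integer(seed)),
            class = "sbm_config")
}

#' Generate a multiview network set from the stochastic block model
#'
#' Draws one independent SBM graph per view, each with its own block-size
#' vector (the views may therefore carry consistent or differential cluster
#' patterns), all sharing the node set.
#'
#' @param config An \code{\link{sbm_config}}.
#' @return Object of class \code{multiview_graphs}: list with
#'   \code{adjacency} (list of M symmetric 0/1 matrices), \code{labels}
#'   (list of M ground-truth label vectors), and the counts \code{n_nodes},
#'   \code{n_views}, \code{n_clusters}.
#' @examples
#' cfg <- sbm_config(list(c(10, 10), c(5, 15)),
#'                   matrix(c(.8, .05, .05, .8), 2), seed = 7)
#' g <- generate_multiview_sbm(cfg)
#' @export
generate_multiview_sbm <- function(config) {
  stopifnot(inherits(config, "sbm_config"))
  set.seed(config$seed)
  view_seeds <- sample.int(.Machine$integer.max, config$n_views)
  views <- lapply(seq_len(config$n_views), function(m) {
    generate_sbm_view(config$cluster_sizes[[m]], config$prob_matrix,
                      seed = view_seeds[m])
  })
  structure(list(adjacency = lapply(views, `[[`, "adjacency"),
                 labels = lapply(views, `[[`, "labels"),
                 n_nodes = config$n_nodes,
                 n_views = config$n_views,
                 n_clusters = config$n_clusters),
            class = "multiview_graphs")
}

#' @export
print.multiview_graphs <- function(x, ...) {
  cat("multiview_graphs:", x$n_views, "view(s),", x$n_nodes, "nodes,",
      x$n_clusters, "clusters\n")
  invisible(x)
}

#' Configuration for simulated Gaussian feature views
#'
#' Describes feature-by-sample matrices with cluster-specific mean shifts,
#' used to exercise the real-data code path (normalisation, similarity,
#' k-NN graph) end to end.
#'
#' @param n_features Integer vector: number of features in each view.
#' @param cluster_sizes Integer vector of cluster sizes (shared by views).
#' @param separation Between-cluster mean separation (per feature).
#' @param noise_sd Within-cluster standard deviation; must be positive.
#' @param seed Integer master seed.
#' @return Object of class \code{feature_sim_config}.
#' @export
feature_sim_config <- function(n_features, cluster_sizes, separation = 2,
                               noise_sd = 1, seed = 1L) {
  if (any(n_features <= 0L) || any(cluster_sizes <= 0L))
    stop("feature and cluster counts must be positive")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_features = as.integer(n_features),
                 cluster_sizes = as.integer(cluster_sizes),
                 n_samples = sum(as.integer(cluster_sizes)),
                 separation = separation,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "feature_sim_config")
}

#' Simulate Gaussian feature matrices for several views
#'
#' Each view is a features x samples matrix; samples in cluster j have
#' feature means \code{(j - 1) * separation} plus N(0, noise_sd) noise.
#'
#' @param config A \code{\link{feature_sim_config}}.
#' @return List with \code{features} (list of matrices, one per view, with
#'   sample and feature ids) and \code{labels} (shared truth).
#' @export
generate_feature_views <- function(config) {
  stopifnot(inherits(config, "feature_sim_config"))
  set.seed(config$seed)
  view_seeds <- sample.int(.Machine$integer.max, length(config$n_features))
  n <- config$n_samples
  labels <- rep.int(seq_along(config$cluster_sizes), config$cluster_sizes)
  features <- lapply(seq_along(config$n_features), function(m) {
    set.seed(view_seeds[m])
    g <- config$n_features[m]
    mu <- matrix((labels - 1) * config$separation, g, n, byrow = TRUE)
    x <- mu + matrix(stats::rnorm(g * n, sd = config$noise_sd), g, n)
    dimnames(x) <- list(paste0("f", seq_len(g), "_v", m),
                        paste0("sample", seq_len(n)))
    x
  })
  list(features = features, labels = labels)
}
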