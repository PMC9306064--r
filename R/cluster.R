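#' Joint k-means over the stacked embedding rows
#'
#' Treats the N rows of every view's block as N*M points in R^K and
#' clusters them jointly. Because a single centroid set is fitted, the
#' labels are directly comparable across views — row (m-1)*N + i carries
#' the label of sample i in view m — with no post-hoc matching.
#'
#' @param x An \code{\link{embedding_blocks}} object (typically the solver
#'   output).
#' @param k Number of clusters (>= 2).
#' @param seed Seed for the k-means restarts.
#' @param restarts Number of random restarts; the best inertia is kept.
#' @param max_retries Re-seeding attempts if a restart degenerates.
#' @return Object of class \code{cluster_result} with
#'   \code{per_view_labels} (list of M length-N integer vectors),
#'   \code{centroids}, \code{inertia}; \code{integrative_labels} is filled
#'   by \code{\link{integrative_assign}}.
#' @export
kmeans_stacked <- function(x, k, seed = 1L, restarts = 20L,
                           max_retries = 5L) {
  stopifnot(inherits(x, "embedding_blocks"), k >= 2L)
  rows <- stack_blocks(x)
  km <- NULL
  for (attempt in seq_len(max_retries)) {
    set.seed(seed + attempt - 1L)
    km <- tryCatch(
      stats::kmeans(rows, centers = k, nstart = restarts, iter.max = 100L),
      error = function(e) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == k) break
    km <- NULL
  }
  if (is.null(km))
    stop("k-means failed to produce ", k,
         " non-empty clusters after ", max_retries, " re-seeded attempts")
  n <- x$n_nodes
  per_view <- lapply(seq_len(x$n_views), function(m) {
    unname(km$cluster[seq_len(n) + (m - 1L) * n])
  })
  structure(list(per_view_labels = per_view,
                 integrative_labels = NULL,
                 consensus_fraction = NULL,
                 centroids = km$centers,
                 inertia = km$tot.withinss,
                 n_clusters = k),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", length(x$per_view_labels), "view(s),",
      length(x$per_view_labels[[1L]]), "samples,", x$n_clusters,
      "clusters\n")
  if (!is.null(x$integrative_labels))
    cat("  integrative labels present; mean consensus",
        round(mean(x$consensus_fraction), 3), "\n")
  invisible(x)
}

#' Integrative label assignment across views
#'
#' Samples labelled identically in every view keep that label. Discordant
#' samples take the majority label across views; when the vote ties, the
#' label is decided by the majority among the \code{k_nn} nearest
#' concordant samples in the view-averaged embedding (mean of the X_m
#' rows), remaining ties going to the smallest label. If no sample is
#' concordant at all, the assignment falls back to k-means on the
#' view-averaged embedding (with a warning).
#'
#' @param result A \code{\link{kmeans_stacked}} result.
#' @param x The \code{embedding_blocks} the labels came from.
#' @param k_nn Number of concordant neighbours consulted on ties
#'   (default 5).
#' @param seed Seed for the fallback k-means.
#' @return The \code{cluster_result} with \code{integrative_labels} and
#'   per-sample \code{consensus_fraction} filled in.
#' @export
integrative_assign <- function(result, x, k_nn = 5L, seed = 1L) {
  stopifnot(inherits(result, "cluster_result"),
            inherits(x, "embedding_blocks"))
  lab <- do.call(cbind, result$per_view_labels)   # N x M
  n <- nrow(lab)
  m <- ncol(lab)
  avg <- Reduce(`+`, x$blocks) / m                # view-averaged embedding
  concordant <- apply(lab, 1L, function(r) all(r == r[1L]))
  integrative <- integer(n)
  integrative[concordant] <- lab[concordant, 1L]

  if (!any(concordant) && any(!concordant)) {
    warning("no concordant samples; falling back to k-means on the ",
            "view-averaged embedding")
    set.seed(seed)
    integrative <- unname(stats::kmeans(avg, centers = result$n_clusters,
                                        nstart = 20L)$cluster)
  } else if (any(!concordant)) {
    conc_idx <- which(concordant)
    for (i in which(!concordant)) {
      votes <- tabulate(lab[i, ], nbins = result$n_clusters)
      top <- which(votes == max(votes))
      if (length(top) == 1L) {
        integrative[i] <- top
      } else {
        d2 <- colSums((t(avg[conc_idx, , drop = FALSE]) - avg[i, ])^2)
        nbr <- conc_idx[order(d2)[seq_len(min(k_nn, length(conc_idx)))]]
        nbr_votes <- tabulate(integrative[nbr], nbins = result$n_clusters)
        nbr_votes[-top] <- -1L   # only the tied labels stay in play
        integrative[i] <- which.max(nbr_votes)
      }
    }
  }
  result$integrative_labels <- integrative
  result$consensus_fraction <-
    rowMeans(lab == matrix(integrative, n, m))
  result
}
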