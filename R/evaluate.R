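#' Rand index between two partitions
#'
#' Over all unordered sample pairs: TP counts pairs co-clustered in both
#' partitions, TN pairs separated in both, and
#' R = (TP + TN) / (TP + TN + FP + FN). The index is invariant to label
#' permutations and lies in [0, 1].
#'
#' @param labels_a,labels_b Label vectors of equal length (N >= 2).
#' @return List with \code{rand} and the pair counts \code{tp}, \code{tn},
#'   \code{fp}, \code{fn}.
#' @examples
#' rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))$rand  # 2/6
#' @export
rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  n <- length(labels_a)
  if (n < 2L) stop("need at least two samples")
  ct <- table(labels_a, labels_b)
  total <- choose(n, 2)
  same_both <- sum(choose(ct, 2))             # co-clustered in both
  same_a <- sum(choose(rowSums(ct), 2))
  same_b <- sum(choose(colSums(ct), 2))
  tp <- same_both
  fn <- same_a - same_both                    # together in a, split in b
  fp <- same_b - same_both
  tn <- total - tp - fn - fp
  list(rand = (tp + tn) / total, tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Run the full clustering pipeline on a set of networks
#'
#' Block operator -> penalty solver -> joint k-means -> integrative labels:
#' the complete procedure applied to prebuilt similarity (or simulated)
#' networks.
#'
#' @param graphs A \code{multiview_graphs} object or list of symmetric
#'   adjacency matrices over the same nodes.
#' @param k Number of clusters K (>= 2).
#' @param beta_couple Cross-view coupling strength (default 1).
#' @param solver A \code{\link{solver_config}}.
#' @param kmeans_restarts Restarts for the final k-means.
#' @param k_nn Neighbours for integrative tie-breaking.
#' @return List with \code{result} (a \code{cluster_result} incl.
#'   integrative labels), \code{embedding}, \code{solver_state}.
#' @export
mvcpm_cluster_graphs <- function(graphs, k, beta_couple = 1,
                                 solver = solver_config(),
                                 kmeans_restarts = 20L, k_nn = 5L) {
  op <- block_operator(graphs, beta_couple = beta_couple)
  fit <- solve_mvcpm(op, k, solver)
  res <- kmeans_stacked(fit$x, k, seed = solver$seed,
                        restarts = kmeans_restarts)
  res <- integrative_assign(res, fit$x, k_nn = k_nn, seed = solver$seed)
  list(result = res, embedding = fit$x, solver_state = fit$state)
}

#' Run the full clustering pipeline on feature matrices
#'
#' The real-data path: standardise features, build Gaussian-similarity
#' k-NN networks, then cluster them with \code{\link{mvcpm_cluster_graphs}}.
#'
#' @param features List of feature x sample matrices over the same,
#'   identically ordered samples.
#' @param k Number of clusters K.
#' @param knn Neighbours for the similarity networks (default 5).
#' @param ... Passed to \code{\link{mvcpm_cluster_graphs}}.
#' @return As \code{\link{mvcpm_cluster_graphs}}, plus \code{graphs}.
#' @export
mvcpm_cluster_features <- function(features, k, knn = 5L, ...) {
  graphs <- build_similarity_networks(features, knn = knn)
  out <- mvcpm_cluster_graphs(graphs, k, ...)
  out$graphs <- graphs
  out
}

#' Benchmark experiment over stochastic block model replicates
#'
#' For each probability matrix and replicate: draw a fresh multiview SBM,
#' run the full pipeline, and score the per-view labels against each
#' view's ground truth with the Rand index, averaged over views. Reports
#' the mean and standard deviation across replicates per setting.
#'
#' @param cluster_sizes List of per-view block-size vectors (one vector per
#'   view; each sums to N).
#' @param prob_matrices Named list of K x K probability matrices (already
#'   scaled to [0,1]), e.g. from \code{\link{sbm_prob_matrices}}.
#' @param replicates Number of replicates per setting (default 50).
#' @param k Number of clusters (default: blocks per view).
#' @param beta_couple Coupling strength (default 1).
#' @param solver A \code{\link{solver_config}}; each replicate re-seeds it
#'   from the experiment seed stream.
#' @param seed Master experiment seed.
#' @param kmeans_restarts Restarts for the final k-means.
#' @return List with \code{summary} (data frame: setting, mean_rand,
#'   sd_rand, replicates, n_converged) and \code{replicate_rand} (matrix,
#'   replicates x settings).
#' @export
run_sbm_experiment <- function(cluster_sizes, prob_matrices,
                               replicates = 50L, k = NULL, beta_couple = 1,
                               solver = solver_config(), seed = 1L,
                               kmeans_restarts = 20L) {
  stopifnot(replicates >= 1L, is.list(prob_matrices))
  if (is.null(names(prob_matrices)))
    names(prob_matrices) <- paste0("P", seq_along(prob_matrices))
  if (is.null(k)) k <- length(cluster_sizes[[1L]])
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max,
                                 replicates * length(prob_matrices)),
                      replicates, length(prob_matrices))
  rand <- matrix(NA_real_, replicates, length(prob_matrices),
                 dimnames = list(NULL, names(prob_matrices)))
  conv <- matrix(FALSE, replicates, length(prob_matrices))
  for (j in seq_along(prob_matrices)) {
    for (r in seq_len(replicates)) {
      s <- rep_seeds[r, j]
      g <- generate_multiview_sbm(
        sbm_config(cluster_sizes, prob_matrices[[j]], seed = s))
      cfg <- solver
      cfg$seed <- s
      fit <- mvcpm_cluster_graphs(g, k, beta_couple = beta_couple,
                                  solver = cfg,
                                  kmeans_restarts = kmeans_restarts)
      rand[r, j] <- mean(vapply(seq_len(g$n_views), function(m) {
        rand_index(fit$result$per_view_labels[[m]], g$labels[[m]])$rand
      }, numeric(1)))
      conv[r, j] <- fit$solver_state$converged
    }
  }
  summary <- data.frame(setting = names(prob_matrices),
                        mean_rand = colMeans(rand),
                        sd_rand = apply(rand, 2L, stats::sd),
                        replicates = replicates,
                        n_converged = colSums(conv),
                        row.names = NULL)
  list(summary = summary, replicate_rand = rand)
}

#' Silhouette scores of a clustering solution
#'
#' Three complementary scores, all with Euclidean distances:
#' \code{common} — silhouette of the integrative labels on the
#' view-averaged embedding; \code{average} — mean over views of the
#' silhouette of view-m labels on the X_m rows; \code{integrative} —
#' silhouette of the integrative labels (replicated per view) on the
#' stacked rows. Singleton clusters contribute silhouette 0.
#'
#' @param x The \code{embedding_blocks} used for clustering.
#' @param result A \code{cluster_result} with integrative labels.
#' @return List with \code{common}, \code{average}, \code{integrative}.
#' @export
silhouette_scores <- function(x, result) {
  stopifnot(inherits(x, "embedding_blocks"),
            inherits(result, "cluster_result"))
  if (is.null(result$integrative_labels))
    stop("integrative labels missing; run integrative_assign() first")
  sil_mean <- function(points, labels) {
    if (length(unique(labels)) < 2L)
      stop("silhouette undefined for a single cluster")
    sw <- cluster::silhouette(labels, stats::dist(points))
    mean(sw[, "sil_width"])
  }
  avg_emb <- Reduce(`+`, x$blocks) / x$n_views
  common <- sil_mean(avg_emb, result$integrative_labels)
  average <- mean(vapply(seq_len(x$n_views), function(m) {
    sil_mean(x$blocks[[m]], result$per_view_labels[[m]])
  }, numeric(1)))
  integrative <- sil_mean(stack_blocks(x),
                          rep(result$integrative_labels, x$n_views))
  list(common = common, average = average, integrative = integrative)
}

#' Log-rank test for survival differences between clusters
#'
#' Standard K-group log-rank chi-square test of equal survival curves
#' across cluster labels.
#'
#' @param labels Length-N cluster labels (at least two distinct).
#' @param surv_data Data frame with columns \code{time} (positive) and
#'   \code{event} (0/1).
#' @return List with \code{p_value}, \code{chisq}, \code{df}.
#' @export
logrank_test <- function(labels, surv_data) {
  if (!all(c("time", "event") %in% names(surv_data)))
    stop("surv_data needs columns 'time' and 'event'")
  if (length(labels) != nrow(surv_data))
    stop("labels and survival table lengths differ")
  if (any(surv_data$time <= 0)) stop("survival times must be positive")
  if (!all(surv_data$event %in% c(0, 1)))
    stop("event indicator must be 0/1")
  groups <- factor(labels)
  if (nlevels(groups) < 2L)
    stop("log-rank test needs at least two groups")
  sd_fit <- survival::survdiff(
    survival::Surv(surv_data$time, surv_data$event) ~ groups)
  df <- nlevels(groups) - 1L
  list(p_value = stats::pchisq(sd_fit$chisq, df = df, lower.tail = FALSE),
       chisq = unname(sd_fit$chisq), df = df)
}
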