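#' Read a feature-by-sample matrix from TSV/CSV
#'
#' Expects a header row of sample IDs and a first column of feature IDs.
#' The delimiter is inferred from the file extension (.csv uses a comma,
#' anything else a tab).
#'
#' @param path File path.
#' @return Numeric matrix with feature row names and sample column names.
#' @export
read_feature_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, comment.char = "")
  mat <- as.matrix(df)
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))
    stop("non-numeric values in columns: ",
         paste(colnames(df)[bad], collapse = ", "))
  }
  mat
}

#' Write a matrix as dense TSV with row and column names
#' @param x Matrix to write.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(x, path) {
  utils::write.table(as.matrix(x), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Write per-view and integrative labels as TSV
#'
#' Columns: sample_id, view_1..view_M, integrative (when present).
#'
#' @param result A \code{cluster_result}.
#' @param path Output path.
#' @param sample_ids Optional sample identifiers.
#' @export
write_labels_tsv <- function(result, path, sample_ids = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  n <- length(result$per_view_labels[[1L]])
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  df <- data.frame(sample_id = sample_ids,
                   stats::setNames(as.data.frame(result$per_view_labels),
                                   paste0("view_",
                                          seq_along(result$per_view_labels))))
  if (!is.null(result$integrative_labels))
    df$integrative <- result$integrative_labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival metadata table
#'
#' Expects columns sample_id (or sample), time, event.
#'
#' @param path TSV path.
#' @return Data frame with columns \code{sample_id}, \code{time},
#'   \code{event}.
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if ("sample" %in% names(df) && !"sample_id" %in% names(df))
    names(df)[names(df) == "sample"] <- "sample_id"
  need <- c("sample_id", "time", "event")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("survival table is missing column(s): ",
         paste(missing, collapse = ", "))
  df[need]
}

#' Write an adjacency matrix as a weighted edge list (TSV)
#' @param a Symmetric adjacency matrix.
#' @param path Output path.
#' @export
write_edge_list_tsv <- function(a, path) {
  a <- as.matrix(a)
  idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  df <- data.frame(node_i = idx[, 1L], node_j = idx[, 2L],
                   weight = a[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
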