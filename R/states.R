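# Two-state clustering of concatenated dynamic secretion profiles.
#
# Each complete course contributes a row of T x K log2 gated signals
# (window-major).  Two routes resolve the activation states: agglomerative
# clustering (Euclidean distance, Ward linkage, tree cut at k), and a 2-D
# t-SNE embedding followed by k-means on the embedding coordinates.
# Cluster 1 is always the more secretion-active cluster (highest overall
# mean signal), matching the convention that the "active" state is listed
# first.

#' Concatenated dynamic feature matrix
#'
#' @param courses Complete `cell_courses`.
#' @return Numeric matrix, cells x (T*K), columns ordered window-major
#'   (`<p>_t0` for all proteins, then `_t1`, ...), rownames = cell ids.
#' @export
build_feature_matrix <- function(courses) {
  if (!all(courses$complete))
    stop("feature matrix requires complete courses only", call. = FALSE)
  panel <- attr(courses, "panel")
  n_t <- attr(courses, "n_timepoints")
  cols <- unlist(lapply(seq_len(n_t) - 1L, function(t)
    sprintf("%s_t%d_log2", panel, t)))
  m <- as.matrix(courses[, cols, drop = FALSE])
  rownames(m) <- courses$cell_id
  colnames(m) <- unlist(lapply(seq_len(n_t) - 1L, function(t)
    sprintf("%s_t%d", panel, t)))
  m
}

relabel_by_activity <- function(labels, mat, k) {
  act <- tapply(rowMeans(mat), labels, mean)
  ord <- order(-act)                     # cluster 1 = most active
  new <- match(labels, as.integer(names(act))[ord])
  stats::setNames(as.integer(new), rownames(mat))
}

#' Hierarchical two-state clustering
#'
#' Euclidean distance, Ward linkage (`ward.D2`), dendrogram cut at `k`.
#' Deterministic given the input.
#'
#' @param mat Feature matrix from [build_feature_matrix()].
#' @param k Number of clusters (default 2).
#' @return List of class `cluster_result`: `method`, named integer
#'   `labels`, `sizes`, `params`.
#' @export
hierarchical_states <- function(mat, k = 2L) {
  if (nrow(mat) < k) stop("k exceeds the number of cells", call. = FALSE)
  hc <- stats::hclust(stats::dist(mat), method = "ward.D2")
  labels <- relabel_by_activity(stats::cutree(hc, k = k), mat, k)
  structure(list(method = "hierarchical", labels = labels,
                 sizes = as.integer(table(labels)),
                 params = list(distance = "euclidean", linkage = "ward.D2",
                               k = k)),
            class = "cluster_result")
}

#' Embedding-based two-state clustering
#'
#' 2-D t-SNE embedding (fixed seed) followed by k-means (10 restarts, best
#' inertia) on the embedding coordinates.
#'
#' @param mat Feature matrix.
#' @param k Number of clusters (default 2).
#' @param seed Integer seed controlling both the embedding and k-means.
#' @param perplexity t-SNE perplexity (default 30, lowered automatically
#'   for small inputs to the Rtsne bound (nrow-1)/3).
#' @return A `cluster_result` (see [hierarchical_states()]).
#' @export
embedding_states <- function(mat, k = 2L, seed = 1L, perplexity = 30) {
  if (nrow(mat) < k) stop("k exceeds the number of cells", call. = FALSE)
  if (all(apply(mat, 2L, stats::var) == 0))
    stop("embedding error: feature matrix is constant", call. = FALSE)
  perplexity <- min(perplexity, floor((nrow(mat) - 1) / 3))
  if (perplexity < 1)
    stop("too few cells for a t-SNE embedding", call. = FALSE)
  restore_rng_on_exit()
  set.seed(as.integer(seed))
  emb <- Rtsne::Rtsne(mat, dims = 2L, perplexity = perplexity,
                      check_duplicates = FALSE, pca = TRUE,
                      verbose = FALSE)$Y
  km <- stats::kmeans(emb, centers = k, nstart = 10L)
  labels <- relabel_by_activity(km$cluster, mat, k)
  structure(list(method = "embedding", labels = labels,
                 sizes = as.integer(table(labels)),
                 params = list(perplexity = perplexity, k = k,
                               seed = as.integer(seed))),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("%s clustering: %d clusters of sizes %s\n", x$method,
              length(x$sizes), paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Agreement between two 2-cluster labelings
#'
#' The aligned agreement is the fraction of cells on which the labelings
#' agree, maximised over the two possible label alignments; it is therefore
#' invariant to swapping either labeling's cluster names and always >= 0.5.
#'
#' @param a,b `cluster_result` objects over the same cell ids.
#' @return List of class `overlap_report`: `agreement`, 2x2 contingency
#'   `table`, and the `alignment` used (`"identity"` or `"swapped"`).
#' @export
cluster_overlap <- function(a, b) {
  ids <- names(a$labels)
  if (is.null(ids) || !setequal(ids, names(b$labels)) ||
      length(ids) != length(b$labels))
    stop("cluster results cover different cell ids", call. = FALSE)
  lb <- b$labels[ids]
  tab <- table(a = a$labels, b = lb)
  if (!all(dim(tab) == c(2L, 2L))) {
    full <- matrix(0L, 2L, 2L, dimnames = list(a = 1:2, b = 1:2))
    full[rownames(tab), colnames(tab)] <- tab
    tab <- as.table(full)
  }
  n <- length(ids)
  same <- (tab[1, 1] + tab[2, 2]) / n
  swapped <- (tab[1, 2] + tab[2, 1]) / n
  structure(list(agreement = max(same, swapped), table = tab,
                 alignment = if (same >= swapped) "identity" else "swapped"),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Aligned cluster agreement: %.1f%% (%s alignment)\n",
              100 * x$agreement, x$alignment))
  print(x$table)
  invisible(x)
}

#' Per-cluster, per-window mean signal
#'
#' Summarises how active each cluster is over time (mean log2 signal over
#' all panel proteins and member cells per window).
#'
#' @param result A `cluster_result`.
#' @param courses The complete `cell_courses` the clustering was built from.
#' @return Data frame `cluster, window, mean_log2`.
#' @export
cluster_activity <- function(result, courses) {
  panel <- attr(courses, "panel")
  n_t <- attr(courses, "n_timepoints")
  labels <- result$labels[courses$cell_id]
  rows <- list()
  for (t in seq_len(n_t) - 1L) {
    sig <- rowMeans(as.matrix(
      courses[, sprintf("%s_t%d_log2", panel, t), drop = FALSE]))
    mu <- tapply(sig, labels, mean)
    rows[[t + 1L]] <- data.frame(cluster = as.integer(names(mu)), window = t,
                                 mean_log2 = as.numeric(mu))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
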