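# In-bag proximity and Ward agglomeration --------------------------------
#
# Proximity between two training patients is the fraction of trees, among
# those where both are in the bootstrap sample, in which they share a
# terminal node. Subtracting it from 1 yields the dissimilarity fed to
# Ward hierarchical clustering.

#' In-bag proximity matrix of a survival forest
#'
#' For every pair of training patients, computes the number of trees where
#' both are in-bag (`pair_counts`) and the proportion of those trees in
#' which they share a terminal node (`values`). The diagonal is 1. Pairs
#' never co-in-bag (vanishingly rare at 1000 trees) get proximity 0 with a
#' warning.
#'
#' @param forest a fitted `survival_forest`.
#' @return An object of class `proximity_matrix`: list with `values`
#'   (symmetric, unit diagonal, entries in `[0,1]`) and `pair_counts`.
#' @export
inbag_proximity <- function(forest) {
  ids <- terminal_node_ids(forest, forest$train_features)
  ib <- inbag_counts(forest) > 0
  n <- nrow(ids)
  shared <- matrix(0, n, n)
  both <- matrix(0, n, n)
  for (t in seq_len(ncol(ids))) {
    w <- which(ib[, t])
    node <- ids[w, t]
    same <- outer(node, node, "==")
    both[w, w] <- both[w, w] + 1
    shared[w, w] <- shared[w, w] + same
  }
  if (any(both == 0))
    warning("some patient pairs were never co-in-bag; proximity set to 0")
  values <- ifelse(both > 0, shared / pmax(both, 1), 0)
  diag(values) <- 1
  rn <- rownames(forest$train_features)
  dimnames(values) <- dimnames(both) <- list(rn, rn)
  structure(list(values = values, pair_counts = both),
            class = "proximity_matrix")
}

#' Convert proximity to dissimilarity
#'
#' Entrywise `D = 1 - P`, with a zero diagonal.
#'
#' @param P a `proximity_matrix` (or plain proximity matrix).
#' @return symmetric numeric dissimilarity matrix.
#' @export
proximity_to_dissimilarity <- function(P) {
  v <- if (inherits(P, "proximity_matrix")) P$values else P
  d <- 1 - v
  diag(d) <- 0
  d
}

#' Ward agglomeration on a precomputed dissimilarity
#'
#' Agglomerative hierarchical clustering on `D` using the Lance-Williams
#' recurrence for Ward's minimum-variance criterion:
#' `d(ab,c) = ((n_a+n_c) d(a,c) + (n_b+n_c) d(b,c) - n_c d(a,b)) /
#' (n_a+n_b+n_c)`. The default dialect (`"ward.D"`) treats the entries of
#' `D` directly as squared distances; `"ward.D2"` squares them first, as
#' appropriate when `D` holds unsquared distances. With squared-Euclidean
#' input the merge heights equal twice the Ward between-cluster variance
#' increment `|c1||c2|/(|c1|+|c2|) * ||mean(c1) - mean(c2)||^2`.
#'
#' @param D symmetric, zero-diagonal, non-negative dissimilarity matrix.
#' @param dialect `"ward.D"` (default: entries used as-is) or `"ward.D2"`.
#' @return An `hclust` object (merge list + heights + leaf order).
#' @export
ward_agglomerate <- function(D, dialect = c("ward.D", "ward.D2")) {
  dialect <- match.arg(dialect)
  if (inherits(D, "proximity_matrix")) D <- proximity_to_dissimilarity(D)
  if (anyNA(D)) stop("dissimilarity matrix contains NA")
  stopifnot(isSymmetric(unname(D)), all(D >= 0), all(diag(D) == 0))
  hclust(as.dist(D), method = dialect)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges and renumbers clusters by decreasing
#' size, so that cluster 1 is always the largest (stable reporting across
#' reruns); equal-sized clusters keep their dendrogram order.
#'
#' @param dendrogram an `hclust` as from [ward_agglomerate()].
#' @param k number of clusters (2..n).
#' @return An object of class `cluster_labels`: integer vector in `1..k`
#'   with attribute `k`.
#' @export
cut_dendrogram <- function(dendrogram, k) {
  n <- length(dendrogram$order)
  if (k < 2 || k > n) stop("k must lie in [2, n]")
  raw <- cutree(dendrogram, k = k)
  sizes <- table(raw)
  new_id <- setNames(rank(-as.numeric(sizes), ties.method = "first"),
                     names(sizes))
  labels <- as.integer(new_id[as.character(raw)])
  names(labels) <- names(raw)
  structure(labels, k = as.integer(k), class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf("<cluster_labels> k = %d; sizes: %s\n", attr(x, "k"),
              paste(table(as.integer(x)), collapse = "/")))
  invisible(x)
}

#' Write clustering artifacts
#'
#' Writes the proximity matrix as a square CSV with patient ids, the merge
#' list as JSON, and the labels as a two-column CSV.
#'
#' @param P `proximity_matrix`; `hc` `hclust`; `labels` `cluster_labels`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_clustering <- function(P, hc, labels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(patient_id = rownames(P$values), P$values,
                       check.names = FALSE),
            file.path(dir, "proximity.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(merges = apply(hc$merge, 1, identity, simplify = FALSE),
         heights = hc$height, order = hc$order),
    file.path(dir, "dendrogram.json"), auto_unbox = FALSE, digits = NA)
  write.csv(data.frame(patient_id = names(labels),
                       cluster = as.integer(labels)),
            file.path(dir, "clusters.csv"), row.names = FALSE)
  invisible(dir)
}
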