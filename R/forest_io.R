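# Forest persistence ------------------------------------------------------
#
# Small forests round-trip through JSON: per tree the split variable ids,
# split values and child pointers are stored together with the in-bag
# multiplicities and fitting metadata. The restored object routes samples
# with the same rule as the fitted forest (value <= split goes left), so
# terminal-node ids — the raw material of the proximity matrix — are
# reproduced exactly.

#' Persist a survival forest as JSON
#'
#' Stores tree structures (split variable per node, split value, left/right
#' child ids, terminal flags), in-bag counts and fitting metadata. Intended
#' for small forests; the file grows linearly in nodes x trees.
#'
#' @param forest a `survival_forest`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(forest, path) {
  rf <- forest$ranger$forest
  trees <- lapply(seq_len(forest$n_trees), function(t) {
    list(split_var = as.integer(rf$split.varIDs[[t]]),
         split_value = as.numeric(rf$split.values[[t]]),
         left = as.integer(rf$child.nodeIDs[[t]][[1]]),
         right = as.integer(rf$child.nodeIDs[[t]][[2]]))
  })
  jsonlite::write_json(
    list(n_trees = forest$n_trees, mtry = forest$mtry,
         min_node_size = forest$min_node_size, seed = forest$seed,
         feature_names = forest$feature_names,
         inbag = lapply(forest$ranger$inbag.counts, as.integer),
         trees = trees),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a persisted forest
#'
#' @param path JSON file written by [write_forest_json()].
#' @return An object of class `survival_forest_json` usable with
#'   [route_terminal_nodes()] and [inbag_counts()].
#' @export
read_forest_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  structure(list(n_trees = j$n_trees, mtry = j$mtry,
                 min_node_size = j$min_node_size, seed = j$seed,
                 feature_names = j$feature_names,
                 inbag = j$inbag, trees = j$trees),
            class = "survival_forest_json")
}

#' Route samples through a restored forest
#'
#' Applies the stored split rules (`value <= split` goes left) and returns
#' the terminal-node id each sample reaches in each tree — the same ids
#' [terminal_node_ids()] reports for the original fitted forest.
#'
#' @param forest a `survival_forest_json`.
#' @param features matrix containing the training columns.
#' @return integer matrix, samples x trees.
#' @export
route_terminal_nodes <- function(forest, features) {
  stopifnot(inherits(forest, "survival_forest_json"))
  x <- features[, forest$feature_names, drop = FALSE]
  n <- nrow(x)
  out <- matrix(0L, n, forest$n_trees)
  for (t in seq_len(forest$n_trees)) {
    tr <- forest$trees[[t]]
    for (i in seq_len(n)) {
      node <- 1L   # 1-based index of the 0-based root
      while (tr$left[node] != 0L) {
        v <- x[i, tr$split_var[node] + 1L]
        node <- (if (v <= tr$split_value[node]) tr$left[node]
                 else tr$right[node]) + 1L
      }
      out[i, t] <- node - 1L
    }
  }
  out
}
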