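# Random survival forest -------------------------------------------------
#
# The forest is grown by ranger with the log-rank splitting rule; this
# module wraps it behind a stable surface that exposes exactly what the
# proximity and feature-ranking steps need: per-tree terminal-node ids for
# arbitrary samples, per-tree bootstrap (in-bag) multiplicities, split
# frequencies per feature, and ensemble-mortality risk predictions.

#' Fit a random survival forest
#'
#' Grows `n_trees` survival trees on bootstrap samples, splitting by the
#' standardized log-rank statistic over `mtry` candidate features per node.
#' Two presets are used in the pipeline: the clustering forest
#' (`min_node_size = 5`) and the feature-selection forest
#' (`min_node_size = 2`), both with 1000 trees.
#'
#' @param features numeric matrix with column names.
#' @param time follow-up time (months), strictly positive.
#' @param event event indicator (0/1).
#' @param n_trees number of trees (default 1000).
#' @param mtry features tried per split; default `ceiling(sqrt(p))`.
#' @param min_node_size minimal terminal-node size (default 5).
#' @param seed integer seed; the forest is bit-reproducible from it.
#' @return An object of class `survival_forest`.
#' @export
fit_survival_forest <- function(features, time, event,
                                n_trees = 1000, mtry = NULL,
                                min_node_size = 5, seed = 1L) {
  stopifnot(is.matrix(features), !anyNA(features),
            length(time) == nrow(features), all(time > 0),
            all(event %in% c(0, 1)))
  if (length(unique(time[event == 1])) < 2)
    stop("need at least 2 distinct event times to grow a survival forest")
  p <- ncol(features)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  if (mtry > p) stop("mtry cannot exceed the number of features")
  fit <- ranger::ranger(
    x = features, y = survival::Surv(time, event),
    num.trees = n_trees, mtry = mtry, min.node.size = min_node_size,
    splitrule = "logrank", keep.inbag = TRUE,
    num.threads = 1, verbose = FALSE, seed = as.integer(seed))
  structure(list(ranger = fit,
                 n_trees = n_trees, mtry = mtry,
                 min_node_size = min_node_size, seed = as.integer(seed),
                 feature_names = colnames(features),
                 train_features = features,
                 train_time = time, train_event = event),
            class = "survival_forest")
}

#' @export
print.survival_forest <- function(x, ...) {
  cat(sprintf("<survival_forest> %d trees, mtry %d, min node %d, %d features\n",
              x$n_trees, x$mtry, x$min_node_size, length(x$feature_names)))
  invisible(x)
}

check_forest_schema <- function(forest, features) {
  if (!all(forest$feature_names %in% colnames(features)))
    stop("feature columns do not match the forest's training schema")
  features[, forest$feature_names, drop = FALSE]
}

#' Terminal-node ids per tree
#'
#' Routes each sample down every tree and reports the id of the terminal
#' node it lands in.
#'
#' @param forest a `survival_forest`.
#' @param features matrix with (at least) the training columns.
#' @return integer matrix, samples x trees.
#' @export
terminal_node_ids <- function(forest, features) {
  x <- check_forest_schema(forest, features)
  predict(forest$ranger, data = x, type = "terminalNodes",
          num.threads = 1)$predictions
}

#' Bootstrap multiplicities per tree
#'
#' @param forest a `survival_forest` (or a restored `survival_forest_json`).
#' @return integer matrix (training samples x trees) of bootstrap draw
#'   counts; a sample is in-bag in tree `t` iff its count is positive.
#' @export
inbag_counts <- function(forest) {
  if (inherits(forest, "survival_forest_json"))
    return(do.call(cbind, forest$inbag))
  do.call(cbind, forest$ranger$inbag.counts)
}

#' Split-frequency variable importance
#'
#' Ranks features by the number of internal nodes, across all trees, that
#' split on them. Ties are broken alphabetically by feature name. Features
#' never split on are included with count 0.
#'
#' @param forest a `survival_forest`.
#' @return data.frame with columns `feature` and `count`, sorted by
#'   decreasing count.
#' @export
variable_importance_frequency <- function(forest) {
  counts <- setNames(numeric(length(forest$feature_names)),
                     forest$feature_names)
  rf <- forest$ranger$forest
  for (t in seq_len(forest$n_trees)) {
    term <- rf$child.nodeIDs[[t]][[1]] == 0 & rf$child.nodeIDs[[t]][[2]] == 0
    ids <- rf$split.varIDs[[t]][!term] + 1L
    tab <- tabulate(ids, nbins = length(counts))
    counts <- counts + tab
  }
  ord <- order(-counts, names(counts))
  data.frame(feature = names(counts)[ord], count = unname(counts[ord]),
             row.names = NULL)
}

#' Repeat-and-average split-frequency importance
#'
#' Refits the forest under `n_repeats` derived seeds and averages the split
#' counts per feature, smoothing over bootstrap randomness.
#'
#' @inheritParams fit_survival_forest
#' @param n_repeats number of forest refits (default 10).
#' @return data.frame with `feature` and mean `count`, sorted decreasing.
#' @export
importance_repeated <- function(features, time, event, n_trees = 1000,
                                mtry = NULL, min_node_size = 2,
                                seed = 1L, n_repeats = 10) {
  acc <- NULL
  for (r in seq_len(n_repeats)) {
    f <- fit_survival_forest(features, time, event, n_trees, mtry,
                             min_node_size,
                             seed = (as.integer(seed) + 7919L * r) %%
                               .Machine$integer.max)
    vi <- variable_importance_frequency(f)
    vi <- vi[order(vi$feature), ]
    acc <- if (is.null(acc)) vi$count else acc + vi$count
  }
  nm <- sort(f$feature_names)
  cnt <- acc / n_repeats
  ord <- order(-cnt, nm)
  data.frame(feature = nm[ord], count = cnt[ord], row.names = NULL)
}

#' Ensemble-mortality risk from a survival forest
#'
#' Risk is the ensemble mortality: the tree-averaged Nelson-Aalen cumulative
#' hazard summed over the grid of unique training event times. Higher values
#' mean higher risk.
#'
#' @param forest a `survival_forest`.
#' @param features matrix with the training columns.
#' @return numeric risk vector.
#' @export
predict_forest_risk <- function(forest, features) {
  x <- check_forest_schema(forest, features)
  chf <- predict(forest$ranger, data = x, num.threads = 1)$chf
  rowSums(chf)
}

#' Forest survival probability at a horizon
#'
#' Evaluates the tree-averaged survival step function at `horizon` months.
#'
#' @param forest a `survival_forest`.
#' @param features matrix with the training columns.
#' @param horizon time in months.
#' @return vector of survival probabilities at the horizon.
#' @export
predict_forest_survival <- function(forest, features, horizon) {
  x <- check_forest_schema(forest, features)
  pr <- predict(forest$ranger, data = x, num.threads = 1)
  tt <- pr$unique.death.times
  surv <- pr$survival
  if (is.null(dim(surv)))   # single-row newdata comes back as a vector
    surv <- matrix(surv, nrow = nrow(x))
  idx <- findInterval(horizon, tt)
  if (idx == 0) rep(1, nrow(x)) else surv[, idx]
}

#' Standardized log-rank splitting statistic
#'
#' The criterion maximized at each forest split: for a candidate binary
#' split, the observed-minus-expected event count in the left daughter
#' summed over distinct event times, standardized by its hypergeometric
#' variance. Its square is the classical two-sample log-rank chi-square.
#'
#' @param time,event outcome vectors at the node.
#' @param left logical vector marking the left daughter.
#' @return list with `numerator`, `variance`, `statistic`
#'   (`numerator/sqrt(variance)`) and `chi2` (its square).
#' @export
logrank_split_stat <- function(time, event, left) {
  stopifnot(length(time) == length(event), length(left) == length(time))
  tk <- sort(unique(time[event == 1]))
  num <- 0; v <- 0
  for (t in tk) {
    at_risk <- time >= t
    Y <- sum(at_risk); Y1 <- sum(at_risk & left)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & left)
    num <- num + (d1 - Y1 * d / Y)
    if (Y > 1)
      v <- v + (Y1 / Y) * (1 - Y1 / Y) * ((Y - d) / (Y - 1)) * d
  }
  stat <- if (v > 0) num / sqrt(v) else 0
  list(numerator = num, variance = v, statistic = stat, chi2 = stat^2)
}
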