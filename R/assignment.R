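# Cluster assignment for held-out patients -------------------------------
#
# Test patients never enter the clustering. They receive a label from a
# multinomial log-linear model trained on the training patients, using the
# forest's most frequently split features as predictors and the training
# cluster labels as the response. Multinomial (not binary) so the same
# machinery covers 2-4 clusters.

#' Fit the cluster-assignment model
#'
#' Multinomial logistic regression of the training cluster labels on the
#' `top_k` features of the split-frequency ranking, z-scored with training
#' means/SDs. Cluster 1 is the reference class. If the optimizer does not
#' converge (e.g. quasi-separation), the fit is repeated with a small L2
#' ridge penalty and this is recorded on the model.
#'
#' @param features training feature matrix.
#' @param labels `cluster_labels` for the training patients.
#' @param importance_ranking data.frame from
#'   [variable_importance_frequency()].
#' @param top_k number of top-ranked features to use (default 10).
#' @return An object of class `assignment_model` carrying the feature
#'   subset, scaler and coefficient matrix.
#' @export
fit_assignment_model <- function(features, labels, importance_ranking,
                                 top_k = 10) {
  stopifnot(top_k >= 1)
  k <- attr(labels, "k")
  if (is.null(k)) k <- max(labels)
  if (length(unique(as.integer(labels))) < 2)
    stop("assignment model needs at least two clusters in the labels")
  subset <- head(importance_ranking$feature, top_k)
  x <- features[, subset, drop = FALSE]
  scaler <- zscore_fit(x)
  xz <- zscore_apply(x, scaler)
  df <- data.frame(xz, check.names = FALSE)
  df$.cluster <- factor(as.integer(labels), levels = seq_len(k))
  fit <- nnet::multinom(.cluster ~ ., data = df, trace = FALSE, maxit = 500)
  ridged <- FALSE
  if (fit$convergence != 0) {
    fit <- nnet::multinom(.cluster ~ ., data = df, trace = FALSE,
                          maxit = 500, decay = 1e-3)
    ridged <- TRUE
    message("assignment model refit with small ridge penalty")
  }
  co <- coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1,
                                     dimnames = list(NULL, names(co)))
  # columns: (Intercept), features in `subset` order
  colnames(co)[1] <- "(Intercept)"
  structure(list(feature_subset = subset,
                 scaler = scaler,
                 coefficients = co,
                 k = as.integer(k),
                 ridged = ridged),
            class = "assignment_model")
}

#' Assign cluster labels to new patients
#'
#' Computes softmax probabilities from the stored coefficient matrix on the
#' z-scored feature subset and assigns the argmax cluster; exact probability
#' ties resolve toward the lower cluster index.
#'
#' @param model an `assignment_model`.
#' @param features matrix containing the model's feature subset.
#' @return `cluster_labels` with a `probabilities` attribute
#'   (patients x k matrix).
#' @export
assign_clusters <- function(model, features) {
  missing <- setdiff(model$feature_subset, colnames(features))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  xz <- zscore_apply(features[, model$feature_subset, drop = FALSE],
                     model$scaler)
  eta <- cbind(1, as.matrix(xz)) %*%
    t(model$coefficients[, c("(Intercept)", model$feature_subset),
                         drop = FALSE])
  eta <- cbind(0, eta)  # reference cluster 1
  eta <- eta - apply(eta, 1, max)
  pr <- exp(eta) / rowSums(exp(eta))
  colnames(pr) <- paste0("C", seq_len(model$k))
  rownames(pr) <- rownames(features)
  lab <- max.col(pr, ties.method = "first")
  names(lab) <- rownames(features)
  structure(as.integer(lab), k = model$k, names = rownames(features),
            probabilities = pr, class = "cluster_labels")
}

#' Serialize / restore an assignment model
#'
#' @param model an `assignment_model`; `path` JSON file path.
#' @return `read_assignment_model` returns the restored model.
#' @export
write_assignment_model <- function(model, path) {
  jsonlite::write_json(
    list(feature_subset = model$feature_subset,
         center = as.list(model$scaler$center),
         scale = as.list(model$scaler$scale),
         coef_values = as.numeric(model$coefficients),  # column-major
         coef_rows = nrow(model$coefficients),
         coef_names = colnames(model$coefficients),
         k = model$k, ridged = model$ridged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_assignment_model
#' @param path JSON file written by `write_assignment_model`.
#' @export
read_assignment_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- matrix(j$coef_values, nrow = j$coef_rows,
               dimnames = list(NULL, j$coef_names))
  structure(list(feature_subset = j$feature_subset,
                 scaler = list(center = unlist(j$center),
                               scale = unlist(j$scale)),
                 coefficients = co,
                 k = as.integer(j$k),
                 ridged = isTRUE(j$ridged)),
            class = "assignment_model")
}
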