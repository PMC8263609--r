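# Stacked risk ensemble ---------------------------------------------------
#
# Five base models predict the probability of an event by the horizon:
# Cox proportional hazards and a random survival forest consume the
# censored outcome directly (their survival functions are evaluated at the
# horizon); a weighted random-forest classifier, weighted logistic
# regression and weighted logistic elastic net consume the IPCW-weighted
# binary horizon outcome. Non-negative least squares on 5-fold out-of-fold
# predictions learns the stacking weights.

.base_model_names <- c("cox", "rsf", "rf", "logistic", "elnet")

# Random fold assignment; a draw leaving any training complement without
# at least two events is redrawn under a derived seed (a complement that
# poor cannot fit the base models).
make_folds <- function(n, n_folds, seed, event) {
  for (try in 0:49) {
    folds <- withr::with_seed((as.integer(seed) + 1013L * try) %%
                                .Machine$integer.max,
                              sample(rep_len(seq_len(n_folds), n)))
    fold_ok <- vapply(seq_len(n_folds), function(f) {
      sum(event[folds != f]) >= 2
    }, logical(1))
    if (all(fold_ok)) {
      if (try > 0) message("fold assignment redrawn ", try, " time(s)")
      return(folds)
    }
  }
  stop("could not build folds whose complements all contain events")
}

#' Fit the five base risk models
#'
#' Fits Cox proportional hazards and a random survival forest on the
#' censored outcome, and an IPCW-weighted random-forest classifier,
#' logistic regression and logistic elastic net (mixing parameter 0.5,
#' penalty chosen by weighted 5-fold cross-validated deviance) on the
#' binary horizon outcome. Zero-weight patients are excluded from the
#' binary learners. Regression-based learners see z-scored inputs
#' (training statistics); forests see raw columns.
#'
#' @param design numeric design matrix (one-hot encoded, no missing values).
#' @param time,event censored outcome vectors.
#' @param horizon horizon in months.
#' @param outcome optional precomputed [ipcw_weights()] result for these
#'   rows; computed from `time`/`event` when `NULL`.
#' @param seed integer seed driving the two forests and the elastic-net
#'   fold assignment.
#' @param n_trees_rsf,n_trees_rf forest sizes.
#' @return object of class `base_models`.
#' @export
fit_base_models <- function(design, time, event, horizon = 60,
                            outcome = NULL, seed = 1L,
                            n_trees_rsf = 1000, n_trees_rf = 500) {
  stopifnot(!anyNA(design))
  if (is.null(outcome)) outcome <- ipcw_weights(time, event, horizon)
  w <- outcome$weight; y <- outcome$label
  keep <- w > 0
  out <- list(horizon = horizon, p = ncol(design), seed = as.integer(seed))
  class(out) <- "base_models"
  if (ncol(design) == 0) {
    out$constant <- sum(w[keep] * y[keep]) / sum(w[keep])
    return(out)
  }
  colnames(design) <- make.names(colnames(design), unique = TRUE)
  out$columns <- colnames(design)
  out$scaler <- zscore_fit(design)
  xz <- zscore_apply(design, out$scaler)

  # Cox PH; collinear columns get NA coefficients, treated as zero
  df <- data.frame(design, check.names = FALSE)
  cox <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ ., data = df,
                    model = FALSE, x = FALSE, y = TRUE),
    warning = function(wn) {
      suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ ., data = df,
                        model = FALSE, x = FALSE, y = TRUE))
    })
  beta <- coef(cox)
  beta[is.na(beta)] <- 0   # collinear columns (e.g. empty fold levels)
  # Breslow baseline cumulative hazard at the horizon, computed from the
  # zeroed coefficient vector so rank-deficient fits stay finite
  # clip the linear predictor: quasi-separated fits (tiny cluster levels)
  # can push coefficients far enough that exp() overflows
  lp_tr <- pmin(pmax(as.numeric(as.matrix(design) %*% beta), -30), 30)
  tk <- sort(unique(time[event == 1 & time <= horizon]))
  H0 <- sum(vapply(tk, function(t)
    sum(time == t & event == 1) / sum(exp(lp_tr[time >= t])), numeric(1)))
  out$cox <- list(beta = beta, H0 = H0)

  out$rsf <- fit_survival_forest(design, time, event,
                                 n_trees = n_trees_rsf, min_node_size = 5,
                                 seed = (seed + 11L) %% .Machine$integer.max)

  yk <- factor(y[keep], levels = c(0, 1))
  if (nlevels(droplevels(yk)) < 2)
    stop("only one horizon class among positive-weight patients")
  out$rf <- ranger::ranger(
    x = design[keep, , drop = FALSE], y = yk,
    case.weights = w[keep], probability = TRUE,
    num.trees = n_trees_rf, num.threads = 1, verbose = FALSE,
    seed = (seed + 12L) %% .Machine$integer.max)

  dlog <- data.frame(.y = y[keep], xz[keep, , drop = FALSE],
                     check.names = FALSE)
  out$logistic <- suppressWarnings(
    glm(.y ~ ., family = quasibinomial(), data = dlog,
        weights = w[keep]))

  xen <- xz[keep, , drop = FALSE]
  if (ncol(xen) < 2) xen <- cbind(xen, .pad = 0)
  foldid <- withr::with_seed((seed + 13L) %% .Machine$integer.max,
                             sample(rep_len(1:5, nrow(xen))))
  out$elnet <- suppressWarnings(
    glmnet::cv.glmnet(xen, y[keep], family = "binomial",
                      weights = w[keep], alpha = 0.5, foldid = foldid,
                      standardize = FALSE))
  out
}

#' Predict horizon-event risks from the base models
#'
#' Cox and survival-forest outputs are mapped to the probability scale as
#' `1 - S_i(horizon)`; the three binary learners predict the positive-class
#' probability directly, so all five columns are horizon-event
#' probabilities.
#'
#' @param models a `base_models`.
#' @param design design matrix with the training columns.
#' @return numeric matrix, patients x 5 (`cox`, `rsf`, `rf`, `logistic`,
#'   `elnet`).
#' @export
predict_base_models <- function(models, design) {
  n <- nrow(design)
  if (models$p == 0)
    return(matrix(models$constant, n, 5,
                  dimnames = list(NULL, .base_model_names)))
  colnames(design) <- make.names(colnames(design), unique = TRUE)
  if (!all(models$columns %in% colnames(design)))
    stop("design columns do not match the fitted base models")
  design <- design[, models$columns, drop = FALSE]
  xz <- zscore_apply(design, models$scaler)

  lp <- pmin(pmax(as.numeric(as.matrix(design) %*% models$cox$beta),
                  -30), 30)
  cox <- 1 - exp(-models$cox$H0 * exp(lp))
  rsf <- 1 - predict_forest_survival(models$rsf, design, models$horizon)
  rf <- predict(models$rf, data = design, num.threads = 1)$predictions[, "1"]
  # unused factor levels in a CV fold make the glm rank-deficient; the
  # prediction is still well-defined on the observed levels
  logi <- as.numeric(suppressWarnings(
    predict(models$logistic, newdata = data.frame(xz, check.names = FALSE),
            type = "response")))
  xen <- xz
  if (ncol(xen) < 2) xen <- cbind(xen, .pad = 0)
  eln <- as.numeric(predict(models$elnet, newx = as.matrix(xen),
                            s = "lambda.min", type = "response"))
  cbind(cox = cox, rsf = rsf, rf = rf, logistic = logi, elnet = eln)
}

#' Out-of-fold base-model predictions
#'
#' Splits the training patients into `n_folds` folds; for each fold the
#' five base models are fit on the complement (IPCW weights re-estimated on
#' the complement) and predict the horizon risk of the held-out fold. A
#' fold draw leaving any fold without events is redrawn under a derived
#' seed.
#'
#' @inheritParams fit_base_models
#' @param n_folds number of folds (default 5).
#' @return matrix Z (patients x 5), rows aligned with the input.
#' @export
out_of_fold_predictions <- function(design, time, event, horizon = 60,
                                    n_folds = 5, seed = 1L,
                                    n_trees_rsf = 1000, n_trees_rf = 500) {
  stopifnot(n_folds >= 2)
  n <- nrow(design)
  folds <- make_folds(n, n_folds, seed, event)
  Z <- matrix(NA_real_, n, 5,
              dimnames = list(rownames(design), .base_model_names))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    m <- fit_base_models(design[tr, , drop = FALSE], time[tr], event[tr],
                         horizon = horizon,
                         seed = (as.integer(seed) + 101L * f) %%
                           .Machine$integer.max,
                         n_trees_rsf = n_trees_rsf, n_trees_rf = n_trees_rf)
    Z[!tr, ] <- predict_base_models(m, design[!tr, , drop = FALSE])
  }
  Z
}

#' Non-negative least-squares stacking weights
#'
#' Minimizes the IPCW-weighted squared error
#' `sum_i w_i (y_i - Z_i beta)^2` subject to `beta >= 0`
#' (Lawson-Hanson active-set algorithm), then normalizes the weights to
#' sum to 1. Zero-weight patients carry no loss and are excluded. An
#' all-zero solution falls back to uniform weights with a warning.
#'
#' @param Z out-of-fold prediction matrix (patients x models).
#' @param outcome a `horizon_outcome` aligned with the rows of `Z`.
#' @return normalized non-negative weight vector, one per model.
#' @export
nnls_stack <- function(Z, outcome) {
  keep <- outcome$weight > 0
  stopifnot(all(is.finite(Z[keep, ])))
  sw <- sqrt(outcome$weight[keep])
  A <- Z[keep, , drop = FALSE] * sw
  b <- outcome$label[keep] * sw
  beta <- pracma::lsqnonneg(A, b)$x
  if (sum(beta) <= 0) {
    warning("NNLS returned the zero vector; falling back to uniform weights")
    beta <- rep(1, ncol(Z))
  }
  setNames(beta / sum(beta), colnames(Z))
}

#' Fit the stacked ensemble
#'
#' Learns stacking weights by NNLS on 5-fold out-of-fold predictions, then
#' refits the five base models on the full training data.
#'
#' @inheritParams out_of_fold_predictions
#' @return object of class `stacked_ensemble` with `base_models`,
#'   `stack_weights`, `oof` (the Z matrix), `horizon` and `cv_seed`.
#' @export
fit_stacked_ensemble <- function(design, time, event, horizon = 60,
                                 n_folds = 5, seed = 1L,
                                 n_trees_rsf = 1000, n_trees_rf = 500) {
  outcome <- ipcw_weights(time, event, horizon)
  Z <- out_of_fold_predictions(design, time, event, horizon, n_folds, seed,
                               n_trees_rsf, n_trees_rf)
  wts <- nnls_stack(Z, outcome)
  base <- fit_base_models(design, time, event, horizon, outcome,
                          seed = as.integer(seed),
                          n_trees_rsf = n_trees_rsf, n_trees_rf = n_trees_rf)
  structure(list(base_models = base, stack_weights = wts, oof = Z,
                 horizon = horizon, cv_seed = as.integer(seed)),
            class = "stacked_ensemble")
}

#' @export
print.stacked_ensemble <- function(x, ...) {
  cat("<stacked_ensemble> horizon", x$horizon, "months; weights:",
      paste(sprintf("%s=%.3f", names(x$stack_weights), x$stack_weights),
            collapse = " "), "\n")
  invisible(x)
}

#' Ensemble risk prediction
#'
#' Convex combination of the base-model horizon risks under the stacking
#' weights, clipped to `[0, 1]`.
#'
#' @param model a `stacked_ensemble`.
#' @param design design matrix with the training columns.
#' @return numeric risk vector in `[0, 1]`.
#' @export
ensemble_predict <- function(model, design) {
  P <- predict_base_models(model$base_models, design)
  pmin(pmax(as.numeric(P %*% model$stack_weights), 0), 1)
}

#' L1-penalized Cox feature selection
#'
#' Fits a lasso-penalized Cox model over a regularization path, picks the
#' penalty by `n_folds`-fold cross-validated partial-likelihood deviance,
#' and returns the features with non-zero coefficients at that penalty.
#'
#' @param features numeric feature matrix.
#' @param time,event censored outcome vectors.
#' @param n_folds CV folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return character vector of selected feature names (possibly empty,
#'   with a message).
#' @export
coxnet_select <- function(features, time, event, n_folds = 5, seed = 1L) {
  if (sum(event) < 2) stop("need at least 2 events for coxnet selection")
  folds <- make_folds(nrow(features), n_folds, seed, event)
  y <- survival::Surv(time, event)
  cv <- glmnet::cv.glmnet(features, y, family = "cox", alpha = 1,
                          foldid = folds)
  co <- as.matrix(coef(cv, s = "lambda.min"))
  sel <- rownames(co)[co[, 1] != 0]
  if (!length(sel))
    message("coxnet selected no features; caller should fall back to ",
            "clinical covariates only")
  sel
}
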