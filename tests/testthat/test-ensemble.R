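# Compact censored fixture with a cluster-style binary covariate.
ens_fixture <- function(n = 150, hr = 3, seed = 9) {
  withr::with_seed(seed, {
    cl <- rep(1:2, length.out = n)
    x <- cbind(risk_grp = cl - 1, noise = rnorm(n))
    t_ev <- rexp(n, 0.004 * hr^(cl - 1))
    t_cn <- pmin(rexp(n, 0.008), 120)
    list(x = x, time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn),
         cl = cl)
  })
}

test_that("five base models fit and predict on the probability scale", {
  d <- ens_fixture()
  m <- fit_base_models(d$x, d$time, d$event, horizon = 60, seed = 1,
                       n_trees_rsf = 100, n_trees_rf = 100)
  P <- predict_base_models(m, d$x)
  expect_equal(colnames(P), c("cox", "rsf", "rf", "logistic", "elnet"))
  expect_true(all(P >= 0 & P <= 1))
  # every model sees the group effect: higher risk for the high-hazard arm
  for (j in 1:5)
    expect_gt(mean(P[d$cl == 2, j]), mean(P[d$cl == 1, j]))
})

test_that("Cox hazard ratio between clusters matches the generator sign", {
  d <- ens_fixture(n = 300)
  m <- fit_base_models(d$x, d$time, d$event, seed = 2,
                       n_trees_rsf = 50, n_trees_rf = 50)
  expect_gt(m$cox$beta[["risk_grp"]], 0)
})

test_that("an empty design yields constant predictions", {
  d <- ens_fixture(n = 80)
  m <- fit_base_models(d$x[, 0, drop = FALSE], d$time, d$event, seed = 3)
  P <- predict_base_models(m, d$x[, 0, drop = FALSE])
  expect_equal(length(unique(as.numeric(P))), 1)
})

test_that("a covariate equal to the horizon label separates perfectly", {
  withr::with_seed(10, {
    n <- 120
    y <- rbinom(n, 1, 0.4)
    time <- ifelse(y == 1, runif(n, 1, 59), runif(n, 61, 100))
    event <- y                      # event before horizon iff y = 1
    x <- cbind(label_leak = y, noise = rnorm(n))
  })
  m <- fit_base_models(x, time, event, horizon = 60, seed = 4,
                       n_trees_rsf = 50, n_trees_rf = 50)
  P <- predict_base_models(m, x)
  o <- ipcw_weights(time, event, 60)
  expect_equal(auc_horizon(P[, "logistic"], o), 1)
})

test_that("out-of-fold predictions are deterministic and fold-honest", {
  d <- ens_fixture(n = 60)
  Z1 <- out_of_fold_predictions(d$x, d$time, d$event, n_folds = 3, seed = 5,
                                n_trees_rsf = 30, n_trees_rf = 30)
  Z2 <- out_of_fold_predictions(d$x, d$time, d$event, n_folds = 3, seed = 5,
                                n_trees_rsf = 30, n_trees_rf = 30)
  expect_identical(Z1, Z2)
  expect_false(anyNA(Z1))
  expect_equal(dim(Z1), c(60, 5))
})

test_that("leave-one-out out-of-fold entries match direct per-holdout refits", {
  d <- ens_fixture(n = 20, seed = 11)
  Z <- out_of_fold_predictions(d$x, d$time, d$event, n_folds = 20, seed = 6,
                               n_trees_rsf = 25, n_trees_rf = 25)
  folds <- proxsurv:::make_folds(20, 20, 6, d$event)
  i <- which(folds == folds[1])   # singleton fold containing patient 1
  tr <- folds != folds[1]
  m <- fit_base_models(d$x[tr, , drop = FALSE], d$time[tr], d$event[tr],
                       horizon = 60,
                       seed = (6L + 101L * folds[1]) %% .Machine$integer.max,
                       n_trees_rsf = 25, n_trees_rf = 25)
  direct <- predict_base_models(m, d$x[i, , drop = FALSE])
  expect_equal(unname(Z[i, ]), unname(as.numeric(direct)), tolerance = 1e-12)
})

test_that("NNLS recovers an exact mixture and normalizes", {
  withr::with_seed(12, {
    Z <- matrix(runif(500), 100, 5,
                dimnames = list(NULL, c("a", "b", "c", "d", "e")))
    y <- 0.3 * Z[, 1] + 0.7 * Z[, 2]
  })
  o <- structure(list(horizon_months = 60, label = y,
                      weight = rep(1, 100)), class = "horizon_outcome")
  w <- nnls_stack(Z, o)
  expect_equal(unname(w), c(0.3, 0.7, 0, 0, 0), tolerance = 1e-6)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1)
})

test_that("NNLS puts full weight on an exact predictor column", {
  withr::with_seed(13, {
    y <- rbinom(60, 1, 0.5)
    Z <- cbind(exact = y, matrix(runif(240), 60, 4))
  })
  o <- structure(list(horizon_months = 60, label = y, weight = rep(1, 60)),
                 class = "horizon_outcome")
  w <- nnls_stack(Z, o)
  expect_equal(unname(w[1]), 1, tolerance = 1e-8)
})

test_that("zero-weight rows never influence the NNLS solution", {
  withr::with_seed(14, {
    Z <- matrix(runif(300), 60, 5)
    y <- 0.5 * Z[, 3] + 0.5 * Z[, 4]
    w <- c(rep(1, 40), rep(0, 20))
    y[w == 0] <- runif(20)          # garbage on the zero-weight rows
  })
  o1 <- structure(list(horizon_months = 60, label = y, weight = w),
                  class = "horizon_outcome")
  o2 <- structure(list(horizon_months = 60, label = y[1:40],
                       weight = w[1:40]), class = "horizon_outcome")
  expect_equal(nnls_stack(Z, o1), nnls_stack(Z[1:40, ], o2))
})

test_that("identical signal columns share the weight mass", {
  withr::with_seed(15, {
    s <- runif(80)
    Z <- cbind(s1 = s, s2 = s, matrix(runif(240), 80, 3))
    y <- s
  })
  o <- structure(list(horizon_months = 60, label = y, weight = rep(1, 80)),
                 class = "horizon_outcome")
  w <- nnls_stack(Z, o)
  expect_equal(unname(w[1] + w[2]), 1, tolerance = 1e-8)
})

test_that("stacked ensemble is convex: agreement passes through, and a
           unit weight vector reproduces its base model", {
  d <- ens_fixture(n = 100, seed = 16)
  ens <- fit_stacked_ensemble(d$x, d$time, d$event, n_folds = 3, seed = 7,
                              n_trees_rsf = 40, n_trees_rf = 40)
  expect_true(all(ens$stack_weights >= 0))
  expect_equal(sum(ens$stack_weights), 1)
  P <- predict_base_models(ens$base_models, d$x)
  r <- ensemble_predict(ens, d$x)
  expect_true(all(r >= apply(P, 1, min) - 1e-12 &
                    r <= apply(P, 1, max) + 1e-12))
  ens2 <- ens
  ens2$stack_weights <- c(cox = 1, rsf = 0, rf = 0, logistic = 0, elnet = 0)
  expect_equal(ensemble_predict(ens2, d$x), unname(P[, "cox"]))
})

test_that("coxnet selects the truly prognostic feature and honors the
           penalty path extremes", {
  hits <- 0
  for (s in 1:5) {
    withr::with_seed(s + 100, {
      n <- 500
      x <- matrix(rnorm(n * 20), n, 20,
                  dimnames = list(NULL, paste0("g", 1:20)))
      lp <- x[, 1]                       # true log-hazard
      t_ev <- rexp(n, 0.01 * exp(lp))
      t_cn <- rexp(n, 0.01)
    })
    sel <- coxnet_select(x, pmin(t_ev, t_cn),
                         as.integer(t_ev <= t_cn), seed = s)
    if ("g1" %in% sel) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("coxnet on correlated noise-heavy blocks selects few features", {
  co <- generate_cohort(cohort_config(n_patients = 300, n_features = 100,
                                      n_informative = 30, seed = 17))
  tm <- co$split == "train"
  sel <- coxnet_select(co$features[tm, ], co$time_months[tm],
                       co$event[tm], seed = 2)
  expect_lt(length(sel), 25)   # sparse relative to 100 inputs
})
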