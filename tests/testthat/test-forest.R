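test_that("a dominant feature wins the root split in most trees", {
  d <- toy_survival(n = 200, hr = 10, seed = 3)
  f <- fit_survival_forest(d$x, d$time, d$event, n_trees = 60,
                           mtry = 3, min_node_size = 15, seed = 1)
  roots <- vapply(seq_len(60), function(t) {
    ti <- ranger::treeInfo(f$ranger, t)
    ti$splitvarName[ti$nodeID == 0]
  }, character(1))
  expect_gte(mean(roots == "signal"), 0.95)
})

test_that("min_node_size = n collapses every tree to a single root node", {
  d <- toy_survival(n = 40, seed = 2)
  f <- fit_survival_forest(d$x, d$time, d$event, n_trees = 10,
                           min_node_size = 40, seed = 1)
  ids <- terminal_node_ids(f, d$x)
  expect_true(all(apply(ids, 2, function(v) length(unique(v)) == 1)))
  vi <- variable_importance_frequency(f)
  expect_true(all(vi$count == 0))
  expect_equal(length(unique(predict_forest_risk(f, d$x))), 1)
})

test_that("forests are bit-identical under the same seed", {
  d <- toy_survival(n = 50, seed = 5)
  f1 <- fit_survival_forest(d$x, d$time, d$event, n_trees = 15, seed = 9)
  f2 <- fit_survival_forest(d$x, d$time, d$event, n_trees = 15, seed = 9)
  expect_identical(terminal_node_ids(f1, d$x), terminal_node_ids(f2, d$x))
  expect_identical(inbag_counts(f1), inbag_counts(f2))
  expect_identical(predict_forest_risk(f1, d$x),
                   predict_forest_risk(f2, d$x))
  f3 <- fit_survival_forest(d$x, d$time, d$event, n_trees = 15, seed = 10)
  expect_false(identical(inbag_counts(f1), inbag_counts(f3)))
})

test_that("split counts match treeInfo and sum to the internal node total", {
  f <- small_forest(n = 40, n_trees = 25)
  vi <- variable_importance_frequency(f)
  ref <- table(factor(unlist(lapply(seq_len(25), function(t) {
    ti <- ranger::treeInfo(f$ranger, t)
    ti$splitvarName[!ti$terminal]
  })), levels = sort(f$feature_names)))
  expect_equal(setNames(vi$count[order(vi$feature)], sort(vi$feature)),
               setNames(as.numeric(ref), names(ref)))
  n_internal <- sum(vapply(seq_len(25), function(t)
    sum(!ranger::treeInfo(f$ranger, t)$terminal), numeric(1)))
  expect_equal(sum(vi$count), n_internal)
})

test_that("importance ranks the informative feature first", {
  d <- toy_survival(n = 200, hr = 10, seed = 3)
  f <- fit_survival_forest(d$x, d$time, d$event, n_trees = 60,
                           mtry = 3, min_node_size = 15, seed = 1)
  vi <- variable_importance_frequency(f)
  expect_equal(vi$feature[1], "signal")
})

test_that("repeat-and-average importance keeps the dominant feature first
           and averages counts over refits", {
  d <- toy_survival(n = 120, hr = 10, seed = 4)
  vi <- importance_repeated(d$x, d$time, d$event, n_trees = 30,
                            mtry = 3, min_node_size = 15, seed = 2,
                            n_repeats = 3)
  expect_equal(vi$feature[1], "signal")
  expect_equal(sort(vi$feature), sort(colnames(d$x)))
  # averaged counts need not be integers
  expect_true(all(vi$count >= 0))
})

test_that("forest risk orders duplicated high- and low-risk profiles", {
  d <- toy_survival(n = 200, hr = 10, seed = 4)
  f <- fit_survival_forest(d$x, d$time, d$event, n_trees = 100,
                           min_node_size = 10, seed = 2)
  lo <- d$x[d$group == 0, , drop = FALSE][1:10, ]
  hi <- d$x[d$group == 1, , drop = FALSE][1:10, ]
  expect_gt(mean(predict_forest_risk(f, hi)),
            mean(predict_forest_risk(f, lo)))
  s_lo <- predict_forest_survival(f, lo, 60)
  s_hi <- predict_forest_survival(f, hi, 60)
  expect_gt(mean(s_lo), mean(s_hi))
})

test_that("splitting is rank-based: monotone transforms preserve tree
           structure and in-bag routing on refit", {
  # Split partitions depend only on value ranks, so refitting on a
  # monotonically transformed feature reproduces every tree. Split *values*
  # are midpoints of in-bag values, and midpoints are not equivariant under
  # nonlinear transforms, so an out-of-bag sample lying strictly between
  # two in-bag values may legitimately switch sides; in-bag routing and the
  # risk ranking are the invariants.
  d <- toy_survival(n = 80, seed = 6)
  f1 <- fit_survival_forest(d$x, d$time, d$event, n_trees = 20, seed = 3)
  x2 <- d$x
  x2[, "signal"] <- exp(x2[, "signal"])   # strictly increasing transform
  f2 <- fit_survival_forest(x2, d$time, d$event, n_trees = 20, seed = 3)
  for (t in 1:20)
    expect_identical(ranger::treeInfo(f1$ranger, t)$splitvarID,
                     ranger::treeInfo(f2$ranger, t)$splitvarID)
  n1 <- terminal_node_ids(f1, d$x)
  n2 <- terminal_node_ids(f2, x2)
  ib <- inbag_counts(f1) > 0
  expect_identical(n1[ib], n2[ib])
  expect_gt(cor(predict_forest_risk(f1, d$x),
                predict_forest_risk(f2, x2), method = "spearman"), 0.99)
})

test_that("bootstrap in-bag fraction is near 1 - exp(-1)", {
  d <- toy_survival(n = 60, seed = 7)
  f <- fit_survival_forest(d$x, d$time, d$event, n_trees = 1000, seed = 4)
  uniq_frac <- mean(colMeans(inbag_counts(f) > 0))
  expect_lt(abs(uniq_frac - (1 - (1 - 1 / 60)^60)), 0.01)
})

test_that("log-rank split statistic matches survdiff's chi-square", {
  withr::with_seed(11, {
    for (i in 1:20) {
      n <- sample(20:60, 1)
      time <- rexp(n, 0.05)
      event <- rbinom(n, 1, 0.7)
      left <- rbinom(n, 1, 0.5) == 1
      if (length(unique(left)) < 2 || sum(event) < 2) next
      ours <- logrank_split_stat(time, event, left)
      ref <- survival::survdiff(survival::Surv(time, event) ~ left)
      expect_equal(ours$chi2, ref$chisq, tolerance = 1e-10)
    }
  })
})

test_that("a forest round-trips through JSON: routing and in-bag counts
           are reproduced exactly", {
  f <- small_forest(n = 30, n_trees = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_forest_json(f, path)
  g <- read_forest_json(path)
  d <- toy_survival(n = 30, seed = 7)   # the forest's training data
  expect_equal(route_terminal_nodes(g, d$x),
               unname(terminal_node_ids(f, d$x)), ignore_attr = TRUE)
  # routing holds for unseen samples too
  new <- toy_survival(n = 15, seed = 99)$x
  expect_equal(route_terminal_nodes(g, new),
               unname(terminal_node_ids(f, new)), ignore_attr = TRUE)
  expect_equal(inbag_counts(g), unname(inbag_counts(f)))
  expect_equal(g$feature_names, f$feature_names)
})

test_that("forest fitting rejects bad inputs", {
  d <- toy_survival(n = 30, seed = 8)
  expect_error(fit_survival_forest(d$x, d$time, d$event, mtry = 99),
               "mtry")
  expect_error(fit_survival_forest(d$x, rep(1, 30), rep(1, 30)),
               "distinct event times")
  f <- small_forest(n = 20, n_trees = 5)
  bad <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(terminal_node_ids(f, bad), "schema")
})
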