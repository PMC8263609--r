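# Brute-force proximity oracle: explicit loop over (tree, pair) tuples.
proximity_bruteforce <- function(forest) {
  ids <- terminal_node_ids(forest, forest$train_features)
  ib <- inbag_counts(forest) > 0
  n <- nrow(ids)
  shared <- both <- matrix(0, n, n)
  for (t in seq_len(ncol(ids)))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (ib[i, t] && ib[j, t]) {
          both[i, j] <- both[i, j] + 1
          if (ids[i, t] == ids[j, t]) shared[i, j] <- shared[i, j] + 1
        }
  v <- ifelse(both > 0, shared / pmax(both, 1), 0)
  diag(v) <- 1
  list(values = v, pair_counts = both)
}

test_that("in-bag proximity matches the brute-force tree-pair enumeration", {
  f <- small_forest(n = 10, n_trees = 20)
  P <- inbag_proximity(f)
  ref <- proximity_bruteforce(f)
  expect_equal(unname(P$values), ref$values)
  expect_equal(unname(P$pair_counts), ref$pair_counts)
  expect_true(isSymmetric(unname(P$values)))
  expect_true(all(diag(P$values) == 1))
  expect_true(all(P$values >= 0 & P$values <= 1))
  expect_true(all(P$pair_counts <= 20))
})

test_that("single-node trees give proximity 1 to every co-in-bag pair", {
  d <- toy_survival(n = 12, seed = 3)
  f <- fit_survival_forest(d$x, d$time, d$event, n_trees = 10,
                           min_node_size = 12, seed = 2)
  P <- inbag_proximity(f)
  off <- P$values[upper.tri(P$values)]
  cnt <- P$pair_counts[upper.tri(P$pair_counts)]
  expect_true(all(off[cnt > 0] == 1))
})

test_that("identical feature rows share every terminal node when co-in-bag", {
  d <- toy_survival(n = 30, seed = 4)
  d$x[2, ] <- d$x[1, ]
  f <- fit_survival_forest(d$x, d$time, d$event, n_trees = 30,
                           min_node_size = 3, seed = 5)
  P <- inbag_proximity(f)
  if (P$pair_counts[1, 2] > 0) expect_equal(P$values[1, 2], 1)
  D <- proximity_to_dissimilarity(P)
  expect_equal(D[1, 2], 0)
})

test_that("dissimilarity is the unit complement of proximity", {
  f <- small_forest(n = 15, n_trees = 10)
  P <- inbag_proximity(f)
  D <- proximity_to_dissimilarity(P)
  expect_true(all(abs((D + P$values)[row(D) != col(D)] - 1) < 1e-12))
  expect_true(all(diag(D) == 0))
  expect_equal(proximity_to_dissimilarity(matrix(1, 3, 3)),
               matrix(0, 3, 3))
})

# Greedy Ward oracle working directly from coordinates: at each step merge
# the pair of clusters minimizing |c1||c2|/(|c1|+|c2|) ||mean1 - mean2||^2.
ward_oracle <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  merges <- list()
  heights <- numeric()
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      ma <- colMeans(X[clusters[[a]], , drop = FALSE])
      mb <- colMeans(X[clusters[[b]], , drop = FALSE])
      na <- length(clusters[[a]]); nb <- length(clusters[[b]])
      delta <- na * nb / (na + nb) * sum((ma - mb)^2)
      if (delta < best_d - 1e-12) { best_d <- delta; best <- c(a, b) }
    }
    merges[[length(merges) + 1]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# Members of each merged cluster along an hclust merge sequence.
hclust_merge_members <- function(hc) {
  members <- list()
  lapply(seq_len(nrow(hc$merge)), function(i) {
    get <- function(v) if (v < 0) -v else members[[v]]
    m <- sort(c(get(hc$merge[i, 1]), get(hc$merge[i, 2])))
    members[[i]] <<- m
    m
  })
}

test_that("Ward on squared Euclidean dissimilarity reproduces the greedy
           coordinate oracle merge-for-merge", {
  for (seed in c(1, 2, 3)) {
    withr::with_seed(seed, {
      n <- sample(6:8, 1)
      X <- matrix(rnorm(n * 2), n, 2)
    })
    D <- as.matrix(dist(X))^2
    hc <- ward_agglomerate(D)
    oracle <- ward_oracle(X)
    expect_equal(hclust_merge_members(hc), oracle$merges)
    # hclust ward.D heights on squared distances are twice the Ward
    # variance increment
    expect_equal(hc$height, 2 * oracle$heights, tolerance = 1e-9)
  }
})

test_that("two singletons merge at their dissimilarity entry", {
  D <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  hc <- ward_agglomerate(D)
  expect_equal(hc$height, 0.4)
})

test_that("Ward merge heights are monotone non-decreasing", {
  f <- small_forest(n = 25, n_trees = 40)
  D <- proximity_to_dissimilarity(inbag_proximity(f))
  hc <- ward_agglomerate(D)
  expect_true(all(diff(hc$height) >= -1e-12))
})

test_that("label permutation yields the same tree up to relabeling", {
  withr::with_seed(9, {
    X <- matrix(rnorm(14), 7, 2)
  })
  D <- as.matrix(dist(X))^2
  perm <- c(3, 1, 7, 2, 5, 6, 4)
  hc1 <- ward_agglomerate(D)
  hc2 <- ward_agglomerate(D[perm, perm])
  m1 <- hclust_merge_members(hc1)
  m2 <- lapply(hclust_merge_members(hc2), function(m) sort(perm[m]))
  expect_equal(sort(hc1$height), sort(hc2$height), tolerance = 1e-12)
  expect_setequal(lapply(m1, paste, collapse = ","),
                  lapply(m2, paste, collapse = ","))
})

test_that("cut_dendrogram labels by decreasing size and validates k", {
  withr::with_seed(2, {
    X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(8, 6), 4, 2))
  })
  hc <- ward_agglomerate(as.matrix(dist(X))^2)
  lab <- cut_dendrogram(hc, 2)
  expect_equal(sum(lab == 1), 10)   # cluster 1 is the larger group
  expect_equal(sum(lab == 2), 4)
  expect_equal(attr(lab, "k"), 2L)
  labn <- cut_dendrogram(hc, 14)
  expect_equal(sort(unique(as.integer(labn))), 1:14)
  expect_error(cut_dendrogram(hc, 1), "k must")
  expect_error(cut_dendrogram(hc, 15), "k must")
})

test_that("ward_agglomerate rejects NA and asymmetric input", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  D_na <- D; D_na[1, 2] <- NA
  expect_error(ward_agglomerate(D_na), "NA")
})
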