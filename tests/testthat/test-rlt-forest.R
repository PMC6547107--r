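test_that("rlt_params validates its fields", {
  expect_error(rlt_params(muting_rate = 1), "muting_rate")
  expect_error(rlt_params(muting_rate = -0.1), "muting_rate")
  expect_error(rlt_params(min_node_size = 1), "min_node_size")
  expect_error(rlt_params(n_trees = 0), "n_trees")
  expect_error(rlt_params(subsample_frac = 0), "subsample_frac")
  expect_error(rlt_params(importance_gate = -1), "importance_gate")
})

test_that("embedded importance: constant response, single candidate, signal ranking", {
  set.seed(51)
  X <- matrix(rnorm(200), 100, 2)
  expect_equal(embedded_importance(X, rep(1, 100)), c(0, 0))
  # single candidate with signal is trivially top-ranked
  y <- X[, 1] + rnorm(100, 0, 0.1)
  imp1 <- embedded_importance(X, y, candidates = 1)
  expect_gt(imp1[1], 0)
  expect_equal(imp1[2], 0)
  # y = 3 x1 + small noise: x1 outranks a pure-noise competitor
  wins <- 0
  for (r in 1:100) {
    set.seed(100 + r)
    Xi <- matrix(rnorm(300), 150, 2)
    yi <- 3 * Xi[, 1] + rnorm(150)
    im <- embedded_importance(Xi, yi)
    wins <- wins + (im[1] > im[2])
  }
  expect_gte(wins, 95)
})

test_that("fit_tree: constant response gives a single leaf", {
  X <- matrix(rnorm(100), 50, 2)
  tr <- fit_tree(X, rep(2.5, 50), rlt_params(seed = 52))
  expect_equal(nrow(tr$nodes), 1)
  expect_equal(tr$nodes[1, "var"], c(var = 0))
  expect_equal(tr$nodes[1, "pred"], c(pred = 2.5))
})

test_that("fit_tree: noise-free step signal splits at the empirical gap", {
  set.seed(53)
  X <- matrix(rnorm(1000), 500, 2)
  y <- as.numeric(X[, 1] > 0)
  tr <- fit_tree(X, y, rlt_params(seed = 53))
  expect_equal(unname(tr$nodes[1, "var"]), 1)
  below <- max(X[X[, 1] <= 0, 1]); above <- min(X[X[, 1] > 0, 1])
  expect_gte(tr$nodes[1, "split"], below)
  expect_lte(tr$nodes[1, "split"], above)
})

test_that("muting_rate = 0 never shrinks candidate sets; muting removes variables", {
  set.seed(54)
  X <- matrix(rnorm(300 * 4), 300, 4)
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(300, 0, 0.2)
  tr0 <- fit_tree(X, y, rlt_params(muting_rate = 0, seed = 54), trace = TRUE)
  for (cs in tr0$candidate_sets) expect_equal(sort(cs), 1:4)
  tr <- fit_tree(X, y, rlt_params(muting_rate = 0.5, seed = 54), trace = TRUE)
  internal <- which(tr$nodes[, "var"] > 0)
  expect_true(any(lengths(tr$muted[internal]) > 0))
  # the split variable is never muted at its own node
  for (i in internal)
    expect_false(tr$nodes[i, "var"] %in% tr$muted[[i]])
})

test_that("single-tree CART configuration equals an independent greedy CART", {
  par <- rlt_params(n_trees = 1, min_node_size = 5, muting_rate = 0,
                    embedded_trees = 1, subsample_frac = 1)
  for (r in 1:10) {
    set.seed(400 + r)
    n <- sample(20:50, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    y <- as.numeric(X[, sample(1:3, 1)] > 0) + rnorm(n, 0, 0.3)
    tr <- fit_tree(X, y, par)
    f <- make_forest(list(tr$nodes), p = 3)
    expect_equal(unname(predict(f, X)),
                 unname(oracle_cart_predict(X, y, X, min_node = 5)),
                 tolerance = 1e-12)
  }
})

test_that("fit_forest is deterministic given a seed", {
  set.seed(55)
  X <- matrix(rnorm(400), 200, 2)
  y <- X[, 1] + rnorm(200, 0, 0.3)
  p <- rlt_params(n_trees = 8, seed = 56)
  f1 <- fit_forest(X, y, p)
  f2 <- fit_forest(X, y, p)
  expect_identical(f1$trees, f2$trees)
})

test_that("forest predictions track a smooth signal (MSE below response variance)", {
  ok <- 0
  for (r in 1:20) {
    set.seed(500 + r)
    X <- matrix(rnorm(500 * 3), 500, 3)
    y <- sqrt(2) * X[, 1] + rnorm(500) # SNR 2
    f <- fit_forest(X, y, rlt_params(n_trees = 20))
    ok <- ok + (mean((predict(f, X) - y)^2) <= var(y))
  }
  expect_gte(ok, 19)
})

test_that("root splits land on the signal variable", {
  set.seed(57)
  X <- matrix(rnorm(500 * 10), 500, 10)
  y <- sqrt(2) * X[, 1] + rnorm(500)
  f <- fit_forest(X, y, rlt_params())
  roots <- vapply(f$trees, function(m) m[1, "var"], numeric(1))
  expect_gte(mean(roots == 1), 0.8)
})

test_that("predict: single-leaf forest, averaging identity, absent-variable invariance", {
  leafy <- make_forest(list(make_node_matrix(node_leaf(0.4, 10)),
                            make_node_matrix(node_leaf(0.8, 10))), p = 2)
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(unname(predict(leafy, X)), rep(0.6, 10))
  # forest mean equals the arithmetic average of per-tree predictions
  t1 <- make_node_matrix(node_split(1, 0, 2, 3, 10),
                         node_leaf(0, 5), node_leaf(1, 5))
  t2 <- make_node_matrix(node_leaf(0.5, 10))
  f <- make_forest(list(t1, t2), p = 2)
  p1 <- predict(make_forest(list(t1), p = 2), X)
  p2 <- predict(make_forest(list(t2), p = 2), X)
  expect_equal(predict(f, X), (p1 + p2) / 2)
  # changing variable 2 (absent from every path) changes nothing
  X2 <- X; X2[, 2] <- X2[, 2] + 100
  expect_equal(predict(f, X2), predict(f, X))
})

test_that("forests serialize to JSON and back", {
  set.seed(58)
  X <- matrix(rnorm(200), 100, 2)
  colnames(X) <- c("a", "A")
  y <- X[, 1] + rnorm(100, 0, 0.2)
  f <- fit_forest(X, y, rlt_params(n_trees = 4, seed = 58), treatment_var = 2)
  path <- tempfile(fileext = ".json")
  forest_to_json(f, path)
  g <- forest_from_json(path)
  expect_equal(g$trees, f$trees, ignore_attr = TRUE)
  expect_equal(g$treatment_var, 2)
  expect_equal(predict(g, X), predict(f, X))
  unlink(path)
})

test_that("input validation: NA and shape mismatches are rejected", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fit_forest(X, c(rep(1, 19), NA)), "complete")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fit_forest(Xna, rnorm(20)), "complete")
  f <- fit_forest(X, rnorm(20), rlt_params(n_trees = 2, seed = 1))
  expect_error(predict(f, X[, 1, drop = FALSE]), "columns")
})
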