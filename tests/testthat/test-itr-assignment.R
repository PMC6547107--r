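test_that("counterfactual rewards: hand-built fixtures route as documented", {
  # single tree with a root split on the treatment column (column 2)
  tA <- make_node_matrix(node_split(2, 0.5, 2, 3, 10),
                         node_leaf(0.4, 5), node_leaf(0.7, 5))
  f <- make_forest(list(tA), p = 2, treatment_var = 2)
  X <- cbind(x = c(-1, 2), A = c(0, 1))
  cf <- counterfactual_rewards(f, X)
  expect_equal(cf$r1, c(0.7, 0.7))
  expect_equal(cf$r0, c(0.4, 0.4))
  expect_true(all(cf$a_on_path))
  # a forest in which no tree splits on A: identical counterfactuals
  tX <- make_node_matrix(node_split(1, 0, 2, 3, 10),
                         node_leaf(0.2, 5), node_leaf(0.9, 5))
  g <- make_forest(list(tX), p = 2, treatment_var = 2)
  cg <- counterfactual_rewards(g, X)
  expect_identical(cg$r1, cg$r0)
  expect_false(any(cg$a_on_path))
  # adding an A-ignoring tree: averaging halves the counterfactual gap
  h <- make_forest(list(tA, tX), p = 2, treatment_var = 2)
  ch <- counterfactual_rewards(h, X)
  expect_equal(ch$r1 - ch$r0, (cf$r1 - cf$r0) / 2)
  expect_equal(ch$r1, (cf$r1 + cg$r1) / 2)
  expect_true(all(ch$a_on_path)) # A on a path in at least one tree
})

test_that("assign_group thresholds and antisymmetry", {
  expect_equal(assign_group(0.6, 0.4), "intervention")
  expect_equal(assign_group(0.4, 0.6), "control")
  expect_equal(assign_group(0.5, 0.5), "muted")
  expect_equal(assign_group(0.52, 0.5, tol = 0.05), "muted")
  expect_error(assign_group(NA, 0.5), "NA")
  set.seed(61)
  r1 <- runif(50); r0 <- runif(50)
  a <- assign_group(r1, r0); b <- assign_group(r0, r1)
  swap <- c(intervention = "control", control = "intervention", muted = "muted")
  expect_equal(unname(swap[a]), b)
})

test_that("plurality vote: strict winner, ties to muted, unanimity", {
  expect_equal(plurality_vote(rep(c("intervention", "control", "muted"),
                                  c(6, 3, 2))), "intervention")
  expect_equal(plurality_vote(rep(c("intervention", "control", "muted"),
                                  c(4, 4, 3))), "muted")
  expect_equal(plurality_vote(rep("intervention", 11)), "intervention")
  expect_error(plurality_vote(rep("muted", 4)), "11")
})

test_that("identical datasets with identical sub-seeds give identical labels", {
  tab <- stratum_cohort(200, effect_lo = 0.4, effect_hi = -0.4, seed = 62)
  st <- stack_of(tab, 3)
  # fixing the seed inside rlt_params makes every per-imputation fit identical
  est <- estimate_itr(st, outcome = "hba1c",
                      params = rlt_params(n_trees = 20, seed = 63))
  expect_true(all(est$labels[, 1] == est$labels[, 2]))
  expect_true(all(est$labels[, 1] == est$labels[, 3]))
  expect_equal(est$assignments$final, unname(est$labels[, 1]))
})

test_that("estimate_itr is deterministic in its master seed", {
  tab <- stratum_cohort(150, effect_lo = 0.4, effect_hi = -0.4, seed = 64)
  st <- stack_of(tab, 3)
  p <- rlt_params(n_trees = 10)
  a <- estimate_itr(st, outcome = "hba1c", params = p, seed = 65)
  b <- estimate_itr(st, outcome = "hba1c", params = p, seed = 65)
  expect_identical(a$assignments, b$assignments)
})

test_that("a null treatment mutes most participants; a strong effect mutes fewer", {
  null_tab <- stratum_cohort(400, effect_lo = 0, effect_hi = 0,
                             lo = -Inf, hi = Inf, seed = 66)
  est_null <- estimate_itr(stack_of(null_tab, 1), outcome = "hba1c", seed = 67)
  frac_null <- mean(est_null$assignments$final == "muted")
  expect_gte(frac_null, 0.5)
  strong <- stratum_cohort(400, effect_lo = 0.4, effect_hi = -0.4, seed = 68)
  est_strong <- estimate_itr(stack_of(strong, 1), outcome = "hba1c", seed = 69)
  expect_gt(frac_null, mean(est_strong$assignments$final == "muted"))
})

test_that("rule_from_itr maps labels to arms with both muted policies", {
  labels <- c("intervention", "control", "muted", "muted")
  A <- c(0, 1, 1, 0)
  expect_equal(as.numeric(rule_from_itr(labels, A)), c(1, 0, 1, 0))
  excl <- rule_from_itr(labels, A, muted = "exclude")
  expect_equal(as.numeric(excl), c(1, 0, NA, NA))
})

test_that("recommend applies a serialized rule to new rows", {
  tA <- make_node_matrix(node_split(2, 0.5, 2, 3, 10),
                         node_leaf(0.4, 5), node_leaf(0.7, 5))
  f <- make_forest(list(tA), p = 2, treatment_var = 2)
  rec <- recommend(f, cbind(x = 0, A = 0))
  expect_equal(rec$group, "intervention")
  expect_equal(rec$r1, 0.7)
})
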