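test_that("summarize_by_group formats the three conventions", {
  tab <- generate_cohort(cohort_spec(n_enrolled = 9, seed = 81, miss_rate = 0,
                                     outcome_miss_rate = 0, cgm_miss_rate = 0))
  tab$selfmgmt <- c(1, 2, 3, rep(10, 6))
  tab$female <- c(1, 1, 1, 0, rep(0, 5))
  tab$hypo70 <- c(5, 5, 5, 0, 1, 2, 6, 50, 50)
  labels <- rep(c("intervention", "muted", "control"), each = 3)
  s <- summarize_by_group(tab, labels)
  row <- s[s$variable == "selfmgmt", ]
  expect_equal(row$intervention, "2 (1)") # mean 2, SD 1
  frow <- s[s$variable == "female" & s$category == "1", ]
  expect_equal(frow$intervention, "3 (100.0%)")
  expect_equal(frow$muted, "0 (0.0%)")
  # skewed: median (IQR) for [0,1,2,6,50] -> 2 (1-6)
  tab2 <- tab[1:5, ]; tab2$hypo70 <- c(0, 1, 2, 6, 50)
  # only the muted group is present, so the empty-group warning is expected
  s2 <- suppressWarnings(summarize_by_group(tab2, rep("muted", 5)))
  expect_match(s2[s2$variable == "hypo70", "muted"], "^2 \\(1-6\\)$")
  # empty group: NA column with a warning
  expect_warning(s3 <- summarize_by_group(tab, rep("muted", 9)), "empty group")
  expect_true(all(is.na(s3$intervention)))
})

test_that("omnibus chi-square reproduces the printed 3x3 table statistic", {
  counts <- matrix(c(24, 95, 11,
                     12, 30, 12,
                     8, 11, 13), nrow = 3, byrow = TRUE)
  values <- rep(rep(c("c1", "c2", "c3"), 3), as.vector(t(counts)))
  labels <- rep(c("intervention", "muted", "control"),
                times = rowSums(counts))
  res <- omnibus_test(values, labels, "categorical")
  expect_equal(res$df, 4)
  expect_equal(round(res$statistic, 2), 24.67)
  expect_lt(res$p_raw, 0.001)
})

test_that("omnibus tests choose the documented procedure per kind", {
  set.seed(82)
  labels <- rep(c("intervention", "control"), each = 30)
  cont <- omnibus_test(rnorm(60), labels, "continuous")
  expect_equal(cont$test, "anova")
  skew <- omnibus_test(rpois(60, 2), labels, "skewed")
  expect_equal(skew$test, "kruskal")
  # expected count < 5 triggers the Fisher fallback
  small <- omnibus_test(rep(c("a", "b"), c(55, 5)), labels, "categorical")
  expect_equal(small$test, "fisher")
  expect_match(small$note, "Fisher")
  # all-identical values: p = 1 convention
  const <- omnibus_test(rep(3.3, 60), labels, "continuous")
  expect_equal(const$p_raw, 1)
  expect_error(omnibus_test(1:5, rep("muted", 5), "continuous"), "2 non-empty")
})

test_that("ANOVA omnibus holds its nominal type-I error under the null", {
  set.seed(83)
  n_rep <- 10000
  labels <- rep(c("intervention", "muted", "control"), each = 10)
  lf <- factor(labels)
  p <- vapply(seq_len(n_rep), function(r) {
    omnibus_test(rnorm(30), lf, "continuous")$p_raw
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.04); expect_lte(rate, 0.06)
})

test_that("chi-square on 2x2 tables equals the squared two-proportion z statistic", {
  set.seed(84)
  for (r in 1:30) {
    n1 <- sample(30:80, 1); n2 <- sample(30:80, 1)
    x1 <- rbinom(1, n1, runif(1, 0.2, 0.8)); x2 <- rbinom(1, n2, runif(1, 0.2, 0.8))
    if (x1 %in% c(0, n1) || x2 %in% c(0, n2)) next
    values <- c(rep(c("y", "n"), c(x1, n1 - x1)), rep(c("y", "n"), c(x2, n2 - x2)))
    labels <- rep(c("intervention", "control"), c(n1, n2))
    res <- omnibus_test(values, labels, "categorical")
    if (res$test != "chisq") next
    p1 <- x1 / n1; p2 <- x2 / n2; pp <- (x1 + x2) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_lt(abs(res$statistic - z^2), 1e-10)
  }
})

test_that("pairwise tests compare each group against intervention", {
  set.seed(85)
  labels <- rep(c("intervention", "muted", "control"), each = 40)
  vals <- rnorm(120)
  pw <- pairwise_tests(vals, labels, "continuous")
  expect_named(pw, c("muted", "control"))
  # identical groups: t statistic near 0
  same <- pairwise_tests(rep(c(1, 2, 3), 40), labels, "continuous")
  expect_lt(abs(same$muted$statistic), 3)
  # power: N(0,1) vs N(1,1) at n=200 per group detected in >= 99/100 repeats
  hits <- 0
  for (r in 1:100) {
    v <- c(rnorm(200), rnorm(200, 1))
    l <- rep(c("intervention", "control"), each = 200)
    hits <- hits + (pairwise_tests(v, l, "continuous")$control$p_raw < 0.05)
  }
  expect_gte(hits, 99)
})

test_that("bh_adjust matches p.adjust conventions on worked examples", {
  r <- bh_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(r$reject))
  one <- bh_adjust(0.03)
  expect_equal(one$adjusted, 0.03)
  flat <- bh_adjust(c(0.5, 0.5, 0.5))
  expect_equal(flat$adjusted, rep(0.5, 3))
  expect_false(any(flat$reject))
  expect_length(bh_adjust(numeric(0))$adjusted, 0)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("bh_adjust agrees with the brute-force step-up oracle", {
  set.seed(86)
  for (r in 1:1000) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(1:3, 1) # mix of sparse and dense signal shapes
    got <- bh_adjust(p)
    want <- oracle_bh(p)
    expect_equal(got$adjusted, want$adjusted, tolerance = 1e-12)
    expect_equal(got$reject, want$reject)
  }
})

test_that("BH rejection is monotone: lowering a raw p never removes rejections", {
  set.seed(87)
  for (r in 1:50) {
    p <- runif(8)
    base <- bh_adjust(p)$reject
    i <- sample(8, 1)
    p2 <- p; p2[i] <- p[i] / 2
    lowered <- bh_adjust(p2)$reject
    expect_true(all(lowered[-i] >= base[-i]))
    expect_gte(lowered[i], base[i])
  }
})

test_that("profile_subgroups assembles tests, adjustment, and pairwise blocks", {
  tab <- generate_cohort(cohort_spec(n_enrolled = 240, seed = 88, miss_rate = 0,
                                     outcome_miss_rate = 0, cgm_miss_rate = 0))
  set.seed(89)
  labels <- sample(c("intervention", "muted", "control"), 240, replace = TRUE)
  prof <- profile_subgroups(tab, labels)
  expect_s3_class(prof, "subgroup_profile")
  expect_true(all(prof$tests$p_adjusted >= prof$tests$p_raw - 1e-12))
  expect_true(all(prof$tests$p_raw >= 0 & prof$tests$p_raw <= 1))
  expect_named(prof$pairwise[["age"]], c("muted", "control"))
  # single-group labelling degrades to descriptives only
  expect_warning(solo <- profile_subgroups(tab, rep("muted", 240)), "empty")
  expect_true(all(solo$tests$test == "none"))
  expect_true(all(is.na(solo$tests$p_raw)))
  expect_false(any(solo$tests$significant))
})
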