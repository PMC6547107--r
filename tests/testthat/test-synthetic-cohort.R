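test_that("covariate and stratum constructors validate their fields", {
  expect_s3_class(cov_continuous(0, 1), "cov_spec")
  expect_error(cov_continuous(0, 1, lower = 2, upper = 1))
  expect_error(cov_binary(1.5), "p")
  expect_error(cov_categorical(c("a", "b"), c(0.6, 0.6)), "probs")
  expect_error(cov_count(-1, 1))
  expect_error(effect_stratum("s", "x", 1, 0))
})

test_that("effect strata must tile the real line on a single known variable", {
  covs <- list(x1 = cov_continuous(0, 1))
  ok <- list(effect_stratum("a", "x1", -Inf, 0), effect_stratum("b", "x1", 0, Inf))
  expect_s3_class(cohort_spec(covariates = covs, effect_spec = ok), "cohort_spec")
  gap <- list(effect_stratum("a", "x1", -Inf, 0), effect_stratum("b", "x1", 1, Inf))
  expect_error(cohort_spec(covariates = covs, effect_spec = gap), "tile")
  expect_error(cohort_spec(covariates = covs, effect_spec = list(
    effect_stratum("a", "zz", -Inf, Inf))), "unknown keying variable")
  expect_error(cohort_spec(covariates = covs, effect_spec = list(
    effect_stratum("a", "x1", -Inf, 0),
    effect_stratum("b", "hba1c_0", 0, Inf))), "same variable")
})

test_that("degenerate generator (no noise, no effects, no drift) reproduces baseline", {
  spec <- cohort_spec(
    n_enrolled = 60,
    effect_spec = list(effect_stratum("null", "hba1c_0", -Inf, Inf)),
    drift = c(hba1c = 0, qol = 0, bmiz = 0),
    noise_sd = c(hba1c = 0, qol = 0, bmiz = 0),
    miss_rate = 0, outcome_miss_rate = 0, cgm_miss_rate = 0, seed = 3)
  tab <- generate_cohort(spec)
  expect_equal(tab$hba1c_18, tab$hba1c_0)
  expect_equal(tab$qol_18, tab$qol_0)
  expect_equal(tab$bmiz_18, tab$bmiz_0)
})

test_that("same spec and seed give identical tables", {
  spec <- cohort_spec(n_enrolled = 120, seed = 9)
  t1 <- generate_cohort(spec)
  t2 <- generate_cohort(spec)
  expect_identical(t1, t2)
  t3 <- generate_cohort(cohort_spec(n_enrolled = 120, seed = 10))
  expect_false(identical(t1$hba1c_0, t3$hba1c_0))
})

test_that("the truth column records the effect stratum of every participant", {
  tab <- stratum_cohort(400, effect_lo = 0.3, effect_hi = -0.3, seed = 21)
  expect_true(all(tab$truth[tab$x1 <= -0.5] == "lo"))
  expect_true(all(tab$truth[tab$x1 > -0.5 & tab$x1 <= 0.5] == "mid"))
  expect_true(all(tab$truth[tab$x1 > 0.5] == "hi"))
})

test_that("potential outcomes are consistent with the observed arm", {
  tab <- stratum_cohort(300, effect_lo = 0.5, effect_hi = -0.5, seed = 4)
  pot <- attr(tab, "potential")
  obs <- ifelse(tab$A == 1, pot$hba1c_18_a1, pot$hba1c_18_a0)
  expect_equal(tab$hba1c_18, obs)
  # the two potential outcomes differ exactly by the stratum effect
  d <- pot$hba1c_18_a1 - pot$hba1c_18_a0
  expect_equal(unname(d[tab$truth == "lo"]),
               rep(0.5, sum(tab$truth == "lo")))
  expect_equal(unname(d[tab$truth == "mid"]),
               rep(0, sum(tab$truth == "mid")))
})

test_that("baseline moments are calibrated to their targets", {
  tab <- generate_cohort(cohort_spec(n_enrolled = 50000, seed = 5,
                                     miss_rate = 0, outcome_miss_rate = 0,
                                     cgm_miss_rate = 0))
  expect_lt(abs(mean(tab$hba1c_0) - 9.6), 0.05)
  expect_lt(abs(sd(tab$hba1c_0) - 1.2), 0.05)
  expect_lt(abs(mean(tab$qol_0) - 81.2), 0.5)
  expect_lt(abs(sd(tab$qol_0) - 12.4), 0.5)
  expect_lt(abs(mean(tab$bmiz_0) - 0.73), 0.05)
  expect_true(all(tab$hba1c_0 >= 8 & tab$hba1c_0 <= 13))
  expect_true(all(tab$qol_0 >= 0 & tab$qol_0 <= 100))
  # hypoglycemia episode counts: median 2, quartiles 1 and 6
  expect_equal(unname(quantile(tab$hypo70, c(0.25, 0.5, 0.75), type = 1)),
               c(1, 2, 6))
})

test_that("eligibility filter drops CGM-incomplete then outcome-missing rows", {
  tab <- generate_cohort(cohort_spec(n_enrolled = 258, seed = 6,
                                     miss_rate = 0, outcome_miss_rate = 0,
                                     cgm_miss_rate = 0))
  # impose the printed flow exactly: 40 CGM-incomplete, then 2 of the
  # remainder missing an 18-month outcome
  tab$cgm_complete <- TRUE
  tab$cgm_complete[1:40] <- FALSE
  tab$hba1c_18[41:42] <- NA
  kept <- apply_eligibility(tab)
  expect_equal(nrow(kept), 216)
  expect_equal(attr(kept, "exclusions"),
               c(cgm_incomplete = 40L, outcome_missing = 2L))
})

test_that("eligibility filter edge cases: identity and full exclusion", {
  tab <- generate_cohort(cohort_spec(n_enrolled = 50, seed = 7, miss_rate = 0,
                                     outcome_miss_rate = 0, cgm_miss_rate = 0))
  kept <- apply_eligibility(tab)
  expect_equal(nrow(kept), 50)
  expect_equal(unname(attr(kept, "exclusions")), c(0L, 0L))
  tab$cgm_complete <- FALSE
  none <- apply_eligibility(tab)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "exclusions"),
               c(cgm_incomplete = 50L, outcome_missing = 0L))
})

test_that("missingness respects rates and never touches CGM covariates", {
  tab <- generate_cohort(cohort_spec(n_enrolled = 4000, seed = 8))
  expect_false(anyNA(tab$hypo70))
  expect_false(anyNA(tab$hypo54))
  miss <- mean(is.na(tab$age))
  expect_gt(miss, 0.02); expect_lt(miss, 0.09)
  expect_lt(abs(mean(!tab$cgm_complete) - 0.155), 0.03)
})

test_that("MAR missingness is keyed to baseline HbA1c", {
  tab <- generate_cohort(cohort_spec(n_enrolled = 6000, miss_rate = 0.15,
                                     miss_mechanism = "MAR", seed = 12))
  hi <- tab$hba1c_0 > median(tab$hba1c_0)
  expect_gt(mean(is.na(tab$age[hi])), mean(is.na(tab$age[!hi])))
})

test_that("cohort CSV round-trips", {
  tab <- generate_cohort(cohort_spec(n_enrolled = 80, seed = 13))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(tab, path)
  back <- read_cohort_csv(path, schema = attr(tab, "schema"))
  expect_equal(as.data.frame(back)$hba1c_0, tab$hba1c_0)
  expect_equal(as.data.frame(back)$race, tab$race)
  expect_equal(is.na(back$age), is.na(tab$age))
  unlink(path)
})
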