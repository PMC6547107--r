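#' End-to-end run configuration
#'
#' Bundles every stage's settings under one master seed: the cohort source
#' (a [cohort_spec()] or a CSV path), reward scaling, imputation settings,
#' forest parameters, value-estimation settings and the outcome list.
#' Stage sub-seeds are derived deterministically from the master seed, and
#' independently per stage, so e.g. changing the number of bootstrap
#' replicates cannot change the ITR assignments.
#'
#' @param cohort A [cohort_spec()], a `participant_table`, or a CSV path.
#' @param outcomes Outcomes to fit rules for (subset of
#'   `c("composite", "hba1c", "qol", "bmiz")`).
#' @param reward_cfg A [reward_config()].
#' @param m,n_cycles Imputation settings (see [generate_imputations()]).
#' @param rlt An [rlt_params()].
#' @param p Randomization probability used by the value estimator.
#' @param B Bootstrap replicates for the value comparisons.
#' @param tol Equivalence tolerance for [assign_group()].
#' @param seed Master seed.
#' @param out_dir Output directory for stage CSVs (`NULL`: return only).
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       outcomes = c("composite", "hba1c", "qol", "bmiz"),
                       reward_cfg = reward_config(),
                       m = 11, n_cycles = 10,
                       rlt = rlt_params(),
                       p = 0.5, B = 1000, tol = 0,
                       seed = 1, out_dir = NULL) {
  if (!length(outcomes)) stop("outcome list must be non-empty")
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  structure(list(cohort = cohort, outcomes = outcomes, reward_cfg = reward_cfg,
                 m = m, n_cycles = n_cycles, rlt = rlt, p = p, B = B,
                 tol = tol, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys: `n_enrolled`, `seed`, `outcomes`, `m`, `n_cycles`, `p`, `B`,
#' `tol`, `out_dir`, and nested `rlt:` / `rewards:` blocks whose entries are
#' passed to [rlt_params()] / [reward_config()].
#'
#' @param path YAML file path.
#' @param cohort_csv Optional participant CSV overriding the simulated cohort.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, cohort_csv = NULL) {
  y <- yaml::read_yaml(path)
  spec_args <- list()
  # NB: the key must be `n_enrolled`, not bare `n` — YAML 1.1 parses `n` as
  # the boolean FALSE
  if (!is.null(y$n_enrolled)) spec_args$n_enrolled <- y$n_enrolled
  if (!is.null(y$seed)) spec_args$seed <- y$seed
  cohort <- if (!is.null(cohort_csv)) cohort_csv else
    do.call(cohort_spec, spec_args)
  args <- list(cohort = cohort)
  for (k in c("outcomes", "m", "n_cycles", "p", "B", "tol", "seed", "out_dir"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$rlt)) args$rlt <- do.call(rlt_params, y$rlt)
  if (!is.null(y$rewards)) args$reward_cfg <- do.call(reward_config, y$rewards)
  do.call(run_config, args)
}

#' Run the full post hoc precision-medicine analysis
#'
#' Executes, in order: cohort acquisition (simulate or load), eligibility
#' filtering, reward construction, multiple imputation (once per cohort),
#' then per requested outcome an individualized-treatment-rule fit, a value
#' comparison against the fixed regimes, and a baseline subgroup profile.
#' Fully reproducible from `(config, seed)`; a participant-flow manifest
#' with telescoping row counts, sub-seeds and logged fallbacks is returned
#' (and written, with all stage tables, when `out_dir` is set).
#'
#' @param config A [run_config()].
#' @return A list of class `run_result`: `manifest`, `cohort` (the eligible
#'   table with rewards), `imputations`, and per-outcome `itr`, `values`,
#'   `profile`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  cohort <- config$cohort
  if (inherits(cohort, "cohort_spec")) {
    cohort$seed <- seed
    tab0 <- generate_cohort(cohort)
  } else if (is.character(cohort)) {
    tab0 <- read_cohort_csv(cohort)
  } else tab0 <- cohort

  tab <- apply_eligibility(tab0)
  ex <- attr(tab, "exclusions")
  tab <- add_rewards(tab, config$reward_cfg)

  stack <- generate_imputations(tab, m = config$m, n_cycles = config$n_cycles,
                                seed = seed + 1000L)

  itr <- list(); values <- list(); profiles <- list()
  sub_seeds <- list(imputation = seed + 1000L)
  for (oi in seq_along(config$outcomes)) {
    oc <- config$outcomes[oi]
    itr_seed <- seed + 2000L + 100L * oi
    boot_seed <- seed + 30000L + oi
    sub_seeds[[paste0("itr_", oc)]] <- itr_seed
    sub_seeds[[paste0("bootstrap_", oc)]] <- boot_seed
    est <- estimate_itr(stack, outcome = oc, reward_cfg = config$reward_cfg,
                        params = config$rlt, tol = config$tol, seed = itr_seed)
    rcol <- c(composite = "r_C", hba1c = "r_H", qol = "r_Q", bmiz = "r_B")[[oc]]
    rule <- rule_from_itr(est, tab$A)
    vc <- value_comparison(tab$A, tab[[rcol]], rule, p = config$p,
                           B = config$B, seed = boot_seed)
    prof <- profile_subgroups(tab, est$assignments$final)
    itr[[oc]] <- est; values[[oc]] <- vc; profiles[[oc]] <- prof
  }

  manifest <- list(
    seed = seed,
    counts = list(enrolled = nrow(tab0),
                  excluded_cgm_incomplete = unname(ex["cgm_incomplete"]),
                  excluded_outcome_missing = unname(ex["outcome_missing"]),
                  analyzed = nrow(tab)),
    outcomes = config$outcomes,
    sub_seeds = sub_seeds,
    imputation = list(m = config$m, n_cycles = config$n_cycles,
                      missing_cells = sum(is.na(as.data.frame(tab)[names(attr(tab, "schema"))])),
                      model_fallbacks = stack$fallbacks),
    value = list(p = config$p, B = config$B,
                 bootstrap_redraws = vapply(values, `[[`, integer(1), "redraws")),
    reconstruction_flags = c(
      "composite acceptability thresholds (HbA1c 9.0, QoL 70) are configurable reconstructions",
      "value estimator is the normalized (ratio) IPW form",
      "bootstrap resamples participants with the rule held fixed",
      "covariates standardized within each imputed dataset"),
    package_version = as.character(utils::packageVersion("itrforest")))

  res <- structure(list(manifest = manifest, cohort = tab,
                        imputations = stack, itr = itr, values = values,
                        profiles = profiles, config = config),
                   class = "run_result")
  if (!is.null(config$out_dir)) write_run_result(res, config$out_dir)
  res
}

write_run_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_csv(res$cohort, file.path(out_dir, "cohort_analyzed.csv"))
  for (oc in names(res$itr)) {
    a <- res$itr[[oc]]$assignments
    write.csv(cbind(a, res$itr[[oc]]$labels), row.names = FALSE,
              file.path(out_dir, sprintf("assignments_%s.csv", oc)))
    vc <- res$values[[oc]]
    vtab <- data.frame(quantity = c("v_opt", "v_trt", "v_ctrl",
                                    vc$comparisons$comparison),
                       estimate = c(vc$v_opt$v_hat, vc$v_trt$v_hat,
                                    vc$v_ctrl$v_hat, vc$comparisons$diff),
                       lo = c(NA, NA, NA, vc$comparisons$lo),
                       hi = c(NA, NA, NA, vc$comparisons$hi))
    write.csv(vtab, file.path(out_dir, sprintf("values_%s.csv", oc)),
              row.names = FALSE)
    write.csv(res$profiles[[oc]]$tests, row.names = FALSE,
              file.path(out_dir, sprintf("profile_tests_%s.csv", oc)))
    write.csv(res$profiles[[oc]]$summary, row.names = FALSE,
              file.path(out_dir, sprintf("profile_summary_%s.csv", oc)))
  }
  yaml::write_yaml(res$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.run_result <- function(x, ...) {
  m <- x$manifest$counts
  cat(sprintf("run_result: %d enrolled -> %d CGM-incomplete excluded -> %d outcome-missing excluded -> %d analyzed\n",
              m$enrolled, m$excluded_cgm_incomplete,
              m$excluded_outcome_missing, m$analyzed))
  for (oc in names(x$itr)) {
    tab <- table(factor(x$itr[[oc]]$assignments$final,
                        levels = c("intervention", "muted", "control")))
    cat(sprintf("  %s: %d intervention / %d muted / %d control; v_opt = %.4f\n",
                oc, tab[1], tab[2], tab[3], x$values[[oc]]$v_opt$v_hat))
  }
  invisible(x)
}

#' Recommend an arm for new participants from a stored rule
#'
#' Applies a serialized forest ([forest_from_json()]) to new standardized
#' covariate rows and returns the three-group recommendation.
#'
#' @param forest An `rlt_forest` with a `treatment_var`.
#' @param newdata Numeric matrix with the forest's training schema (the
#'   treatment column's value is ignored).
#' @param tol Equivalence tolerance.
#' @return A data.frame with `r1`, `r0` and `group`.
#' @export
recommend <- function(forest, newdata, tol = 0) {
  cf <- counterfactual_rewards(forest, newdata)
  cf$group <- assign_group(cf$r1, cf$r0, tol)
  cf
}
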