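#' Profiling schema for baseline variables
#'
#' Maps each baseline variable to the descriptive/testing convention used
#' for it: `"continuous"` (mean/SD, ANOVA, Welch t), `"skewed"` (median/IQR,
#' Kruskal-Wallis, rank-sum -- the convention for right-skewed measures such
#' as hypoglycemia episode counts), or `"categorical"` (n/%, chi-square with
#' Fisher fallback). The designation is schema-driven, not auto-detected.
#'
#' @param table A `participant_table` (used for its covariate schema).
#' @param extra Named character vector of additional variables and kinds
#'   (e.g. `c(hba1c_0 = "continuous")`).
#' @return Named character vector variable -> kind.
#' @export
profile_schema <- function(table, extra = c(hba1c_0 = "continuous",
                                            qol_0 = "continuous",
                                            bmiz_0 = "continuous")) {
  schema <- attr(table, "schema")
  kinds <- vapply(schema, function(cv) switch(cv$kind,
    continuous = "continuous", count = "skewed",
    binary = "categorical", categorical = "categorical"), character(1))
  c(kinds, extra)
}

fmt_num <- function(x) trimws(formatC(x, format = "g", digits = 3))

#' Descriptive summary by ITR-assigned subgroup
#'
#' Continuous variables as mean (SD), skewed variables as median (IQR),
#' categorical variables as n (%) per category; group columns ordered
#' intervention, muted, control. An empty group yields a column of `NA` with
#' a warning.
#'
#' @param table A `participant_table`.
#' @param labels Group label per participant
#'   (`intervention`/`muted`/`control`).
#' @param schema Named character vector variable -> kind
#'   ([profile_schema()]).
#' @return A data.frame with columns `variable`, `category` and one
#'   formatted column per group.
#' @export
summarize_by_group <- function(table, labels, schema = profile_schema(table)) {
  stopifnot(length(labels) == nrow(table))
  groups <- c("intervention", "muted", "control")
  labels <- factor(labels, levels = groups)
  present <- table(labels)
  if (any(present == 0))
    warning("empty group(s): ", paste(groups[present == 0], collapse = ", "))
  rows <- list()
  for (v in names(schema)) {
    x <- table[[v]]
    if (schema[[v]] == "categorical") {
      cats <- if (is.factor(x)) levels(x) else sort(unique(x))
      for (ct in cats) {
        cells <- vapply(groups, function(g) {
          xg <- x[labels == g & !is.na(labels)]
          if (!length(xg)) return(NA_character_)
          sprintf("%d (%.1f%%)", sum(xg == ct), 100 * mean(xg == ct))
        }, character(1))
        rows[[length(rows) + 1]] <- c(variable = v, category = as.character(ct), cells)
      }
    } else {
      cells <- vapply(groups, function(g) {
        xg <- x[labels == g & !is.na(labels)]
        if (!length(xg)) return(NA_character_)
        if (schema[[v]] == "skewed") {
          q <- quantile(xg, c(0.25, 0.5, 0.75)) # linear-interpolation quartiles
          sprintf("%s (%s-%s)", fmt_num(q[2]), fmt_num(q[1]), fmt_num(q[3]))
        } else sprintf("%s (%s)", fmt_num(mean(xg)), fmt_num(sd(xg)))
      }, character(1))
      rows[[length(rows) + 1]] <- c(variable = v, category = NA_character_, cells)
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("variable", "category", groups)
  out
}

test_result <- function(variable, test, statistic, df, p_raw, note = NA_character_) {
  structure(list(variable = variable, test = test, statistic = statistic,
                 df = df, p_raw = p_raw, note = note), class = "test_result")
}

#' Omnibus test across subgroups
#'
#' Categorical variables: Pearson chi-square on the group-by-category
#' contingency table without continuity correction, switching to Fisher's
#' exact test when any expected count is below 5. Continuous variables:
#' one-way ANOVA. Skewed variables: Kruskal-Wallis. All-identical values
#' yield the `p = 1` convention.
#'
#' @param values Variable values.
#' @param labels Group label per value.
#' @param kind `"continuous"`, `"skewed"` or `"categorical"`.
#' @param variable Variable name carried into the result.
#' @return A `test_result` with `test`, `statistic`, `df`, `p_raw`.
#' @export
omnibus_test <- function(values, labels, kind = c("continuous", "skewed",
                                                  "categorical"),
                         variable = NA_character_) {
  kind <- match.arg(kind)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- droplevels(factor(labels[keep]))
  if (nlevels(labels) < 2) stop("omnibus_test needs >= 2 non-empty groups")
  if (kind == "categorical") {
    tab <- table(labels, factor(values))
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd < 5)) {
      ft <- tryCatch(fisher.test(tab),
                     error = function(e) fisher.test(tab, simulate.p.value = TRUE,
                                                     B = 1e4))
      return(test_result(variable, "fisher", NA_real_, NA_real_, ft$p.value,
                         note = "expected count < 5: Fisher exact used"))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    return(test_result(variable, "chisq", unname(ct$statistic),
                       unname(ct$parameter), ct$p.value))
  }
  if (max(values) - min(values) < .Machine$double.eps * 100)
    return(test_result(variable, if (kind == "skewed") "kruskal" else "anova",
                       0, NA_real_, 1))
  if (kind == "skewed") {
    kt <- kruskal.test(values, labels)
    return(test_result(variable, "kruskal", unname(kt$statistic),
                       unname(kt$parameter), kt$p.value))
  }
  fit <- stats::aov(values ~ labels)
  an <- summary(fit)[[1]]
  f <- an[["F value"]][1]
  pv <- an[["Pr(>F)"]][1]
  if (!is.finite(f)) { f <- 0; pv <- 1 } # a group-wise constant response
  test_result(variable, "anova", f, an[["Df"]][1], pv)
}

#' Pairwise comparisons against the intervention subgroup
#'
#' Each non-reference group is compared with the reference (default
#' intervention) group: Welch two-sample t test for continuous variables,
#' Wilcoxon rank-sum for skewed, chi-square (Fisher fallback) for
#' categorical.
#'
#' @inheritParams omnibus_test
#' @param reference_group Reference label (default `"intervention"`).
#' @return List of `test_result`, one per non-reference group, named by group.
#' @export
pairwise_tests <- function(values, labels, kind = c("continuous", "skewed",
                                                    "categorical"),
                           reference_group = "intervention",
                           variable = NA_character_) {
  kind <- match.arg(kind)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels[keep])
  others <- setdiff(unique(labels), reference_group)
  others <- others[order(match(others, c("intervention", "muted", "control")))]
  res <- list()
  for (g in others) {
    sel <- labels %in% c(reference_group, g)
    res[[g]] <- if (kind == "categorical") {
      omnibus_test(values[sel], labels[sel], "categorical", variable)
    } else if (kind == "skewed") {
      wt <- tryCatch(suppressWarnings(
        wilcox.test(values[sel & labels == g],
                    values[sel & labels == reference_group])),
        error = function(e) NULL)
      if (is.null(wt)) test_result(variable, "ranksum", 0, NA_real_, 1)
      else test_result(variable, "ranksum", unname(wt$statistic), NA_real_,
                       min(wt$p.value, 1))
    } else {
      tt <- tryCatch(t.test(values[sel & labels == g],
                            values[sel & labels == reference_group]),
                     error = function(e) NULL) # constant data
      if (is.null(tt)) test_result(variable, "welch_t", 0, NA_real_, 1)
      else test_result(variable, "welch_t", unname(tt$statistic),
                       unname(tt$parameter), tt$p.value)
    }
  }
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of raw p values
#' (via [stats::p.adjust]), with rejection flags at level `alpha`.
#'
#' @param p_values Raw p values in `[0, 1]`.
#' @param alpha FDR level.
#' @return A list with `adjusted` (same order as input) and `reject`.
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(list(adjusted = numeric(0), reject = logical(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Full subgroup profile for one outcome's rule
#'
#' The descriptive summary, omnibus tests with Benjamini-Hochberg adjustment
#' (one family per outcome: all profiled baseline variables), and pairwise
#' tests against the intervention subgroup.
#'
#' @inheritParams summarize_by_group
#' @param alpha Two-tailed significance / FDR level (default 0.05).
#' @return A list of class `subgroup_profile`: `summary`, `tests`
#'   (data.frame with `p_raw`, `p_adjusted`, `significant`), `pairwise`.
#' @export
profile_subgroups <- function(table, labels, schema = profile_schema(table),
                              alpha = 0.05) {
  groups_present <- length(unique(labels[!is.na(labels)]))
  om <- if (groups_present < 2) {
    # a rule can assign every participant to one group (e.g. all muted);
    # the profile then carries descriptives only, with no tests to run
    lapply(names(schema), function(v)
      test_result(v, "none", NA_real_, NA_real_, NA_real_,
                  note = "single group: no between-group test"))
  } else lapply(names(schema), function(v)
    omnibus_test(table[[v]], labels, schema[[v]], variable = v))
  tests <- data.frame(
    variable = names(schema),
    test = vapply(om, `[[`, character(1), "test"),
    statistic = vapply(om, `[[`, numeric(1), "statistic"),
    df = vapply(om, `[[`, numeric(1), "df"),
    p_raw = vapply(om, `[[`, numeric(1), "p_raw"))
  bh <- bh_adjust(tests$p_raw, alpha)
  tests$p_adjusted <- bh$adjusted
  tests$significant <- bh$reject
  pw <- if (groups_present > 1 && "intervention" %in% labels) {
    lapply(stats::setNames(names(schema), names(schema)), function(v)
      pairwise_tests(table[[v]], labels, schema[[v]], variable = v))
  } else list()
  structure(list(summary = summarize_by_group(table, labels, schema),
                 tests = tests, pairwise = pw, alpha = alpha),
            class = "subgroup_profile")
}

#' @export
print.subgroup_profile <- function(x, ...) {
  cat("subgroup profile (omnibus tests, BH-adjusted):\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
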