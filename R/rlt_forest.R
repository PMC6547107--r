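#' Reinforcement-learning-tree forest parameters
#'
#' Hyperparameters of the muting-aware regression forest. At every internal
#' node the candidate split variable is chosen by an *embedded* importance
#' ensemble rather than by raw marginal gain, and after each split the
#' lowest-importance fraction `muting_rate` of the remaining candidate
#' variables is muted -- removed from the candidate set of both children --
#' so that low-signal variables (including, where the data do not support a
#' treatment effect, the treatment indicator itself) have their effect set
#' to zero over whole regions of the covariate space.
#'
#' @param n_trees Number of trees.
#' @param min_node_size Minimum rows per child node; nodes below
#'   `2 * min_node_size` become leaves.
#' @param muting_rate Fraction of the remaining candidates muted at each
#'   internal node (`0 <= muting_rate < 1`).
#' @param embedded_trees Size of the per-node embedded importance ensemble.
#'   With `embedded_trees = 1` the importance is the exact best-single-split
#'   variance reduction per candidate, so together with `muting_rate = 0`,
#'   `subsample_frac = 1` and `n_trees = 1` the fit reduces to a classical
#'   greedy CART regression tree.
#' @param embedded_depth Depth of each embedded greedy tree (default 2: one
#'   level of lookahead, enough for a variable whose effect appears only
#'   after conditioning on another variable to register importance).
#' @param subsample_frac Per-tree row subsampling fraction (without
#'   replacement).
#' @param importance_gate Signal gate on the embedded importance (ignored
#'   when `embedded_trees = 1`): a candidate's permutation importance is kept
#'   only when its one-sided t statistic across the embedded trees exceeds
#'   this threshold; otherwise the candidate scores exactly zero and cannot
#'   be split on. The conservative default (4) makes a pure-noise variable's
#'   chance of ever splitting per node of order 1e-3, so that across an
#'   entire forest a treatment indicator carrying no signal stays off
#'   essentially every routing path -- the mechanism behind the muted group.
#' @param seed Optional integer seed set before fitting.
#' @return A list of class `rlt_params`.
#' @export
rlt_params <- function(n_trees = 100, min_node_size = 10, muting_rate = 0.3,
                       embedded_trees = 20, embedded_depth = 2,
                       subsample_frac = 0.8, importance_gate = 4, seed = NULL) {
  if (!is.numeric(muting_rate) || muting_rate < 0 || muting_rate >= 1)
    stop("muting_rate must satisfy 0 <= muting_rate < 1")
  if (min_node_size < 2) stop("min_node_size must be >= 2")
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (embedded_trees < 1) stop("embedded_trees must be >= 1")
  if (subsample_frac <= 0 || subsample_frac > 1)
    stop("subsample_frac must be in (0, 1]")
  if (!is.numeric(importance_gate) || importance_gate < 0)
    stop("importance_gate must be >= 0")
  structure(list(n_trees = as.integer(n_trees),
                 min_node_size = as.integer(min_node_size),
                 muting_rate = muting_rate,
                 embedded_trees = as.integer(embedded_trees),
                 embedded_depth = as.integer(embedded_depth),
                 subsample_frac = subsample_frac,
                 importance_gate = importance_gate, seed = seed),
            class = "rlt_params")
}

check_xy <- function(X, y) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X)) stop("X must be a complete numeric matrix")
  if (length(y) != nrow(X) || anyNA(y)) stop("y must be complete, one value per row of X")
  X
}

#' Embedded variable importance at a node
#'
#' The split-selection signal of the reinforcement-learning tree: a
#' nonnegative importance score per candidate variable, computed from an
#' ensemble of `embedded_trees` depth-limited greedy trees fit on
#' row-subsamples of the node's data with all candidates offered
#' (out-of-bag permutation importance, averaged over the ensemble, kept
#' only when decisively positive -- see `importance_gate` in
#' [rlt_params()]). A variable never selected by the ensemble, or whose
#' permutation importance is not consistently positive across the ensemble,
#' scores exactly zero. With `embedded_trees = 1` the score is the exact
#' best-single-split variance reduction of each candidate.
#'
#' @param X Numeric matrix of the node's rows.
#' @param y Numeric response (rewards).
#' @param candidates Integer column indices still candidate at this node.
#' @param params An [rlt_params()].
#' @return Numeric vector of length `ncol(X)`; zero outside `candidates`.
#' @export
embedded_importance <- function(X, y, candidates = seq_len(ncol(as.matrix(X))),
                                params = rlt_params()) {
  X <- check_xy(X, y)
  rlt_embedded_importance_cpp(X, as.numeric(y), as.integer(candidates),
                              params$embedded_trees, params$embedded_depth,
                              params$min_node_size, params$importance_gate)
}

#' Fit a single reinforcement-learning tree
#'
#' Recursively: compute embedded importances over the candidate set, split
#' on the top-importance variable at its variance-minimizing cutpoint
#' (importance ties broken by lowest column index; every split leaves both
#' children with at least `min_node_size` rows), then mute the bottom
#' `ceiling(muting_rate * |remaining|)` variables from both children's
#' candidate sets -- never the split variable at its own node; importance
#' ties during muting mute the higher index first. Recursion stops at
#' `2 * min_node_size` rows, constant response, or all-zero importances.
#'
#' @inheritParams embedded_importance
#' @param trace Keep per-node candidate sets and muted variables (for
#'   inspection; adds memory).
#' @return A list of class `rlt_tree`: `nodes` (matrix with columns `var`
#'   -- 1-based split column, 0 for a leaf -- `split`, `left`, `right`,
#'   `pred`, `n`), plus `candidate_sets` and `muted` when traced.
#' @export
fit_tree <- function(X, y, params = rlt_params(), trace = FALSE) {
  X <- check_xy(X, y)
  if (nrow(X) < params$min_node_size) stop("fewer rows than min_node_size")
  if (!is.null(params$seed)) set.seed(params$seed)
  out <- rlt_fit_tree_cpp(X, as.numeric(y), seq_len(nrow(X)),
                          seq_len(ncol(X)), params$min_node_size,
                          params$muting_rate, params$embedded_trees,
                          params$embedded_depth, params$importance_gate,
                          isTRUE(trace))
  structure(c(out, list(params = params)), class = "rlt_tree")
}

#' Fit a reinforcement-learning-tree forest
#'
#' `n_trees` reinforcement-learning trees, each on an independent row
#' subsample (fraction `subsample_frac`, without replacement). The forest
#' prediction is the unweighted mean over trees. When the treatment
#' indicator is one of the columns, give its index as `treatment_var` so
#' counterfactual predictions and treatment-routing queries are available.
#'
#' @inheritParams embedded_importance
#' @param treatment_var Column index of the treatment indicator in `X`
#'   (`NULL` if none).
#' @return A list of class `rlt_forest`: `trees` (list of node matrices),
#'   `oob_error` (per-tree out-of-bag MSE), `params`, `treatment_var`, `p`.
#' @examples
#' set.seed(1)
#' X <- cbind(x1 = rnorm(120), x2 = rnorm(120))
#' y <- as.numeric(X[, 1] > 0) + rnorm(120, 0, 0.1)
#' f <- fit_forest(X, y, rlt_params(n_trees = 10, seed = 7))
#' cor(predict(f, X), y)
#' @export
fit_forest <- function(X, y, params = rlt_params(), treatment_var = NULL) {
  X <- check_xy(X, y)
  if (nrow(X) < params$min_node_size) stop("fewer rows than min_node_size")
  if (!is.null(params$seed)) set.seed(params$seed)
  out <- rlt_fit_forest_cpp(X, as.numeric(y), params$n_trees,
                            params$subsample_frac, params$min_node_size,
                            params$muting_rate, params$embedded_trees,
                            params$embedded_depth, params$importance_gate)
  structure(list(trees = out$trees, oob_error = out$oob_error,
                 params = params, treatment_var = treatment_var,
                 p = ncol(X), feature_names = colnames(X)),
            class = "rlt_forest")
}

#' @export
print.rlt_forest <- function(x, ...) {
  cat(sprintf("rlt_forest: %d trees, %d features%s\n", length(x$trees), x$p,
              if (!is.null(x$treatment_var))
                sprintf(", treatment column %d", x$treatment_var) else ""))
  cat(sprintf("  mean OOB MSE: %.4g\n", mean(x$oob_error, na.rm = TRUE)))
  invisible(x)
}

#' Predict expected reward from a fitted forest
#'
#' Routes each row down every tree (`x[split_var] <= split` goes left) and
#' averages the leaf predictions.
#'
#' @param object An `rlt_forest`.
#' @param newdata Numeric matrix with the training schema (same columns).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rlt_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("newdata has ", ncol(newdata), " columns; forest was trained on ", object$p)
  rlt_predict_cpp(object$trees, newdata)
}

#' Does the treatment variable lie on any routing path?
#'
#' For each row, routes it down every tree under both treatment codes and
#' reports whether any split on the treatment column is encountered. Rows
#' where it never is have *identically equal* counterfactual predictions:
#' the treatment was muted along all their routing paths.
#'
#' @param forest An `rlt_forest` with a `treatment_var`.
#' @param newdata Numeric matrix with the training schema.
#' @return Logical vector.
#' @export
treatment_on_path <- function(forest, newdata) {
  stopifnot(inherits(forest, "rlt_forest"), !is.null(forest$treatment_var))
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != forest$p) stop("newdata does not match the training schema")
  rlt_counterfactual_cpp(forest$trees, newdata, forest$treatment_var)$a_on_path
}

#' Serialize a forest to/from JSON
#'
#' Trees are written as arrays of node records (`var`, `split`, `left`,
#' `right`, `pred`, `n`; `var = 0` marks a leaf) so a stored rule can be
#' reloaded and applied to new participants.
#'
#' @param forest An `rlt_forest`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @param json A JSON string or file path to read.
#' @return `forest_to_json()` returns `path` (or the JSON string);
#'   `forest_from_json()` returns the `rlt_forest`.
#' @export
forest_to_json <- function(forest, path = NULL) {
  stopifnot(inherits(forest, "rlt_forest"))
  obj <- list(
    p = forest$p, treatment_var = forest$treatment_var,
    feature_names = forest$feature_names,
    params = forest$params[setdiff(names(forest$params), "seed")],
    oob_error = forest$oob_error,
    trees = lapply(forest$trees, function(m) as.data.frame(m)))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname forest_to_json
#' @export
forest_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- paste(readLines(json), collapse = "")
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  trees <- lapply(if (is.data.frame(obj$trees)) list(obj$trees) else obj$trees,
                  function(d) as.matrix(d[, c("var", "split", "left", "right",
                                              "pred", "n")]))
  pr <- obj$params
  params <- rlt_params(pr$n_trees, pr$min_node_size, pr$muting_rate,
                       pr$embedded_trees, pr$embedded_depth, pr$subsample_frac,
                       if (!is.null(pr$importance_gate)) pr$importance_gate else 4)
  structure(list(trees = trees, oob_error = obj$oob_error, params = params,
                 treatment_var = obj$treatment_var, p = obj$p,
                 feature_names = obj$feature_names),
            class = "rlt_forest")
}
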