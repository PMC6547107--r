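# Independent reference implementations ("oracles") used only by the tests.
# They are deliberately written in plain R, with no shared code with the
# package internals, so agreement is evidence of correctness rather than of
# shared bugs.

# ---- greedy CART regression tree (variance-reduction splitting) ----
# Conventions mirror the documented package conventions: split when the node
# has at least 2 * min_node rows and some variable admits a cutpoint leaving
# >= min_node rows on each side with positive SSE reduction; best variable by
# gain with ties to the lowest column index; cutpoint at the midpoint of the
# best boundary with ties to the lowest cutpoint; route left when x <= cut.
oracle_cart_predict <- function(X, y, newdata, min_node) {
  best_cut <- function(xj, yy) {
    o <- order(xj)
    xs <- xj[o]; ys <- yy[o]
    m <- length(ys)
    if (xs[1] == xs[m]) return(NULL)
    S <- sum(ys); base <- S^2 / m
    best <- -Inf; cut <- NA_real_
    SL <- 0
    for (i in seq_len(m - 1)) {
      SL <- SL + ys[i]
      if (i < min_node || (m - i) < min_node) next
      if (xs[i] == xs[i + 1]) next
      g <- SL^2 / i + (S - SL)^2 / (m - i) - base
      if (g > best + 1e-12) { best <- g; cut <- (xs[i] + xs[i + 1]) / 2 }
    }
    if (!is.finite(best) || best <= 0) return(NULL)
    list(gain = best, cut = cut)
  }
  grow <- function(idx) {
    node <- list(pred = mean(y[idx]))
    if (length(idx) < 2 * min_node || diff(range(y[idx])) < 1e-12) return(node)
    bg <- -Inf; bj <- NA_integer_; bc <- NA_real_
    for (j in seq_len(ncol(X))) {
      r <- best_cut(X[idx, j], y[idx])
      if (!is.null(r) && r$gain > bg + 1e-12) { bg <- r$gain; bj <- j; bc <- r$cut }
    }
    if (!is.finite(bg)) return(node)
    node$var <- bj; node$cut <- bc
    node$left <- grow(idx[X[idx, bj] <= bc])
    node$right <- grow(idx[X[idx, bj] > bc])
    node
  }
  root <- grow(seq_len(nrow(X)))
  route <- function(node, x) {
    while (!is.null(node$var))
      node <- if (x[node$var] <= node$cut) node$left else node$right
    node$pred
  }
  apply(newdata, 1, route, node = root)
}

# ---- brute-force Benjamini-Hochberg ----
# Rejection set by the textbook step-up scan (largest i with p_(i) <= i*a/m);
# adjusted p by the explicit double minimization, independent of p.adjust.
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  if (!m) return(list(adjusted = numeric(0), reject = logical(0)))
  o <- order(p)
  ps <- p[o]
  passes <- which(ps <= seq_len(m) * alpha / m)
  k <- if (length(passes)) max(passes) else 0
  reject_sorted <- seq_len(m) <= k
  adjusted_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  adjusted <- numeric(m); reject <- logical(m)
  adjusted[o] <- adjusted_sorted
  reject[o] <- reject_sorted
  list(adjusted = adjusted, reject = reject)
}

# ---- hand-built tree fixtures ----
# Node matrix in the package's serialization format: columns var (1-based
# split column, 0 = leaf), split, left, right (1-based node row, 0 = none),
# pred, n.
make_node_matrix <- function(...) {
  rows <- list(...)
  M <- do.call(rbind, rows)
  colnames(M) <- c("var", "split", "left", "right", "pred", "n")
  M
}
node_split <- function(var, split, left, right, n = 0) c(var, split, left, right, NA, n)
node_leaf <- function(pred, n = 0) c(0, NA, 0, 0, pred, n)

make_forest <- function(trees, p, treatment_var = NULL, feature_names = NULL) {
  structure(list(trees = trees, oob_error = rep(NA_real_, length(trees)),
                 params = rlt_params(n_trees = length(trees)),
                 treatment_var = treatment_var, p = p,
                 feature_names = feature_names),
            class = "rlt_forest")
}

# ---- shared synthetic scenarios ----
# Three-stratum cohort keyed to a standard-normal covariate x1: intervention
# effect on 18-month HbA1c of `effect_lo` for x1 <= lo, 0 on (lo, hi],
# `effect_hi` for x1 > hi; no drift, small outcome noise, no missingness.
stratum_cohort <- function(n, effect_lo, effect_hi, lo = -0.5, hi = 0.5,
                           noise = 0.1, seed = 1, n_covariates = 5) {
  covs <- stats::setNames(lapply(seq_len(n_covariates),
                                 function(i) cov_continuous(0, 1)),
                          paste0("x", seq_len(n_covariates)))
  strata <- if (lo == -Inf || hi == Inf) { # degenerate: single global stratum
    list(effect_stratum("mid", "x1", -Inf, Inf, hba1c = 0))
  } else {
    list(effect_stratum("lo", "x1", -Inf, lo, hba1c = effect_lo),
         effect_stratum("mid", "x1", lo, hi),
         effect_stratum("hi", "x1", hi, Inf, hba1c = effect_hi))
  }
  generate_cohort(cohort_spec(
    n_enrolled = n, covariates = covs, effect_spec = strata,
    drift = c(hba1c = 0, qol = 0, bmiz = 0),
    noise_sd = c(hba1c = noise, qol = 10, bmiz = 0.25),
    miss_rate = 0, outcome_miss_rate = 0, cgm_miss_rate = 0,
    potential_outcomes = TRUE, seed = seed))
}

# Wrap a complete table as a stack of m identical datasets.
stack_of <- function(table, m) {
  structure(list(datasets = rep(list(table), m), m = as.integer(m),
                 n_cycles = 0L, seed = NULL,
                 mask = matrix(FALSE, nrow(table),
                               length(attr(table, "schema")),
                               dimnames = list(NULL, names(attr(table, "schema")))),
                 fallbacks = 0L),
            class = "imputed_stack")
}
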