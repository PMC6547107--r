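#' Reward scaling configuration
#'
#' Fixed clinical scaling bounds mapping raw 18-month changes onto the
#' unit-interval rewards the individualized treatment rule maximizes, plus
#' the acceptability thresholds of the hierarchical composite. Fixed bounds
#' (rather than per-sample min-max) keep the reward scale stable across
#' imputations and bootstrap resamples.
#'
#' @param hba1c_delta_bounds `(worst, best)` HbA1c change in percentage
#'   points; a change at or beyond `worst` scores 0, at or beyond `best`
#'   scores 1. Negative change (improvement) is better.
#' @param qol_delta_bounds `(worst, best)` PedsQL change in points; positive
#'   change is better.
#' @param bmiz_threshold BMI z-score at 18 months at or below which weight
#'   status is healthy (1.04, the 85th percentile for age and sex).
#' @param bmiz_penalty_scale z-units of BMIz worsening that map the weight
#'   reward from 1 down to 0.
#' @param hba1c_acceptable 18-month HbA1c at or above which glycemic control
#'   is unacceptable for composite tiering.
#' @param qol_acceptable 18-month QoL below which quality of life is
#'   unacceptable for composite tiering.
#' @return A list of class `reward_config`.
#' @export
reward_config <- function(hba1c_delta_bounds = c(worst = 5, best = -5),
                          qol_delta_bounds = c(worst = -30, best = 30),
                          bmiz_threshold = 1.04,
                          bmiz_penalty_scale = 1.0,
                          hba1c_acceptable = 9.0,
                          qol_acceptable = 70) {
  if (hba1c_delta_bounds[1] <= hba1c_delta_bounds[2])
    stop("hba1c_delta_bounds must be ordered (worst, best) with worst > best (lower change is better)")
  if (qol_delta_bounds[1] >= qol_delta_bounds[2])
    stop("qol_delta_bounds must be ordered (worst, best) with best > worst (higher change is better)")
  if (!is.finite(bmiz_threshold) || !is.finite(hba1c_acceptable) ||
      !is.finite(qol_acceptable))
    stop("thresholds must be finite")
  if (bmiz_penalty_scale <= 0) stop("bmiz_penalty_scale must be > 0")
  structure(list(hba1c_delta_bounds = unname(hba1c_delta_bounds),
                 qol_delta_bounds = unname(qol_delta_bounds),
                 bmiz_threshold = bmiz_threshold,
                 bmiz_penalty_scale = bmiz_penalty_scale,
                 hba1c_acceptable = hba1c_acceptable,
                 qol_acceptable = qol_acceptable),
            class = "reward_config")
}

#' Univariate clinical rewards
#'
#' Scaled 0-1 rewards for the three 18-month outcomes; higher is clinically
#' better for every component. HbA1c: the change `h18 - h0` is clipped to
#' the scaling bounds and mapped linearly so the worst change scores 0 and
#' the best scores 1 (monotone decreasing in `h18`). QoL: symmetric
#' construction, monotone increasing in `q18`. BMIz: 1 if the 18-month
#' z-score is at or below the healthy threshold, 1 if above the threshold
#' but improved from baseline, otherwise a linear penalty
#' `max(0, 1 - (b18 - b0)/penalty_scale)` on the amount of worsening.
#'
#' @param h0,h18 HbA1c percentage at baseline / 18 months.
#' @param q0,q18 PedsQL score (0-100) at baseline / 18 months.
#' @param b0,b18 BMI z-score at baseline / 18 months.
#' @param cfg A [reward_config()].
#' @return Numeric reward(s) in `[0, 1]`.
#' @examples
#' cfg <- reward_config()
#' hba1c_reward(9.6, 9.6, cfg)  # no change -> 0.5 under symmetric bounds
#' bmiz_reward(2.0, 1.0, cfg)   # healthy at 18 mo -> 1
#' @export
hba1c_reward <- function(h0, h18, cfg = reward_config()) {
  if (anyNA(h0) || anyNA(h18) || any(!is.finite(h0)) || any(!is.finite(h18)))
    stop("hba1c_reward: inputs must be finite and non-missing")
  b <- cfg$hba1c_delta_bounds
  d <- pmin(pmax(h18 - h0, b[2]), b[1])
  (b[1] - d) / (b[1] - b[2])
}

#' @rdname hba1c_reward
#' @export
qol_reward <- function(q0, q18, cfg = reward_config()) {
  if (anyNA(q0) || anyNA(q18)) stop("qol_reward: inputs must be non-missing")
  if (any(q0 < 0 | q0 > 100 | q18 < 0 | q18 > 100))
    stop("qol_reward: scores must lie in [0, 100]")
  b <- cfg$qol_delta_bounds
  d <- pmin(pmax(q18 - q0, b[1]), b[2])
  (d - b[1]) / (b[2] - b[1])
}

#' @rdname hba1c_reward
#' @export
bmiz_reward <- function(b0, b18, cfg = reward_config()) {
  if (anyNA(b0) || anyNA(b18) || any(!is.finite(b0)) || any(!is.finite(b18)))
    stop("bmiz_reward: inputs must be finite and non-missing")
  r <- pmax(0, 1 - (b18 - b0) / cfg$bmiz_penalty_scale)
  r[b18 < b0] <- 1
  r[b18 <= cfg$bmiz_threshold] <- 1
  pmin(r, 1)
}

#' Hierarchical composite reward
#'
#' A 0-3 composite approximating constrained optimization over a hierarchy
#' of the univariate outcomes, glycemic control prioritized highest and
#' weight status lowest. Three tiers on the raw 18-month values: if HbA1c is
#' unacceptable (`h18 >= hba1c_acceptable`) the composite is the HbA1c
#' reward alone (range 0-1), regardless of QoL and BMIz; if HbA1c is
#' acceptable but QoL is unacceptable (`q18 < qol_acceptable`) it is
#' `1 + r_Q` (range 1-2); if both are acceptable it is `2 + r_B` (range
#' 2-3). Every participant in a higher tier therefore scores at least the
#' floor of that tier, above everyone in lower tiers' sub-ranges.
#'
#' @param h18,q18 Raw 18-month HbA1c percentage and QoL score.
#' @param r_H,r_Q,r_B Univariate rewards from [hba1c_reward()],
#'   [qol_reward()], [bmiz_reward()].
#' @param cfg A [reward_config()].
#' @return Numeric composite reward(s) in `[0, 3]`.
#' @export
composite_reward <- function(h18, q18, r_H, r_Q, r_B, cfg = reward_config()) {
  args <- list(h18, q18, r_H, r_Q, r_B)
  if (any(vapply(args, anyNA, logical(1))))
    stop("composite_reward: all tier inputs must be non-missing")
  n <- length(h18)
  out <- numeric(n)
  tier0 <- h18 >= cfg$hba1c_acceptable
  tier1 <- !tier0 & q18 < cfg$qol_acceptable
  tier2 <- !tier0 & !tier1
  out[tier0] <- rep(r_H, length.out = n)[tier0]
  out[tier1] <- 1 + rep(r_Q, length.out = n)[tier1]
  out[tier2] <- 2 + rep(r_B, length.out = n)[tier2]
  out
}

#' Append reward columns to a participant table
#'
#' Computes `r_H`, `r_Q`, `r_B` and the composite `r_C` from the six
#' outcome columns and appends them.
#'
#' @param table A `participant_table` with complete outcome columns.
#' @param cfg A [reward_config()].
#' @return The table with four additional columns.
#' @export
add_rewards <- function(table, cfg = reward_config()) {
  table$r_H <- hba1c_reward(table$hba1c_0, table$hba1c_18, cfg)
  table$r_Q <- qol_reward(table$qol_0, table$qol_18, cfg)
  table$r_B <- bmiz_reward(table$bmiz_0, table$bmiz_18, cfg)
  table$r_C <- composite_reward(table$hba1c_18, table$qol_18,
                                table$r_H, table$r_Q, table$r_B, cfg)
  table
}

#' Standardize continuous covariate columns
#'
#' Centers and scales each column to sample mean 0 and sample SD 1 (n - 1
#' denominator), returning the per-column location and scale so the same
#' transform can be reused on counterfactual queries. A zero-variance column
#' is passed through as all zeros with a warning.
#'
#' @param X Numeric matrix (or data.frame of numeric columns).
#' @param center,scale Optional precomputed location/scale to apply instead
#'   of estimating from `X`.
#' @return A list with `X` (standardized matrix), `center`, `scale`.
#' @export
standardize_covariates <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric")
  if (nrow(X) < 2 && is.null(center)) stop("need at least 2 rows to estimate moments")
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) scale <- apply(X, 2, sd)
  zero <- !is.finite(scale) | scale == 0
  if (any(zero)) {
    warning("zero-variance column(s) passed through as zeros: ",
            paste(colnames(X)[zero], collapse = ", "))
    scale[zero] <- 1
  }
  Z <- sweep(sweep(X, 2, center, `-`), 2, scale, `/`)
  list(X = Z, center = center, scale = scale)
}

#' Build the forest design matrix from a participant table
#'
#' Continuous and count covariates (including the three baseline outcomes,
#' which are legitimate baseline predictors) are standardized to mean 0 /
#' SD 1 within the table; categorical covariates are expanded to 0/1
#' indicator columns (one per category); the treatment indicator `A` is
#' appended unstandardized as the final column, by construction convention.
#'
#' @param table A completed `participant_table` (no missing covariates).
#' @param schema Covariate schema; defaults to the table's `"schema"` attribute.
#' @return A list with `X` (numeric matrix, treatment last), `treatment_var`
#'   (its column index), `center`, `scale`.
#' @export
build_design <- function(table, schema = attr(table, "schema")) {
  if (is.null(schema)) stop("table has no covariate schema")
  cols <- list(); cont <- character(0)
  for (v in names(schema)) {
    cv <- schema[[v]]
    if (anyNA(table[[v]])) stop("build_design: covariate '", v, "' has missing values")
    if (cv$kind == "categorical") {
      f <- factor(table[[v]], levels = cv$categories)
      for (lev in cv$categories[-1])  # first category is the reference
        cols[[paste0(v, ".", lev)]] <- as.numeric(f == lev)
    } else if (cv$kind == "binary") {
      cols[[v]] <- as.numeric(table[[v]])
    } else {
      cols[[v]] <- as.numeric(table[[v]]); cont <- c(cont, v)
    }
  }
  for (v in c("hba1c_0", "qol_0", "bmiz_0")) {
    cols[[v]] <- table[[v]]; cont <- c(cont, v)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  std <- standardize_covariates(X[, cont, drop = FALSE])
  X[, cont] <- std$X
  X <- cbind(X, A = as.numeric(table$A))
  list(X = X, treatment_var = ncol(X), center = std$center, scale = std$scale)
}
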