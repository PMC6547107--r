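#' Covariate distribution descriptors
#'
#' Small constructors describing one baseline covariate of a synthetic
#' cohort. `cov_continuous()` draws from a normal distribution whose parent
#' parameters are, when `lower`/`upper` are finite, numerically calibrated so
#' that the *realized* (truncated or clipped) distribution has the requested
#' mean and SD. `cov_count()` draws from a negative binomial, the
#' conventional choice for right-skewed episode counts such as CGM-derived
#' hypoglycemia counts. `cgm = TRUE` marks a covariate as derived from
#' continuous glucose monitoring: such covariates are never made missing
#' (participants lacking CGM data are excluded wholesale instead).
#'
#' @param mean,sd Target mean and SD of the realized values.
#' @param lower,upper Support bounds (default unbounded).
#' @param clip If `TRUE`, values outside the bounds are clipped to them;
#'   otherwise the distribution is truncated (redrawn mass inside bounds).
#' @param p Success probability of a binary covariate.
#' @param categories,probs Category labels and probabilities.
#' @param mu,size Negative-binomial mean and dispersion (as in [stats::rnbinom()]).
#' @param cgm Is the covariate CGM-derived (exempt from missingness)?
#' @param missable May the covariate be set missing by the generator?
#' @return A list of class `cov_spec` describing the covariate.
#' @seealso [cohort_spec()], [generate_cohort()]
#' @export
cov_continuous <- function(mean, sd, lower = -Inf, upper = Inf, clip = FALSE,
                           cgm = FALSE, missable = !cgm) {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0, lower < upper)
  structure(list(kind = "continuous", mean = mean, sd = sd, lower = lower,
                 upper = upper, clip = clip, cgm = cgm, missable = missable),
            class = "cov_spec")
}

#' @rdname cov_continuous
#' @export
cov_binary <- function(p, cgm = FALSE, missable = !cgm) {
  if (!is.numeric(p) || p < 0 || p > 1) stop("invalid covariate field 'p': must be in [0, 1]")
  structure(list(kind = "binary", p = p, cgm = cgm, missable = missable),
            class = "cov_spec")
}

#' @rdname cov_continuous
#' @export
cov_categorical <- function(categories, probs, cgm = FALSE, missable = !cgm) {
  if (length(categories) != length(probs) || any(probs < 0) ||
      abs(sum(probs) - 1) > 1e-8)
    stop("invalid covariate field 'probs': must be nonnegative and sum to 1, one per category")
  structure(list(kind = "categorical", categories = as.character(categories),
                 probs = probs, cgm = cgm, missable = missable),
            class = "cov_spec")
}

#' @rdname cov_continuous
#' @export
cov_count <- function(mu, size, cgm = FALSE, missable = !cgm) {
  stopifnot(is.finite(mu), mu >= 0, is.finite(size), size > 0)
  structure(list(kind = "count", mu = mu, size = size, cgm = cgm,
                 missable = missable), class = "cov_spec")
}

#' Treatment-effect stratum
#'
#' One stratum of the ground-truth heterogeneous treatment effect: a
#' half-open interval `(lower, upper]` on a single keying variable (a
#' covariate or a baseline outcome column such as `"hba1c_0"`), together
#' with the additive effect of randomization to intervention on each
#' 18-month outcome. The strata of an effect specification must tile the
#' real line exactly.
#'
#' @param name Stratum label stored in the generated table's `truth` column.
#' @param var Name of the keying variable.
#' @param lower,upper Interval bounds; membership is `lower < x <= upper`.
#' @param hba1c,qol,bmiz Additive intervention effects on the 18-month
#'   outcome (HbA1c percentage points, PedsQL points, BMI z-units). Negative
#'   HbA1c/BMIz effects and positive QoL effects are beneficial.
#' @return A list of class `effect_stratum`.
#' @export
effect_stratum <- function(name, var, lower = -Inf, upper = Inf,
                           hba1c = 0, qol = 0, bmiz = 0) {
  stopifnot(is.character(name), is.character(var), lower < upper)
  structure(list(name = name, var = var, lower = lower, upper = upper,
                 effects = c(hba1c = hba1c, qol = qol, bmiz = bmiz)),
            class = "effect_stratum")
}

#' Default baseline covariate schema
#'
#' Demographics, clinical measures, CGM-derived hypoglycemia episode counts
#' and a psychosocial self-management score for an adolescent type 1
#' diabetes cohort. Hypoglycemia counts are negative binomial with defaults
#' chosen so the episode count has median 2 and IQR 1-6 (severe episodes:
#' median 1, IQR 0-2).
#'
#' @return Named list of [cov_continuous()]-family descriptors.
#' @export
default_covariates <- function() {
  list(
    age = cov_continuous(14.9, 1.1, lower = 13, upper = 17),
    female = cov_binary(0.5),
    race = cov_categorical(c("nh_white", "nh_black", "hispanic", "other"),
                           c(0.769, 0.080, 0.080, 0.071)),
    diabetes_duration = cov_continuous(6.3, 3.7, lower = 1),
    selfmgmt = cov_continuous(60, 15, lower = 0, upper = 100),
    hypo70 = cov_count(4.2, 0.8, cgm = TRUE),
    hypo54 = cov_count(1.2, 0.7, cgm = TRUE)
  )
}

#' Default baseline outcome distributions
#'
#' Baseline HbA1c is truncated to the trial eligibility window 8.0-13.0
#' with realized mean 9.6 and SD 1.2; PedsQL quality of life is clipped to
#' its 0-100 range with realized mean 81.2 and SD 12.4; BMI z-score is
#' normal with mean 0.73 and SD 0.91.
#'
#' @return Named list of [cov_continuous()] descriptors for
#'   `hba1c`, `qol`, `bmiz`.
#' @export
default_outcome_params <- function() {
  list(
    hba1c = cov_continuous(9.6, 1.2, lower = 8, upper = 13),
    qol = cov_continuous(81.2, 12.4, lower = 0, upper = 100, clip = TRUE),
    bmiz = cov_continuous(0.73, 0.91)
  )
}

#' Default ground-truth effect strata
#'
#' Three strata keyed to baseline HbA1c: participants with poor glycemic
#' control (> 10.2) benefit from the intervention, a middle stratum
#' (9.0, 10.2] has a true zero effect on every outcome, and well-controlled
#' participants (<= 9.0) experience a mild adverse effect. The marginal
#' (cohort-average) intervention effect is close to zero, mimicking an
#' overall-null trial with heterogeneous response.
#'
#' @return List of [effect_stratum()] objects.
#' @export
default_effect_spec <- function() {
  list(
    effect_stratum("harm", "hba1c_0", -Inf, 9.0, hba1c = 0.25, qol = -2, bmiz = 0.05),
    effect_stratum("null", "hba1c_0", 9.0, 10.2),
    effect_stratum("benefit", "hba1c_0", 10.2, Inf, hba1c = -0.55, qol = 4, bmiz = -0.05)
  )
}

#' Synthetic-cohort specification
#'
#' Full description of a two-arm RCT-like cohort: enrollment size,
#' randomization probability, baseline covariate and outcome distributions,
#' ground-truth treatment-effect strata, arm-independent 18-month drift,
#' residual noise, and missingness rates. Defaults are calibrated to the
#' printed baseline distribution of a 258-participant adolescent type 1
#' diabetes trial (HbA1c mean 9.6, SD 1.2, eligibility 8.0-13.0; QoL mean
#' 81.2, SD 12.4; BMIz mean 0.73, SD 0.91; 1:1 randomization; 15.5% of
#' participants lacking complete baseline CGM data).
#'
#' @param n_enrolled Number of enrolled participants (>= 2).
#' @param randomization_prob Probability of assignment to intervention.
#' @param covariates Named list of covariate descriptors
#'   ([default_covariates()]).
#' @param outcome_params Baseline outcome descriptors
#'   ([default_outcome_params()]).
#' @param effect_spec List of [effect_stratum()] tiling the keying
#'   variable's support ([default_effect_spec()]).
#' @param drift Named numeric: arm-independent mean 18-month change per
#'   outcome (`hba1c`, `qol`, `bmiz`).
#' @param noise_sd Named numeric: residual SD of the 18-month outcome.
#' @param miss_rate Missingness probability per missable covariate cell.
#' @param miss_mechanism `"MCAR"` or `"MAR"` (MAR keys the missingness
#'   probability to observed baseline HbA1c).
#' @param outcome_miss_rate Probability a participant misses the 18-month
#'   outcome visit (all three 18-month outcomes set missing).
#' @param cgm_miss_rate Probability a participant lacks complete baseline
#'   CGM data (flagged, later excluded by [apply_eligibility()]).
#' @param potential_outcomes Keep both potential 18-month outcomes (under
#'   intervention and usual care, sharing the same residual noise) as an
#'   attribute, for ground-truth policy-value computations.
#' @param seed RNG seed (integer or `NULL` to use the current RNG state).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_enrolled = 258,
                        randomization_prob = 0.5,
                        covariates = default_covariates(),
                        outcome_params = default_outcome_params(),
                        effect_spec = default_effect_spec(),
                        drift = c(hba1c = 0.2, qol = -1, bmiz = 0.05),
                        noise_sd = c(hba1c = 1.0, qol = 10, bmiz = 0.25),
                        miss_rate = 0.05,
                        miss_mechanism = c("MCAR", "MAR"),
                        outcome_miss_rate = 0.008,
                        cgm_miss_rate = 0.155,
                        potential_outcomes = FALSE,
                        seed = NULL) {
  miss_mechanism <- match.arg(miss_mechanism)
  if (!is.numeric(n_enrolled) || n_enrolled < 2)
    stop("invalid spec field 'n_enrolled': must be >= 2")
  if (!is.numeric(randomization_prob) || randomization_prob <= 0 ||
      randomization_prob >= 1)
    stop("invalid spec field 'randomization_prob': must be strictly inside (0, 1)")
  for (fld in c("miss_rate", "outcome_miss_rate", "cgm_miss_rate")) {
    v <- get(fld)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("invalid spec field '%s': must be in [0, 1]", fld))
  }
  if (!length(covariates) || is.null(names(covariates)) ||
      any(!nzchar(names(covariates))) ||
      !all(vapply(covariates, inherits, logical(1), "cov_spec")))
    stop("invalid spec field 'covariates': must be a named list of cov_* descriptors")
  need <- c("hba1c", "qol", "bmiz")
  if (!all(need %in% names(outcome_params)))
    stop("invalid spec field 'outcome_params': needs entries hba1c, qol, bmiz")
  drift <- drift[need]; noise_sd <- noise_sd[need]
  if (anyNA(drift)) stop("invalid spec field 'drift': needs hba1c, qol, bmiz")
  if (anyNA(noise_sd) || any(noise_sd < 0))
    stop("invalid spec field 'noise_sd': needs nonnegative hba1c, qol, bmiz")
  validate_effect_spec(effect_spec,
                       c(names(covariates), paste0(need, "_0")))
  structure(list(n_enrolled = as.integer(n_enrolled),
                 randomization_prob = randomization_prob,
                 covariates = covariates, outcome_params = outcome_params,
                 effect_spec = effect_spec, drift = drift,
                 noise_sd = noise_sd, miss_rate = miss_rate,
                 miss_mechanism = miss_mechanism,
                 outcome_miss_rate = outcome_miss_rate,
                 cgm_miss_rate = cgm_miss_rate,
                 potential_outcomes = isTRUE(potential_outcomes),
                 seed = seed),
            class = "cohort_spec")
}

validate_effect_spec <- function(effect_spec, known_vars) {
  if (!length(effect_spec) ||
      !all(vapply(effect_spec, inherits, logical(1), "effect_stratum")))
    stop("invalid spec field 'effect_spec': must be a list of effect_stratum()")
  vars <- unique(vapply(effect_spec, `[[`, character(1), "var"))
  if (length(vars) != 1)
    stop("invalid spec field 'effect_spec': all strata must key the same variable")
  if (!vars %in% known_vars)
    stop(sprintf("invalid spec field 'effect_spec': unknown keying variable '%s'", vars))
  lo <- vapply(effect_spec, `[[`, numeric(1), "lower")
  hi <- vapply(effect_spec, `[[`, numeric(1), "upper")
  o <- order(lo)
  if (lo[o][1] != -Inf || hi[o][length(o)] != Inf ||
      (length(o) > 1 && any(abs(hi[o][-length(o)] - lo[o][-1]) > 0)))
    stop("invalid spec field 'effect_spec': strata intervals must tile (-Inf, Inf] exactly")
  invisible(TRUE)
}

# Parent parameters of a normal whose truncation to [lower, upper] has the
# requested mean/sd (moment match on closed-form truncated moments).
truncnorm_parent <- function(mean, sd, lower, upper) {
  mom <- function(mu, s) {
    al <- (lower - mu) / s; be <- (upper - mu) / s
    Z <- pnorm(be) - pnorm(al)
    m <- mu + s * (dnorm(al) - dnorm(be)) / Z
    v <- s^2 * (1 + (ifelse(is.finite(al), al * dnorm(al), 0) -
                     ifelse(is.finite(be), be * dnorm(be), 0)) / Z -
                ((dnorm(al) - dnorm(be)) / Z)^2)
    c(m, sqrt(pmax(v, 0)))
  }
  obj <- function(p) sum((mom(p[1], exp(p[2])) - c(mean, sd))^2)
  fit <- optim(c(mean, log(sd)), obj, control = list(reltol = 1e-14, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Parent parameters of a normal whose clipping to [lower, upper] has the
# requested mean/sd (closed-form censored-normal moments).
clipnorm_parent <- function(mean, sd, lower, upper) {
  mom <- function(mu, s) {
    al <- (lower - mu) / s; be <- (upper - mu) / s
    P <- pnorm(be) - pnorm(al)
    a_term <- if (is.finite(lower)) lower * pnorm(al) else 0
    b_term <- if (is.finite(upper)) upper * (1 - pnorm(be)) else 0
    m <- a_term + b_term + mu * P + s * (dnorm(al) - dnorm(be))
    m2mid <- mu^2 * P + 2 * mu * s * (dnorm(al) - dnorm(be)) +
      s^2 * (P + ifelse(is.finite(al), al * dnorm(al), 0) -
               ifelse(is.finite(be), be * dnorm(be), 0))
    a2 <- if (is.finite(lower)) lower^2 * pnorm(al) else 0
    b2 <- if (is.finite(upper)) upper^2 * (1 - pnorm(be)) else 0
    m2 <- a2 + b2 + m2mid
    c(m, sqrt(pmax(m2 - m^2, 0)))
  }
  obj <- function(p) sum((mom(p[1], exp(p[2])) - c(mean, sd))^2)
  fit <- optim(c(mean, log(sd)), obj, control = list(reltol = 1e-14, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

draw_continuous <- function(n, cv) {
  bounded <- is.finite(cv$lower) || is.finite(cv$upper)
  if (!bounded) return(rnorm(n, cv$mean, cv$sd))
  if (cv$sd == 0) return(rep(pmin(pmax(cv$mean, cv$lower), cv$upper), n))
  if (isTRUE(cv$clip)) {
    p <- clipnorm_parent(cv$mean, cv$sd, cv$lower, cv$upper)
    pmin(pmax(rnorm(n, p$mu, p$sigma), cv$lower), cv$upper)
  } else {
    p <- truncnorm_parent(cv$mean, cv$sd, cv$lower, cv$upper)
    # inverse-CDF truncated draw
    lo <- pnorm(cv$lower, p$mu, p$sigma); hi <- pnorm(cv$upper, p$mu, p$sigma)
    qnorm(lo + runif(n) * (hi - lo), p$mu, p$sigma)
  }
}

draw_covariate <- function(n, cv) {
  switch(cv$kind,
    continuous = draw_continuous(n, cv),
    binary = rbinom(n, 1, cv$p),
    categorical = factor(sample(cv$categories, n, replace = TRUE, prob = cv$probs),
                         levels = cv$categories),
    count = rnbinom(n, mu = cv$mu, size = cv$size),
    stop("unknown covariate kind: ", cv$kind))
}

#' Generate a synthetic two-arm cohort
#'
#' Draws baseline covariates and outcomes from the spec's distributions,
#' randomizes the arm indicator `A` independently of the covariates, and
#' builds 18-month outcomes as
#' `baseline + drift + A * stratum_effect + noise`. QoL at 18 months is
#' clipped to its 0-100 instrument range. Covariate missingness is applied
#' at `miss_rate` on missable (non-CGM) covariates, MCAR by default or MAR
#' keyed to observed baseline HbA1c. The ground-truth stratum of every
#' participant is stored in the `truth` column.
#'
#' @param spec A [cohort_spec()].
#' @return A `participant_table`: a data.frame with columns `id`, the
#'   covariates, `A`, `hba1c_0`, `hba1c_18`, `qol_0`, `qol_18`, `bmiz_0`,
#'   `bmiz_18`, `cgm_complete`, `truth`, carrying the covariate schema as
#'   attribute `"schema"` (and, if requested, both potential 18-month
#'   outcomes as attribute `"potential"`).
#' @examples
#' tab <- generate_cohort(cohort_spec(n_enrolled = 50, seed = 1))
#' mean(tab$hba1c_0)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec()")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_enrolled
  X <- lapply(spec$covariates, function(cv) draw_covariate(n, cv))
  out0 <- lapply(spec$outcome_params, function(cv) draw_continuous(n, cv))
  A <- rbinom(n, 1, spec$randomization_prob)

  key_var <- spec$effect_spec[[1]]$var
  keyvals <- if (key_var %in% names(X)) as.numeric(X[[key_var]]) else
    out0[[sub("_0$", "", key_var)]]
  truth <- rep(NA_character_, n)
  eff <- matrix(0, n, 3, dimnames = list(NULL, c("hba1c", "qol", "bmiz")))
  for (st in spec$effect_spec) {
    inb <- keyvals > st$lower & keyvals <= st$upper
    truth[inb] <- st$name
    eff[inb, ] <- matrix(st$effects, sum(inb), 3, byrow = TRUE)
  }

  noise <- vapply(c("hba1c", "qol", "bmiz"),
                  function(o) rnorm(n, 0, spec$noise_sd[[o]]), numeric(n))
  pot <- function(a) {
    v <- vapply(c("hba1c", "qol", "bmiz"), function(o)
      out0[[o]] + spec$drift[[o]] + a * eff[, o] + noise[, o], numeric(n))
    v[, "qol"] <- pmin(pmax(v[, "qol"], 0), 100)
    v
  }
  y1 <- pot(1); y0 <- pot(0)
  y <- y1 * A + y0 * (1 - A)

  tab <- data.frame(id = seq_len(n), X, A = A,
                    hba1c_0 = out0$hba1c, hba1c_18 = y[, "hba1c"],
                    qol_0 = out0$qol, qol_18 = y[, "qol"],
                    bmiz_0 = out0$bmiz, bmiz_18 = y[, "bmiz"],
                    cgm_complete = runif(n) >= spec$cgm_miss_rate,
                    truth = truth, stringsAsFactors = FALSE)

  if (spec$outcome_miss_rate > 0) {
    lost <- runif(n) < spec$outcome_miss_rate
    tab[lost, c("hba1c_18", "qol_18", "bmiz_18")] <- NA
  }

  missable <- names(spec$covariates)[vapply(spec$covariates, function(cv)
    isTRUE(cv$missable) && !isTRUE(cv$cgm), logical(1))]
  if (spec$miss_rate > 0 && length(missable)) {
    pr <- if (spec$miss_mechanism == "MCAR") rep(spec$miss_rate, n) else {
      z <- as.numeric(scale(tab$hba1c_0))
      shift <- tryCatch(
        stats::uniroot(function(c0) mean(stats::plogis(c0 + z)) - spec$miss_rate,
                       c(-20, 20))$root,
        error = function(e) stats::qlogis(spec$miss_rate))
      stats::plogis(shift + z)
    }
    for (v in missable) tab[[v]][runif(n) < pr] <- NA
  }

  attr(tab, "schema") <- spec$covariates
  if (spec$potential_outcomes) {
    attr(tab, "potential") <- data.frame(
      hba1c_18_a1 = y1[, "hba1c"], hba1c_18_a0 = y0[, "hba1c"],
      qol_18_a1 = y1[, "qol"], qol_18_a0 = y0[, "qol"],
      bmiz_18_a1 = y1[, "bmiz"], bmiz_18_a0 = y0[, "bmiz"])
  }
  class(tab) <- c("participant_table", "data.frame")
  tab
}

#' Apply the trial's analysis eligibility filter
#'
#' Drops participants without complete baseline CGM data, then participants
#' missing any of the six outcome measurements (HbA1c, QoL, BMIz at
#' baseline or 18 months), preserving row order. The per-step exclusion
#' counts are attached as attribute `"exclusions"`.
#'
#' @param table A `participant_table` with `cgm_complete` and outcome columns.
#' @return The filtered table; `attr(, "exclusions")` is a named integer
#'   vector `c(cgm_incomplete = , outcome_missing = )`.
#' @export
apply_eligibility <- function(table) {
  ocols <- c("hba1c_0", "hba1c_18", "qol_0", "qol_18", "bmiz_0", "bmiz_18")
  stopifnot(all(c("cgm_complete", ocols) %in% names(table)))
  keep1 <- as.logical(table$cgm_complete)
  n_cgm <- sum(!keep1)
  t1 <- table[keep1, , drop = FALSE]
  keep2 <- !Reduce(`|`, lapply(t1[ocols], is.na))
  n_out <- sum(!keep2)
  res <- t1[keep2, , drop = FALSE]
  for (a in c("schema", "potential")) attr(res, a) <- attr(table, a)
  if (!is.null(attr(res, "potential")))
    attr(res, "potential") <- attr(table, "potential")[keep1, , drop = FALSE][keep2, , drop = FALSE]
  class(res) <- class(table)
  attr(res, "exclusions") <- c(cgm_incomplete = n_cgm, outcome_missing = n_out)
  res
}

#' @export
print.participant_table <- function(x, ...) {
  cat(sprintf("participant_table: %d participants, %d baseline covariates\n",
              nrow(x), length(attr(x, "schema"))))
  if (!is.null(attr(x, "exclusions"))) {
    ex <- attr(x, "exclusions")
    cat(sprintf("  exclusions applied: %d CGM-incomplete, %d outcome-missing\n",
                ex[["cgm_incomplete"]], ex[["outcome_missing"]]))
  }
  print(head(as.data.frame(x), 6))
  invisible(x)
}

#' Read/write a participant table as CSV
#'
#' Missing values are written as empty fields. `read_cohort_csv()` restores
#' the covariate schema either from the supplied descriptor list or by
#' inference (character columns become categorical, everything else
#' continuous).
#'
#' @param table A `participant_table`.
#' @param path File path.
#' @param schema Optional named list of covariate descriptors.
#' @return `read_cohort_csv()` returns a `participant_table`.
#' @export
write_cohort_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, schema = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  fixed <- c("id", "A", "hba1c_0", "hba1c_18", "qol_0", "qol_18",
             "bmiz_0", "bmiz_18", "cgm_complete", "truth")
  covs <- setdiff(names(tab), fixed)
  if (is.null(schema)) {
    schema <- lapply(tab[covs], function(col) {
      if (is.character(col)) cov_categorical(sort(unique(col[!is.na(col)])),
        rep(1 / length(unique(col[!is.na(col)])), length(unique(col[!is.na(col)]))))
      else cov_continuous(mean(col, na.rm = TRUE), sd(col, na.rm = TRUE))
    })
  }
  for (v in covs) if (schema[[v]]$kind == "categorical")
    tab[[v]] <- factor(tab[[v]], levels = schema[[v]]$categories)
  if ("cgm_complete" %in% names(tab)) tab$cgm_complete <- as.logical(tab$cgm_complete)
  attr(tab, "schema") <- schema[covs]
  class(tab) <- c("participant_table", "data.frame")
  tab
}
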