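#' Warm-start fill of missing covariate cells
#'
#' Each missing continuous/count cell is filled by a random draw from the
#' column's observed values; each missing categorical cell by a random
#' observed category. This is the standard chained-equations warm start;
#' fills are refined by [mice_sweep()].
#'
#' @param table A `participant_table` (missingness only in non-CGM baseline
#'   covariates).
#' @param seed Optional seed.
#' @return The completed table.
#' @export
initial_fill <- function(table, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (v in names(attr(table, "schema"))) {
    mis <- is.na(table[[v]])
    if (!any(mis)) next
    obs <- table[[v]][!mis]
    if (!length(obs)) stop("column '", v, "' is entirely missing; cannot impute")
    table[[v]][mis] <- sample(obs, sum(mis), replace = TRUE)
  }
  table
}

# numeric design matrix of predictors for imputing column `target`
impute_design <- function(table, target) {
  schema <- attr(table, "schema")
  preds <- setdiff(names(schema), target)
  d <- as.data.frame(table)[, c(preds, "A", "hba1c_0", "hba1c_18", "qol_0",
                                "qol_18", "bmiz_0", "bmiz_18"), drop = FALSE]
  stats::model.matrix(~ ., data = d)[, -1, drop = FALSE]
}

#' One chained-equations sweep
#'
#' Visits the columns with missingness in order of increasing missingness
#' fraction. For each, a conditional model is fit on the originally observed
#' rows with all other covariates, the arm indicator and the outcomes as
#' predictors: continuous and count columns use a linear model followed by a
#' predictive-mean-matching draw from the `k = 5` observed donors with the
#' nearest fitted values (so imputed values always lie in the observed
#' support); categorical and binary columns use a multinomial-probability
#' draw ([nnet::multinom]). Only originally missing cells are replaced. A
#' singular or failed model falls back to a marginal donor draw; the number
#' of fallbacks is returned in attribute `"fallbacks"`.
#'
#' @param table A fully filled `participant_table` (post [initial_fill()]).
#' @param mask Logical matrix (rows x missable columns), `TRUE` where the
#'   cell was originally missing.
#' @param k Number of predictive-mean-matching donors.
#' @return The updated table, with attribute `"fallbacks"`.
#' @export
mice_sweep <- function(table, mask, k = 5) {
  schema <- attr(table, "schema")
  nmis <- colSums(mask)
  visit <- colnames(mask)[order(nmis, seq_along(nmis))]
  visit <- visit[nmis[visit] > 0]
  fallbacks <- 0L
  for (v in visit) {
    mis <- mask[, v]
    obs_y <- table[[v]][!mis]
    kind <- schema[[v]]$kind
    filled <- tryCatch({
      Xd <- impute_design(table, v)
      if (kind %in% c("continuous", "count")) {
        fit <- stats::lm.fit(cbind(1, Xd[!mis, , drop = FALSE]),
                             as.numeric(obs_y))
        beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        yhat <- as.numeric(cbind(1, Xd) %*% beta)
        vapply(which(mis), function(i) {
          d <- abs(yhat[!mis] - yhat[i])
          donors <- order(d)[seq_len(min(k, length(d)))]
          obs_y[sample(donors, 1)]
        }, numeric(1))
      } else {
        yf <- factor(table[[v]][!mis])
        if (nlevels(yf) < 2) rep(obs_y[1], sum(mis)) else {
          fit <- nnet::multinom(yf ~ ., data = data.frame(Xd[!mis, , drop = FALSE]),
                                trace = FALSE)
          pr <- predict(fit, newdata = data.frame(Xd[mis, , drop = FALSE]),
                        type = "probs")
          if (is.null(dim(pr))) pr <- cbind(1 - pr, pr) # two-level case
          lv <- levels(yf)
          draw <- vapply(seq_len(nrow(pr)), function(i)
            sample(lv, 1, prob = pmax(pr[i, ], 0)), character(1))
          if (kind == "binary") as.numeric(draw)
          else factor(draw, levels = schema[[v]]$categories)
        }
      }
    }, error = function(e) NULL)
    if (is.null(filled)) {
      fallbacks <- fallbacks + 1L
      filled <- sample(obs_y, sum(mis), replace = TRUE)
    }
    # keep integer columns integer so observed cells stay byte-identical
    if (is.integer(table[[v]]) && is.numeric(filled))
      filled <- as.integer(round(filled))
    table[[v]][mis] <- filled
  }
  attr(table, "fallbacks") <- fallbacks
  table
}

#' Generate multiply imputed datasets
#'
#' Runs `m` independent chained-equation chains (distinct sub-seeds), each
#' consisting of [initial_fill()] plus `n_cycles` sweeps of [mice_sweep()].
#' `m` must be odd: the downstream per-participant group assignment is a
#' plurality vote over the `m` per-imputation labels, and an odd count was
#' chosen to preclude two-way vote ties. Observed cells are identical to the
#' input in every completed dataset.
#'
#' @param table A `participant_table` with complete outcomes and arm
#'   (apply [apply_eligibility()] first) and missingness only in non-CGM
#'   baseline covariates.
#' @param m Number of completed datasets (odd; default 11).
#' @param n_cycles Chained-equation sweeps per dataset.
#' @param seed Master seed; chain `i` uses `seed + i`.
#' @return A list of class `imputed_stack`: `datasets` (list of completed
#'   tables), `m`, `n_cycles`, `seed`, `fallbacks`.
#' @export
generate_imputations <- function(table, m = 11, n_cycles = 10, seed = NULL) {
  if (m %% 2 == 0)
    stop("m must be odd so the plurality vote cannot tie two ways")
  ocols <- c("A", "hba1c_0", "hba1c_18", "qol_0", "qol_18", "bmiz_0", "bmiz_18")
  if (anyNA(as.data.frame(table)[, ocols]))
    stop("outcomes or arm indicator contain missing values; apply_eligibility() first")
  covs <- names(attr(table, "schema"))
  mask <- vapply(covs, function(v) is.na(table[[v]]), logical(nrow(table)))
  mask <- matrix(mask, nrow = nrow(table), dimnames = list(NULL, covs))
  cgm <- vapply(attr(table, "schema"), function(cv) isTRUE(cv$cgm), logical(1))
  if (any(mask[, cgm, drop = FALSE]))
    stop("CGM-derived covariates must not be missing (exclude such participants)")
  datasets <- vector("list", m)
  fallbacks <- 0L
  for (i in seq_len(m)) {
    if (!is.null(seed)) set.seed(seed + i)
    d <- initial_fill(table)
    if (any(mask)) for (cyc in seq_len(n_cycles)) {
      d <- mice_sweep(d, mask)
      fallbacks <- fallbacks + attr(d, "fallbacks")
    }
    attr(d, "fallbacks") <- NULL
    datasets[[i]] <- d
  }
  structure(list(datasets = datasets, m = as.integer(m),
                 n_cycles = as.integer(n_cycles), seed = seed,
                 mask = mask, fallbacks = fallbacks),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("imputed_stack: %d completed datasets, %d participants, %d missing cells\n",
              x$m, nrow(x$datasets[[1]]), sum(x$mask)))
  invisible(x)
}

#' Complete-case subset
#'
#' The sensitivity-analysis companion to multiple imputation: participants
#' with any missing covariate are dropped.
#'
#' @param table A `participant_table`.
#' @return The subset with no missing covariates.
#' @export
complete_cases_table <- function(table) {
  covs <- names(attr(table, "schema"))
  keep <- !Reduce(`|`, lapply(as.data.frame(table)[covs], is.na))
  res <- table[keep, , drop = FALSE]
  attr(res, "schema") <- attr(table, "schema")
  class(res) <- class(table)
  res
}
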