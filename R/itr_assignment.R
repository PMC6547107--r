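#' Counterfactual reward predictions
#'
#' Predicted expected clinical reward for each participant under both arms:
#' the treatment column is forced to 1 (intervention) and to 0 (usual care)
#' with all other coordinates untouched. When the treatment variable was
#' muted along all of a participant's routing paths, the two predictions are
#' identically equal.
#'
#' @param forest An `rlt_forest` fit with a `treatment_var`.
#' @param newdata Numeric matrix with the training schema.
#' @return A data.frame with columns `r1`, `r0`, `a_on_path`.
#' @export
counterfactual_rewards <- function(forest, newdata) {
  stopifnot(inherits(forest, "rlt_forest"))
  if (is.null(forest$treatment_var))
    stop("forest was fit without a treatment_var")
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != forest$p) stop("newdata does not match the training schema")
  res <- rlt_counterfactual_cpp(forest$trees, newdata, forest$treatment_var)
  data.frame(r1 = res$r1, r0 = res$r0, a_on_path = res$a_on_path)
}

#' Three-group assignment from counterfactual rewards
#'
#' `intervention` when the predicted reward under intervention exceeds the
#' one under usual care by more than `tol`, `control` in the mirror case,
#' `muted` otherwise. With the default `tol = 0`, muted means the two
#' predictions are exactly equal -- which occurs precisely when the
#' treatment variable lies on no routing path. A small positive `tol` is
#' available for finite-precision robustness.
#'
#' @param r1,r0 Predicted rewards under intervention / usual care.
#' @param tol Nonnegative equivalence tolerance.
#' @return Character vector in `c("intervention", "control", "muted")`.
#' @examples
#' assign_group(0.6, 0.4)  # intervention
#' assign_group(0.5, 0.5)  # muted
#' @export
assign_group <- function(r1, r0, tol = 0) {
  if (anyNA(r1) || anyNA(r0)) stop("assign_group: predictions must not be NA")
  stopifnot(tol >= 0)
  ifelse(r1 - r0 > tol, "intervention",
         ifelse(r0 - r1 > tol, "control", "muted"))
}

#' Plurality vote over per-imputation labels
#'
#' The label with the strictly greatest count wins. With three categories a
#' plurality tie is possible even for an odd number of votes (e.g. 4/4/3);
#' ties resolve to `muted`, the conservative choice when the imputations do
#' not agree on a direction of benefit.
#'
#' @param labels Character vector of per-imputation labels.
#' @param m Expected number of labels (default 11).
#' @return A single label.
#' @export
plurality_vote <- function(labels, m = 11) {
  if (length(labels) != m)
    stop("expected ", m, " labels, got ", length(labels))
  counts <- table(factor(labels, levels = c("intervention", "control", "muted")))
  top <- counts[counts == max(counts)]
  if (length(top) > 1) "muted" else names(top)
}

#' Estimate the individualized treatment rule across imputations
#'
#' For each completed dataset in the stack: compute rewards, build the
#' standardized design (treatment indicator last), fit an
#' reinforcement-learning-tree forest of the reward on covariates plus arm,
#' predict both counterfactual rewards per participant, and assign one of
#' the three group labels. The final rule is the per-participant plurality
#' vote over the `m` per-imputation labels. One forest is fit per imputed
#' dataset with the same parameters; sub-seeds derive deterministically from
#' `seed` and the imputation index.
#'
#' @param stack An `imputed_stack` (or a single complete
#'   `participant_table`, treated as a stack of one).
#' @param outcome Which clinical reward the rule maximizes:
#'   `"composite"`, `"hba1c"`, `"qol"`, or `"bmiz"`.
#' @param reward_cfg A [reward_config()].
#' @param params An [rlt_params()].
#' @param tol Equivalence tolerance passed to [assign_group()].
#' @param seed Master seed for the per-imputation forests.
#' @return A list of class `itr_assignment`: `assignments` (data.frame with
#'   `id`, `final`, vote counts and mean counterfactual rewards), `labels`
#'   (n x m matrix), `r1`, `r0` (n x m matrices), `forests` (list), plus the
#'   settings used.
#' @export
estimate_itr <- function(stack, outcome = c("composite", "hba1c", "qol", "bmiz"),
                         reward_cfg = reward_config(), params = rlt_params(),
                         tol = 0, seed = NULL) {
  outcome <- match.arg(outcome)
  if (inherits(stack, "participant_table"))
    stack <- list(datasets = list(stack), m = 1L)
  m <- stack$m
  rcol <- c(composite = "r_C", hba1c = "r_H", qol = "r_Q", bmiz = "r_B")[[outcome]]
  labels <- NULL; R1 <- NULL; R0 <- NULL
  forests <- vector("list", m)
  for (i in seq_len(m)) {
    d <- add_rewards(stack$datasets[[i]], reward_cfg)
    des <- build_design(d)
    if (!is.null(seed)) set.seed(seed + i)
    f <- fit_forest(des$X, d[[rcol]], params, treatment_var = des$treatment_var)
    cf <- counterfactual_rewards(f, des$X)
    labels <- cbind(labels, assign_group(cf$r1, cf$r0, tol))
    R1 <- cbind(R1, cf$r1); R0 <- cbind(R0, cf$r0)
    forests[[i]] <- f
  }
  final <- apply(labels, 1, plurality_vote, m = m)
  votes <- t(apply(labels, 1, function(l)
    table(factor(l, levels = c("intervention", "control", "muted")))))
  assignments <- data.frame(
    id = stack$datasets[[1]]$id, final = final,
    votes_intervention = votes[, "intervention"],
    votes_control = votes[, "control"], votes_muted = votes[, "muted"],
    mean_r1 = rowMeans(R1), mean_r0 = rowMeans(R0))
  structure(list(assignments = assignments, labels = labels, r1 = R1, r0 = R0,
                 forests = forests, outcome = outcome, m = m, tol = tol,
                 params = params, seed = seed),
            class = "itr_assignment")
}

#' @export
print.itr_assignment <- function(x, ...) {
  cat(sprintf("itr_assignment (%s reward, %d imputations):\n", x$outcome, x$m))
  print(table(factor(x$assignments$final,
                     levels = c("intervention", "muted", "control"))))
  invisible(x)
}

#' Turn an ITR assignment into an evaluable rule
#'
#' Maps the three group labels to a recommended arm per participant. Muted
#' participants -- for whom the rule declares the arms equivalent -- follow
#' their observed arm by default (every participant then remains eligible to
#' be rule-concordant in the value estimator); alternatively they can be
#' excluded from value estimation.
#'
#' @param itr An `itr_assignment` (or a character vector of final labels).
#' @param A Observed arm vector (needed for `muted = "observed"`).
#' @param muted Handling of muted participants: follow `"observed"` arm or
#'   `"exclude"` from evaluation (`NA` in the returned rule).
#' @return Numeric vector of recommended arms (0/1, `NA` = excluded), with
#'   attribute `"provenance" = "estimated ITR"`.
#' @export
rule_from_itr <- function(itr, A, muted = c("observed", "exclude")) {
  muted <- match.arg(muted)
  labels <- if (inherits(itr, "itr_assignment")) itr$assignments$final else itr
  d <- ifelse(labels == "intervention", 1,
              ifelse(labels == "control", 0, NA))
  if (muted == "observed") d[is.na(d)] <- A[is.na(d)]
  attr(d, "provenance") <- "estimated ITR"
  d
}
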