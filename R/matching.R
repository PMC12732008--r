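#' Estimate the propensity score for DOAC treatment
#'
#' Maximum-likelihood logistic regression of treatment (DOAC = 1) on the
#' four matching covariates: age, sex, USVT site (two dummies vs the SVT
#' reference) and active cancer. Complete separation is detected from
#' non-convergence or exploding coefficients and triggers a ridge-penalized
#' refit (flagged).
#'
#' @param cohort a `usvt_cohort` containing both arms.
#' @return an object of class `propensity_model`: coefficients, per-record
#'   `scores` (fitted probabilities of DOAC), and a `penalized` flag.
#' @export
estimate_propensity <- function(cohort) {
  if (length(unique(cohort$treatment)) < 2) {
    stop("degenerate cohort: both treatment arms required", call. = FALSE)
  }
  X <- propensity_design(cohort)
  X <- X[, apply(X, 2, function(c) stats::var(c) > 0), drop = FALSE]
  y <- as.numeric(cohort$treatment == "DOAC")
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                         family = stats::binomial()))
  coefs <- fit$coefficients
  penalized <- !fit$converged || any(!is.finite(coefs)) || any(abs(coefs) > 10)
  if (penalized) {
    coefs <- firth_logistic(cbind(1, X), y)
  }
  names(coefs) <- c("(Intercept)", colnames(X))
  eta <- drop(cbind(1, X) %*% coefs)
  scores <- pmin(pmax(inv_logit(eta), 1e-8), 1 - 1e-8)
  structure(list(coefficients = coefs, scores = scores, penalized = penalized,
                 predictors = c("age", "sex", "usvt_site", "active_cancer")),
            class = "propensity_model")
}

propensity_design <- function(cohort) {
  cbind(age = cohort$age,
        sex_male = as.numeric(cohort$sex == "male"),
        site_UEDVT = as.numeric(cohort$usvt_site == "UEDVT"),
        site_CVT = as.numeric(cohort$usvt_site == "CVT"),
        active_cancer = as.numeric(cohort$active_cancer))
}

# Newton-Raphson logistic regression with an L2 penalty per coefficient
# (penalty 0 on the intercept), used for the optional site-dummy ridge.
ridge_logistic <- function(X, y, penalty, max_iter = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- inv_logit(eta)
    w <- pmax(p * (1 - p), 1e-10)
    grad <- drop(crossprod(X, y - p)) - penalty * beta
    H <- crossprod(X * w, X) + diag(penalty, ncol(X))
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Firth bias-reduced logistic regression: the penalized score is
# X'(y - p + h (1/2 - p)) with h the hat diagonals. Keeps estimates finite
# under complete separation (the standard small-sample fallback).
firth_logistic <- function(X, y, max_iter = 200, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- inv_logit(eta)
    w <- pmax(p * (1 - p), 1e-10)
    XW <- X * sqrt(w)
    I <- crossprod(XW)
    Iinv <- solve(I)
    h <- rowSums((XW %*% Iinv) * XW)
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(Iinv %*% U)
    # dampen large Newton steps for stability
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

#' 1:1 greedy caliper matching on the propensity score
#'
#' Greedy nearest-neighbour matching without replacement on the logit score
#' scale: the smaller arm is iterated in random order (fixed seed) and each
#' of its records is paired with the closest unused record of the other arm;
#' pairs farther apart than `caliper` standard deviations of the logit score
#' are rejected.
#'
#' @param scores propensity scores for every record.
#' @param arms treatment arm per record (`"VKA"`/`"DOAC"`).
#' @param caliper caliper width in SDs of the logit score (`Inf` disables).
#' @param seed integer seed for the iteration order.
#' @return an object of class `matched_cohort`: `pairs` (data.frame of
#'   `doac_id`, `vka_id` row indices), `unmatched` ids, and the absolute
#'   caliper used.
#' @export
match_pairs <- function(scores, arms, caliper = 0.2, seed = NULL) {
  stopifnot(length(scores) == length(arms))
  lg <- logit(pmin(pmax(scores, 1e-8), 1 - 1e-8))
  sd_lg <- stats::sd(lg)
  cal_abs <- if (!is.finite(caliper)) Inf else {
    if (!is.finite(sd_lg) || sd_lg == 0) caliper else caliper * sd_lg
  }
  doac_ids <- which(arms == "DOAC")
  vka_ids <- which(arms == "VKA")
  small_is_doac <- length(doac_ids) <= length(vka_ids)
  small <- if (small_is_doac) doac_ids else vka_ids
  large <- if (small_is_doac) vka_ids else doac_ids
  large <- large[order(lg[large])]  # score order, for permutation-invariant ties
  pairs <- list()
  with_seed(seed, {
    # iterate the smaller arm in a seeded random order over its score ranks:
    # deterministic under the seed and invariant to permutations of the
    # input record order (the rank sequence visited is the same); distance
    # ties go to the lowest-score candidate
    small_sorted <- small[order(lg[small])]
    order_small <- small_sorted[sample.int(length(small_sorted))]
    available <- rep(TRUE, length(large))
    for (id in order_small) {
      if (!any(available)) break
      d <- abs(lg[large] - lg[id])
      d[!available] <- Inf
      j <- which.min(d)
      if (d[j] <= cal_abs) {
        available[j] <- FALSE
        pairs[[length(pairs) + 1L]] <-
          if (small_is_doac) c(doac_id = id, vka_id = large[j])
          else c(doac_id = large[j], vka_id = id)
      }
    }
  })
  pairs_df <- if (length(pairs)) as.data.frame(do.call(rbind, pairs)) else
    data.frame(doac_id = integer(0), vka_id = integer(0))
  matched_ids <- c(pairs_df$doac_id, pairs_df$vka_id)
  if (!nrow(pairs_df)) {
    warning("no admissible pairs under the caliper", call. = FALSE)
  }
  structure(list(pairs = pairs_df,
                 unmatched = setdiff(seq_along(scores), matched_ids),
                 caliper_sd = caliper, caliper_abs = cal_abs, seed = seed),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("<matched_cohort> ", nrow(x$pairs), " pairs, ",
      length(x$unmatched), " unmatched (caliper ",
      format(x$caliper_sd), " SD)\n", sep = "")
  invisible(x)
}

#' Extract the matched records as a cohort
#'
#' @param matched a `matched_cohort`.
#' @param cohort the cohort `match_pairs` indices refer to.
#' @return a `usvt_cohort` restricted to the matched records.
#' @export
matched_records <- function(matched, cohort) {
  idx <- c(matched$pairs$doac_id, matched$pairs$vka_id)
  as_cohort(as.data.frame(cohort)[idx, , drop = FALSE], schema_of(cohort),
            label = "matched twin cohort")
}

#' Covariate balance of a matched cohort
#'
#' Per-variable ASMD between the matched DOAC and VKA records over the four
#' matching covariates, with the MASMD (mean +/- SD) and pass flags at the
#' < 0.10 target and <= 0.20 acceptability thresholds.
#'
#' @param matched a `matched_cohort`.
#' @param cohort the cohort the pair indices refer to.
#' @param variables covariates to balance-check.
#' @return a list of class `balance_report` with `table` (per-variable
#'   ASMDs), `masmd`, `masmd_sd` and the flags.
#' @export
balance_report <- function(matched, cohort,
                           variables = c("age", "sex", "usvt_site", "active_cancer")) {
  if (!nrow(matched$pairs)) stop("no pairs to balance-check", call. = FALSE)
  schema <- schema_of(cohort)
  d <- as.data.frame(cohort)[matched$pairs$doac_id, , drop = FALSE]
  v <- as.data.frame(cohort)[matched$pairs$vka_id, , drop = FALSE]
  per_var <- vapply(variables, function(nm) {
    asmd(d[[nm]], v[[nm]], schema[[nm]]$kind,
         levels = if (schema[[nm]]$kind == "categorical")
           schema[[nm]]$levels[schema[[nm]]$levels %in% c(d[[nm]], v[[nm]])])
  }, numeric(1))
  m <- mean(per_var)
  structure(list(
    table = data.frame(variable = variables, asmd = unname(per_var),
                       pass_target = unname(per_var) < 0.10,
                       pass_acceptable = unname(per_var) <= 0.20),
    masmd = m,
    masmd_sd = if (length(per_var) > 1) stats::sd(per_var) else 0,
    pass_target = m < 0.10, pass_acceptable = m <= 0.20
  ), class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report> MASMD ", sprintf("%.3f (±%.3f)", x$masmd, x$masmd_sd),
      if (x$pass_target) " [target met]" else if (x$pass_acceptable) " [acceptable]" else " [FAIL]",
      "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Build the conditioned (matched) twin cohort in one call
#'
#' Convenience wrapper: estimates the propensity model on a twin cohort,
#' performs 1:1 greedy caliper matching and returns the matched cohort with
#' its balance report.
#'
#' @param twins a twin `usvt_cohort` containing both arms.
#' @param caliper caliper in SD units of the logit score.
#' @param seed integer seed.
#' @return list with `cohort` (matched records), `matched`, `propensity`
#'   and `balance`.
#' @export
condition_twins <- function(twins, caliper = 0.2, seed = NULL) {
  ps <- estimate_propensity(twins)
  mt <- match_pairs(ps$scores, twins$treatment, caliper = caliper, seed = seed)
  list(cohort = matched_records(mt, twins), matched = mt, propensity = ps,
       balance = balance_report(mt, twins))
}
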