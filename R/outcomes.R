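outcome_endpoints <- function() c("recanalization_complete", "recurrence", "major_bleed")

# Binary endpoint vector and the rows it is observed on. Complete
# recanalization is coded complete=1 vs not_complete=0 and is observed only
# for records with follow-up imaging.
endpoint_response <- function(cohort, endpoint) {
  if (endpoint == "recanalization_complete") {
    keep <- cohort$recanalization != "missing"
    list(y = as.numeric(cohort$recanalization[keep] == "complete"), rows = which(keep))
  } else {
    y <- cohort[[endpoint]]
    keep <- which(!is.na(y))
    list(y = as.numeric(y[keep]), rows = keep)
  }
}

# Model design matrix (without intercept) for a predictor set. Site enters
# as two dummies vs the SVT reference; ttr_control is the binary
# good-VKA-control stratum indicator (TTR >= threshold, 0 for DOAC rows).
outcome_design <- function(data, predictors, ttr_threshold = 70) {
  cols <- list()
  if ("treatment" %in% predictors) {
    cols$treatmentDOAC <- as.numeric(data$treatment == "DOAC")
  }
  if ("usvt_site" %in% predictors) {
    cols$siteUEDVT <- as.numeric(data$usvt_site == "UEDVT")
    cols$siteCVT <- as.numeric(data$usvt_site == "CVT")
  }
  if ("active_cancer" %in% predictors) {
    cols$active_cancer <- as.numeric(data$active_cancer)
  }
  if ("age" %in% predictors) cols$age <- as.numeric(data$age)
  if ("sex" %in% predictors) cols$sexmale <- as.numeric(data$sex == "male")
  if ("ttr_control" %in% predictors) {
    cols$ttr_control <- if ("ttr_control" %in% names(data)) {
      as.numeric(data$ttr_control)
    } else {
      as.numeric(data$treatment == "VKA" & !is.na(data$ttr) & data$ttr >= ttr_threshold)
    }
  }
  do.call(cbind, cols)
}

#' Fit a per-endpoint logistic outcome model
#'
#' Maximum-likelihood logistic regression of a binary study endpoint on the
#' default predictor set (treatment, USVT site, active cancer; optional age,
#' sex and the binary TTR "good control" stratum). Complete recanalization
#' is fit on records with follow-up imaging only and the fitted distribution
#' is later applied to all records via [predict_risk()]. An optional ridge
#' penalty on the site dummies stabilizes the sparse CVT cell; separation
#' triggers a penalized refit with a flag.
#'
#' @param cohort a `usvt_cohort`.
#' @param endpoint one of `"recanalization_complete"`, `"recurrence"`,
#'   `"major_bleed"`.
#' @param predictors predictor set.
#' @param site_ridge L2 penalty applied to the site dummies (0 = plain ML).
#' @param ttr_threshold TTR percentage defining good VKA control.
#' @return an object of class `outcome_model`.
#' @export
fit_outcome_model <- function(cohort, endpoint = outcome_endpoints(),
                              predictors = c("treatment", "usvt_site", "active_cancer"),
                              site_ridge = 0, ttr_threshold = 70) {
  endpoint <- match.arg(endpoint)
  resp <- endpoint_response(cohort, endpoint)
  y <- resp$y
  if (length(unique(y)) < 2) {
    stop("degenerate fit: endpoint '", endpoint, "' is single-class", call. = FALSE)
  }
  data <- as.data.frame(cohort)[resp$rows, , drop = FALSE]
  X <- outcome_design(data, predictors, ttr_threshold)
  keep_cols <- apply(X, 2, function(c) stats::var(c) > 0)
  dropped <- colnames(X)[!keep_cols]
  X <- X[, keep_cols, drop = FALSE]
  Xi <- cbind("(Intercept)" = 1, X)
  penalty <- rep(0, ncol(Xi))
  penalty[colnames(Xi) %in% c("siteUEDVT", "siteCVT")] <- site_ridge
  method <- if (any(penalty > 0)) "ridge" else "ml"
  coefs <- if (method == "ml") {
    fit <- suppressWarnings(stats::glm.fit(Xi, y, family = stats::binomial()))
    if (fit$converged && all(is.finite(fit$coefficients)) &&
        all(abs(fit$coefficients) < 15)) fit$coefficients else NULL
  } else {
    cf <- ridge_logistic(Xi, y, penalty)
    if (all(is.finite(cf)) && all(abs(cf) < 15)) cf else NULL
  }
  if (is.null(coefs)) {            # separation: Firth bias-reduced fallback
    method <- "firth"
    coefs <- firth_logistic(Xi, y)
  }
  penalized <- method != "ml"
  names(coefs) <- colnames(Xi)
  p_hat <- inv_logit(drop(Xi %*% coefs))
  w <- pmax(p_hat * (1 - p_hat), 1e-10)
  se <- sqrt(diag(solve(crossprod(Xi * sqrt(w)))))  # Wald, observed information
  names(se) <- colnames(Xi)
  loglik <- sum(y * log(pmax(p_hat, 1e-12)) + (1 - y) * log(pmax(1 - p_hat, 1e-12)))
  structure(list(endpoint = endpoint, predictors = predictors,
                 coefficients = coefs, se = se, dropped_terms = dropped,
                 penalized = penalized, method = method, site_ridge = site_ridge,
                 ttr_threshold = ttr_threshold,
                 loglik = loglik, converged = all(is.finite(coefs)),
                 n = length(y), brier = mean((p_hat - y)^2)),
            class = "outcome_model")
}

#' Construct an outcome model directly from coefficients
#'
#' Builds an `outcome_model` from a known coefficient vector without
#' fitting, e.g. a treatment-only model with per-arm event probabilities
#' `p_vka` and `p_doac` (intercept `logit(p_vka)`, treatment coefficient
#' `logit(p_doac) - logit(p_vka)`).
#'
#' @param endpoint endpoint name.
#' @param coefficients named coefficient vector including `"(Intercept)"`.
#' @param predictors predictor set the coefficients refer to.
#' @return an `outcome_model`.
#' @export
outcome_model <- function(endpoint, coefficients, predictors = "treatment") {
  stopifnot("(Intercept)" %in% names(coefficients))
  structure(list(endpoint = endpoint, predictors = predictors,
                 coefficients = coefficients, dropped_terms = character(0),
                 penalized = FALSE, site_ridge = 0, ttr_threshold = 70,
                 loglik = NA_real_, converged = TRUE, n = NA_integer_,
                 brier = NA_real_),
            class = "outcome_model")
}

#' Treatment-only outcome model from per-arm event probabilities
#'
#' @param endpoint endpoint name.
#' @param p_vka,p_doac event probabilities per arm.
#' @return an `outcome_model` whose predictions are exactly `p_vka` for VKA
#'   records and `p_doac` for DOAC records.
#' @export
fixed_rate_model <- function(endpoint, p_vka, p_doac) {
  outcome_model(endpoint,
                c("(Intercept)" = logit(p_vka),
                  treatmentDOAC = logit(p_doac) - logit(p_vka)))
}

#' @export
print.outcome_model <- function(x, ...) {
  cat("<outcome_model> ", x$endpoint,
      if (x$penalized) " (penalized)", "\n", sep = "")
  print(round(x$coefficients, 4))
  if (!is.na(x$brier)) cat(sprintf("  Brier (training): %.4f\n", x$brier))
  invisible(x)
}

#' Predicted event probabilities
#'
#' Inverse-logit of the linear predictor for each record.
#'
#' @param model an `outcome_model`.
#' @param records a cohort or data.frame carrying all model predictors.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_risk <- function(model, records) {
  data <- as.data.frame(records)
  X <- outcome_design(data, model$predictors, model$ttr_threshold)
  terms <- setdiff(names(model$coefficients), "(Intercept)")
  missing_terms <- setdiff(terms, colnames(X))
  if (length(missing_terms)) {
    stop("contract error: records lack predictor term(s): ",
         paste(missing_terms, collapse = ", "), call. = FALSE)
  }
  eta <- rep(model$coefficients[["(Intercept)"]], nrow(data)) +
    if (length(terms)) drop(X[, terms, drop = FALSE] %*% model$coefficients[terms]) else 0
  inv_logit(eta)
}

#' Counterfactual marginal event rates per arm
#'
#' Marginal standardization: every record is scored once with treatment set
#' to VKA and once to DOAC; the per-arm marginal rate is the mean predicted
#' probability (x100). Confidence intervals by nonparametric percentile
#' bootstrap over records.
#'
#' @param model an `outcome_model`.
#' @param cohort cohort providing the case-mix.
#' @param n_boot bootstrap resamples (0 disables the CI).
#' @param conf confidence level.
#' @param seed integer seed.
#' @return a list of class `marginal_rates`: `vka`, `doac` (percent, with
#'   CIs), and `difference` (DOAC - VKA, percentage points).
#' @export
marginal_rates <- function(model, cohort, n_boot = 1000, conf = 0.95,
                           seed = NULL) {
  data <- as.data.frame(cohort)
  if (!nrow(data)) stop("empty cohort", call. = FALSE)
  point <- function(d) {
    dv <- d; dv$treatment <- "VKA"
    dd <- d; dd$treatment <- "DOAC"
    c(vka = 100 * mean(predict_risk(model, dv)),
      doac = 100 * mean(predict_risk(model, dd)))
  }
  est <- point(data)
  ci <- NULL
  if (n_boot > 0) {
    with_seed(seed, {
      boots <- vapply(seq_len(n_boot), function(i) {
        point(data[sample.int(nrow(data), replace = TRUE), , drop = FALSE])
      }, numeric(2))
      alpha <- (1 - conf) / 2
      ci <- apply(boots, 1, stats::quantile, probs = c(alpha, 1 - alpha))
    })
  }
  structure(list(
    vka = est[["vka"]], doac = est[["doac"]],
    vka_ci = if (!is.null(ci)) unname(ci[, "vka"]),
    doac_ci = if (!is.null(ci)) unname(ci[, "doac"]),
    difference = est[["doac"]] - est[["vka"]],
    endpoint = model$endpoint, n = nrow(data), n_boot = n_boot
  ), class = "marginal_rates")
}

#' @export
print.marginal_rates <- function(x, ...) {
  fmt <- function(v, ci) {
    if (is.null(ci)) sprintf("%.1f", v)
    else sprintf("%.1f (%.1f-%.1f)", v, ci[1], ci[2])
  }
  cat("<marginal_rates> ", x$endpoint, "\n", sep = "")
  cat("  VKA:  ", fmt(x$vka, x$vka_ci), "%\n", sep = "")
  cat("  DOAC: ", fmt(x$doac, x$doac_ci), "%\n", sep = "")
  cat(sprintf("  difference (DOAC - VKA): %+.1f pp\n", x$difference))
  invisible(x)
}

#' Brier score of an outcome model on a cohort
#'
#' Mean squared difference between the predicted probability and the
#' observed 0/1 endpoint, over records where the endpoint is observed.
#'
#' @inheritParams marginal_rates
#' @return scalar Brier score.
#' @export
brier_score <- function(model, cohort) {
  resp <- endpoint_response(cohort, model$endpoint)
  p <- predict_risk(model, as.data.frame(cohort)[resp$rows, , drop = FALSE])
  mean((p - resp$y)^2)
}

#' Calibration bins for a calibration plot
#'
#' Equal-frequency bins over the predicted probabilities with the mean
#' prediction, observed event rate and count per bin.
#'
#' @inheritParams marginal_rates
#' @param n_bins number of bins (>= 2).
#' @return data.frame with `bin`, `mean_predicted`, `observed_rate`, `n`.
#' @export
calibration_bins <- function(model, cohort, n_bins = 10) {
  if (n_bins < 2) stop("contract error: n_bins must be >= 2", call. = FALSE)
  resp <- endpoint_response(cohort, model$endpoint)
  p <- predict_risk(model, as.data.frame(cohort)[resp$rows, , drop = FALSE])
  if (length(p) < n_bins) {
    warning("fewer rows than bins; reducing to ", length(p), " bins", call. = FALSE)
    n_bins <- max(1L, length(p))
  }
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- if (length(br) < 2) rep(1L, length(p)) else
    cut(p, breaks = br, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    sel <- bins == b
    data.frame(bin = b, mean_predicted = mean(p[sel]),
               observed_rate = mean(resp$y[sel]), n = sum(sel))
  }))
  out
}

#' Predicted-outcome table by treatment arm
#'
#' @param models named list of `outcome_model`s per endpoint.
#' @param cohort the conditioned cohort supplying the case-mix.
#' @param n_boot,seed bootstrap settings passed to [marginal_rates()].
#' @return data.frame with one row per endpoint: per-arm rates with CIs and
#'   the absolute DOAC - VKA difference in percentage points.
#' @export
render_table2 <- function(models, cohort, n_boot = 1000, seed = NULL) {
  rows <- lapply(names(models), function(ep) {
    mr <- marginal_rates(models[[ep]], cohort, n_boot = n_boot,
                         seed = derive_seed(seed %||% 0, match(ep, names(models))))
    data.frame(outcome = ep,
               vka = round(mr$vka, 1),
               vka_lo = round(mr$vka_ci[1], 1), vka_hi = round(mr$vka_ci[2], 1),
               doac = round(mr$doac, 1),
               doac_lo = round(mr$doac_ci[1], 1), doac_hi = round(mr$doac_ci[2], 1),
               difference = round(mr$doac - mr$vka, 1))
  })
  do.call(rbind, rows)
}
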