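#' Scenario specification for the Monte Carlo engine
#'
#' Five supported case-mix scenarios: `baseline` (the conditioned cohort's
#' own case-mix), `doac70` (70% DOAC / 30% VKA, the inverse of the
#' real-world distribution), `cancer_plus50` (+50% relative increase in
#' active-cancer prevalence), `cvt40` (CVT raised to 40% of all cases) and
#' `ttr100` (all VKA patients reassigned to the perfect-control TTR
#' stratum). Each non-baseline scenario carries exactly one perturbation.
#'
#' @param id scenario identifier.
#' @param resample_size per-iteration case-mix size M.
#' @param iterations number of Monte Carlo iterations R.
#' @param seed optional scenario seed (normally derived from the master
#'   seed in [run_simulation()]).
#' @return a list of class `scenario_spec`.
#' @export
scenario_spec <- function(id = c("baseline", "doac70", "cancer_plus50",
                                 "cvt40", "ttr100"),
                          resample_size = 4000, iterations = 500, seed = NULL) {
  id <- match.arg(id)
  stopifnot(resample_size >= 1, iterations >= 1)
  structure(list(id = id, resample_size = resample_size,
                 iterations = iterations, seed = seed),
            class = "scenario_spec")
}

#' All five study scenarios
#'
#' @inheritParams scenario_spec
#' @return list of `scenario_spec`s.
#' @export
default_scenarios <- function(resample_size = 4000, iterations = 500) {
  lapply(c("baseline", "doac70", "cancer_plus50", "cvt40", "ttr100"),
         scenario_spec, resample_size = resample_size, iterations = iterations)
}

#' Build one scenario case-mix by stratified resampling (Layer 1)
#'
#' Rows are drawn with replacement within the strata defined by the
#' perturbed variable so that the target marginal is hit in expectation
#' while all within-stratum joint structure is preserved (resampling, never
#' editing) — except `ttr100`, which is a plain resample followed by the
#' deterministic reassignment of VKA rows to the perfect-control stratum
#' (`ttr_control = 1`, TTR 100).
#'
#' @param dt_cohort the conditioned digital-twin cohort.
#' @param spec a [scenario_spec()].
#' @param seed iteration seed.
#' @return a data.frame case-mix of `spec$resample_size` rows (carrying a
#'   `ttr_control` column).
#' @export
build_scenario_casemix <- function(dt_cohort, spec, seed = NULL) {
  data <- as.data.frame(dt_cohort)
  n <- nrow(data); M <- spec$resample_size
  if ("ttr_control" %in% names(data) == FALSE) {
    data$ttr_control <- as.numeric(data$treatment == "VKA" & !is.na(data$ttr) &
                                     data$ttr >= 70)
  }
  draw_strata <- function(strata_of, target_probs) {
    # target_probs: named per-stratum probabilities; unnamed rows impossible
    for (s in names(target_probs)) {
      if (target_probs[[s]] > 0 && !any(strata_of == s)) {
        stop("scenario infeasible: stratum '", s, "' is empty in the cohort",
             call. = FALSE)
      }
    }
    lab <- sample(names(target_probs), M, replace = TRUE,
                  prob = unlist(target_probs))
    idx <- integer(M)
    for (s in unique(lab)) {
      pool <- which(strata_of == s)
      sel <- lab == s
      idx[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
    }
    idx
  }
  with_seed(seed, {
    idx <- switch(spec$id,
      baseline = sample.int(n, M, replace = TRUE),
      doac70 = draw_strata(data$treatment, list(DOAC = 0.70, VKA = 0.30)),
      cancer_plus50 = {
        p0 <- mean(data$active_cancer)
        q <- min(1, 1.5 * p0)
        draw_strata(as.character(data$active_cancer), list(`1` = q, `0` = 1 - q))
      },
      cvt40 = {
        p_cvt <- 0.40
        draw_strata(ifelse(data$usvt_site == "CVT", "CVT", "other"),
                    list(CVT = p_cvt, other = 1 - p_cvt))
      },
      ttr100 = sample.int(n, M, replace = TRUE))
    mix <- data[idx, , drop = FALSE]
    rownames(mix) <- NULL
    if (spec$id == "ttr100") {
      vka <- mix$treatment == "VKA"
      mix$ttr_control[vka] <- 1
      mix$ttr[vka] <- 100
    }
    mix
  })
}

#' Simulate one Monte Carlo iteration (Layer 2)
#'
#' For each record of the case-mix and each endpoint, draws a Bernoulli
#' outcome with the model-predicted probability and averages the draws
#' within each treatment arm.
#'
#' @param casemix data.frame from [build_scenario_casemix()].
#' @param models named list of `outcome_model`s.
#' @param seed iteration seed.
#' @return named list per endpoint of per-arm simulated event rates
#'   (fractions); arms absent from the case-mix yield `NA` with a flag.
#' @export
simulate_iteration <- function(casemix, models, seed = NULL) {
  with_seed(seed, {
    arms <- casemix$treatment
    out <- lapply(models, function(model) {
      p <- predict_risk(model, casemix)
      draw <- stats::rbinom(length(p), 1, p)
      c(vka = if (any(arms == "VKA")) mean(draw[arms == "VKA"]) else NA_real_,
        doac = if (any(arms == "DOAC")) mean(draw[arms == "DOAC"]) else NA_real_)
    })
    attr(out, "arm_missing") <- !all(c("VKA", "DOAC") %in% arms)
    out
  })
}

#' Run the full two-layer Monte Carlo simulation
#'
#' For each scenario, runs R iterations; every iteration draws a fresh
#' case-mix (Layer 1) and fresh Bernoulli outcomes (Layer 2) under a
#' deterministic per-iteration seed derived from the master seed. Reports
#' per scenario x endpoint x arm the mean rate (%), empirical 95% CI
#' (2.5/97.5 percentiles over iterations), Monte Carlo standard error (both
#' absolute and as % of the mean) and coefficient of variation, with
#' convergence flags at MCSE < 5% and CV < 10%.
#'
#' @param dt_cohort the conditioned digital-twin cohort.
#' @param models named list of `outcome_model`s per endpoint.
#' @param specs list of [scenario_spec()]s.
#' @param seed master seed.
#' @param conf level of the empirical interval.
#' @return an object of class `simulation_result` with `summary` (one row
#'   per scenario x endpoint x arm) and `iterations` (per-iteration rates,
#'   retained for directionality scoring).
#' @export
run_simulation <- function(dt_cohort, models, specs = default_scenarios(),
                           seed = 1L, conf = 0.95) {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  alpha <- (1 - conf) / 2
  all_summ <- list(); all_iter <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    scen_seed <- spec$seed %||% derive_seed(seed, si, salt = 11L)
    R <- spec$iterations
    iter_rates <- array(NA_real_, dim = c(R, length(models), 2),
                        dimnames = list(NULL, names(models), c("vka", "doac")))
    for (r in seq_len(R)) {
      iter_seed <- derive_seed(scen_seed, r, salt = 13L)
      mix <- build_scenario_casemix(dt_cohort, spec, seed = iter_seed)
      res <- simulate_iteration(mix, models, seed = derive_seed(iter_seed, 1L, salt = 17L))
      for (ep in names(models)) iter_rates[r, ep, ] <- res[[ep]]
    }
    for (ep in names(models)) {
      for (arm in c("vka", "doac")) {
        x <- 100 * iter_rates[, ep, arm]
        m <- mean(x); s <- stats::sd(x)
        mcse <- s / sqrt(R)
        all_summ[[length(all_summ) + 1L]] <- data.frame(
          scenario = spec$id, outcome = ep, arm = toupper(arm),
          mean = m,
          ci_lo = unname(stats::quantile(x, alpha)),
          ci_hi = unname(stats::quantile(x, 1 - alpha)),
          mcse_abs = mcse,
          mcse_pct = 100 * mcse / m,
          cv_pct = 100 * s / m,
          R = R, M = spec$resample_size,
          converged = (100 * mcse / m < 5) && (100 * s / m < 10))
      }
    }
    all_iter[[spec$id]] <- iter_rates
  }
  structure(list(summary = do.call(rbind, all_summ), iterations = all_iter,
                 seed = seed, conf = conf),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", length(x$iterations), " scenario(s)\n", sep = "")
  s <- x$summary
  s$mean <- round(s$mean, 1); s$ci_lo <- round(s$ci_lo, 1); s$ci_hi <- round(s$ci_hi, 1)
  s$mcse_pct <- round(s$mcse_pct, 2); s$cv_pct <- round(s$cv_pct, 2)
  print(s[c("scenario", "outcome", "arm", "mean", "ci_lo", "ci_hi",
            "mcse_pct", "cv_pct", "converged")], row.names = FALSE)
  invisible(x)
}

#' Directionality preservation of the simulated treatment effect
#'
#' Fraction of iterations in which the sign of the simulated DOAC - VKA
#' difference equals the reference sign (e.g. the sign observed in the real
#' cohort). Zero differences count as non-preserving (conservative).
#'
#' @param result a `simulation_result`.
#' @param reference_signs named vector of +1/-1 per endpoint.
#' @param scenario which scenario's iterations to score.
#' @return list with `per_endpoint` fractions and the `pooled` fraction.
#' @export
directionality <- function(result, reference_signs, scenario = "baseline") {
  rates <- result$iterations[[scenario]]
  if (is.null(rates)) stop("scenario '", scenario, "' not in result", call. = FALSE)
  eps <- names(reference_signs)
  per <- vapply(eps, function(ep) {
    d <- rates[, ep, "doac"] - rates[, ep, "vka"]
    mean(sign(d) == sign(reference_signs[[ep]]) & d != 0)
  }, numeric(1))
  list(per_endpoint = per, pooled = mean(per))
}

#' Sensitivity of the simulation to iteration count and resampling scheme
#'
#' Reruns a scenario at R in `r_grid` and once under an alternative
#' case-mix scheme (simple weighted resampling of whole rows instead of
#' stratified resampling) and reports the maximum absolute deviation of the
#' mean rates from the reference configuration.
#'
#' @param dt_cohort,models,spec as in [run_simulation()].
#' @param r_grid iteration counts to compare.
#' @param seed master seed.
#' @return data.frame with one row per configuration: the configuration
#'   label and the maximum absolute deviation (percentage points) of any
#'   endpoint x arm mean from the reference run.
#' @export
sensitivity_suite <- function(dt_cohort, models, spec = scenario_spec("baseline"),
                              r_grid = c(100, 250, 500, 1000), seed = 1L) {
  ref <- run_simulation(dt_cohort, models, list(spec), seed = seed)
  ref_means <- ref$summary$mean
  rows <- list()
  add_row <- function(label, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      configuration = label,
      max_abs_deviation = max(abs(res$summary$mean - ref_means)))
  }
  for (R in r_grid) {
    sp <- spec; sp$iterations <- R
    add_row(sprintf("R=%d", R),
            run_simulation(dt_cohort, models, list(sp), seed = derive_seed(seed, R)))
  }
  add_row("weighted_resampling",
          run_weighted_simulation(dt_cohort, models, spec,
                                  seed = derive_seed(seed, 999L)))
  out <- do.call(rbind, rows)
  attr(out, "reference") <- ref
  out
}

# Alternative Layer-1 scheme: one weighted resample of whole rows, with row
# weights chosen so the perturbed marginal is hit in expectation.
run_weighted_simulation <- function(dt_cohort, models, spec, seed = 1L) {
  data <- as.data.frame(dt_cohort)
  if (!"ttr_control" %in% names(data)) {
    data$ttr_control <- as.numeric(data$treatment == "VKA" & !is.na(data$ttr) &
                                     data$ttr >= 70)
  }
  w <- rep(1, nrow(data))
  if (spec$id == "doac70") {
    pd <- mean(data$treatment == "DOAC")
    w <- ifelse(data$treatment == "DOAC", 0.70 / pd, 0.30 / (1 - pd))
  } else if (spec$id == "cancer_plus50") {
    p0 <- mean(data$active_cancer); q <- min(1, 1.5 * p0)
    w <- ifelse(data$active_cancer == 1, q / p0, (1 - q) / (1 - p0))
  } else if (spec$id == "cvt40") {
    p0 <- mean(data$usvt_site == "CVT")
    if (p0 == 0) stop("scenario infeasible: stratum 'CVT' is empty in the cohort",
                      call. = FALSE)
    w <- ifelse(data$usvt_site == "CVT", 0.40 / p0, 0.60 / (1 - p0))
  }
  R <- spec$iterations; M <- spec$resample_size
  iter_rates <- array(NA_real_, dim = c(R, length(models), 2),
                      dimnames = list(NULL, names(models), c("vka", "doac")))
  for (r in seq_len(R)) {
    iter_seed <- derive_seed(seed, r, salt = 23L)
    mix <- with_seed(iter_seed, {
      m <- data[sample.int(nrow(data), M, replace = TRUE, prob = w), , drop = FALSE]
      if (spec$id == "ttr100") {
        vka <- m$treatment == "VKA"
        m$ttr_control[vka] <- 1
        m$ttr[vka] <- 100
      }
      m
    })
    res <- simulate_iteration(mix, models, seed = derive_seed(iter_seed, 1L, salt = 17L))
    for (ep in names(models)) iter_rates[r, ep, ] <- res[[ep]]
  }
  summ <- list()
  for (ep in names(models)) {
    for (arm in c("vka", "doac")) {
      x <- 100 * iter_rates[, ep, arm]
      summ[[length(summ) + 1L]] <- data.frame(
        scenario = spec$id, outcome = ep, arm = toupper(arm), mean = mean(x))
    }
  }
  structure(list(summary = do.call(rbind, summ), iterations = list(iter_rates)),
            class = "simulation_result")
}
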