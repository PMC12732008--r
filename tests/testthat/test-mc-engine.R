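# A deterministic two-arm cohort with CVT present, used as the case-mix
# source throughout.
mc_cohort <- reference_cohort()
eps <- c("recanalization_complete", "recurrence", "major_bleed")
fixed_models <- list(
  recanalization_complete = fixed_rate_model("recanalization_complete", 0.380, 0.403),
  recurrence = fixed_rate_model("recurrence", 0.086, 0.109),
  major_bleed = fixed_rate_model("major_bleed", 0.091, 0.076))

test_that("scenario case-mixes hit their target marginals in expectation", {
  probe <- function(id, stat) {
    mean(vapply(1:40, function(i) {
      stat(build_scenario_casemix(mc_cohort, scenario_spec(id, 1000), seed = i))
    }, numeric(1)))
  }
  tol <- function(p, M) 3 * sqrt(p * (1 - p) / (40 * M))

  p_doac0 <- mean(mc_cohort$treatment == "DOAC")
  expect_lt(abs(probe("baseline", function(m) mean(m$treatment == "DOAC")) - p_doac0),
            tol(p_doac0, 1000))
  expect_lt(abs(probe("doac70", function(m) mean(m$treatment == "DOAC")) - 0.70),
            tol(0.7, 1000))
  p_c0 <- mean(mc_cohort$active_cancer)
  expect_lt(abs(probe("cancer_plus50", function(m) mean(m$active_cancer)) - 1.5 * p_c0),
            tol(1.5 * p_c0, 1000))
  expect_lt(abs(probe("cvt40", function(m) mean(m$usvt_site == "CVT")) - 0.40),
            tol(0.4, 1000))
})

test_that("resampling preserves within-stratum joint structure", {
  mix <- build_scenario_casemix(mc_cohort, scenario_spec("doac70", 5000), seed = 2)
  # within the DOAC stratum, the agent distribution is the cohort's own
  p_apix <- mean(mc_cohort$doac_agent[mc_cohort$treatment == "DOAC"] == "apixaban")
  got <- mean(mix$doac_agent[mix$treatment == "DOAC"] == "apixaban")
  expect_lt(abs(got - p_apix), 3 * sqrt(p_apix * (1 - p_apix) / 3000))
})

test_that("infeasible strata and the TTR edit are handled as specified", {
  no_cvt <- as_cohort(as.data.frame(mc_cohort)[mc_cohort$usvt_site != "CVT", ])
  expect_error(build_scenario_casemix(no_cvt, scenario_spec("cvt40", 100), seed = 1),
               "scenario infeasible.*CVT")

  mix <- build_scenario_casemix(mc_cohort, scenario_spec("ttr100", 500), seed = 3)
  vka <- mix$treatment == "VKA"
  expect_true(all(mix$ttr_control[vka] == 1))
  expect_true(all(mix$ttr[vka] == 100))
  expect_true(all(mix$ttr_control[!vka] == 0))
})

test_that("iteration draws are Bernoulli with the model probabilities", {
  mix <- build_scenario_casemix(mc_cohort, scenario_spec("baseline", 10000), seed = 4)
  zero <- list(recurrence = outcome_model("recurrence", c("(Intercept)" = -40)))
  r0 <- simulate_iteration(mix, zero, seed = 5)
  expect_equal(unname(r0$recurrence), c(0, 0))

  flat <- list(recurrence = fixed_rate_model("recurrence", 0.4, 0.4))
  r <- simulate_iteration(mix, flat, seed = 6)
  expect_lt(abs(r$recurrence[["vka"]] - 0.4), 0.03)
  expect_lt(abs(r$recurrence[["doac"]] - 0.4), 0.03)

  expect_identical(simulate_iteration(mix, fixed_models, seed = 7),
                   simulate_iteration(mix, fixed_models, seed = 7))
})

test_that("the simulation aggregates means, CIs and convergence diagnostics", {
  sim <- run_simulation(mc_cohort, fixed_models,
                        list(scenario_spec("baseline", 2000, 200)), seed = 31)
  s <- sim$summary
  expect_equal(nrow(s), 6)
  expect_true(all(s$ci_lo <= s$mean & s$mean <= s$ci_hi))
  # unbiasedness: fixed probabilities are recovered within 3 MCSE
  for (ep in eps) {
    for (arm in c("VKA", "DOAC")) {
      row <- s[s$outcome == ep & s$arm == arm, ]
      target <- 100 * unname(plogis(sum(fixed_models[[ep]]$coefficients *
                                          c(1, arm == "DOAC"))))
      expect_lt(abs(row$mean - target), 3 * row$mcse_abs + 1e-9)
    }
  }

  one <- run_simulation(mc_cohort, fixed_models,
                        list(scenario_spec("baseline", 500, 1)), seed = 32)
  expect_equal(one$summary$ci_lo, one$summary$mean)
  expect_equal(one$summary$ci_hi, one$summary$mean)
})

test_that("MCSE shrinks like 1/sqrt(R)", {
  m <- fixed_models["recurrence"]
  s100 <- run_simulation(mc_cohort, m, list(scenario_spec("baseline", 1000, 100)),
                         seed = 41)$summary
  s400 <- run_simulation(mc_cohort, m, list(scenario_spec("baseline", 1000, 400)),
                         seed = 42)$summary
  ratio <- mean(s100$mcse_abs / s400$mcse_abs)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.6)
})

test_that("directionality scores signs with ties counted against", {
  sim <- run_simulation(mc_cohort, fixed_models,
                        list(scenario_spec("baseline", 4000, 300)), seed = 51)
  refs <- c(recanalization_complete = 1, recurrence = 1, major_bleed = -1)
  d <- directionality(sim, refs)
  expect_true(all(d$per_endpoint >= 0 & d$per_endpoint <= 1))
  flipped <- directionality(sim, -refs)
  # complements exactly when no iteration ties occur
  it <- sim$iterations$baseline
  no_ties <- all(it[, , "doac"] != it[, , "vka"])
  if (no_ties) {
    expect_equal(unname(d$per_endpoint + flipped$per_endpoint), rep(1, 3))
  }

  # equal probabilities across arms: the sign is a fair coin
  null_m <- list(recurrence = fixed_rate_model("recurrence", 0.3, 0.3))
  sim0 <- run_simulation(mc_cohort, null_m,
                         list(scenario_spec("baseline", 2000, 400)), seed = 52)
  d0 <- directionality(sim0, c(recurrence = 1))
  expect_gt(d0$per_endpoint[["recurrence"]], 0.38)
  expect_lt(d0$per_endpoint[["recurrence"]], 0.62)
})

test_that("sensitivity analyses agree with the reference within Monte Carlo error", {
  spec <- scenario_spec("baseline", 1500, 150)
  out <- sensitivity_suite(mc_cohort, fixed_models, spec,
                           r_grid = c(100, 250), seed = 61)
  expect_equal(nrow(out), 3)
  ref <- attr(out, "reference")$summary
  # every configuration estimates the same marginal: deviations bounded by
  # a few combined MCSEs (the largest MCSE doubles as a conservative bound)
  bound <- 6 * max(ref$mcse_abs) + 1e-9
  expect_true(all(out$max_abs_deviation < bound))
})
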