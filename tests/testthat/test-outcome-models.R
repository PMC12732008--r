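test_that("two-group fits recover the saturated closed form", {
  co <- two_group_cohort(n_vka = 50, n_doac = 25, recur_vka = 18, recur_doac = 10)
  m <- fit_outcome_model(co, "recurrence", predictors = "treatment")
  expect_equal(unname(m$coefficients["(Intercept)"]), qlogis(0.36), tolerance = 1e-6)
  expect_equal(unname(m$coefficients["treatmentDOAC"]),
               qlogis(0.40) - qlogis(0.36), tolerance = 1e-6)
  expect_false(m$penalized)

  # recanalization restricts to imaged rows and codes complete = 1
  co2 <- two_group_cohort(imaged_vka = 25, complete_vka = 9,
                          imaged_doac = 15, complete_doac = 6)
  m2 <- fit_outcome_model(co2, "recanalization_complete", predictors = "treatment")
  expect_equal(m2$n, 40)
  expect_equal(unname(m2$coefficients["(Intercept)"]), qlogis(9 / 25), tolerance = 1e-6)

  all_zero <- two_group_cohort(recur_vka = 0, recur_doac = 0)
  expect_error(fit_outcome_model(all_zero, "recurrence"), "degenerate fit")
})

test_that("separation triggers the penalized fallback with finite estimates", {
  co <- two_group_cohort(recur_vka = 18, recur_doac = 0)  # no DOAC events
  m <- fit_outcome_model(co, "recurrence", predictors = "treatment")
  expect_true(m$penalized)
  expect_equal(m$method, "firth")
  expect_true(all(is.finite(m$coefficients)))
  # Firth estimate for the empty cell behaves like (0 + 1/2) successes
  p_doac <- predict_risk(m, data.frame(treatment = "DOAC"))
  expect_gt(p_doac, 0)
  expect_lt(p_doac, 0.1)
})

test_that("predicted risks equal the inverse-logit of the linear predictor", {
  m0 <- outcome_model("recurrence", c("(Intercept)" = 0, treatmentDOAC = 0))
  expect_equal(predict_risk(m0, data.frame(treatment = c("VKA", "DOAC"))),
               c(0.5, 0.5))

  m1 <- outcome_model("recurrence", c("(Intercept)" = qlogis(0.36)))
  expect_equal(predict_risk(m1, data.frame(treatment = "VKA")), 0.36)

  m2 <- outcome_model(
    "recurrence",
    c("(Intercept)" = -2, treatmentDOAC = 0.5, siteUEDVT = 0.3, siteCVT = 1,
      active_cancer = -0.4),
    predictors = c("treatment", "usvt_site", "active_cancer"))
  rec <- data.frame(treatment = "DOAC", usvt_site = "CVT", active_cancer = 1)
  expect_equal(predict_risk(m2, rec), plogis(-2 + 0.5 + 1 - 0.4))

  expect_error(predict_risk(m2, data.frame(treatment = "DOAC")), "contract error")

  # monotone and sign-consistent in each covariate
  lo <- predict_risk(m2, data.frame(treatment = "VKA", usvt_site = "SVT",
                                    active_cancer = 1))
  hi <- predict_risk(m2, data.frame(treatment = "DOAC", usvt_site = "SVT",
                                    active_cancer = 1))
  expect_gt(hi, lo)   # positive treatment coefficient
  expect_lt(predict_risk(m2, rec),
            predict_risk(m2, transform(rec, active_cancer = 0)))
})

test_that("marginal rates of a treatment-only model equal raw arm rates exactly", {
  co <- two_group_cohort(n_vka = 50, n_doac = 25, recur_vka = 18, recur_doac = 10)
  m <- fit_outcome_model(co, "recurrence", predictors = "treatment")
  mr <- marginal_rates(m, co, n_boot = 0)
  expect_equal(mr$vka, 36)
  expect_equal(mr$doac, 40)
  expect_equal(mr$difference, 4)

  mr_ci <- marginal_rates(m, co, n_boot = 200, seed = 8)
  expect_true(mr_ci$vka_ci[1] <= mr_ci$vka && mr_ci$vka <= mr_ci$vka_ci[2])
  # a cohort of identical records leaves nothing to bootstrap over
  one <- as_cohort(as.data.frame(co)[rep(1, 20), ])
  mr1 <- marginal_rates(m, one, n_boot = 100, seed = 9)
  expect_equal(mr1$vka_ci[1], mr1$vka_ci[2])
})

test_that("Brier score matches hand computation", {
  co <- two_group_cohort(n_vka = 2, n_doac = 2, recur_vka = 1, recur_doac = 1,
                         imaged_vka = 2, complete_vka = 1,
                         imaged_doac = 2, complete_doac = 1)
  const <- outcome_model("recurrence", c("(Intercept)" = 0))
  expect_equal(brier_score(const, co), 0.25)

  # outcomes for the 4 rows: 1,0 (VKA), 1,0 (DOAC); predictions .8/.8/.3/.3
  m <- outcome_model("recurrence",
                     c("(Intercept)" = qlogis(0.8),
                       treatmentDOAC = qlogis(0.3) - qlogis(0.8)))
  expect_equal(brier_score(m, co),
               mean(c((0.8 - 1)^2, (0.8 - 0)^2, (0.3 - 1)^2, (0.3 - 0)^2)))

  sharp <- outcome_model("recurrence",
                         c("(Intercept)" = 40, treatmentDOAC = -80))
  co_perfect <- two_group_cohort(n_vka = 3, n_doac = 3, recur_vka = 3,
                                 recur_doac = 0)
  expect_lt(brier_score(sharp, co_perfect), 1e-10)
})

test_that("calibration bins contract and large-sample calibration hold", {
  co <- two_group_cohort()
  m <- fit_outcome_model(co, "recurrence", predictors = "treatment")
  expect_error(calibration_bins(m, co, n_bins = 1), "contract error")

  const <- outcome_model("recurrence", c("(Intercept)" = qlogis(0.3)))
  cb <- calibration_bins(const, co, n_bins = 5)
  expect_equal(nrow(cb), 1)  # constant predictions collapse to one bin

  # simulated perfectly calibrated data at large n
  withr::with_seed(123, {
    n <- 4000
    base <- as.data.frame(two_group_cohort(n_vka = n / 2, n_doac = n / 2))
    truth <- outcome_model(
      "recurrence",
      c("(Intercept)" = qlogis(0.15), treatmentDOAC = 0.8, active_cancer = -0.6),
      predictors = c("treatment", "active_cancer"))
    p <- predict_risk(truth, base)
    base$recurrence <- rbinom(n, 1, p)
    co_sim <- as_cohort(base)
    cb2 <- calibration_bins(truth, co_sim, n_bins = 4)
    for (i in seq_len(nrow(cb2))) {
      se <- sqrt(cb2$mean_predicted[i] * (1 - cb2$mean_predicted[i]) / cb2$n[i])
      expect_lt(abs(cb2$mean_predicted[i] - cb2$observed_rate[i]), 3 * se)
    }
  })
})

test_that("logistic fits recover known coefficients with near-nominal coverage", {
  truth <- c("(Intercept)" = -1.5, treatmentDOAC = 0.4, siteUEDVT = 0.3,
             siteCVT = 0.6, active_cancer = -0.5)
  reps <- 30
  covered <- 0; total <- 0
  withr::with_seed(2024, {
    n <- 5000
    base <- as.data.frame(two_group_cohort(n_vka = n / 2, n_doac = n / 2))
    base$usvt_site <- sample(c("SVT", "UEDVT", "CVT"), n, replace = TRUE,
                             prob = c(0.5, 0.35, 0.15))
    X <- cbind(1, usvtwin:::outcome_design(base,
                 c("treatment", "usvt_site", "active_cancer")))
    p <- plogis(drop(X %*% truth))
    for (r in seq_len(reps)) {
      base$recurrence <- rbinom(n, 1, p)
      m <- fit_outcome_model(as_cohort(base), "recurrence",
                             predictors = c("treatment", "usvt_site", "active_cancer"))
      for (term in names(truth)) {
        ci <- m$coefficients[term] + c(-1.96, 1.96) * m$se[term]
        covered <- covered + (truth[term] >= ci[1] && truth[term] <= ci[2])
        total <- total + 1
      }
    }
  })
  expect_gte(covered / total, 0.9)
})
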