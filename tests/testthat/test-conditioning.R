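test_that("propensity model reduces to the saturated closed form", {
  # only active_cancer varies: scores must equal the per-level DOAC fractions
  n <- 200
  cancer <- rep(c(1L, 0L), each = n / 2)
  doac <- c(rep(c("DOAC", "VKA"), times = c(40, 60)),   # 40% DOAC | cancer
            rep(c("DOAC", "VKA"), times = c(20, 80)))   # 20% DOAC | no cancer
  df <- data.frame(
    age = 60, sex = "female", usvt_site = "SVT", treatment = doac,
    doac_agent = ifelse(doac == "DOAC", "apixaban", NA_character_),
    hypertension = 0L, diabetes = 0L, dyslipidemia = 0L, obesity = 0L,
    smoker = 0L, chf = 0L, copd_asthma = 0L, cerebrovascular = 0L, ckd = 0L,
    estrogen = 0L, liver_disease = 0L, active_cancer = cancer, mps = 0L,
    thrombophilia = 0L, hemoglobin = 13, platelets = 240, d_dimer = 3000,
    ttr = ifelse(doac == "VKA", 60, NA_real_), antiplatelet = 0L,
    follow_up = 24, recanalization = "missing", recurrence = 0L,
    major_bleed = 0L, death = 0L, stringsAsFactors = FALSE)
  co <- as_cohort(df)
  ps <- estimate_propensity(co)
  expect_equal(unname(ps$scores[cancer == 1]), rep(0.4, 100), tolerance = 1e-6)
  expect_equal(unname(ps$scores[cancer == 0]), rep(0.2, 100), tolerance = 1e-6)
  expect_false(ps$penalized)

  one_arm <- df; one_arm$treatment <- "VKA"
  one_arm$doac_agent <- NA_character_; one_arm$ttr <- 60
  expect_error(estimate_propensity(as_cohort(one_arm)), "degenerate")
})

test_that("covariates independent of the arm give scores near the marginal rate", {
  co <- sample_cohort(source_config(
    n_total = 2000,
    site_probs = list(VKA = c(SVT = .6, UEDVT = .35, CVT = .05),
                      DOAC = c(SVT = .6, UEDVT = .35, CVT = .05)),
    sex_female = c(VKA = .5, DOAC = .5),
    age = list(VKA = c(mean = 65, sd = 15), DOAC = c(mean = 65, sd = 15),
               bounds = c(18, 100)),
    comorbidity_probs = list(
      VKA = replace(source_config()$comorbidity_probs$VKA, "active_cancer", .3),
      DOAC = replace(source_config()$comorbidity_probs$DOAC, "active_cancer", .3))),
    seed = 77)
  ps <- estimate_propensity(co)
  p_doac <- mean(co$treatment == "DOAC")
  expect_lt(max(abs(ps$scores - p_doac)), 0.15)
  expect_lt(unname(quantile(abs(ps$scores - p_doac), 0.95)), 0.1)
})

test_that("greedy caliper matching enumerates the expected pairs", {
  # all scores identical: every smaller-arm record matches
  m <- match_pairs(rep(0.3, 10), rep(c("DOAC", "VKA"), times = c(4, 6)),
                   caliper = 0.2, seed = 1)
  expect_equal(nrow(m$pairs), 4)
  expect_equal(length(m$unmatched), 2)
  expect_true(all(table(c(m$pairs$doac_id, m$pairs$vka_id)) == 1))

  # two DOAC (logit 0 and 5), one VKA (logit 0.1), caliper 0.2 SD:
  # only the logit-0 DOAC is admissible
  scores <- plogis(c(0, 5, 0.1))
  m2 <- match_pairs(scores, c("DOAC", "DOAC", "VKA"), caliper = 0.2, seed = 1)
  expect_equal(nrow(m2$pairs), 1)
  expect_equal(m2$pairs$doac_id, 1L)
  expect_equal(m2$pairs$vka_id, 3L)

  # caliper zero with no exact ties: nothing matches
  expect_warning(
    m3 <- match_pairs(plogis(c(0, 1, 2)), c("DOAC", "VKA", "VKA"),
                      caliper = 0, seed = 1),
    "no admissible")
  expect_equal(nrow(m3$pairs), 0)
})

test_that("matching is deterministic and invariant to record order", {
  withr::with_seed(5, {
    scores <- runif(40, 0.1, 0.9)
    arms <- rep(c("DOAC", "VKA"), times = c(15, 25))
  })
  m1 <- match_pairs(scores, arms, caliper = 0.5, seed = 9)
  m2 <- match_pairs(scores, arms, caliper = 0.5, seed = 9)
  expect_identical(m1$pairs, m2$pairs)

  perm <- c(40:1)
  mp <- match_pairs(scores[perm], arms[perm], caliper = 0.5, seed = 9)
  pair_scores <- function(m, s) {
    ps <- cbind(s[m$pairs$doac_id], s[m$pairs$vka_id])
    ps[order(ps[, 1]), ]
  }
  expect_equal(pair_scores(mp, scores[perm]), pair_scores(m1, scores))
})

test_that("balance report matches direct computation and flags duplicates", {
  co <- sample_cohort(seed = 14)
  ps <- estimate_propensity(co)
  m <- match_pairs(ps$scores, co$treatment, caliper = Inf, seed = 3)

  # duplicate-pair construction: match each record with itself conceptually
  dup <- m
  dup$pairs <- data.frame(doac_id = which(co$treatment == "DOAC"),
                          vka_id = which(co$treatment == "DOAC"))
  b0 <- balance_report(dup, co)
  expect_true(all(b0$table$asmd == 0))
  expect_equal(b0$masmd, 0)

  # hand-computed ASMD for a 4-pair cohort
  hb <- as.data.frame(co)[c(1, 2, 3, 4, 5, 6, 7, 8), ]
  hb$treatment <- rep(c("DOAC", "VKA"), each = 4)
  hb$doac_agent <- ifelse(hb$treatment == "DOAC", "apixaban", NA_character_)
  hb$ttr <- ifelse(hb$treatment == "VKA", 60, NA_real_)
  hb$age <- c(60, 70, 50, 80, 55, 65, 45, 75)
  hco <- as_cohort(hb)
  hm <- list(pairs = data.frame(doac_id = 1:4, vka_id = 5:8))
  b <- balance_report(hm, hco, variables = "age")
  expect_equal(b$table$asmd,
               abs(65 - 60) / sqrt((var(c(60, 70, 50, 80)) + var(c(55, 65, 45, 75))) / 2))

  expect_error(balance_report(list(pairs = data.frame()), co), "no pairs")
})

test_that("matching does not worsen covariate balance on emulated cohorts", {
  deltas <- vapply(1:5, function(i) {
    co <- sample_cohort(seed = 300 + i)
    vars <- c("age", "sex", "usvt_site", "active_cancer")
    un <- masmd(as_cohort(as.data.frame(co)[co$treatment == "DOAC", ]),
                as_cohort(as.data.frame(co)[co$treatment == "VKA", ]),
                vars, schema_of(co))$masmd
    cd <- condition_twins(co, caliper = 0.2, seed = i)
    cd$balance$masmd - un
  }, numeric(1))
  expect_lte(mean(deltas), 0)
})
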