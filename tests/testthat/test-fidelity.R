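test_that("ASMD matches hand-computed values for all variable kinds", {
  x <- as.numeric(scale(rnorm(50)))          # exact mean 0, sd 1
  expect_equal(asmd(x, x, "continuous"), 0)
  expect_equal(asmd(x, x + 1, "continuous"), 1)

  a <- rep(c(0, 1), each = 5)                # p = 0.5
  b <- c(rep(1, 6), rep(0, 4))               # p = 0.6
  expect_equal(asmd(a, b, "binary"), 0.1 / sqrt((0.25 + 0.24) / 2),
               tolerance = 1e-12)

  # zero pooled variance
  expect_equal(asmd(rep(2, 5), rep(2, 7), "continuous"), 0)
  expect_equal(asmd(rep(2, 5), rep(3, 7), "continuous"), Inf)

  # k-level categorical = mean of per-level dummies
  ca <- c("a", "a", "b", "c"); cb <- c("a", "b", "b", "c")
  by_hand <- mean(c(asmd(ca == "a", cb == "a", "binary"),
                    asmd(ca == "b", cb == "b", "binary"),
                    asmd(ca == "c", cb == "c", "binary")))
  expect_equal(asmd(ca, cb, "categorical"), by_hand)
})

test_that("ASMD is symmetric and invariant under common affine rescaling", {
  withr::with_seed(11, {
    for (i in 1:5) {
      x <- rnorm(40, 2, 3); y <- rnorm(35, 1, 2)
      expect_equal(asmd(x, y, "continuous"), asmd(y, x, "continuous"))
      expect_equal(asmd(5 * x - 7, 5 * y - 7, "continuous"),
                   asmd(x, y, "continuous"), tolerance = 1e-10)
    }
  })
})

test_that("MASMD aggregates per-variable ASMDs with the sample-SD convention", {
  co <- sample_cohort(seed = 5)
  self <- masmd(co, co)
  expect_equal(self$masmd, 0)
  expect_equal(self$sd, 0)

  sch <- cohort_schema(variable_spec("v1", "continuous"),
                       variable_spec("v2", "continuous"))
  x <- as.numeric(scale(rnorm(100)))
  a <- structure(data.frame(v1 = x, v2 = x), schema = sch)
  b <- structure(data.frame(v1 = x + 0.1, v2 = x + 0.3), schema = sch)
  m <- masmd(a, b, c("v1", "v2"), schema = sch)
  expect_equal(m$masmd, 0.2, tolerance = 1e-10)
  expect_equal(m$sd, sd(c(0.1, 0.3)), tolerance = 1e-10)  # 0.1414

  expect_error(masmd(a, b, character(0), schema = sch), "empty variable list")
})

test_that("squared MMD equals the brute-force kernel double sum", {
  A <- matrix(c(0, 0, 1, 1, 0.5, 2), ncol = 2, byrow = TRUE)
  B <- matrix(c(0.2, 0.1, 1.4, 0.9), ncol = 2, byrow = TRUE)
  res <- mmd2(A, B, bandwidth = 1.3)
  expect_equal(res$mmd2, mmd2_oracle(A, B, 1.3), tolerance = 1e-12)

  # invariance under identical row permutations
  withr::with_seed(2, {
    P <- matrix(rnorm(40), 20)
    Q <- matrix(rnorm(40, 1), 20)
    r1 <- mmd2(P, Q, 1)$mmd2
    r2 <- mmd2(P[sample(20), ], Q[sample(20), ], 1)$mmd2
    expect_equal(r1, r2, tolerance = 1e-12)
  })
  expect_error(mmd2(A[1, , drop = FALSE], B), "insufficient sample")
})

test_that("MMD permutation test separates gross shifts and accepts the null", {
  withr::with_seed(31, {
    pool <- matrix(rnorm(200), ncol = 2)
    null_case <- mmd2_permutation(pool[1:50, ], pool[51:100, ], seed = 1)
    expect_lt(abs(null_case$mmd2), 3 * sd(null_case$null) +
                abs(mean(null_case$null)))
    expect_gt(null_case$p_value, 0.01)

    far <- matrix(rnorm(100, 10), ncol = 2)
    sep <- mmd2_permutation(pool[1:50, ], far, seed = 2)
    expect_gt(sep$mmd2, quantile(sep$null, 0.99))
    expect_lt(sep$p_value, 0.01)
  })
})

test_that("KS statistic equals the ECDF supremum distance", {
  expect_equal(ks_two_sample(1:10, 1:10)$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1, 3))$statistic, 0.5)
})

test_that("correlation similarity counts pairs against the hand enumeration", {
  sch <- cohort_schema(variable_spec("v1", "continuous"),
                       variable_spec("v2", "continuous"),
                       variable_spec("v3", "continuous"))
  a <- structure(data.frame(v1 = 1:4, v2 = c(1, 2, 4, 3), v3 = c(4, 3, 2, 1)),
                 schema = sch)
  b <- structure(data.frame(v1 = 1:4, v2 = 1:4, v3 = c(4, 3, 2, 1)),
                 schema = sch)
  # pairs: (v1,v2) rho 0.8 vs 1.0 -> not similar; (v1,v3) -1 vs -1 similar;
  # (v2,v3) -0.8 vs -1 -> not similar => 1/3
  res <- correlation_similarity(a, b, c("v1", "v2", "v3"), schema = sch)
  expect_equal(res$fraction_similar, 1 / 3)

  co <- sample_cohort(seed = 8)
  self <- correlation_similarity(co, co, c("age", "hemoglobin", "platelets",
                                           "treatment", "active_cancer"))
  expect_equal(self$fraction_similar, 1)

  # independent white noise: both matrices near identity
  withr::with_seed(9, {
    mk <- function() structure(
      data.frame(v1 = rnorm(5000), v2 = rnorm(5000), v3 = rnorm(5000)),
      schema = sch)
    wn <- correlation_similarity(mk(), mk(), c("v1", "v2", "v3"), schema = sch)
    expect_equal(wn$fraction_similar, 1)
  })

  # constant variables are excluded and reported
  a2 <- structure(data.frame(v1 = 1:4, v2 = c(1, 2, 4, 3), v3 = rep(1, 4)),
                  schema = sch)
  res2 <- correlation_similarity(a2, a2, c("v1", "v2", "v3"), schema = sch)
  expect_equal(res2$excluded, "v3")
})

test_that("the fidelity report is internally consistent", {
  co <- sample_cohort(seed = 21)
  twin_like <- sample_cohort(seed = 22)   # an independent draw, same process
  rep <- fidelity_report(co, twin_like, n_perm = 50, seed = 5)
  expect_equal(rep$masmd, mean(rep$per_variable_asmd))
  expect_true(all(rep$per_variable_asmd >= 0))
  expect_gte(rep$corr_similarity, 0)
  expect_lte(rep$corr_similarity, 1)
  tab <- fidelity_table(rep)
  expect_equal(nrow(tab), length(rep$per_variable_asmd))
})
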