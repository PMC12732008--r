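# File-level fixture: one moderately trained model reused across tests.
fixture_cohort <- sample_cohort(seed = 42)
fixture_model <- suppressWarnings(
  train_cgan(fixture_cohort, default_dag(), gan_config(epochs = 600, seed = 7)))

test_that("the DAG validates acyclicity and terminal outcomes", {
  expect_error(dag_spec(c("a", "b"), rbind(c("a", "b"), c("b", "a"))), "cycle")
  expect_error(dag_spec(c("a", "b"), rbind(c("a", "b")), terminal_outcomes = "a"),
               "no outgoing")
  d <- default_dag()
  expect_setequal(d$terminal_outcomes, c("recanalization", "recurrence", "major_bleed"))
  expect_setequal(usvtwin:::dag_parents(d, "recurrence"),
                  c("age", "sex", "active_cancer", "usvt_site", "treatment"))
})

test_that("conditioning on terminal outcomes is rejected at training time", {
  cfg <- gan_config(epochs = 10, seed = 1,
                    conditioning_vars = c("treatment", "recurrence"))
  expect_error(train_cgan(fixture_cohort, default_dag(), cfg),
               "exclude terminal outcomes")
})

test_that("generator heads only see their DAG parents", {
  # outcomes are DAG members: context == parents, never other outcomes
  for (o in c("recanalization", "recurrence", "major_bleed")) {
    expect_setequal(head_context(fixture_model, o),
                    usvtwin:::dag_parents(fixture_model$dag, o))
  }
  # non-DAG variables fall back to the conditioning set
  expect_setequal(head_context(fixture_model, "hemoglobin"),
                  fixture_model$cond_vars)
  expect_error(head_context(fixture_model, "treatment"), "not a generated")
})

test_that("training is deterministic under a fixed seed", {
  cfg <- gan_config(epochs = 120, seed = 33)
  m1 <- suppressWarnings(train_cgan(fixture_cohort, default_dag(), cfg))
  m2 <- suppressWarnings(train_cgan(fixture_cohort, default_dag(), cfg))
  expect_identical(m1$loss_history, m2$loss_history)
  t1 <- generate_twins(m1, seed = 4)
  t2 <- generate_twins(m2, seed = 4)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("generated twins honor size, conditions and schema domains", {
  tw <- generate_twins(fixture_model, seed = 2)
  expect_equal(nrow(tw), nrow(fixture_cohort))
  # 1:1 twins reuse the training conditioning rows exactly
  expect_identical(tw$treatment, fixture_cohort$treatment)
  expect_identical(tw$age, fixture_cohort$age)

  forced <- generate_twins(fixture_model, n = 40,
                           conditions = list(treatment = "DOAC"), seed = 3)
  expect_true(all(forced$treatment == "DOAC"))
  expect_true(all(!is.na(forced$doac_agent)))
  expect_true(all(is.na(forced$ttr)))

  expect_equal(nrow(generate_twins(fixture_model, n = 0)), 0L)
  expect_error(generate_twins(fixture_model, conditions = list(recurrence = 1)),
               "contract error")
})

test_that("generated continuous values stay in the widened training domain", {
  tw <- generate_twins(fixture_model, n = 200, seed = 6)
  for (v in c("hemoglobin", "platelets", "d_dimer", "follow_up")) {
    map <- fixture_model$maps[[v]]
    slack <- fixture_model$config$domain_slack * (map$max - map$min)
    expect_true(all(tw[[v]] >= map$min - slack - 1e-9))
    expect_true(all(tw[[v]] <= map$max + slack + 1e-9))
  }
  for (v in c("usvt_site", "recanalization", "sex")) {
    expect_true(all(tw[[v]] %in% usvt_schema()[[v]]$levels))
  }
})

test_that("a degenerate training distribution collapses the twins", {
  one <- as.data.frame(fixture_cohort)[rep(1L, 30), ]
  rownames(one) <- NULL
  co1 <- as_cohort(one)
  # smoothing off: the discriminator target is the point mass itself
  m <- suppressWarnings(train_cgan(co1, default_dag(),
                                   gan_config(epochs = 1500, seed = 9,
                                              smoothing = 0)))
  tw <- generate_twins(m, seed = 10)
  for (v in c("recanalization", "recurrence", "major_bleed", "hypertension")) {
    expect_gte(mean(tw[[v]] == one[[v]][1]), 0.9)
  }
  # zero training range pins continuous values to the constant
  expect_true(all(tw$hemoglobin == one$hemoglobin[1]))
})

test_that("loss-stabilization criterion behaves on constructed histories", {
  const <- data.frame(generator = rep(1, 300), discriminator = rep(0.7, 300))
  expect_true(check_convergence(const, window = 100, tol = 0.05))

  diverging <- data.frame(generator = rep(1, 300),
                          discriminator = 2^(seq_len(300) / 10))
  expect_false(check_convergence(diverging, window = 100, tol = 0.05))

  # sinusoid with amplitude well below tol * mean, period << window
  sinus <- data.frame(generator = 1 + 0.04 * sin(seq_len(300) * 2 * pi / 10),
                      discriminator = rep(1, 300))
  expect_true(check_convergence(sinus, window = 100, tol = 0.05))

  expect_error(check_convergence(const[1:50, ], window = 100), "insufficient history")
})

test_that("replicas are reproducible and distinct across seeds", {
  cfg <- gan_config(epochs = 150)
  r1 <- suppressWarnings(replicate_twins(fixture_cohort, default_dag(), cfg,
                                         n_replicas = 2, seed_base = 50))
  r2 <- suppressWarnings(replicate_twins(fixture_cohort, default_dag(), cfg,
                                         n_replicas = 2, seed_base = 50))
  expect_identical(as.data.frame(r1$twins[[1]]), as.data.frame(r2$twins[[1]]))
  expect_identical(as.data.frame(r1$twins[[2]]), as.data.frame(r2$twins[[2]]))
  expect_false(identical(as.data.frame(r1$twins[[1]]),
                         as.data.frame(r1$twins[[2]])))
  expect_equal(r1$seeds, c(51, 52))

  s <- summary(r1, fixture_cohort)
  expect_equal(nrow(s), 2)
  expect_true(all(is.finite(s$masmd)))
  expect_true(is.finite(attr(s, "masmd_sd")))
})
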