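#' Full-pipeline configuration
#'
#' Single configuration object covering every stage: source-cohort
#' emulation, CGAN training, DAG, matching, outcome models and the Monte
#' Carlo scenarios.
#'
#' @param source a [source_config()].
#' @param gan a [gan_config()].
#' @param dag a [dag_spec()].
#' @param caliper matching caliper (SD units of the logit score).
#' @param predictors outcome-model predictor set.
#' @param site_ridge ridge penalty on the site dummies.
#' @param scenarios list of [scenario_spec()]s (may be empty: the pipeline
#'   then stops after the predicted-outcome table).
#' @param n_boot bootstrap resamples for the predicted-outcome table.
#' @param seed master seed for the whole run.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(source = source_config(), gan = gan_config(),
                            dag = default_dag(), caliper = 0.2,
                            predictors = c("treatment", "usvt_site", "active_cancer"),
                            site_ridge = 0.5, scenarios = default_scenarios(),
                            n_boot = 1000, seed = 1L) {
  structure(list(source = source, gan = gan, dag = dag, caliper = caliper,
                 predictors = predictors, site_ridge = site_ridge,
                 scenarios = scenarios, n_boot = n_boot, seed = seed),
            class = "pipeline_config")
}

#' Run the end-to-end digital-twin pipeline
#'
#' Executes, in order: source-cohort emulation, baseline descriptive
#' summary, CGAN training and 1:1 twin generation with a fidelity report,
#' propensity matching with balance reporting, per-endpoint outcome models
#' with a predicted-outcome table and, when scenarios are
#' configured, the two-layer Monte Carlo simulation with a scenario results
#' table plus directionality diagnostics. Every stage writes its
#' CSV artifact to `out_dir` and all seeds are recorded in a manifest, from
#' which the run is bit-reproducible.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param make_plots also write the correlation-heatmap triple and the
#'   simulated-vs-observed distribution figure (PNG).
#' @param quiet suppress stage logging.
#' @return (invisibly) a list with every stage result.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = ".",
                         make_plots = FALSE, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0, units = "secs")), ...)
  seeds <- list(master = config$seed)

  say("stage 1/6: source cohort emulation")
  seeds$source <- derive_seed(config$seed, 1L)
  source_cohort <- sample_cohort(config$source, seed = seeds$source)
  write_cohort(source_cohort, file.path(out_dir, "source_cohort.csv"))
  table1 <- summarize_cohort(source_cohort)
  utils::write.csv(table1, file.path(out_dir, "table1_baseline.csv"), row.names = FALSE)
  say("  n = ", nrow(source_cohort))

  say("stage 2/6: CGAN twin generation")
  gan_cfg <- config$gan
  gan_cfg$seed <- derive_seed(config$seed, 2L)
  seeds$gan <- gan_cfg$seed
  model <- train_cgan(source_cohort, config$dag, gan_cfg)
  seeds$twins <- derive_seed(config$seed, 3L)
  twins <- generate_twins(model, seed = seeds$twins)
  write_cohort(twins, file.path(out_dir, "twin_cohort.csv"))

  say("stage 3/6: fidelity validation")
  seeds$fidelity <- derive_seed(config$seed, 4L)
  fidelity <- fidelity_report(source_cohort, twins, seed = seeds$fidelity)
  utils::write.csv(fidelity_table(fidelity),
                   file.path(out_dir, "fidelity_report.csv"), row.names = FALSE)
  say("  MASMD = ", sprintf("%.3f", fidelity$masmd))

  say("stage 4/6: propensity matching")
  seeds$matching <- derive_seed(config$seed, 5L)
  conditioned <- condition_twins(twins, caliper = config$caliper,
                                 seed = seeds$matching)
  write_cohort(conditioned$cohort, file.path(out_dir, "matched_cohort.csv"))
  utils::write.csv(conditioned$balance$table,
                   file.path(out_dir, "balance_table.csv"), row.names = FALSE)
  say("  ", nrow(conditioned$matched$pairs), " pairs, balance MASMD = ",
      sprintf("%.3f", conditioned$balance$masmd))

  say("stage 5/6: outcome models")
  models <- lapply(outcome_endpoints(), function(ep) {
    fit_outcome_model(conditioned$cohort, ep, predictors = config$predictors,
                      site_ridge = config$site_ridge)
  })
  names(models) <- outcome_endpoints()
  seeds$table2 <- derive_seed(config$seed, 6L)
  table2 <- render_table2(models, conditioned$cohort, n_boot = config$n_boot,
                          seed = seeds$table2)
  utils::write.csv(table2, file.path(out_dir, "table2_predicted_outcomes.csv"),
                   row.names = FALSE)

  simulation <- NULL; table3 <- NULL; direction <- NULL
  if (length(config$scenarios)) {
    say("stage 6/6: Monte Carlo scenarios")
    seeds$simulation <- derive_seed(config$seed, 7L)
    simulation <- run_simulation(conditioned$cohort, models, config$scenarios,
                                 seed = seeds$simulation)
    table3 <- render_table3(simulation)
    utils::write.csv(table3, file.path(out_dir, "table3_scenarios.csv"),
                     row.names = FALSE)
    ref_signs <- observed_difference_signs(source_cohort)
    direction <- directionality(simulation, ref_signs)
  } else {
    say("no scenarios configured: stopping after the predicted-outcome table")
  }

  if (make_plots) {
    ggplot2::ggsave(file.path(out_dir, "correlation_triple.png"),
                    plot_correlation_triple(fidelity), width = 12, height = 4.2, dpi = 120)
    if (!is.null(simulation)) {
      obs <- observed_rates(source_cohort)
      ggplot2::ggsave(file.path(out_dir, "simulation_distributions.png"),
                      plot_simulation(simulation, obs), width = 9, height = 5, dpi = 120)
    }
  }

  manifest <- list(
    timestamp = format(t0, "%Y-%m-%d %H:%M:%S"),
    seeds = seeds,
    n_source = nrow(source_cohort), n_twins = nrow(twins),
    n_matched_pairs = nrow(conditioned$matched$pairs),
    caliper = config$caliper, site_ridge = config$site_ridge,
    gan_epochs = gan_cfg$epochs, gan_converged = model$converged,
    scenarios = vapply(config$scenarios, `[[`, character(1), "id"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  cfg_file <- file.path(out_dir, "manifest.yaml")
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  say("done")

  invisible(list(source = source_cohort, table1 = table1, model = model,
                 twins = twins, fidelity = fidelity, conditioned = conditioned,
                 models = models, table2 = table2, simulation = simulation,
                 table3 = table3, directionality = direction,
                 manifest = manifest))
}

# Observed per-arm event rates of a cohort (fractions), per endpoint.
observed_rates <- function(cohort) {
  out <- lapply(outcome_endpoints(), function(ep) {
    resp <- endpoint_response(cohort, ep)
    arms <- cohort$treatment[resp$rows]
    c(vka = mean(resp$y[arms == "VKA"]), doac = mean(resp$y[arms == "DOAC"]))
  })
  names(out) <- outcome_endpoints()
  out
}

# Signs of the observed DOAC - VKA differences (ties get sign 0).
observed_difference_signs <- function(cohort) {
  obs <- observed_rates(cohort)
  vapply(obs, function(x) sign(x[["doac"]] - x[["vka"]]), numeric(1))
}

#' Scenario results table
#'
#' One row per scenario x outcome: per-arm mean simulated rates with their
#' empirical 95% CIs and the absolute difference in percentage points
#' (DOAC - VKA).
#'
#' @param result a `simulation_result`.
#' @return data.frame.
#' @export
render_table3 <- function(result) {
  s <- result$summary
  rows <- list()
  for (scen in unique(s$scenario)) {
    for (ep in unique(s$outcome)) {
      v <- s[s$scenario == scen & s$outcome == ep & s$arm == "VKA", ]
      d <- s[s$scenario == scen & s$outcome == ep & s$arm == "DOAC", ]
      if (!nrow(v) || !nrow(d)) next
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = scen, outcome = ep,
        vka = round(v$mean, 1), vka_lo = round(v$ci_lo, 1), vka_hi = round(v$ci_hi, 1),
        doac = round(d$mean, 1), doac_lo = round(d$ci_lo, 1), doac_hi = round(d$ci_hi, 1),
        difference = round(d$mean - v$mean, 1))
    }
  }
  do.call(rbind, rows)
}

#' Text rendering of a scenario table
#'
#' @param table3 data.frame from [render_table3()].
#' @return character vector of aligned lines.
#' @export
format_table3 <- function(table3) {
  hdr <- sprintf("%-14s %-24s %-20s %-20s %6s", "Scenario", "Outcome",
                 "VKA % (95% CI)", "DOAC % (95% CI)", "Delta")
  lines <- vapply(seq_len(nrow(table3)), function(i) {
    r <- table3[i, ]
    sprintf("%-14s %-24s %-20s %-20s %+6.1f", r$scenario, r$outcome,
            sprintf("%.1f [%.1f-%.1f]", r$vka, r$vka_lo, r$vka_hi),
            sprintf("%.1f [%.1f-%.1f]", r$doac, r$doac_lo, r$doac_hi),
            r$difference)
  }, character(1))
  c(hdr, lines)
}

#' Correlation-heatmap triple (real, synthetic, mismatch mask)
#'
#' @param fidelity a `fidelity_report`.
#' @param threshold mismatch threshold on the correlation difference.
#' @return a ggplot object with three facets.
#' @export
plot_correlation_triple <- function(fidelity, threshold = 0.1) {
  melt <- function(m, panel) {
    data.frame(panel = panel,
               x = rep(colnames(m), each = nrow(m)),
               y = rep(rownames(m), times = ncol(m)),
               value = as.vector(m))
  }
  ma <- fidelity$corr_matrices$matrix_a
  mb <- fidelity$corr_matrices$matrix_b
  dd <- (abs(ma - mb) > threshold) * 1
  df <- rbind(melt(ma, "real"), melt(mb, "synthetic"),
              melt(dd, sprintf("|difference| > %.1f", threshold)))
  df$panel <- factor(df$panel, levels = unique(df$panel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  limits = c(-1, 1)) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho")
}

#' Simulated outcome distributions with observed values overlaid
#'
#' Boxplots of the per-iteration simulated rates per scenario, endpoint and
#' arm, with the source cohort's observed rates as points.
#'
#' @param result a `simulation_result`.
#' @param observed named list of per-arm observed rates (fractions) as
#'   produced internally by the pipeline; optional.
#' @return a ggplot object.
#' @export
plot_simulation <- function(result, observed = NULL) {
  rows <- list()
  for (scen in names(result$iterations)) {
    it <- result$iterations[[scen]]
    for (ep in dimnames(it)[[2]]) {
      for (arm in c("vka", "doac")) {
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = scen, outcome = ep, arm = toupper(arm),
          rate = 100 * it[, ep, arm])
      }
    }
  }
  df <- do.call(rbind, rows)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$rate,
                                        fill = .data$arm)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "simulated event rate (%)", fill = NULL)
  if (!is.null(observed)) {
    obs <- do.call(rbind, lapply(names(observed), function(ep) {
      data.frame(outcome = ep, arm = c("VKA", "DOAC"),
                 rate = 100 * unname(observed[[ep]]))
    }))
    p <- p + ggplot2::geom_point(
      data = transform(obs, scenario = "baseline"),
      ggplot2::aes(x = .data$scenario, y = .data$rate, group = .data$arm),
      color = "red", size = 1.6,
      position = ggplot2::position_dodge(width = 0.75))
  }
  p
}
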