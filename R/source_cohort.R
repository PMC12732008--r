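#' Configuration of the synthetic source-cohort emulator
#'
#' Defaults reproduce the published real-world USVT cohort margins: 90
#' patients, 72.2% VKA, per-arm site mixes (SVT/UEDVT/CVT), per-arm
#' comorbidity prevalences, per-arm log-normal labs matched to the printed
#' medians/IQRs, VKA time-in-therapeutic-range as a scaled Beta matched to
#' median 60.9 (IQR 51.4-70.8), follow-up imaging availability of 25/65 VKA
#' and 15/25 DOAC, and arm-conditional outcome rates (complete
#' recanalization among imaged patients 0.36/0.40, recurrence 0.077/0.080,
#' major bleeding 0.108/0.080, death 0.60/0.20 for VKA/DOAC respectively).
#'
#' @param n_total cohort size.
#' @param p_vka probability a patient is VKA-treated.
#' @param seed integer seed (may be overridden in [sample_cohort()]).
#' @param ... named overrides of any default component (see the returned
#'   list for the component names).
#' @return a list of class `source_config`.
#' @export
source_config <- function(n_total = 90, p_vka = 65 / 90, seed = NULL, ...) {
  cfg <- list(
    n_total = n_total,
    p_vka = p_vka,
    sex_female = c(VKA = 33 / 65, DOAC = 16 / 25),
    site_probs = list(VKA = c(SVT = 45, UEDVT = 20, CVT = 0) / 65,
                      DOAC = c(SVT = 10, UEDVT = 13, CVT = 2) / 25),
    age = list(VKA = c(mean = 68.9, sd = 17.2), DOAC = c(mean = 63.9, sd = 18.6),
               bounds = c(18, 100)),
    comorbidity_probs = list(
      VKA = c(hypertension = 39, diabetes = 21, dyslipidemia = 29, obesity = 10,
              smoker = 23, chf = 7, copd_asthma = 18, cerebrovascular = 8,
              ckd = 8, estrogen = 1, liver_disease = 22, active_cancer = 25,
              mps = 0) / 65,
      DOAC = c(hypertension = 9, diabetes = 5, dyslipidemia = 11, obesity = 8,
               smoker = 8, chf = 2, copd_asthma = 5, cerebrovascular = 3,
               ckd = 5, estrogen = 0, liver_disease = 3, active_cancer = 4,
               mps = 1) / 25),
    thrombophilia = c(VKA = 14 / 65, DOAC = 5 / 25),
    antiplatelet = c(VKA = 6 / 65, DOAC = 1 / 25),
    doac_agent_probs = c(apixaban = 7, edoxaban = 7, rivaroxaban = 6,
                         dabigatran = 5) / 25,
    labs = list(
      hemoglobin = list(VKA = c(median = 12.9, q1 = 11.6, q3 = 14.2),
                        DOAC = c(median = 13.6, q1 = 12.3, q3 = 14.9)),
      platelets = list(VKA = c(median = 231, q1 = 178, q3 = 282),
                       DOAC = c(median = 251, q1 = 190, q3 = 315)),
      d_dimer = list(VKA = c(median = 3123, q1 = 2256, q3 = 4050),
                     DOAC = c(median = 2743, q1 = 2080, q3 = 3615))),
    follow_up = list(VKA = c(median = 30.1, q1 = 20.3, q3 = 45.2),
                     DOAC = c(median = 27.9, q1 = 19.8, q3 = 42.1)),
    ttr = c(median = 60.9, q1 = 51.4, q3 = 70.8),
    p_imaging = c(VKA = 25 / 65, DOAC = 15 / 25),
    outcome_rates = list(
      recanalization_complete = c(VKA = 0.36, DOAC = 0.40),
      recurrence = c(VKA = 0.077, DOAC = 0.080),
      major_bleed = c(VKA = 0.108, DOAC = 0.080),
      death = c(VKA = 0.60, DOAC = 0.20)),
    seed = seed
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  validate_source_config(cfg)
  structure(cfg, class = "source_config")
}

validate_source_config <- function(cfg) {
  chk01 <- function(p, what) {
    if (any(p < 0 | p > 1)) stop("config error: ", what, " outside [0,1]", call. = FALSE)
  }
  chk01(cfg$p_vka, "p_vka")
  chk01(unlist(cfg$comorbidity_probs), "comorbidity probability")
  chk01(unlist(cfg$outcome_rates), "outcome rate")
  chk01(cfg$p_imaging, "imaging probability")
  chk01(cfg$sex_female, "sex probability")
  for (arm in names(cfg$site_probs)) {
    if (abs(sum(cfg$site_probs[[arm]]) - 1) > 1e-8) {
      stop("config error: site probabilities for ", arm, " do not sum to 1",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

# Log-normal parameters from a printed median and IQR.
lognormal_params <- function(q) {
  c(meanlog = log(q[["median"]]),
    sdlog = (log(q[["q3"]]) - log(q[["q1"]])) / (2 * stats::qnorm(0.75)))
}

# Beta(a, b) on [0, 100] matched to the printed TTR median and quartiles.
ttr_beta_params <- function(q) {
  target <- c(q[["q1"]], q[["median"]], q[["q3"]]) / 100
  obj <- function(par) {
    sum((stats::qbeta(c(0.25, 0.5, 0.75), exp(par[1]), exp(par[2])) - target)^2)
  }
  par <- stats::optim(c(log(5), log(3)), obj)$par
  c(shape1 = exp(par[1]), shape2 = exp(par[2]))
}

#' Sample a synthetic source cohort
#'
#' Draws `n_total` patient records from the configured arm-conditional
#' marginals: treatment is Bernoulli, and sex, site, age, comorbidities,
#' labs, TTR, follow-up, imaging availability and the four outcomes are each
#' drawn conditional on the treatment arm (the arm-specific prevalences are
#' the only dependencies the published tables identify). Deterministic under
#' a fixed seed.
#'
#' @param config a [source_config()].
#' @param seed integer seed; overrides `config$seed`.
#' @return a `usvt_cohort` of `config$n_total` records.
#' @export
sample_cohort <- function(config = source_config(), seed = config$seed) {
  validate_source_config(config)
  with_seed(seed, {
    n <- config$n_total
    arm <- ifelse(stats::runif(n) < config$p_vka, "VKA", "DOAC")
    is_vka <- arm == "VKA"

    pick <- function(per_arm) unname(per_arm[arm])
    draw_flag <- function(per_arm) as.integer(stats::runif(n) < pick(per_arm))

    age <- numeric(n)
    for (a in c("VKA", "DOAC")) {
      idx <- which(arm == a)
      pars <- config$age[[a]]
      vals <- stats::rnorm(length(idx), pars[["mean"]], pars[["sd"]])
      # rejection sampling keeps the configured location/scale inside the
      # plausible adult range
      bad <- which(vals < config$age$bounds[1] | vals > config$age$bounds[2])
      while (length(bad)) {
        vals[bad] <- stats::rnorm(length(bad), pars[["mean"]], pars[["sd"]])
        bad <- bad[vals[bad] < config$age$bounds[1] | vals[bad] > config$age$bounds[2]]
      }
      age[idx] <- vals
    }

    sex <- ifelse(stats::runif(n) < pick(config$sex_female), "female", "male")
    site <- character(n)
    for (a in c("VKA", "DOAC")) {
      idx <- which(arm == a)
      p <- config$site_probs[[a]]
      site[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
    }

    df <- data.frame(age = round(age, 1), sex = sex, usvt_site = site,
                     treatment = arm, stringsAsFactors = FALSE)
    df$doac_agent <- NA_character_
    n_doac <- sum(!is_vka)
    if (n_doac) {
      df$doac_agent[!is_vka] <- sample(names(config$doac_agent_probs), n_doac,
                                       replace = TRUE, prob = config$doac_agent_probs)
    }
    for (nm in comorbidity_names()) {
      df[[nm]] <- draw_flag(c(VKA = config$comorbidity_probs$VKA[[nm]],
                              DOAC = config$comorbidity_probs$DOAC[[nm]]))
    }
    df$thrombophilia <- draw_flag(config$thrombophilia)

    draw_lab <- function(per_arm_q, digits) {
      out <- numeric(n)
      for (a in c("VKA", "DOAC")) {
        idx <- which(arm == a)
        pars <- lognormal_params(per_arm_q[[a]])
        out[idx] <- stats::rlnorm(length(idx), pars[["meanlog"]], pars[["sdlog"]])
      }
      round(out, digits)
    }
    df$hemoglobin <- draw_lab(config$labs$hemoglobin, 1)
    df$platelets <- draw_lab(config$labs$platelets, 0)
    df$d_dimer <- draw_lab(config$labs$d_dimer, 0)

    df$ttr <- NA_real_
    n_vka <- sum(is_vka)
    if (n_vka) {
      bp <- ttr_beta_params(config$ttr)
      df$ttr[is_vka] <- round(100 * stats::rbeta(n_vka, bp[["shape1"]], bp[["shape2"]]), 1)
    }
    df$antiplatelet <- draw_flag(config$antiplatelet)
    df$follow_up <- draw_lab(config$follow_up, 1)

    imaged <- stats::runif(n) < pick(config$p_imaging)
    recan_complete <- stats::runif(n) < pick(config$outcome_rates$recanalization_complete)
    df$recanalization <- ifelse(!imaged, "missing",
                                ifelse(recan_complete, "complete", "not_complete"))
    df$recurrence <- draw_flag(config$outcome_rates$recurrence)
    df$major_bleed <- draw_flag(config$outcome_rates$major_bleed)
    df$death <- draw_flag(config$outcome_rates$death)

    as_cohort(df, usvt_schema(), label = "synthetic source cohort")
  })
}

#' Simulate an INR measurement series
#'
#' Mean-reverting AR(1) walk around INR 2.5 whose stationary spread is
#' calibrated so that the expected fraction of interpolated time inside the
#' therapeutic range \[2.0, 3.0\] approximates `control_quality`. At
#' `control_quality = 100` the series is constant at 2.5 (TTR exactly 100);
#' at `control_quality = 0` all values are held outside the range (TTR 0).
#'
#' @param n_points number of INR measurements (>= 2).
#' @param days total span of the series in days.
#' @param control_quality target time-in-range percentage in \[0, 100\].
#' @param seed integer seed.
#' @param persistence AR(1) autocorrelation between consecutive visits.
#' @return an object of class `inr_series` with `times`, `values` and
#'   `target_range`.
#' @export
simulate_inr_series <- function(n_points, days = 180, control_quality = 60,
                                seed = NULL, persistence = 0.8) {
  if (n_points < 2) stop("insufficient series: need at least 2 INR points", call. = FALSE)
  stopifnot(control_quality >= 0, control_quality <= 100, days > 0)
  with_seed(seed, {
    times <- seq(0, days, length.out = n_points)
    f <- control_quality / 100
    if (f >= 0.999) {
      values <- rep(2.5, n_points)
    } else if (f <= 0.001) {
      values <- stats::runif(n_points, 3.6, 4.8)  # held above range
    } else {
      sigma <- 0.5 / stats::qnorm((1 + f) / 2)  # P(|INR - 2.5| < 0.5) = f
      eps_sd <- sigma * sqrt(1 - persistence^2)
      values <- numeric(n_points)
      values[1] <- 2.5 + stats::rnorm(1, 0, sigma)
      for (i in 2:n_points) {
        values[i] <- 2.5 + persistence * (values[i - 1] - 2.5) + stats::rnorm(1, 0, eps_sd)
      }
      values <- pmax(values, 0.3)
    }
    structure(list(times = times, values = values, target_range = c(2, 3)),
              class = "inr_series")
  })
}

#' Rosendaal time in therapeutic range
#'
#' Linear interpolation between consecutive INR measurements; TTR is the
#' percentage of total elapsed time the interpolated INR spends inside the
#' target range (boundaries inclusive). The in-range time of each segment is
#' computed exactly from the crossing points of the linear path.
#'
#' @param series an `inr_series` (or a list with `times`, `values`,
#'   `target_range`).
#' @return TTR as a percentage in \[0, 100\].
#' @export
rosendaal_ttr <- function(series) {
  t <- series$times; v <- series$values
  rng <- series$target_range %||% c(2, 3)
  if (length(t) < 2) stop("insufficient series: need at least 2 INR points", call. = FALSE)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  total <- t[length(t)] - t[1]
  if (total <= 0) stop("undefined TTR: zero elapsed time", call. = FALSE)
  lo <- rng[1]; hi <- rng[2]
  in_time <- 0
  for (i in seq_len(length(t) - 1)) {
    dt <- t[i + 1] - t[i]
    v1 <- v[i]; v2 <- v[i + 1]
    if (v1 == v2) {
      if (v1 >= lo && v1 <= hi) in_time <- in_time + dt
    } else {
      s_lo <- (lo - v1) / (v2 - v1)
      s_hi <- (hi - v1) / (v2 - v1)
      a <- max(0, min(s_lo, s_hi))
      b <- min(1, max(s_lo, s_hi))
      if (b > a) in_time <- in_time + (b - a) * dt
    }
  }
  100 * in_time / total
}
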