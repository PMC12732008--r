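# Shared fixtures built in code. Seeds are fixed so the suite is
# deterministic.

# A small two-arm cohort with exact event counts, for closed-form logistic
# checks: n_vka / n_doac records with the given numbers of recurrence
# events and imaged/complete recanalizations.
two_group_cohort <- function(n_vka = 50, n_doac = 25,
                             recur_vka = 18, recur_doac = 10,
                             imaged_vka = n_vka, complete_vka = round(0.36 * n_vka),
                             imaged_doac = n_doac, complete_doac = round(0.4 * n_doac)) {
  block <- function(n, arm, recur, imaged, complete) {
    data.frame(
      age = seq(40, 80, length.out = n),
      sex = rep(c("female", "male"), length.out = n),
      usvt_site = rep(c("SVT", "UEDVT"), length.out = n),
      treatment = arm,
      doac_agent = if (arm == "DOAC") "apixaban" else NA_character_,
      hypertension = 0L, diabetes = 0L, dyslipidemia = 0L, obesity = 0L,
      smoker = 0L, chf = 0L, copd_asthma = 0L, cerebrovascular = 0L,
      ckd = 0L, estrogen = 0L, liver_disease = 0L,
      active_cancer = rep(c(1L, 0L), length.out = n),
      mps = 0L, thrombophilia = 0L,
      hemoglobin = 13, platelets = 240, d_dimer = 3000,
      ttr = if (arm == "VKA") 60 else NA_real_,
      antiplatelet = 0L,
      follow_up = 24,
      recanalization = c(rep("complete", complete),
                         rep("not_complete", imaged - complete),
                         rep("missing", n - imaged)),
      recurrence = c(rep(1L, recur), rep(0L, n - recur)),
      major_bleed = 0L, death = 0L,
      stringsAsFactors = FALSE)
  }
  as_cohort(rbind(block(n_vka, "VKA", recur_vka, imaged_vka, complete_vka),
                  block(n_doac, "DOAC", recur_doac, imaged_doac, complete_doac)))
}

# Fine-grid numerical oracle for the Rosendaal TTR: densely interpolate the
# piecewise-linear INR path and count grid points inside the range.
grid_ttr_oracle <- function(times, values, lo = 2, hi = 3, n_grid = 2e5) {
  g <- seq(times[1], times[length(times)], length.out = n_grid)
  v <- stats::approx(times, values, xout = g)$y
  100 * mean(v >= lo & v <= hi)
}

# Brute-force double-sum oracle for the unbiased squared-MMD estimator.
mmd2_oracle <- function(A, B, sigma) {
  k <- function(x, y) exp(-sum((x - y)^2) / (2 * sigma^2))
  n <- nrow(A); m <- nrow(B)
  saa <- 0; for (i in 1:n) for (j in 1:n) if (i != j) saa <- saa + k(A[i, ], A[j, ])
  sbb <- 0; for (i in 1:m) for (j in 1:m) if (i != j) sbb <- sbb + k(B[i, ], B[j, ])
  sab <- 0; for (i in 1:n) for (j in 1:m) sab <- sab + k(A[i, ], B[j, ])
  saa / (n * (n - 1)) + sbb / (m * (m - 1)) - 2 * sab / (n * m)
}
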