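#' Absolute standardized mean difference
#'
#' Balance/fidelity metric with the pooled-variance (Cohen's d style)
#' denominator. For continuous samples `|m_a - m_b| / sqrt((v_a + v_b)/2)`;
#' for binary samples `|p_a - p_b| / sqrt((p_a(1-p_a) + p_b(1-p_b))/2)`;
#' for categorical variables with more than two levels, the mean of the
#' per-level binary ASMDs. Zero pooled variance yields 0 when the means are
#' equal and `Inf` otherwise.
#'
#' @param sample_a,sample_b vectors of values of the same variable in the
#'   two samples (`NA`s dropped). For `kind = "categorical"` these are label
#'   vectors.
#' @param kind one of `"continuous"`, `"binary"`, `"categorical"`.
#' @param levels optional explicit level set for categorical variables.
#' @return a nonnegative scalar.
#' @export
asmd <- function(sample_a, sample_b, kind = c("continuous", "binary", "categorical"),
                 levels = NULL) {
  kind <- match.arg(kind)
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  if (!length(a) || !length(b)) stop("asmd: empty sample", call. = FALSE)
  asmd_num <- function(ma, mb, va, vb) {
    pooled <- sqrt((va + vb) / 2)
    d <- abs(ma - mb)
    if (pooled == 0) return(if (d == 0) 0 else Inf)
    d / pooled
  }
  switch(kind,
    continuous = asmd_num(mean(a), mean(b), stats::var(a), stats::var(b)),
    binary = {
      pa <- mean(a); pb <- mean(b)
      asmd_num(pa, pb, pa * (1 - pa), pb * (1 - pb))
    },
    categorical = {
      levels <- levels %||% sort(unique(c(a, b)))
      if (length(levels) == 2) {
        asmd(as.numeric(a == levels[2]), as.numeric(b == levels[2]), "binary")
      } else {
        mean(vapply(levels, function(l) {
          asmd(as.numeric(a == l), as.numeric(b == l), "binary")
        }, numeric(1)))
      }
    })
}

#' Mean absolute standardized mean difference across variables
#'
#' @param cohort_a,cohort_b two `usvt_cohort`s (or data.frames sharing the
#'   schema of `cohort_a`).
#' @param variables variables to compare; defaults to every schema variable
#'   present in both cohorts except structurally missing ones.
#' @param schema schema used to resolve variable kinds.
#' @return list with `masmd`, `sd` (sample SD over variables) and the
#'   per-variable ASMD vector.
#' @export
masmd <- function(cohort_a, cohort_b, variables = NULL,
                  schema = schema_of(cohort_a) %||% usvt_schema()) {
  variables <- variables %||% intersect(names(schema), intersect(names(cohort_a), names(cohort_b)))
  if (!length(variables)) stop("masmd: empty variable list", call. = FALSE)
  per_var <- vapply(variables, function(v) {
    s <- schema[[v]]
    asmd(cohort_a[[v]], cohort_b[[v]], s$kind,
         levels = if (s$kind == "categorical") s$levels[s$levels %in% c(cohort_a[[v]], cohort_b[[v]])])
  }, numeric(1))
  list(masmd = mean(per_var),
       sd = if (length(per_var) > 1) stats::sd(per_var) else 0,
       per_variable = per_var)
}

#' Unbiased squared maximum mean discrepancy
#'
#' Gaussian-kernel U-statistic estimate of the squared MMD between two
#' multivariate samples. The automatic bandwidth is the median pairwise
#' Euclidean distance of the pooled sample (median heuristic).
#'
#' @param matrix_a,matrix_b numeric matrices with identical columns
#'   (rows = records), expected to be standardized.
#' @param bandwidth Gaussian kernel bandwidth sigma, or `"auto"`.
#' @return list with `mmd2` and the `bandwidth` used.
#' @export
mmd2 <- function(matrix_a, matrix_b, bandwidth = "auto") {
  matrix_a <- as.matrix(matrix_a); matrix_b <- as.matrix(matrix_b)
  n <- nrow(matrix_a); m <- nrow(matrix_b)
  if (n < 2 || m < 2) stop("insufficient sample: need >= 2 rows per matrix", call. = FALSE)
  stopifnot(ncol(matrix_a) == ncol(matrix_b))
  pooled <- rbind(matrix_a, matrix_b)
  d2 <- as.matrix(stats::dist(pooled))^2
  if (identical(bandwidth, "auto")) {
    dvec <- sqrt(d2[upper.tri(d2)])
    bandwidth <- stats::median(dvec[dvec > 0])
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  K <- exp(-d2 / (2 * bandwidth^2))
  ia <- seq_len(n); ib <- n + seq_len(m)
  kaa <- K[ia, ia]; kbb <- K[ib, ib]; kab <- K[ia, ib, drop = FALSE]
  term_aa <- (sum(kaa) - n) / (n * (n - 1))     # off-diagonal mean
  term_bb <- (sum(kbb) - m) / (m * (m - 1))
  term_ab <- mean(kab)
  list(mmd2 = term_aa + term_bb - 2 * term_ab, bandwidth = bandwidth)
}

#' Permutation null for the squared MMD
#'
#' @inheritParams mmd2
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list with the observed `mmd2`, permutation `p_value` and the
#'   vector of `null` statistics.
#' @export
mmd2_permutation <- function(matrix_a, matrix_b, bandwidth = "auto",
                             n_perm = 200, seed = NULL) {
  obs <- mmd2(matrix_a, matrix_b, bandwidth)
  n <- nrow(matrix_a)
  pooled <- rbind(as.matrix(matrix_a), as.matrix(matrix_b))
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(nrow(pooled))
      mmd2(pooled[idx[seq_len(n)], , drop = FALSE],
           pooled[idx[-seq_len(n)], , drop = FALSE], obs$bandwidth)$mmd2
    }, numeric(1))
    list(mmd2 = obs$mmd2, bandwidth = obs$bandwidth,
         p_value = (1 + sum(null >= obs$mmd2)) / (1 + n_perm), null = null)
  })
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Supremum distance between the empirical CDFs with the asymptotic
#' p-value.
#'
#' @param x,y continuous samples (`NA`s dropped).
#' @return list with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("ks_two_sample: empty sample", call. = FALSE)
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

# Fixed documented encoding of mixed clinical variables for rank
# correlations: binary flags as 0/1, site ordinal SVT=0 < UEDVT=1 < CVT=2,
# treatment VKA=0 / DOAC=1, sex female=0 / male=1, recanalization
# not_complete=0 / complete=1 (missing -> NA).
encode_ordinal <- function(cohort, variables, schema = schema_of(cohort) %||% usvt_schema()) {
  enc <- lapply(variables, function(v) {
    s <- schema[[v]]
    x <- cohort[[v]]
    if (s$kind == "categorical") {
      if (v == "recanalization") {
        out <- ifelse(x == "missing", NA_real_, as.numeric(x == "complete"))
      } else {
        out <- as.numeric(match(x, s$levels) - 1)
      }
      out
    } else as.numeric(x)
  })
  names(enc) <- variables
  as.data.frame(enc)
}

#' Spearman correlation-structure similarity
#'
#' Computes the Spearman rank-correlation matrices of the encoded variables
#' in two cohorts and the fraction of off-diagonal variable pairs whose
#' correlations differ by less than `threshold` in absolute value.
#' Variables constant in either cohort are excluded and reported.
#'
#' @param cohort_a,cohort_b the two cohorts.
#' @param variables variables to correlate (>= 2).
#' @param threshold similarity tolerance on the correlation difference.
#' @param schema schema used for the ordinal encoding.
#' @return list with `matrix_a`, `matrix_b`, `fraction_similar`, and
#'   `excluded` (constant variables).
#' @export
correlation_similarity <- function(cohort_a, cohort_b, variables,
                                   threshold = 0.1,
                                   schema = schema_of(cohort_a) %||% usvt_schema()) {
  if (length(variables) < 2) stop("need >= 2 variables", call. = FALSE)
  ea <- encode_ordinal(cohort_a, variables, schema)
  eb <- encode_ordinal(cohort_b, variables, schema)
  is_const <- function(x) length(unique(x[!is.na(x)])) < 2
  excluded <- variables[vapply(variables, function(v) is_const(ea[[v]]) || is_const(eb[[v]]), logical(1))]
  keep <- setdiff(variables, excluded)
  if (length(keep) < 2) stop("fewer than 2 non-constant variables", call. = FALSE)
  # pairwise deletion can leave locally-constant pairs; their NA entries are
  # dropped from the similarity fraction
  ma <- suppressWarnings(stats::cor(ea[keep], method = "spearman",
                                    use = "pairwise.complete.obs"))
  mb <- suppressWarnings(stats::cor(eb[keep], method = "spearman",
                                    use = "pairwise.complete.obs"))
  diff <- abs(ma - mb)[upper.tri(ma)]
  list(matrix_a = ma, matrix_b = mb,
       fraction_similar = mean(diff < threshold, na.rm = TRUE),
       excluded = excluded)
}

# Total-variation distance between the empirical level distributions of a
# categorical variable (reported for categorical marginals where KS is
# invalid due to ties).
tv_distance <- function(a, b, levels) {
  pa <- vapply(levels, function(l) mean(a == l, na.rm = TRUE), numeric(1))
  pb <- vapply(levels, function(l) mean(b == l, na.rm = TRUE), numeric(1))
  sum(abs(pa - pb)) / 2
}

#' Full real-vs-synthetic fidelity report
#'
#' Assembles the per-variable ASMDs (with MASMD and its SD), two-sample
#' Kolmogorov-Smirnov tests for continuous variables, total-variation
#' distances for categorical marginals, the unbiased squared MMD with a
#' permutation p-value, and the Spearman correlation-structure similarity
#' fraction, against the 0.10 target / 0.20 acceptability thresholds.
#'
#' @param real,synthetic the two cohorts.
#' @param variables variables entering ASMD / correlation comparisons;
#'   default: all shared schema variables except `doac_agent` and `ttr`
#'   (structurally missing by arm).
#' @param mmd_variables continuous variables entering the MMD (default: the
#'   conditioning covariate `age` plus the labs and follow-up).
#' @param n_perm permutations for the MMD null.
#' @param seed integer seed for the permutation null.
#' @return an object of class `fidelity_report`.
#' @export
fidelity_report <- function(real, synthetic, variables = NULL,
                            mmd_variables = c("age", "hemoglobin", "platelets",
                                              "d_dimer", "follow_up"),
                            n_perm = 200, seed = NULL) {
  schema <- schema_of(real) %||% usvt_schema()
  variables <- variables %||% setdiff(intersect(names(schema), names(synthetic)),
                                      c("doac_agent", "ttr"))
  bal <- masmd(real, synthetic, variables, schema)
  kinds <- schema_kinds(schema)[variables]
  ks <- lapply(variables[kinds == "continuous"], function(v) {
    ks_two_sample(real[[v]], synthetic[[v]])
  })
  names(ks) <- variables[kinds == "continuous"]
  tv <- vapply(variables[kinds %in% c("categorical", "binary")], function(v) {
    s <- schema[[v]]
    lv <- if (s$kind == "binary") c(0, 1) else s$levels
    tv_distance(real[[v]], synthetic[[v]], lv)
  }, numeric(1))
  std <- function(cohort) {
    m <- as.matrix(as.data.frame(cohort)[mmd_variables])
    m
  }
  pooled <- rbind(std(real), std(synthetic))
  mu <- colMeans(pooled); sdv <- apply(pooled, 2, stats::sd)
  sdv[sdv == 0] <- 1
  za <- sweep(sweep(std(real), 2, mu), 2, sdv, "/")
  zb <- sweep(sweep(std(synthetic), 2, mu), 2, sdv, "/")
  mmd <- mmd2_permutation(za, zb, n_perm = n_perm, seed = seed)
  corr <- correlation_similarity(real, synthetic, variables, schema = schema)
  structure(list(
    per_variable_asmd = bal$per_variable,
    masmd = bal$masmd, masmd_sd = bal$sd,
    ks_results = ks, tv_distances = tv,
    mmd2 = mmd$mmd2, mmd_bandwidth = mmd$bandwidth, mmd_p_value = mmd$p_value,
    corr_similarity = corr$fraction_similar,
    corr_matrices = corr[c("matrix_a", "matrix_b")],
    corr_excluded = corr$excluded,
    thresholds = c(target = 0.10, acceptable = 0.20),
    pass_target = bal$masmd < 0.10,
    pass_acceptable = bal$masmd <= 0.20
  ), class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("<fidelity_report>\n")
  cat(sprintf("  MASMD: %.3f (±%.3f)  [target <%.2f, acceptable <=%.2f] -> %s\n",
              x$masmd, x$masmd_sd, x$thresholds["target"], x$thresholds["acceptable"],
              if (x$pass_target) "target met" else if (x$pass_acceptable) "acceptable" else "FAIL"))
  cat(sprintf("  MMD^2: %.4f (sigma=%.2f, perm p=%.3f)\n", x$mmd2, x$mmd_bandwidth, x$mmd_p_value))
  cat(sprintf("  Spearman similarity (|drho|<0.1): %.1f%%\n", 100 * x$corr_similarity))
  worst <- sort(x$per_variable_asmd, decreasing = TRUE)[seq_len(min(3, length(x$per_variable_asmd)))]
  cat("  worst ASMDs: ", paste(sprintf("%s=%.3f", names(worst), worst), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Render a fidelity report as a per-variable data.frame
#'
#' @param report a `fidelity_report`.
#' @return data.frame with one row per variable (ASMD, KS statistic and
#'   p-value where applicable, total-variation distance where applicable).
#' @export
fidelity_table <- function(report) {
  vars <- names(report$per_variable_asmd)
  data.frame(
    variable = vars,
    asmd = unname(report$per_variable_asmd),
    ks_statistic = vapply(vars, function(v)
      if (v %in% names(report$ks_results)) report$ks_results[[v]]$statistic else NA_real_, numeric(1)),
    ks_p = vapply(vars, function(v)
      if (v %in% names(report$ks_results)) report$ks_results[[v]]$p_value else NA_real_, numeric(1)),
    tv_distance = vapply(vars, function(v)
      if (v %in% names(report$tv_distances)) report$tv_distances[[v]] else NA_real_, numeric(1)),
    stringsAsFactors = FALSE
  )
}
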