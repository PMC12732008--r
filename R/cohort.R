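#' Construct a validated cohort
#'
#' Wraps a patient-level data.frame together with its schema after checking
#' every record against the schema domains and the structural invariants
#' (TTR defined iff VKA, DOAC agent defined iff DOAC, age >= 18,
#' follow-up >= 0).
#'
#' @param data data.frame with one row per patient and one column per schema
#'   variable.
#' @param schema a [cohort_schema()]; defaults to [usvt_schema()].
#' @param label free-text cohort label.
#' @return an object of class `usvt_cohort` (a data.frame).
#' @export
as_cohort <- function(data, schema = usvt_schema(), label = "") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(schema), names(data))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- data[names(schema)]
  problems <- validate_cohort_rows(data, schema)
  if (length(problems)) {
    stop("validation error:\n  ", paste(problems, collapse = "\n  "), call. = FALSE)
  }
  structure(data, schema = schema, label = label,
            class = c("usvt_cohort", "data.frame"))
}

#' @export
print.usvt_cohort <- function(x, ...) {
  lab <- attr(x, "label")
  cat("<usvt_cohort> ", nrow(x), " patients",
      if (nzchar(lab)) paste0(" [", lab, "]"), "\n", sep = "")
  if (nrow(x)) {
    tr <- table(x$treatment)
    cat("  treatment: ", paste(sprintf("%s=%d", names(tr), tr), collapse = ", "), "\n", sep = "")
    st <- table(x$usvt_site)
    cat("  site:      ", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
#' @rdname as_cohort
#' @param x object to extract the schema from.
schema_of <- function(x) attr(x, "schema")

# Returns a character vector of row-level problems (empty when valid).
validate_cohort_rows <- function(data, schema) {
  problems <- character(0)
  note <- function(rows, var, what) {
    if (length(rows)) {
      sprintf("row %s, variable '%s': %s", paste(rows, collapse = ","), var, what)
    } else character(0)
  }
  for (s in schema) {
    v <- data[[s$name]]
    if (s$kind == "categorical") {
      bad <- which(!is.na(v) & !(v %in% s$levels))
      problems <- c(problems, note(bad, s$name, "out-of-domain level"))
    } else if (s$kind == "binary") {
      bad <- which(!is.na(v) & !(v %in% c(0, 1)))
      problems <- c(problems, note(bad, s$name, "not 0/1"))
    } else {
      if (!is.numeric(v)) {
        problems <- c(problems, sprintf("variable '%s': not numeric", s$name))
        next
      }
    }
    if (!s$missing_allowed) {
      bad <- which(is.na(v))
      problems <- c(problems, note(bad, s$name, "missing value not allowed"))
    }
  }
  if (!nrow(data)) return(problems)
  if (is.numeric(data$age)) {
    problems <- c(problems, note(which(data$age < 18), "age", "must be >= 18"))
  }
  if (is.numeric(data$follow_up)) {
    problems <- c(problems, note(which(data$follow_up < 0), "follow_up", "must be >= 0"))
  }
  is_vka <- data$treatment == "VKA"
  problems <- c(problems,
    note(which(!is.na(data$ttr) & !is_vka), "ttr", "TTR defined only for VKA"),
    note(which(is.na(data$ttr) & is_vka), "ttr", "TTR required for VKA"),
    note(which(!is.na(data$doac_agent) & is_vka), "doac_agent", "agent defined only for DOAC"),
    note(which(is.na(data$doac_agent) & !is_vka), "doac_agent", "agent required for DOAC"))
  problems
}

#' Read a cohort CSV
#'
#' Comma-separated, UTF-8, one header row, missing values as empty strings.
#' Rows violating the schema invariants are rejected with their row index.
#'
#' @param path CSV file.
#' @inheritParams as_cohort
#' @return a `usvt_cohort`.
#' @export
read_cohort <- function(path, schema = usvt_schema(), label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  kinds <- schema_kinds(schema)
  classes <- ifelse(kinds == "continuous", "numeric",
                    ifelse(kinds == "binary", "integer", "character"))
  names(classes) <- names(schema)
  data <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                          fileEncoding = "UTF-8")
  missing_cols <- setdiff(names(schema), names(data))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(schema)) {
    data[[nm]] <- switch(classes[[nm]],
                         numeric = as.numeric(data[[nm]]),
                         integer = as.integer(data[[nm]]),
                         character = as.character(data[[nm]]))
  }
  as_cohort(data, schema, label = label)
}

#' Write a cohort CSV
#'
#' @param cohort a `usvt_cohort`.
#' @param path output file.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Percentage with one-decimal clinical rounding
#'
#' @param events event count.
#' @param denom denominator (> 0).
#' @return `100 * events / denom` rounded to one decimal (half away from
#'   zero).
#' @export
proportion <- function(events, denom) {
  if (any(denom == 0)) stop("undefined proportion: zero denominator", call. = FALSE)
  stopifnot(all(events >= 0), all(events <= denom))
  round_half_up(100 * events / denom, 1)
}

# Decide the between-group test for a contingency table: Fisher's exact test
# iff any expected cell count under independence is < 5, chi-square otherwise.
select_categorical_test <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) "fisher" else "chisq"
}

run_categorical_test <- function(tab) {
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(list(test = "none", p = NA_real_))
  test <- select_categorical_test(tab)
  p <- if (test == "fisher") {
    stats::fisher.test(tab, workspace = 2e6)$p.value
  } else {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  list(test = test, p = p)
}

#' Baseline ("Table 1 style") cohort summary
#'
#' Summarizes every schema variable by a binary grouping variable.
#' Continuous variables are summarized mean (SD) or median (IQR) depending on
#' a pooled Shapiro-Wilk normality test at alpha = 0.05, and compared with
#' Student's t-test (normal) or the Mann-Whitney U test (non-normal).
#' Categorical and binary variables are reported as counts (percent) per
#' level and compared with the chi-square test, or Fisher's exact test when
#' any expected cell count is below five. Recanalization is summarized over
#' patients with available follow-up imaging only (complete-case).
#'
#' @param cohort a `usvt_cohort`.
#' @param group_var name of a binary grouping variable (default
#'   `"treatment"`).
#' @param shapiro_alpha normality threshold for the parametric /
#'   non-parametric switch.
#' @return a data.frame of class `baseline_table` with one row per variable
#'   (continuous) or variable level (categorical), formatted summaries per
#'   group, the test used and its p-value.
#' @export
summarize_cohort <- function(cohort, group_var = "treatment", shapiro_alpha = 0.05) {
  schema <- schema_of(cohort)
  g <- cohort[[group_var]]
  lev <- if (schema[[group_var]]$kind == "categorical") {
    schema[[group_var]]$levels
  } else c(0, 1)
  lev <- lev[lev %in% unique(g)]
  if (length(unique(g)) != 2) {
    stop("degenerate group: '", group_var, "' must have exactly two non-empty levels",
         call. = FALSE)
  }
  g1 <- g == lev[1]; g2 <- g == lev[2]

  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(..., stringsAsFactors = FALSE)

  for (s in schema) {
    if (s$name == group_var) next
    v <- cohort[[s$name]]
    if (s$kind == "continuous") {
      vv <- v[!is.na(v)]
      if (!length(vv)) next
      normal <- length(unique(vv)) > 2 && length(vv) >= 3 &&
        stats::shapiro.test(vv)$p.value >= shapiro_alpha
      fmt <- function(x) {
        x <- x[!is.na(x)]
        if (!length(x)) return("-")
        if (normal) sprintf("%.1f (±%.1f)", mean(x), stats::sd(x))
        else sprintf("%.1f (%.1f-%.1f)", stats::median(x),
                     stats::quantile(x, 0.25), stats::quantile(x, 0.75))
      }
      both <- sum(!is.na(v[g1])) > 1 && sum(!is.na(v[g2])) > 1
      p <- if (!both) NA_real_
      else if (normal) stats::t.test(v[g1], v[g2])$p.value
      else suppressWarnings(stats::wilcox.test(v[g1], v[g2], exact = FALSE))$p.value
      add(variable = s$name, level = NA_character_, kind = "continuous",
          summary_total = fmt(v), summary_g1 = fmt(v[g1]), summary_g2 = fmt(v[g2]),
          count_total = NA_real_, count_g1 = NA_real_, count_g2 = NA_real_,
          pct_total = NA_real_, pct_g1 = NA_real_, pct_g2 = NA_real_,
          test = if (!both) "none" else if (normal) "t" else "mann-whitney",
          p_value = p, p_label = format_p(p))
    } else {
      if (s$name == "recanalization") {
        keep <- v != "missing"
        v_use <- v[keep]; g1_use <- g1[keep]; g2_use <- g2[keep]
        levels_use <- setdiff(s$levels, "missing")
      } else {
        keep <- !is.na(v)
        v_use <- v[keep]; g1_use <- g1[keep]; g2_use <- g2[keep]
        levels_use <- if (s$kind == "binary") c(0, 1) else s$levels
      }
      if (!length(v_use)) next
      tab <- rbind(vapply(levels_use, function(l) sum(v_use[g1_use] == l), numeric(1)),
                   vapply(levels_use, function(l) sum(v_use[g2_use] == l), numeric(1)))
      res <- if (sum(g1_use) == 0 || sum(g2_use) == 0) {
        list(test = "none", p = NA_real_)  # variable observed in one arm only
      } else run_categorical_test(t(tab))
      report_levels <- if (s$kind == "binary") list(1) else as.list(levels_use)
      for (l in report_levels) {
        n_t <- sum(v_use == l); n_1 <- sum(v_use[g1_use] == l); n_2 <- sum(v_use[g2_use] == l)
        d_t <- length(v_use); d_1 <- sum(g1_use); d_2 <- sum(g2_use)
        fmt_np <- function(n, d) if (d == 0) "-" else sprintf("%d (%.1f)", n, proportion(n, d))
        add(variable = s$name,
            level = if (s$kind == "binary") NA_character_ else as.character(l),
            kind = s$kind,
            summary_total = fmt_np(n_t, d_t), summary_g1 = fmt_np(n_1, d_1),
            summary_g2 = fmt_np(n_2, d_2),
            count_total = n_t, count_g1 = n_1, count_g2 = n_2,
            pct_total = if (d_t) proportion(n_t, d_t) else NA_real_,
            pct_g1 = if (d_1) proportion(n_1, d_1) else NA_real_,
            pct_g2 = if (d_2) proportion(n_2, d_2) else NA_real_,
            test = res$test, p_value = res$p, p_label = format_p(res$p))
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "summary_g1"] <- paste0("summary_", lev[1])
  names(out)[names(out) == "summary_g2"] <- paste0("summary_", lev[2])
  attr(out, "groups") <- lev
  class(out) <- c("baseline_table", "data.frame")
  out
}

#' Deterministic reference cohort matching the printed study margins
#'
#' A synthetic 90-patient reconstruction whose per-arm categorical counts
#' equal the published baseline table of the real-world study: 65 VKA / 25
#' DOAC, sites 55/33/2 (SVT/UEDVT/CVT), all comorbidity, thrombophilia,
#' antiplatelet and outcome counts as printed, and follow-up imaging in
#' 25 VKA / 15 DOAC patients (9 and 6 complete recanalizations).
#' Continuous values are deterministic plausible sequences; joint structure
#' beyond the per-arm margins is arbitrary. Intended as a fixture for the
#' descriptive-summary operations, not as patient data.
#'
#' @return a `usvt_cohort` of 90 records.
#' @export
reference_cohort <- function() {
  arm_block <- function(n, treatment, sites, female, comorb_counts, thromb, ap,
                        imaged, recan_complete, recurrence, bleed, death,
                        age_center, agents = NULL) {
    first_k <- function(k) c(rep(1L, k), rep(0L, n - k))
    df <- data.frame(
      age = round(age_center + seq(-20, 20, length.out = n), 1),
      sex = c(rep("female", female), rep("male", n - female)),
      usvt_site = rep(c("SVT", "UEDVT", "CVT"), times = sites),
      treatment = rep(treatment, n),
      doac_agent = if (is.null(agents)) rep(NA_character_, n) else
        rep(names(agents), times = agents),
      stringsAsFactors = FALSE
    )
    for (nm in names(comorb_counts)) {
      # rotate the 1-block per variable so flags are not all stacked on the
      # same patients
      k <- comorb_counts[[nm]]
      off <- (match(nm, names(comorb_counts)) * 7L) %% n
      df[[nm]] <- first_k(k)[((seq_len(n) - 1L + off) %% n) + 1L]
    }
    df$thrombophilia <- first_k(thromb)
    df$hemoglobin <- round(seq(10.5, 15.5, length.out = n), 1)
    df$platelets <- round(seq(150, 330, length.out = n))
    df$d_dimer <- round(seq(1500, 5200, length.out = n))
    df$ttr <- if (treatment == "VKA") round(seq(40, 85, length.out = n), 1) else NA_real_
    df$antiplatelet <- first_k(ap)
    df$follow_up <- round(seq(13, 55, length.out = n), 1)
    df$recanalization <- c(rep("complete", recan_complete),
                           rep("not_complete", imaged - recan_complete),
                           rep("missing", n - imaged))
    df$recurrence <- first_k(recurrence)
    df$major_bleed <- first_k(bleed)
    df$death <- first_k(death)
    df
  }
  vka <- arm_block(65, "VKA", sites = c(45, 20, 0), female = 33,
                   comorb_counts = c(hypertension = 39, diabetes = 21,
                                     dyslipidemia = 29, obesity = 10, smoker = 23,
                                     chf = 7, copd_asthma = 18, cerebrovascular = 8,
                                     ckd = 8, estrogen = 1, liver_disease = 22,
                                     active_cancer = 25, mps = 0),
                   thromb = 14, ap = 6, imaged = 25, recan_complete = 9,
                   recurrence = 5, bleed = 7, death = 39, age_center = 68.9)
  doac <- arm_block(25, "DOAC", sites = c(10, 13, 2), female = 16,
                    comorb_counts = c(hypertension = 9, diabetes = 5,
                                      dyslipidemia = 11, obesity = 8, smoker = 8,
                                      chf = 2, copd_asthma = 5, cerebrovascular = 3,
                                      ckd = 5, estrogen = 0, liver_disease = 3,
                                      active_cancer = 4, mps = 1),
                    thromb = 5, ap = 1, imaged = 15, recan_complete = 6,
                    recurrence = 2, bleed = 2, death = 5, age_center = 63.9,
                    agents = c(apixaban = 7, edoxaban = 7, rivaroxaban = 6,
                               dabigatran = 5))
  as_cohort(rbind(vka, doac), usvt_schema(), label = "reference (printed margins)")
}
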