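#' Declare one cohort variable
#'
#' A `variable_spec` describes a single column of a patient-level cohort
#' table: its measurement kind, the allowed categorical levels, units and
#' whether missing values are permitted.
#'
#' @param name variable identifier (unique within a schema).
#' @param kind one of `"continuous"`, `"binary"`, `"categorical"`.
#' @param levels ordered character vector of allowed labels; required for
#'   (and only for) categorical variables.
#' @param units free-text units (continuous variables).
#' @param missing_allowed may the column contain `NA`?
#' @return an object of class `variable_spec`.
#' @export
variable_spec <- function(name, kind = c("continuous", "binary", "categorical"),
                          levels = NULL, units = "", missing_allowed = FALSE) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) == 0) {
      stop("categorical variable '", name, "' needs non-empty levels", call. = FALSE)
    }
  } else if (!is.null(levels)) {
    stop("levels are only valid for categorical variables ('", name, "')", call. = FALSE)
  }
  structure(
    list(name = name, kind = kind, levels = levels,
         units = units, missing_allowed = isTRUE(missing_allowed)),
    class = "variable_spec"
  )
}

#' Build a schema from variable specs
#'
#' @param ... `variable_spec` objects.
#' @return a named list of class `cohort_schema`.
#' @export
cohort_schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1]]) && !inherits(specs[[1]], "variable_spec")) {
    specs <- specs[[1]]
  }
  stopifnot(all(vapply(specs, inherits, logical(1), "variable_spec")))
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate variable names in schema", call. = FALSE)
  names(specs) <- nms
  structure(specs, class = "cohort_schema")
}

# The comorbidity flags shared by the schema and the source generator.
comorbidity_names <- function() {
  c("hypertension", "diabetes", "dyslipidemia", "obesity", "smoker",
    "chf", "copd_asthma", "cerebrovascular", "ckd", "estrogen",
    "liver_disease", "active_cancer", "mps")
}

#' Default USVT cohort schema
#'
#' The patient data model used throughout the package: demographics,
#' thrombosis site (splanchnic / upper-extremity / cerebral), treatment arm
#' (VKA / DOAC and agent), comorbidity flags, thrombophilia, admission labs,
#' VKA time-in-therapeutic-range, antiplatelet co-medication, follow-up, and
#' the four study outcomes. Recanalization carries an explicit `"missing"`
#' level for patients without follow-up imaging; TTR is defined only for VKA
#' patients and the DOAC agent only for DOAC patients.
#'
#' @return a `cohort_schema`.
#' @export
usvt_schema <- function() {
  specs <- c(
    list(
      variable_spec("age", "continuous", units = "years"),
      variable_spec("sex", "categorical", levels = c("female", "male")),
      variable_spec("usvt_site", "categorical", levels = c("SVT", "UEDVT", "CVT")),
      variable_spec("treatment", "categorical", levels = c("VKA", "DOAC")),
      variable_spec("doac_agent", "categorical",
                    levels = c("apixaban", "edoxaban", "rivaroxaban", "dabigatran"),
                    missing_allowed = TRUE)
    ),
    lapply(comorbidity_names(), function(v) variable_spec(v, "binary")),
    list(
      variable_spec("thrombophilia", "binary"),
      variable_spec("hemoglobin", "continuous", units = "g/dL"),
      variable_spec("platelets", "continuous", units = "10^9/L"),
      variable_spec("d_dimer", "continuous", units = "ng/mL"),
      variable_spec("ttr", "continuous", units = "%", missing_allowed = TRUE),
      variable_spec("antiplatelet", "binary"),
      variable_spec("follow_up", "continuous", units = "months"),
      variable_spec("recanalization", "categorical",
                    levels = c("complete", "not_complete", "missing")),
      variable_spec("recurrence", "binary"),
      variable_spec("major_bleed", "binary"),
      variable_spec("death", "binary")
    )
  )
  cohort_schema(specs)
}

schema_kinds <- function(schema) {
  vapply(schema, `[[`, character(1), "kind")
}

#' Write a schema to YAML
#'
#' @param schema a `cohort_schema`.
#' @param path output file.
#' @export
write_schema <- function(schema, path) {
  out <- lapply(unclass(schema), function(s) {
    s[!vapply(s, is.null, logical(1))]
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a schema from YAML
#'
#' @param path YAML file written by [write_schema()].
#' @return a `cohort_schema`.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort_schema(lapply(raw, function(s) {
    variable_spec(s$name, s$kind, levels = unlist(s$levels),
                  units = s$units %||% "", missing_allowed = isTRUE(s$missing_allowed))
  }))
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat("<cohort_schema> ", length(x), " variables\n", sep = "")
  for (s in x) {
    cat(sprintf("  %-16s %-12s%s\n", s$name, s$kind,
                if (s$kind == "categorical") paste0("{", paste(s$levels, collapse = ", "), "}") else s$units))
  }
  invisible(x)
}
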