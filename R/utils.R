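#' @keywords internal
#' @importFrom ggplot2 .data
"_PACKAGE"

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a base seed
#'
#' Deterministic seed ladder used throughout the package: replica, scenario
#' and iteration seeds are all derived from a single master seed so that any
#' artifact can be reproduced from the manifest. The result always lies in
#' `[0, 2^31 - 2]`.
#'
#' @param base integer master seed.
#' @param k integer index (replica, scenario or iteration number).
#' @param salt optional extra integer to separate seed streams.
#' @return a single integer seed.
#' @export
derive_seed <- function(base, k = 0L, salt = 0L) {
  stopifnot(is.numeric(base), length(base) == 1L)
  as.integer((abs(base) * 48271 + k * 104729 + salt * 7919) %% 2147483647)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# round() in R uses banker's rounding; clinical tables round half away
# from zero (10.75 -> 10.8).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_p <- function(p) {
  ifelse(is.na(p), "-", ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}
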